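# Four-channel synaptic-puncta quantification: detection, gephyrin- and
# soma-proximity filtering, per-soma counting, and the innervation-bias
# ratio. All distances are in micrometres; puncta-puncta distances are
# centroid-to-centroid, puncta-soma distances are centroid-to-polygon
# boundary with interior points counting as distance 0.

## ---- polygon geometry (no polygon package in the dependency set) --------

# Distance from points (n x 2) to a segment (a, b), vectorized over points.
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Distance from points (n x 2) to the boundary of a closed polygon
# (vertex matrix, not repeated at the end).
point_polygon_boundary_distance <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  nv <- nrow(poly)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    d <- pmin(d, point_segment_distance(pts, poly[i, ], poly[j, ]))
  }
  d
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  nv <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Distance from points to a soma: 0 inside the contour, else boundary
# distance.
point_soma_distance <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  d <- point_polygon_boundary_distance(pts, poly)
  d[point_in_polygon(pts, poly)] <- 0
  d
}

#' Construct a soma contour
#'
#' @param vertices n x 2 matrix of polygon vertices (µm), unclosed.
#' @param marker_positive logical calbindin status.
#' @param soma_id integer id.
#' @param in_analysis include this soma when counting? Default `TRUE`.
#' @return List of class `soma_contour`.
#' @export
soma_contour <- function(vertices, marker_positive, soma_id,
                         in_analysis = TRUE) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop_ca1("polygon needs >= 3 vertices",
                                    class = "ca1quant_data_error")
  structure(list(vertices = vertices, marker_positive = marker_positive,
                 soma_id = as.integer(soma_id), in_analysis = in_analysis),
            class = "soma_contour")
}

#' Construct a puncta scene
#'
#' @param somas list of [soma_contour()] objects.
#' @param puncta named list of puncta tables per channel (e.g.
#'   `presynaptic`, `gephyrin`), each a data.frame with `x`, `y`,
#'   `diameter_um`.
#' @param pixel_size_um pixel size used when rasterizing. Default 0.04.
#' @param images optional named list of 2D channel images.
#' @return List of class `puncta_scene`.
#' @export
puncta_scene <- function(somas, puncta, pixel_size_um = 0.04,
                         images = NULL) {
  structure(list(somas = somas, puncta = puncta,
                 pixel_size_um = pixel_size_um, images = images),
            class = "puncta_scene")
}

#' Maximum-intensity projection of the first n slices
#'
#' @param stack 3D array (rows x cols x slices).
#' @param n_slices number of leading slices to project over.
#' @return 2D matrix of per-pixel maxima.
#' @export
max_intensity_projection <- function(stack, n_slices) {
  d <- dim(stack)
  if (length(d) != 3L) stop_ca1("stack must be a 3D array",
                                class = "ca1quant_shape_error")
  if (n_slices > d[3] || n_slices < 1L) {
    stop_ca1("n_slices (", n_slices, ") outside stack depth (", d[3], ")",
             class = "ca1quant_sizing_error")
  }
  apply(stack[, , seq_len(n_slices), drop = FALSE], c(1, 2), max)
}

# Laplacian-of-Gaussian kernel, sign-flipped so bright blobs respond
# positively, scale-normalized (sigma^2 * LoG).
log_kernel <- function(sigma_px) {
  half <- max(2L, ceiling(3 * sigma_px))
  ax <- (-half):half
  g <- outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma_px^2)))
  g <- g / sum(g)
  r2 <- outer(ax, ax, function(x, y) x^2 + y^2)
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * g
  k - mean(k)  # zero response to constant background
}

#' Detect fluorescent puncta by scale-matched blob detection
#'
#' Convolves the channel with a scale-normalized Laplacian-of-Gaussian
#' kernel matched to `expected_diameter_um` (`sigma = d / (2 sqrt 2)`),
#' takes local maxima of the response whose underlying intensity exceeds a
#' robust background threshold (`median + k_sd * 1.4826 mad` of the image by
#' default), and refines each centre to sub-pixel precision by an
#' intensity-weighted mean over the blob neighbourhood.
#'
#' @param img 2D image matrix (rows = y, cols = x).
#' @param pixel_size_um µm per pixel.
#' @param expected_diameter_um expected punctum diameter (default 0.25, the
#'   approximate gephyrin punctum size).
#' @param k_sd background-threshold multiplier. Default 4.
#' @return data.frame with `x`, `y` (µm, pixel centres at
#'   `(index - 0.5) * pixel_size`), `diameter_um`, `intensity`,
#'   `provenance = "detected"`. A blank (zero-variance) image returns an
#'   empty table with a warning.
#' @export
detect_puncta <- function(img, pixel_size_um, expected_diameter_um = 0.25,
                          k_sd = 4) {
  sigma_px <- expected_diameter_um / (2 * sqrt(2)) / pixel_size_um
  if (2 * sigma_px * sqrt(2) < 1) {
    stop_ca1("expected diameter below 2 pixels at this pixel size",
             class = "ca1quant_config_error")
  }
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      diameter_um = numeric(0), intensity = numeric(0),
                      provenance = character(0))
  if (stats::sd(img) == 0) {
    warning("blank or saturated image: no puncta detected")
    return(empty)
  }
  thr <- stats::median(img) + k_sd * stats::mad(img)
  resp <- EBImage::filter2(img, log_kernel(sigma_px))
  nr <- nrow(img); nc <- ncol(img)
  # strict local maxima of the LoG response in the 3x3 neighbourhood
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  m <- resp[inner_r, inner_c]
  is_max <- m > resp[inner_r - 1, inner_c] & m >= resp[inner_r + 1, inner_c] &
    m > resp[inner_r, inner_c - 1] & m >= resp[inner_r, inner_c + 1] &
    m > resp[inner_r - 1, inner_c - 1] & m >= resp[inner_r + 1, inner_c + 1] &
    m > resp[inner_r - 1, inner_c + 1] & m >= resp[inner_r + 1, inner_c - 1] &
    img[inner_r, inner_c] > thr & m > 0
  hits <- which(is_max, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  half <- max(1L, round(sigma_px))
  cent <- t(apply(hits, 1, function(h) {
    r0 <- h[1] + 1L; c0 <- h[2] + 1L  # back to full-image indices
    rr <- max(1L, r0 - half):min(nr, r0 + half)
    cc <- max(1L, c0 - half):min(nc, c0 + half)
    w <- pmax(img[rr, cc, drop = FALSE] - thr, 0)
    if (sum(w) == 0) w[] <- 1
    c(sum(outer(rr, rep(1, length(cc))) * w) / sum(w),
      sum(outer(rep(1, length(rr)), cc) * w) / sum(w),
      img[r0, c0])
  }))
  data.frame(x = (cent[, 2] - 0.5) * pixel_size_um,
             y = (cent[, 1] - 0.5) * pixel_size_um,
             diameter_um = expected_diameter_um,
             intensity = cent[, 3],
             provenance = "detected")
}

#' Filter gephyrin puncta by soma proximity
#'
#' Keeps puncta whose distance to the nearest soma contour is at most
#' `radius_um` (interior puncta count as distance 0).
#'
#' @param geph data.frame with `x`, `y`.
#' @param somas list of [soma_contour()] objects.
#' @param radius_um default 1.0.
#' @return The retained subset of `geph`.
#' @export
filter_gephyrin_by_soma <- function(geph, somas, radius_um = 1.0) {
  if (!length(somas)) stop_ca1("no somas supplied",
                               class = "ca1quant_precondition_error")
  if (!nrow(geph)) return(geph)
  pts <- cbind(geph$x, geph$y)
  d <- Reduce(pmin, lapply(somas, function(s)
    point_soma_distance(pts, s$vertices)))
  geph[d <= radius_um, , drop = FALSE]
}

#' Filter presynaptic puncta by gephyrin proximity
#'
#' Keeps presynaptic puncta with at least one retained gephyrin punctum
#' within `radius_um`, centroid to centroid.
#'
#' @param pre data.frame with `x`, `y`.
#' @param geph_kept gephyrin puncta surviving [filter_gephyrin_by_soma()].
#' @param radius_um default 1.0.
#' @return The retained subset of `pre`.
#' @export
filter_presyn_by_gephyrin <- function(pre, geph_kept, radius_um = 1.0) {
  if (!nrow(pre)) return(pre)
  if (!nrow(geph_kept)) return(pre[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(pre)), function(i) {
    any((pre$x[i] - geph_kept$x)^2 + (pre$y[i] - geph_kept$y)^2 <=
          radius_um^2)
  }, logical(1))
  pre[keep, , drop = FALSE]
}

#' Count filtered puncta on analysis somas
#'
#' Each surviving punctum is assigned to the nearest qualifying soma
#' (contour distance at most `radius_um`; interior = 0) among somas flagged
#' `in_analysis`, counted at most once; exact distance ties go to the lower
#' `soma_id`.
#'
#' @param pre_kept data.frame with `x`, `y` (filtered presynaptic puncta).
#' @param somas list of [soma_contour()] objects.
#' @param radius_um default 0.2.
#' @return data.frame: `soma_id`, `marker_positive`, `count`.
#' @export
count_on_somas <- function(pre_kept, somas, radius_um = 0.2) {
  somas <- Filter(function(s) s$in_analysis, somas)
  if (!length(somas)) stop_ca1("no somas flagged in_analysis",
                               class = "ca1quant_precondition_error")
  ids <- vapply(somas, `[[`, integer(1), "soma_id")
  ord <- order(ids)
  somas <- somas[ord]; ids <- ids[ord]
  counts <- stats::setNames(integer(length(somas)), ids)
  if (nrow(pre_kept)) {
    pts <- cbind(pre_kept$x, pre_kept$y)
    dmat <- vapply(somas, function(s) point_soma_distance(pts, s$vertices),
                   numeric(nrow(pts)))
    dmat <- matrix(dmat, nrow = nrow(pts))
    for (i in seq_len(nrow(pts))) {
      j <- which.min(dmat[i, ])  # first minimum = lowest soma_id on ties
      if (dmat[i, j] <= radius_um) counts[j] <- counts[j] + 1L
    }
  }
  data.frame(soma_id = ids,
             marker_positive = vapply(somas, `[[`, logical(1),
                                      "marker_positive"),
             count = as.integer(counts))
}

#' Innervation-bias ratio
#'
#' Summed counts on marker-positive somas divided by summed counts on
#' marker-negative somas. Values above one indicate a preference for the
#' marker-positive (calbindin-expressing) class.
#'
#' @param counts data.frame from [count_on_somas()].
#' @return List of class `bias_result`: `per_soma`, `total_pos`,
#'   `total_neg`, `bias_ratio`.
#' @export
innervation_bias <- function(counts) {
  total_pos <- sum(counts$count[counts$marker_positive])
  total_neg <- sum(counts$count[!counts$marker_positive])
  if (total_neg == 0) {
    stop_ca1("zero puncta on marker-negative somas: bias undefined",
             class = "ca1quant_undefined_ratio_error")
  }
  structure(list(per_soma = counts, total_pos = total_pos,
                 total_neg = total_neg,
                 bias_ratio = total_pos / total_neg),
            class = "bias_result")
}

#' Full puncta-quantification pipeline on a scene
#'
#' Applies the gephyrin soma-proximity filter, the presynaptic
#' gephyrin-proximity filter, per-soma counting, and the bias ratio.
#'
#' @param scene a [puncta_scene()] with `presynaptic` and `gephyrin`
#'   puncta tables.
#' @param geph_soma_radius_um default 1.0.
#' @param presyn_geph_radius_um default 1.0.
#' @param soma_count_radius_um default 0.2.
#' @return A `bias_result` with the intermediate tables attached as
#'   `geph_kept` and `pre_kept` attributes.
#' @export
quantify_scene <- function(scene, geph_soma_radius_um = 1.0,
                           presyn_geph_radius_um = 1.0,
                           soma_count_radius_um = 0.2) {
  stopifnot(inherits(scene, "puncta_scene"))
  gk <- filter_gephyrin_by_soma(scene$puncta$gephyrin, scene$somas,
                                geph_soma_radius_um)
  pk <- filter_presyn_by_gephyrin(scene$puncta$presynaptic, gk,
                                  presyn_geph_radius_um)
  counts <- count_on_somas(pk, scene$somas, soma_count_radius_um)
  res <- innervation_bias(counts)
  attr(res, "geph_kept") <- gk
  attr(res, "pre_kept") <- pk
  res
}
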