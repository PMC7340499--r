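# Somatic-position bookkeeping: the two depth conventions, normalized
# position histograms, per-band marker fractions, and birth-dating
# colocalization fractions.

#' Band regions of interest
#'
#' Deep and superficial bands given as depth intervals along the chosen
#' depth axis. Bands must be disjoint; for single-layer controls the layer
#' extent is split into two equal radial halves via [split_single_pcl()].
#'
#' @param deep,superficial length-2 numeric intervals (µm), `[lo, hi)`
#'   except that a cell exactly on a band boundary is assigned superficial
#'   (documented tie rule, applied in [assign_bands()]).
#' @param depth_field which depth convention the intervals refer to:
#'   `"depth_radial_um"` (default) or `"depth_pcl_um"`.
#' @return List of class `band_rois`.
#' @export
band_rois <- function(deep, superficial, depth_field = "depth_radial_um") {
  ov <- max(deep[1], superficial[1]) < min(deep[2], superficial[2])
  if (ov) stop_ca1("deep and superficial bands overlap",
                   class = "ca1quant_config_error")
  structure(list(deep = deep, superficial = superficial,
                 depth_field = depth_field),
            class = "band_rois")
}

#' Split a single principal cell layer into equal radial halves
#'
#' The control-tissue convention: one layer spanning `[lo, hi]` along the
#' radial axis is divided in half radially, the half nearer the alveus
#' being the deep band.
#'
#' @param extent length-2 interval (µm) covered by the single layer, on the
#'   radial-depth axis (0 = alveus border).
#' @return A [band_rois()] with two contiguous half-bands.
#' @export
split_single_pcl <- function(extent) {
  mid <- mean(extent)
  band_rois(deep = c(extent[1], mid), superficial = c(mid, extent[2]))
}

#' Assign cells to depth bands
#'
#' @param cells data.frame with the depth column named by the ROI's
#'   `depth_field`.
#' @param rois a [band_rois()].
#' @return `cells` with a `band` column in `{deep, superficial, none}`;
#'   a cell exactly on a shared boundary is superficial.
#' @export
assign_bands <- function(cells, rois) {
  d <- cells[[rois$depth_field]]
  if (is.null(d)) stop_ca1("cells lack depth column ", rois$depth_field,
                           class = "ca1quant_data_error")
  band <- rep("none", nrow(cells))
  band[d >= rois$deep[1] & d < rois$deep[2]] <- "deep"
  band[d >= rois$superficial[1] & d <= rois$superficial[2]] <- "superficial"
  cells$band <- band
  cells
}

#' Per-band marker fraction
#'
#' Marker-positive count divided by DAPI-identified count within each band.
#'
#' @param cells data.frame with logical columns `dapi` and the marker,
#'   plus the ROI depth column.
#' @param rois a [band_rois()].
#' @param marker marker column name, e.g. `"calbindin"`.
#' @return data.frame: `band`, `n_marker`, `n_dapi`, `fraction` (`NA` with
#'   a flag for an empty band).
#' @export
band_marker_fraction <- function(cells, rois, marker = "calbindin") {
  cells <- assign_bands(cells, rois)
  out <- lapply(c("deep", "superficial"), function(b) {
    sub <- cells[cells$band == b & cells$dapi, , drop = FALSE]
    n_dapi <- nrow(sub)
    n_mark <- sum(sub[[marker]])
    data.frame(band = b, n_marker = n_mark, n_dapi = n_dapi,
               fraction = if (n_dapi > 0) n_mark / n_dapi else NA_real_)
  })
  do.call(rbind, out)
}

#' Normalized soma-position histogram
#'
#' @param depths_um numeric depths.
#' @param bin_um bin width (> 0). Default 20.
#' @param normalize scale counts to unit sum? Default `TRUE`.
#' @return data.frame: `bin_lo_um`, `bin_hi_um`, `count`, `value` (count or
#'   normalized mass).
#' @export
position_histogram <- function(depths_um, bin_um = 20, normalize = TRUE) {
  if (bin_um <= 0) stop_ca1("bin_um must be > 0",
                            class = "ca1quant_config_error")
  breaks <- seq(0, bin_um * ceiling(max(depths_um, bin_um) / bin_um),
                by = bin_um)
  h <- hist(depths_um, breaks = breaks, plot = FALSE, right = FALSE)
  value <- if (normalize && sum(h$counts) > 0) h$counts / sum(h$counts)
           else h$counts
  data.frame(bin_lo_um = breaks[-length(breaks)], bin_hi_um = breaks[-1],
             count = h$counts, value = value)
}

#' Colocalization fraction of a marked population
#'
#' Fraction of marked (e.g. tamoxifen-birthdated) cells that co-stain for a
#' second marker: `|marked intersect costained| / |marked|`.
#'
#' @param marked ids of marked cells.
#' @param costained ids of co-stained cells.
#' @return Fraction in `[0, 1]`; `NA` with a warning when `marked` is empty.
#' @export
colocalization_fraction <- function(marked, costained) {
  if (!length(marked)) {
    warning("empty marked set: colocalization undefined")
    return(NA_real_)
  }
  length(intersect(marked, costained)) / length(unique(marked))
}

# Distance from points (n x 2) to a polyline given as a vertex matrix.
point_polyline_distance <- function(pts, polyline) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  if (nrow(polyline) == 1L) {
    return(sqrt((pts[, 1] - polyline[1, 1])^2 +
                (pts[, 2] - polyline[1, 2])^2))
  }
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(polyline) - 1L)) {
    d <- pmin(d, point_segment_distance(pts, polyline[i, ],
                                        polyline[i + 1L, ]))
  }
  d
}

#' Compute both somatic depth conventions from landmark polylines
#'
#' Depth is the distance to the nearest point on each landmark polyline:
#' `depth_pcl_um` from the superficial front of the principal cell layer,
#' `depth_radial_um` from the alveus/cortex border (toward radiatum). A
#' soma lying on the far side of a landmark from the other landmark draws a
#' negative-depth warning.
#'
#' @param cells data.frame with `x_um`, `y_um`.
#' @param pcl_front polyline vertex matrix (µm) for the PCL front.
#' @param alveus_border polyline vertex matrix (µm) for the alveus border.
#' @return `cells` with `depth_pcl_um` and `depth_radial_um` columns.
#' @export
depth_convert <- function(cells, pcl_front, alveus_border) {
  pts <- cbind(cells$x_um, cells$y_um)
  d_pcl <- point_polyline_distance(pts, pcl_front)
  d_rad <- point_polyline_distance(pts, alveus_border)
  gap <- point_polyline_distance(matrix(colMeans(alveus_border), ncol = 2),
                                 pcl_front)
  outside <- d_pcl > gap + 1e-9 | d_rad > gap + 1e-9
  if (any(outside)) {
    warning(sum(outside), " soma(s) lie beyond a landmark line ",
            "(negative-depth side)")
  }
  cells$depth_pcl_um <- d_pcl
  cells$depth_radial_um <- d_rad
  cells
}
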