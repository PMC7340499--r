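# Supervised k-means (k = 2) on morphological indices, PCA + k-means on
# intrinsic physiology, elbow diagnostics, nearest-centre assignment of new
# cells, and morphology-physiology concordance.

#' Build a feature matrix for clustering
#'
#' Rows with any missing feature are dropped (their ids are recorded), since
#' k-means and PCA require complete cases.
#'
#' @param df data.frame of numeric features, or a numeric matrix.
#' @param id_col optional column name holding cell ids; otherwise rownames
#'   (or row numbers) are used.
#' @param standardize z-score each column? Default `FALSE`; [zscore_pca()]
#'   and physiological clustering standardize internally.
#' @return A numeric matrix with rownames = cell ids and attributes
#'   `dropped` (ids of incomplete rows), `center`, `scale` (per-column
#'   standardization record when `standardize = TRUE`).
#' @export
feature_matrix <- function(df, id_col = NULL, standardize = FALSE) {
  df <- as.data.frame(df)
  if (!is.null(id_col)) {
    ids <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  } else {
    ids <- rownames(df)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ok <- stats::complete.cases(m)
  dropped <- ids[!ok]
  m <- m[ok, , drop = FALSE]
  ctr <- scl <- NULL
  if (standardize) {
    ctr <- colMeans(m)
    scl <- apply(m, 2, stats::sd)
    if (any(scl == 0)) {
      stop_ca1("zero-variance column: ",
               paste(colnames(m)[scl == 0], collapse = ", "),
               class = "ca1quant_config_error")
    }
    m <- scale(m, center = ctr, scale = scl)
    attributes(m)[c("scaled:center", "scaled:scale")] <- NULL
  }
  structure(m, dropped = dropped, center = ctr, scale = scl)
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then
# each subsequent centre drawn with probability proportional to the squared
# distance to the nearest centre chosen so far.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1, ] <- x[i, ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  if (k > 1L) for (j in 2:k) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

run_lloyd <- function(x, centers) {
  # Guard against empty clusters from duplicate seed points.
  centers <- centers[!duplicated(round(centers, 12)), , drop = FALSE]
  suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
}

#' Seeded k-means clustering (k-means++, best of restarts)
#'
#' Lloyd's algorithm (via `stats::kmeans`) started from k-means++ seeds,
#' keeping the best of `n_init` restarts by within-cluster sum of squares.
#' Deterministic given `seed`. Cluster indices are fixed post hoc by centre
#' ordering, never by initialization: cluster 1 is the cluster whose centre
#' has the greatest coordinate sum (for the (LRI, ORI) plane this is the
#' *complex* cluster), and so on in decreasing order.
#'
#' @param features numeric matrix (see [feature_matrix()]).
#' @param k number of clusters (`1 <= k <= nrow`).
#' @param seed integer seed.
#' @param n_init number of k-means++ restarts. Default 50.
#' @return List of class `cluster_result`: `labels` (named integer vector),
#'   `centers`, `wss` (total within-cluster sum of squares), `k`, `seed`,
#'   `n_init`.
#' @export
km_cluster <- function(features, k, seed = 1L, n_init = 50L) {
  x <- as.matrix(features)
  if (k < 1L) stop_ca1("k must be >= 1", class = "ca1quant_sizing_error")
  if (nrow(x) < k) {
    stop_ca1("fewer rows (", nrow(x), ") than clusters (", k, ")",
             class = "ca1quant_sizing_error")
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      f <- run_lloyd(x, kmeanspp_init(x, k))
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  ord <- order(-rowSums(fit$centers), seq_len(nrow(fit$centers)))
  relabel <- match(seq_len(nrow(fit$centers)), ord)
  labels <- relabel[fit$cluster]
  names(labels) <- rownames(x)
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(nrow(centers))
  structure(list(labels = labels, centers = centers,
                 wss = fit$tot.withinss, k = nrow(centers),
                 seed = seed, n_init = n_init),
            class = "cluster_result")
}

#' Elbow diagnostic: within-cluster sum of squares over k
#'
#' For each `k` in `1..k_max` runs [km_cluster()]; additionally evaluates a
#' candidate derived from the `k-1` solution (its centres plus the point
#' farthest from its assigned centre) so the reported curve is non-increasing
#' in `k`.
#'
#' @param features numeric matrix.
#' @param k_max largest k (>= 2).
#' @param seed integer seed.
#' @param n_init restarts per k.
#' @return data.frame with columns `k`, `wss`.
#' @export
elbow_wss <- function(features, k_max, seed = 1L, n_init = 50L) {
  x <- as.matrix(features)
  if (k_max < 2L) stop_ca1("k_max must be >= 2",
                           class = "ca1quant_sizing_error")
  wss <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    fit <- km_cluster(x, k, seed = derive_seed(seed, k), n_init = n_init)
    wss_k <- fit$wss
    if (!is.null(prev) && prev$wss > 0) {
      d2 <- rowSums((x - prev$centers[prev$labels, , drop = FALSE])^2)
      cand <- rbind(prev$centers, x[which.max(d2), ])
      f2 <- run_lloyd(x, cand)
      if (f2$tot.withinss < wss_k) {
        wss_k <- f2$tot.withinss
        fit$wss <- wss_k
        fit$centers <- f2$centers
        fit$labels <- f2$cluster
      }
    }
    wss[k] <- if (is.null(prev)) wss_k else min(wss_k, prev$wss)
    fit$wss <- wss[k]
    prev <- fit
  }
  data.frame(k = seq_len(k_max), wss = wss)
}

#' Z-score + principal component scores of a feature table
#'
#' Columns are z-scored (zero-variance columns are removed with a warning),
#' then projected on the top `n_components` eigenvectors of the correlation
#' structure. Component signs follow the convention that each loading
#' vector's largest-magnitude entry is positive.
#'
#' @param features numeric matrix or data.frame; incomplete rows are dropped.
#' @param n_components number of components to keep. Default 2.
#' @return Score matrix (rows = cells, cols = `PC1..`) with attributes
#'   `loadings`, `var_explained`, `dropped` (ids of incomplete rows),
#'   `removed_columns`.
#' @export
zscore_pca <- function(features, n_components = 2L) {
  m <- feature_matrix(features)
  dropped <- attr(m, "dropped")
  v <- apply(m, 2, stats::sd)
  removed <- colnames(m)[v == 0]
  if (length(removed)) {
    warning("removing zero-variance column(s): ",
            paste(removed, collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  n_components <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)),
                 function(j) sign(rot[which.max(abs(rot[, j])), j]),
                 numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- scale(m) %*% rot
  attributes(scores)[c("scaled:center", "scaled:scale")] <- NULL
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(scores, loadings = rot,
            var_explained = p$sdev^2 / sum(p$sdev^2),
            dropped = dropped, removed_columns = removed)
}

#' Assign new cells to an existing clustering
#'
#' Nearest-centre assignment in the reference's feature space; exact
#' distance ties go to the lower cluster index.
#'
#' @param points numeric matrix (or vector for one cell) with the same
#'   feature dimensionality as the reference centres.
#' @param reference a `cluster_result` from [km_cluster()].
#' @return Integer vector of cluster labels.
#' @export
assign_new <- function(points, reference) {
  stopifnot(inherits(reference, "cluster_result"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != ncol(reference$centers)) {
    stop_ca1("points have ", ncol(points), " features; reference has ",
             ncol(reference$centers), class = "ca1quant_shape_error")
  }
  d2 <- vapply(seq_len(nrow(reference$centers)), function(j) {
    rowSums(sweep(points, 2, reference$centers[j, ])^2)
  }, numeric(nrow(points)))
  d2 <- matrix(d2, nrow = nrow(points))
  apply(d2, 1, which.min)  # which.min takes the first (lowest) index on ties
}

#' Concordance between two label sets over the same cells
#'
#' Builds the contingency table, pairs cluster indices by majority matching
#' (the pairing of `b`-labels to `a`-labels maximizing the matched count),
#' and reports the agreement fraction under that pairing.
#'
#' @param labels_a,labels_b named vectors of cluster labels over identical
#'   cell ids (order-insensitive when named).
#' @return List: `table` (contingency, a rows x b columns), `pairing`
#'   (named vector mapping b-levels to a-levels), `agreement` in `[0,1]`.
#' @export
concordance <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    miss <- c(setdiff(names(labels_a), names(labels_b)),
              setdiff(names(labels_b), names(labels_a)))
    if (length(miss)) {
      stop_ca1("cell ids missing from one label set: ",
               paste(unique(miss), collapse = ", "),
               class = "ca1quant_join_error")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop_ca1("label sets differ in length", class = "ca1quant_join_error")
  }
  tab <- table(a = labels_a, b = labels_b)
  a_lev <- rownames(tab); b_lev <- colnames(tab)
  # Exhaustive search over assignments of b-levels to a-levels (k is tiny).
  k <- min(length(a_lev), length(b_lev))
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- NULL; best_n <- -1
  for (p in perms(seq_along(b_lev))) {
    n_match <- sum(vapply(seq_len(k), function(i) tab[i, p[i]], numeric(1)))
    if (n_match > best_n) { best_n <- n_match; best <- p }
  }
  pairing <- stats::setNames(a_lev[seq_len(k)], b_lev[best[seq_len(k)]])
  list(table = tab, pairing = pairing,
       agreement = best_n / length(labels_a))
}
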