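# Apical-tree morphometrics: compartment extraction, branch-based indices
# (LRI/ORI), first-prominent-bifurcation distance, and Sholl profiles.

#' Extract one compartment of a morphology as a rooted dendritic tree
#'
#' Returns the subtree of `neuron` restricted to one compartment class,
#' rooted at the stem node (the compartment node whose parent lies outside
#' the compartment) nearest the soma. Cumulative path distances from the
#' soma are computed by summing 3D segment lengths, including the segment
#' that attaches the stem to its (somatic) parent.
#'
#' @param neuron a [neuron_morphology].
#' @param compartment compartment class to extract; default `"apical"`.
#' @return A `dendritic_tree`: data.frame with columns `id`, `parent`
#'   (`NA` at the stem), `x`, `y`, `z`, `edge_len` (µm, from parent),
#'   `cum_dist` (µm path distance from soma), `n_children`, in topological
#'   order; attributes `soma_centroid` and `compartment`.
#' @export
extract_apical <- function(neuron, compartment = "apical") {
  stopifnot(inherits(neuron, "neuron_morphology"))
  in_comp <- neuron$compartment == compartment
  if (!any(in_comp)) {
    stop_ca1("morphology has no '", compartment, "' nodes",
             class = "ca1quant_empty_compartment_error")
  }
  soma <- attr(neuron, "soma_centroid")
  parent_comp <- neuron$compartment[neuron$parent]
  is_stem <- in_comp & (is.na(neuron$parent) | parent_comp != compartment)
  stems <- which(is_stem)
  d_soma <- sqrt((neuron$x[stems] - soma[1])^2 +
                 (neuron$y[stems] - soma[2])^2 +
                 (neuron$z[stems] - soma[3])^2)
  stem <- stems[which.min(d_soma)]

  # Descendants of the stem staying inside the compartment.
  n <- nrow(neuron)
  keep <- logical(n)
  keep[stem] <- TRUE
  for (i in seq_len(n)) {  # topological order guarantees parents first
    p <- neuron$parent[i]
    if (!keep[i] && !is.na(p) && keep[p] && in_comp[i]) keep[i] <- TRUE
  }
  sub <- neuron[keep, c("id", "parent", "x", "y", "z"), drop = FALSE]
  rownames(sub) <- NULL

  # Attach point: the stem's parent position if it has one, else the soma
  # centroid; the stem edge length is measured from there.
  p_stem <- neuron$parent[stem]
  attach <- if (is.na(p_stem)) soma else
    c(neuron$x[p_stem], neuron$y[p_stem], neuron$z[p_stem])

  idx <- match(sub$parent, sub$id)
  px <- ifelse(is.na(idx), attach[1], sub$x[idx])
  py <- ifelse(is.na(idx), attach[2], sub$y[idx])
  pz <- ifelse(is.na(idx), attach[3], sub$z[idx])
  sub$edge_len <- sqrt((sub$x - px)^2 + (sub$y - py)^2 + (sub$z - pz)^2)
  sub$parent <- idx  # local indices; NA for the stem
  sub$id <- seq_len(nrow(sub))

  cum <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    p <- sub$parent[i]
    cum[i] <- sub$edge_len[i] + if (is.na(p)) 0 else cum[p]
  }
  sub$cum_dist <- cum
  sub$n_children <- tabulate(sub$parent[!is.na(sub$parent)], nbins = nrow(sub))
  structure(sub,
            soma_centroid = soma,
            compartment = compartment,
            class = c("dendritic_tree", "data.frame"))
}

#' Total cable length of a dendritic tree
#' @param tree a `dendritic_tree`.
#' @return Sum of all segment lengths (µm), including the soma-attachment
#'   segment.
#' @export
tree_total_length <- function(tree) sum(tree$edge_len)

#' Number of bifurcation nodes (out-degree >= 2)
#' @param tree a `dendritic_tree`.
#' @export
tree_bifurcation_count <- function(tree) sum(tree$n_children >= 2L)

# Per-node total subtree cable length (edge from the parent included),
# computed in reverse topological order.
subtree_lengths <- function(tree) {
  n <- nrow(tree)
  sub <- tree$edge_len
  for (i in rev(seq_len(n))) {
    p <- tree$parent[i]
    if (!is.na(p)) sub[p] <- sub[p] + sub[i]
  }
  sub
}

# Per-node count of bifurcations within the node's subtree (node included).
subtree_bif_counts <- function(tree) {
  n <- nrow(tree)
  cnt <- as.integer(tree$n_children >= 2L)
  for (i in rev(seq_len(n))) {
    p <- tree$parent[i]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

children_list <- function(tree) {
  split(seq_len(nrow(tree)),
        factor(tree$parent, levels = seq_len(nrow(tree))))
}

#' First prominent bifurcation along the primary apical path
#'
#' Walks the primary path from the stem (at each branch point following the
#' daughter with the greater total subtree length; ties broken by lower node
#' id). At each bifurcation the smaller daughter's share of the remaining
#' cable length distal to the node is computed; the first node where that
#' share reaches `prominence_frac` is the first *prominent* bifurcation —
#' small twigs are skipped. If no bifurcation qualifies, the distal-most
#' bifurcation on the primary path is returned with `prominent = FALSE`; an
#' unbranched tree returns its full extent with `n_bifurcations = 0`.
#'
#' @param tree a `dendritic_tree`.
#' @param prominence_frac minimum share, in `(0, 0.5]`, of the remaining
#'   cable length that the smaller daughter subtree must carry. Default 0.2.
#' @return List with `node` (row index or `NA`), `distance_um` (path
#'   distance from soma), `prominent` (logical), `n_skipped` (non-prominent
#'   bifurcations passed before the selected node).
#' @export
first_prominent_bifurcation <- function(tree, prominence_frac = 0.2) {
  stopifnot(inherits(tree, "dendritic_tree"))
  if (prominence_frac <= 0 || prominence_frac > 0.5) {
    stop_ca1("prominence_frac must lie in (0, 0.5]",
             class = "ca1quant_config_error")
  }
  sub_len <- subtree_lengths(tree)
  kids <- children_list(tree)
  node <- which(is.na(tree$parent))  # stem
  last_bif <- NA_integer_
  n_skipped <- 0L
  repeat {
    ch <- kids[[node]]
    if (length(ch) >= 2L) {
      shares <- sub_len[ch] / sum(sub_len[ch])
      if (min(shares) >= prominence_frac) {
        return(list(node = node, distance_um = tree$cum_dist[node],
                    prominent = TRUE, n_skipped = n_skipped))
      }
      last_bif <- node
      n_skipped <- n_skipped + 1L
    }
    if (length(ch) == 0L) break
    best <- ch[order(-sub_len[ch], ch)][1]  # longer daughter, tie: lower id
    node <- best
  }
  if (is.na(last_bif)) {
    list(node = NA_integer_, distance_um = tree$cum_dist[node],
         prominent = FALSE, n_skipped = 0L)
  } else {
    list(node = last_bif, distance_um = tree$cum_dist[last_bif],
         prominent = FALSE, n_skipped = n_skipped - 1L)
  }
}

#' Configuration for the branch-structure indices
#'
#' @param prominence_frac passed to [first_prominent_bifurcation()].
#' @param d0_um distant-node threshold D0 (µm): when the selected node lies
#'   farther than `d0_um` along the path from the soma, both indices are
#'   scaled by `d0_um / Lp`. Default 150.
#' @return A list of class `index_config`.
#' @export
index_config <- function(prominence_frac = 0.2, d0_um = 150) {
  structure(list(prominence_frac = prominence_frac, d0_um = d0_um),
            class = "index_config")
}

#' Length-ratio and node-ratio indices of an apical tree
#'
#' At the selected node (from [first_prominent_bifurcation()]) with
#' soma-to-node path length `Lp`, daughter subtree cable lengths `Ld1, Ld2`
#' (the two longest daughters) and daughter-subtree bifurcation counts
#' `Nd1, Nd2`:
#' \deqn{LRI = \ln((L_{d1}+L_{d2})/L_p)}
#' \deqn{ORI = \ln((N_{d1}+N_{d2}+2)/(N_p+1))}
#' where `Np` is the number of non-prominent bifurcations skipped proximal
#' to the node. When `Lp > D0` both indices are multiplied by `D0/Lp` (the
#' distant-node modification). Complex cells score high on both axes.
#' These formulas are the documented defaults; pass a different
#' `index_fun` to swap in an alternative definition with the same call
#' signature.
#'
#' @param tree a `dendritic_tree`.
#' @param cfg an [index_config()].
#' @param index_fun optional replacement `function(Lp, Ld, Nd, Np)` returning
#'   `c(lri, ori)` before the distant-node scaling.
#' @return List of class `morpho_features`: `lri`, `ori`, `defined`
#'   (FALSE for unbranched trees), `first_bifurcation_um`,
#'   `selected_node_distance_um`, `total_apical_length_um`,
#'   `bifurcation_count`, `distant_scaled`.
#' @export
lri_ori <- function(tree, cfg = index_config(), index_fun = NULL) {
  stopifnot(inherits(tree, "dendritic_tree"))
  fb <- first_prominent_bifurcation(tree, cfg$prominence_frac)
  total_len <- tree_total_length(tree)
  n_bif <- tree_bifurcation_count(tree)
  base <- list(
    lri = NA_real_, ori = NA_real_, defined = FALSE,
    first_bifurcation_um = fb$distance_um,
    selected_node_distance_um = fb$distance_um,
    total_apical_length_um = total_len,
    bifurcation_count = n_bif,
    distant_scaled = FALSE
  )
  if (is.na(fb$node)) {
    return(structure(base, class = "morpho_features"))
  }
  sub_len <- subtree_lengths(tree)
  sub_bif <- subtree_bif_counts(tree)
  ch <- children_list(tree)[[fb$node]]
  ch <- ch[order(-sub_len[ch], ch)][1:2]
  Lp <- tree$cum_dist[fb$node]
  Ld <- sub_len[ch]
  Nd <- sub_bif[ch]
  Np <- fb$n_skipped
  vals <- if (is.null(index_fun)) {
    c(log(sum(Ld) / Lp), log((sum(Nd) + 2) / (Np + 1)))
  } else {
    index_fun(Lp, Ld, Nd, Np)
  }
  scaled <- Lp > cfg$d0_um
  if (scaled) vals <- vals * cfg$d0_um / Lp
  base$lri <- vals[1]
  base$ori <- vals[2]
  base$defined <- TRUE
  base$distant_scaled <- scaled
  structure(base, class = "morpho_features")
}

#' Sholl profile of a dendritic tree
#'
#' Counts crossings of concentric spheres centred on the soma centroid at
#' uniform radial steps. A segment contributes one crossing to every radius
#' lying strictly between its endpoints' radial distances (lower end
#' exclusive, upper end inclusive), i.e. the radial distance is linearly
#' interpolated along each segment.
#'
#' @param tree a `dendritic_tree`.
#' @param step_um radius step in µm (> 0). Default 20.
#' @return List of class `sholl_profile`: `radii`, `intersections`,
#'   `peak_count`, `peak_radius_um`.
#' @export
sholl <- function(tree, step_um = 20) {
  stopifnot(inherits(tree, "dendritic_tree"))
  if (step_um <= 0) stop_ca1("step_um must be > 0",
                             class = "ca1quant_config_error")
  soma <- attr(tree, "soma_centroid")
  r_node <- sqrt((tree$x - soma[1])^2 + (tree$y - soma[2])^2 +
                 (tree$z - soma[3])^2)
  idx <- tree$parent
  r_par <- ifelse(is.na(idx), 0, r_node[idx])
  r_max <- max(r_node, 0)
  radii <- seq(step_um, by = step_um,
               length.out = max(1L, ceiling(r_max / step_um) + 1L))
  lo <- pmin(r_par, r_node)
  hi <- pmax(r_par, r_node)
  counts <- vapply(radii, function(r) sum(lo < r & r <= hi), integer(1))
  peak <- which.max(counts)
  structure(list(radii = radii, intersections = counts,
                 peak_count = counts[peak], peak_radius_um = radii[peak]),
            class = "sholl_profile")
}

#' Per-cell morphometric feature table for a cohort
#'
#' Convenience wrapper applying [extract_apical()], [lri_ori()] and
#' [first_prominent_bifurcation()] to a list of morphologies.
#'
#' @param neurons named list of [neuron_morphology] objects.
#' @param cfg an [index_config()].
#' @return data.frame with one row per cell: `cell_id`, `lri`, `ori`,
#'   `first_bif_um`, `total_apical_length_um`, `bifurcation_count`,
#'   `defined`.
#' @export
morpho_feature_table <- function(neurons, cfg = index_config()) {
  ids <- names(neurons)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_along(neurons))
  rows <- lapply(seq_along(neurons), function(i) {
    tr <- extract_apical(neurons[[i]])
    f <- lri_ori(tr, cfg)
    data.frame(cell_id = ids[i], lri = f$lri, ori = f$ori,
               first_bif_um = f$first_bifurcation_um,
               total_apical_length_um = f$total_apical_length_um,
               bifurcation_count = f$bifurcation_count,
               defined = f$defined)
  })
  do.call(rbind, rows)
}
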