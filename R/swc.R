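# SWC ingest/egress and the validated NeuronMorphology container.

SWC_TYPES <- c("other", "soma", "axon", "basal", "apical")

swc_code_to_compartment <- function(code) {
  out <- rep("other", length(code))
  out[code == 1] <- "soma"
  out[code == 2] <- "axon"
  out[code == 3] <- "basal"
  out[code == 4] <- "apical"
  out
}

compartment_to_swc_code <- function(comp) {
  codes <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L, other = 5L)
  unname(codes[comp])
}

#' Construct a validated neuron morphology
#'
#' A `neuron_morphology` is a rooted tree of 3D sample points in micrometres,
#' each labelled with a compartment class (`soma`, `apical`, `basal`, `axon`,
#' `other`). Nodes are re-indexed so ids are contiguous and every non-root
#' node's parent precedes it (topological order), which downstream code
#' relies on.
#'
#' @param nodes data.frame with columns `id`, `parent` (`NA` for the root),
#'   `x`, `y`, `z`, `radius`, `compartment`.
#' @param metadata optional named list of free-form tags (genotype, slice id).
#' @return An object of class `neuron_morphology`: the node table (in
#'   topological order, ids remapped to `1..n`), plus `soma_centroid` and
#'   `metadata` attributes.
#' @export
neuron_morphology <- function(nodes, metadata = list()) {
  required <- c("id", "parent", "x", "y", "z", "radius", "compartment")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    stop_ca1("missing node columns: ", paste(missing_cols, collapse = ", "),
             class = "ca1quant_structure_error")
  }
  nodes <- as.data.frame(nodes)[required]
  num_cols <- c("x", "y", "z", "radius")
  if (!all(vapply(nodes[num_cols], is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(nodes[num_cols])))) {
    stop_ca1("non-finite or non-numeric coordinates",
             class = "ca1quant_structure_error")
  }
  if (anyDuplicated(nodes$id)) {
    stop_ca1("duplicate node id: ", nodes$id[duplicated(nodes$id)][1],
             class = "ca1quant_structure_error")
  }
  if (!any(nodes$compartment == "soma")) {
    stop_ca1("morphology has no soma node", class = "ca1quant_structure_error")
  }
  roots <- which(is.na(nodes$parent))
  if (length(roots) != 1L) {
    stop_ca1("expected exactly one root node, found ", length(roots),
             class = "ca1quant_structure_error")
  }
  idx <- match(nodes$parent, nodes$id)
  orphan <- which(!is.na(nodes$parent) & is.na(idx))
  if (length(orphan)) {
    stop_ca1("node ", nodes$id[orphan[1]], " references absent parent ",
             nodes$parent[orphan[1]], class = "ca1quant_structure_error")
  }

  # Topological order via BFS from the root; any node not reached sits on a
  # cycle or a disconnected component.
  n <- nrow(nodes)
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  order <- integer(n)
  order[1] <- roots
  head <- 1L; tail <- 1L
  while (head <= tail && tail < n) {
    kids <- children[[order[head]]]
    if (length(kids)) {
      order[(tail + 1L):(tail + length(kids))] <- kids
      tail <- tail + length(kids)
    }
    head <- head + 1L
  }
  if (tail < n || any(order == 0L)) {
    bad <- setdiff(seq_len(n), order)
    stop_ca1("cycle or disconnected subtree involving node id ",
             nodes$id[bad[1]], class = "ca1quant_structure_error")
  }
  nodes <- nodes[order, , drop = FALSE]
  remap <- seq_len(n)
  names(remap) <- as.character(nodes$id)
  nodes$id <- remap
  nodes$parent <- ifelse(is.na(nodes$parent), NA_integer_,
                         remap[as.character(nodes$parent)])
  rownames(nodes) <- NULL

  soma <- nodes[nodes$compartment == "soma", c("x", "y", "z")]
  structure(nodes,
            soma_centroid = colMeans(soma),
            metadata = metadata,
            class = c("neuron_morphology", "data.frame"))
}

#' Read a neuron reconstruction from an SWC file
#'
#' Parses the standard 7-column SWC encoding (`id type x y z radius parent`,
#' `#` comments, parent `-1` for the root), validates tree structure, and
#' remaps ids to be contiguous. Coordinates are taken to be micrometres.
#'
#' @param path path to an SWC file.
#' @return A [neuron_morphology].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) {
    stop_ca1("file not found: ", path, class = "ca1quant_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (!length(data_lines)) {
    stop_ca1("no SWC records in ", path, class = "ca1quant_parse_error")
  }
  fields <- strsplit(trimws(data_lines), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop_ca1("line ", line_no[bad[1]], ": expected 7 fields, found ",
             lengths(fields)[bad[1]], class = "ca1quant_parse_error")
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  nn <- which(apply(is.na(mat), 1, any))
  if (length(nn)) {
    stop_ca1("line ", line_no[nn[1]], ": non-numeric field",
             class = "ca1quant_parse_error")
  }
  nodes <- data.frame(
    id = as.integer(mat[, 1]),
    parent = ifelse(mat[, 7] < 0, NA_integer_, as.integer(mat[, 7])),
    x = mat[, 3], y = mat[, 4], z = mat[, 5],
    radius = mat[, 6],
    compartment = swc_code_to_compartment(as.integer(mat[, 2]))
  )
  neuron_morphology(nodes, metadata = list(source = path))
}

#' Write a neuron morphology to an SWC file
#'
#' @param neuron a [neuron_morphology].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(neuron, path) {
  stopifnot(inherits(neuron, "neuron_morphology"))
  rec <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                 neuron$id, compartment_to_swc_code(neuron$compartment),
                 neuron$x, neuron$y, neuron$z, neuron$radius,
                 ifelse(is.na(neuron$parent), -1L, neuron$parent))
  writeLines(c("# SWC exported by ca1quant", rec), path)
  invisible(path)
}

#' @export
print.neuron_morphology <- function(x, ...) {
  tab <- table(x$compartment)
  cat("<neuron_morphology> ", nrow(x), " nodes (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
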