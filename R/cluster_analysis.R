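# Nucleated-cluster node pack: neighbour lists (cell list under the
# minimum-image convention), connected-component grouping, largest-cluster
# masks, recurrent cluster tracking and colour graduation. All distance
# criteria are closed (<= cutoff) and all ties break toward the smallest
# index or id, so results are deterministic.

#' Neighbour list within a cutoff (cell-list implementation)
#'
#' An atom j is a neighbour of i iff the minimum-image distance is `<=
#' cutoff` (closed criterion) and `j != i`. Implemented with a spatial cell
#' list; on periodic axes the cutoff may not exceed half the box length
#' (minimum-image validity).
#'
#' @param positions n x 3 numeric matrix, angstrom.
#' @param box An [md_box()].
#' @param cutoff Positive cutoff distance, angstrom.
#' @return A list of class `neighbor_list`: `neighbors` (per-atom sorted
#'   integer vectors), `counts`, `edges` (m x 2 matrix, i < j) and `cutoff`.
#' @export
list_neighbors <- function(positions, box, cutoff) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  for (k in 1:3)
    if (box$periodic[k] && cutoff > box$lengths[k] / 2)
      stop(sprintf("cutoff %g exceeds half the box length on periodic axis %d",
                   cutoff, k))
  # cell geometry per axis: periodic axes span the box, open axes the extent
  origin <- numeric(3); span <- numeric(3); ncell <- integer(3)
  for (k in 1:3) {
    if (box$periodic[k]) {
      origin[k] <- 0
      span[k] <- box$lengths[k]
      positions[, k] <- positions[, k] - span[k] * floor(positions[, k] / span[k])
    } else {
      origin[k] <- min(positions[, k])
      span[k] <- max(positions[, k]) - origin[k] + 1e-9
    }
    ncell[k] <- max(1L, floor(span[k] / cutoff))
  }
  csize <- span / ncell
  ci <- sapply(1:3, function(k)
    pmin(ncell[k] - 1L, pmax(0L, floor((positions[, k] - origin[k]) / csize[k]))))
  ci <- matrix(as.integer(ci), ncol = 3L)
  cell_id <- ci[, 1L] + ncell[1L] * (ci[, 2L] + ncell[2L] * ci[, 3L])
  members <- split(seq_len(n), cell_id)
  # neighbouring cell ids for each occupied cell
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr_cells <- function(c3) {
    cand <- sweep(offsets, 2L, c3, "+")
    keep <- rep(TRUE, nrow(cand))
    for (k in 1:3) {
      if (box$periodic[k]) cand[, k] <- cand[, k] %% ncell[k]
      else keep <- keep & cand[, k] >= 0L & cand[, k] < ncell[k]
    }
    cand <- cand[keep, , drop = FALSE]
    unique(cand[, 1L] + ncell[1L] * (cand[, 2L] + ncell[2L] * cand[, 3L]))
  }
  neighbors <- vector("list", n)
  occupied <- unique(cell_id)
  cand_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- as.character(cell_id[i])
    cand <- cand_cache[[key]]
    if (is.null(cand)) {
      cells <- nbr_cells(ci[i, ])
      cand <- unlist(members[as.character(cells[cells %in% occupied])],
                     use.names = FALSE)
      cand_cache[[key]] <- cand
    }
    js <- cand[cand != i]
    if (length(js)) {
      d <- disp_to_all(positions[i, ], positions[js, , drop = FALSE], box)
      js <- js[rowSums(d * d) <= cutoff^2]
    }
    neighbors[[i]] <- sort(unique(js))
  }
  counts <- lengths(neighbors)
  ii <- rep(seq_len(n), counts)
  jj <- unlist(neighbors, use.names = FALSE)
  edges <- if (length(ii)) {
    e <- cbind(ii, jj)[ii < jj, , drop = FALSE]
    colnames(e) <- NULL
    e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  } else matrix(integer(0), 0L, 2L)
  structure(list(neighbors = neighbors, counts = counts,
                 edges = edges, cutoff = cutoff),
            class = "neighbor_list")
}

#' Connected-component group labels
#'
#' Labels the connected components of the neighbour graph. Group ids are
#' consecutive `1..k`, assigned in order of each component's smallest atom
#' index.
#'
#' @param n_atoms Number of atoms.
#' @param edges m x 2 integer matrix of undirected edges (or a
#'   `neighbor_list`).
#' @return Integer per-atom group id vector.
#' @export
group_list <- function(n_atoms, edges) {
  if (inherits(n_atoms, "neighbor_list")) {
    edges <- n_atoms$edges
    n_atoms <- length(n_atoms$neighbors)
  }
  if (NROW(edges)) edges <- matrix(as.integer(edges), ncol = 2L)
  parent <- seq_len(n_atoms)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (NROW(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n_atoms), find, 0L)
  # consecutive ids ordered by smallest member index: roots are minimal
  # members by construction, so ordering by root value suffices
  match(roots, sort(unique(roots)))
}

#' Mask of the most frequent group
#'
#' @param labels Integer per-atom group ids.
#' @return Numeric 0/1 mask of the atoms whose label appears most often;
#'   ties go to the smallest label.
#' @export
mode_mask <- function(labels) {
  tab <- table(labels)
  winner <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest label
  as.numeric(labels == winner)
}

#' Recurrent cluster tracking step
#'
#' For each current cluster (a group of at least `min_size` members) the
#' number of its members that carried a nonzero label in the previous step
#' is counted. The cluster with the largest count becomes the main cluster
#' and its members are labelled 1 (ties go to the smallest group id). If
#' every count is zero the tracked cluster has dissipated and all labels
#' are cleared. Single atoms are not clusters, so a fully dispersed cluster
#' clears the labels rather than following one stray atom.
#'
#' @param prev_labels Per-atom numeric labels from the previous step (0 =
#'   unlabelled).
#' @param group_labels Integer per-atom group ids for the current frame.
#' @param min_size Minimum group size to count as a cluster (default 2).
#' @return Per-atom numeric labels (1 on the main cluster, else 0).
#' @export
track_cluster <- function(prev_labels, group_labels, min_size = 2L) {
  if (length(prev_labels) != length(group_labels))
    stop("label arrays must have equal length")
  sizes <- tabulate(group_labels)
  eligible <- which(sizes >= min_size)
  if (!length(eligible)) return(numeric(length(prev_labels)))
  overlap <- vapply(eligible, function(g)
    sum(group_labels == g & prev_labels != 0), 0)
  if (max(overlap) == 0) return(numeric(length(prev_labels)))
  main <- eligible[which.max(overlap)]  # first max = smallest group id
  as.numeric(group_labels == main)
}

#' Colour graduation from labels
#'
#' Labelled atoms fade toward red (colour 1), unlabelled atoms toward blue
#' (colour 0), by `fade_rate` per step, clamped to `[0, 1]`.
#'
#' @param labels Per-atom numeric labels (nonzero = labelled).
#' @param prev_colors Per-atom colours in `[0, 1]` from the previous step.
#' @param fade_rate Step size in `(0, 1]`.
#' @return Updated per-atom colours.
#' @export
labels2colors <- function(labels, prev_colors, fade_rate = 0.05) {
  if (!is.numeric(fade_rate) || length(fade_rate) != 1L ||
      fade_rate <= 0 || fade_rate > 1)
    stop("fade_rate must lie in (0, 1]")
  if (length(labels) != length(prev_colors))
    stop("label and colour arrays must have equal length")
  ifelse(labels != 0,
         pmin(1, prev_colors + fade_rate),
         pmax(0, prev_colors - fade_rate))
}

register_cluster_node_kinds <- function() {
  register_node_kind(
    "list_neighbors", params = list(cutoff = NULL),
    inputs = list(positions = port("float", 2)),
    outputs = list(edges = port("int", 2), counts = port("int", 1)),
    check = function(p) if (!is.numeric(p$cutoff) || p$cutoff <= 0)
      "list_neighbors needs a positive 'cutoff' parameter" else character(0),
    fn = function(inputs, params, ctx) {
      nl <- list_neighbors(inputs$positions, ctx$box, params$cutoff)
      list(edges = nl$edges, counts = as.integer(nl$counts))
    })

  register_node_kind(
    "group_list", inputs = list(edges = port("int", 2)),
    outputs = list(labels = port("int", 1)),
    fn = function(inputs, params, ctx)
      list(labels = group_list(ctx$n_atoms, inputs$edges)))

  register_node_kind(
    "mode_mask", inputs = list(labels = port("int", 1)),
    outputs = list(mask = port("int", 1)),
    fn = function(inputs, params, ctx)
      list(mask = as.integer(mode_mask(inputs$labels))))

  register_node_kind(
    "track_cluster", params = list(min_size = 2),
    inputs = list(prev = port("float", 1), groups = port("int", 1)),
    outputs = list(labels = port("float", 1)),
    fn = function(inputs, params, ctx)
      list(labels = track_cluster(inputs$prev, inputs$groups, params$min_size)))

  register_node_kind(
    "labels2colors", params = list(fade_rate = 0.05),
    inputs = list(labels = port("float", 1), colors = port("float", 1)),
    outputs = list(colors = port("float", 1)),
    check = function(p) if (!is.numeric(p$fade_rate) || p$fade_rate <= 0 ||
                            p$fade_rate > 1)
      "fade_rate must lie in (0, 1]" else character(0),
    fn = function(inputs, params, ctx)
      list(colors = labels2colors(inputs$labels, inputs$colors, params$fade_rate)))
}
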