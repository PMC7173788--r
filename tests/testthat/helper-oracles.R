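# Independent oracles used to check the package's algorithms: an O(N^2)
# minimum-image neighbour search, a breadth-first component labeller, and
# an exhaustive subset/permutation ring enumerator. All are deliberately
# written without reusing the implementation's code paths.

# all-pairs neighbour edges by direct minimum-image distances
brute_force_edges <- function(pos, lengths, periodic, cutoff) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    d <- sweep(pos[(i + 1L):n, , drop = FALSE], 2L, pos[i, ], "-")
    for (k in 1:3) {
      if (periodic[k]) {
        L <- lengths[k]
        d[, k] <- d[, k] - L * floor(d[, k] / L + 0.5)
      }
    }
    js <- which(rowSums(d * d) <= cutoff^2) + i
    if (length(js)) out <- rbind(out, cbind(i, js))
  }
  if (is.null(out)) matrix(integer(0), 0L, 2L) else {
    colnames(out) <- NULL
    out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  }
}

# breadth-first-search component labels, ids 1..k in order of smallest member
bfs_components <- function(n, edges) {
  adj <- vector("list", n)
  if (NROW(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  labels <- integer(n)
  next_id <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    next_id <- next_id + 1L
    queue <- s
    labels[s] <- next_id
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (labels[w] == 0L) {
          labels[w] <- next_id
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# all permutations of 1..m (recursive, deterministic order)
all_perms <- function(m) {
  if (m == 1L) return(list(1L))
  sub <- all_perms(m - 1L)
  out <- list()
  for (p in sub)
    for (pos in 0:(m - 1L))
      out[[length(out) + 1L]] <- append(p, m, after = pos)
  out
}

# exhaustive enumeration of simple n-cycles: every n-subset of vertices,
# every cyclic order, canonical form (min vertex first, second < last)
exhaustive_rings <- function(edges, n) {
  if (NROW(edges) < n) return(list())
  verts <- sort(unique(as.integer(edges)))
  top <- max(verts)
  A <- matrix(FALSE, top, top)
  A[edges] <- TRUE
  A[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  deg <- rowSums(A)
  cand <- verts[deg[verts] >= 2L]
  if (length(cand) < n) return(list())
  perms <- all_perms(n - 1L)
  out <- list()
  for (S in utils::combn(cand, n, simplify = FALSE)) {
    if (any(rowSums(A[S, S, drop = FALSE]) < 2L)) next
    rest <- S[-1L]
    for (p in perms) {
      cyc <- c(S[1L], rest[p])
      if (cyc[2L] > cyc[n]) next
      ok <- TRUE
      for (k in seq_len(n)) {
        nk <- if (k == n) 1L else k + 1L
        if (!A[cyc[k], cyc[nk]]) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <- cyc
    }
  }
  if (!length(out)) return(out)
  out[order(vapply(out, function(r) paste(sprintf("%09d", r), collapse = ""), ""))]
}

# random undirected graph as an edge matrix (unique, i < j)
random_graph_edges <- function(n_vertices, n_edges) {
  if (n_vertices < 2L || n_edges < 1L) return(matrix(integer(0), 0L, 2L))
  a <- sample.int(n_vertices, n_edges, replace = TRUE)
  b <- sample.int(n_vertices, n_edges, replace = TRUE)
  keep <- a != b
  e <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  e <- unique(e)
  if (!nrow(e)) return(matrix(integer(0), 0L, 2L))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

# ring lists as comparable canonical string sets
ring_strings <- function(rings) {
  sort(vapply(rings, function(r) paste(r, collapse = "-"), ""))
}
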