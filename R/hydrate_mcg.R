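# Mutually Coordinated Guest (MCG-1) node pack for clathrate-hydrate
# recognition: guest pairing within a cutoff, coordinated waters inside the
# symmetric double cone between a guest pair, geometric hydrogen bonds,
# O-H -> O-O edge reconnection, n-membered ring perception on the oxygen
# network, and guest/cage labelling.

deg2rad <- function(x) x * pi / 180

vec_angle <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Guest pairs within a cutoff
#'
#' All unordered pairs of guest atoms whose minimum-image distance is at
#' most `pair_cutoff` (default 9 angstrom).
#'
#' @param positions n x 3 matrix of all atom positions.
#' @param box An [md_box()].
#' @param guest_idx Integer indices of the guest atoms.
#' @param pair_cutoff Positive cutoff, angstrom.
#' @return m x 2 integer matrix of atom-index pairs, `g1 < g2`, sorted.
#' @export
filter_guests <- function(positions, box, guest_idx, pair_cutoff = 9.0) {
  if (!is.numeric(pair_cutoff) || pair_cutoff <= 0)
    stop("pair_cutoff must be positive")
  for (k in 1:3)
    if (box$periodic[k] && pair_cutoff > box$lengths[k] / 2)
      stop(sprintf("pair_cutoff %g exceeds half the box length on periodic axis %d",
                   pair_cutoff, k))
  guest_idx <- sort(unique(as.integer(guest_idx)))
  m <- length(guest_idx)
  if (m < 2L) return(matrix(integer(0), 0L, 2L))
  out <- list()
  for (a in seq_len(m - 1L)) {
    i <- guest_idx[a]
    js <- guest_idx[(a + 1L):m]
    d <- disp_to_all(positions[i, ], positions[js, , drop = FALSE], box)
    hit <- js[rowSums(d * d) <= pair_cutoff^2]
    if (length(hit)) out[[length(out) + 1L]] <- cbind(i, hit)
  }
  if (!length(out)) return(matrix(integer(0), 0L, 2L))
  e <- do.call(rbind, out)
  colnames(e) <- NULL
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Waters coordinated to each guest pair (double-cone criterion)
#'
#' A water oxygen O is coordinated to the pair (g1, g2) iff the angle
#' between O - g1 and g2 - g1 and the angle between O - g2 and g1 - g2 are
#' both at most `cone_angle`: the lens-shaped intersection of two cones
#' whose apices sit on the guests and whose axes point at each other. An
#' optional `max_dist` additionally caps the O-guest distance so alternate
#' readings of the criterion can be expressed. All displacements use the
#' minimum image.
#'
#' @param positions n x 3 matrix of all atom positions.
#' @param box An [md_box()].
#' @param pairs m x 2 guest pair matrix from [filter_guests()].
#' @param water_o_idx Integer indices of water oxygen atoms.
#' @param cone_angle Half-angle in degrees, in (0, 90).
#' @param max_dist Optional cap on the O-guest distance (angstrom).
#' @return List with `pair_waters` (per pair, sorted oxygen indices) and
#'   `selected` (sorted union of all coordinated oxygens).
#' @export
filter_waters <- function(positions, box, pairs, water_o_idx,
                          cone_angle = 45, max_dist = NULL) {
  if (!is.numeric(cone_angle) || cone_angle <= 0 || cone_angle >= 90)
    stop("cone_angle must lie in (0, 90) degrees")
  water_o_idx <- sort(unique(as.integer(water_o_idx)))
  pair_waters <- vector("list", NROW(pairs))
  for (p in seq_len(NROW(pairs))) {
    g1 <- pairs[p, 1L]; g2 <- pairs[p, 2L]
    axis <- minimum_image(positions[g1, ], positions[g2, ], box)
    La <- sqrt(sum(axis * axis))
    if (La < 1e-9) {
      warning(sprintf("guest pair (%d, %d) has zero separation; skipped", g1, g2))
      pair_waters[[p]] <- integer(0)
      next
    }
    d1 <- disp_to_all(positions[g1, ], positions[water_o_idx, , drop = FALSE], box)
    d2 <- disp_to_all(positions[g2, ], positions[water_o_idx, , drop = FALSE], box)
    n1 <- sqrt(rowSums(d1 * d1)); n2 <- sqrt(rowSums(d2 * d2))
    cosmax <- cos(deg2rad(cone_angle))
    c1 <- as.vector(d1 %*% axis) / (n1 * La)        # cos angle(O-g1, g2-g1)
    c2 <- as.vector(d2 %*% (-axis)) / (n2 * La)     # cos angle(O-g2, g1-g2)
    ok <- !is.na(c1) & !is.na(c2) & c1 >= cosmax & c2 >= cosmax & n1 > 0 & n2 > 0
    if (!is.null(max_dist)) ok <- ok & n1 <= max_dist & n2 <= max_dist
    pair_waters[[p]] <- water_o_idx[ok]
  }
  list(pair_waters = pair_waters,
       selected = sort(unique(unlist(pair_waters))))
}

# oxygen -> its molecule's two hydrogens, from the atom table
water_hydrogens <- function(atoms, o_idx) {
  hmap <- vector("list", length(o_idx))
  is_h <- toupper(atoms$element) == "H"
  for (k in seq_along(o_idx)) {
    o <- o_idx[k]
    hs <- which(atoms$molid == atoms$molid[o] & is_h)
    if (length(hs) != 2L)
      stop(sprintf("water molecule %d (oxygen atom %d) must have exactly 2 hydrogens, found %d",
                   atoms$molid[o], o, length(hs)))
    hmap[[k]] <- hs
  }
  hmap
}

#' Geometric hydrogen bonds between selected waters
#'
#' A candidate (O_donor, H, O_acceptor) is accepted iff both oxygens are
#' selected, the molecules differ, the O-O distance is at most `d_oo_max`
#' and the angle between H - O_donor and O_acceptor - O_donor is at most
#' `angle_max` (all minimum image).
#'
#' @param positions n x 3 matrix of all atom positions.
#' @param box An [md_box()].
#' @param atoms The trajectory's [atom_table()] (for molecule membership).
#' @param selected_o Integer indices of the selected water oxygens.
#' @param d_oo_max O-O distance cutoff, angstrom (default 3.5).
#' @param angle_max Donor angle cutoff, degrees (default 30).
#' @return m x 3 integer matrix with columns donor oxygen, hydrogen,
#'   acceptor oxygen.
#' @export
hbonds_filtered <- function(positions, box, atoms, selected_o,
                            d_oo_max = 3.5, angle_max = 30) {
  selected_o <- sort(unique(as.integer(selected_o)))
  if (length(selected_o) < 2L) return(matrix(integer(0), 0L, 3L))
  hmap <- water_hydrogens(atoms, selected_o)
  out <- list()
  for (k in seq_along(selected_o)) {
    od <- selected_o[k]
    doo <- disp_to_all(positions[od, ], positions[selected_o, , drop = FALSE], box)
    dist <- sqrt(rowSums(doo * doo))
    cand <- which(dist <= d_oo_max & selected_o != od &
                    atoms$molid[selected_o] != atoms$molid[od])
    for (a in cand) {
      oa <- selected_o[a]
      for (h in hmap[[k]]) {
        oh <- minimum_image(positions[od, ], positions[h, ], box)
        ang <- vec_angle(oh, doo[a, ])
        if (!is.na(ang) && ang <= angle_max)
          out[[length(out) + 1L]] <- c(od, h, oa)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), 0L, 3L))
  hb <- do.call(rbind, out)
  colnames(hb) <- NULL
  hb[order(hb[, 1L], hb[, 3L], hb[, 2L]), , drop = FALSE]
}

#' Reconnect hydrogen bonds as O-O edges
#'
#' Each (O_donor, H, O_acceptor) becomes the undirected edge
#' (min(O_d, O_a), max(O_d, O_a)); duplicates collapse.
#'
#' @param hbonds m x 3 matrix from [hbonds_filtered()].
#' @return m' x 2 integer edge matrix, i < j, unique, sorted.
#' @export
reconnect_water <- function(hbonds) {
  if (NROW(hbonds) == 0L) return(matrix(integer(0), 0L, 2L))
  e <- cbind(pmin(hbonds[, 1L], hbonds[, 3L]), pmax(hbonds[, 1L], hbonds[, 3L]))
  e <- unique(e)
  colnames(e) <- NULL
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Hydrogen-to-acceptor pairs of a hydrogen-bond list
#'
#' Convenience for drawing the bonds in O-H form (hydrogen to acceptor
#' oxygen), the alternative wiring of the extra-bonds node.
#'
#' @param hbonds m x 3 matrix from [hbonds_filtered()].
#' @return m x 2 integer matrix (H, O_acceptor), deduplicated.
#' @export
oh_pairs <- function(hbonds) {
  if (NROW(hbonds) == 0L) return(matrix(integer(0), 0L, 2L))
  normalize_pairs(hbonds[, c(2L, 3L), drop = FALSE],
                  max(hbonds), what = "O-H bond")
}

#' Find all simple rings of a given size
#'
#' Enumerates every simple cycle of length exactly `n` in the undirected
#' edge graph, each reported once in canonical form (rotated so the
#' smallest vertex leads, direction chosen so its smaller neighbour comes
#' second).
#'
#' @param edges m x 2 integer edge matrix.
#' @param n Ring size, at least 3 (default 5, the pentagonal rings of
#'   hydrate cages).
#' @return List of integer vectors of length `n`, sorted lexicographically.
#' @export
find_links <- function(edges, n = 5L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("ring size n must be at least 3")
  if (NROW(edges) < n) return(list())
  edges <- matrix(as.integer(edges), ncol = 2L)
  verts <- sort(unique(as.integer(edges)))
  adj <- new.env(parent = emptyenv())
  for (v in verts) adj[[as.character(v)]] <- integer(0)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    if (a == b) next
    adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
    adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
  }
  for (v in verts) adj[[as.character(v)]] <- sort(unique(adj[[as.character(v)]]))
  rings <- list()
  # DFS from each root v: paths v -> ... of length n with every intermediate
  # vertex > v; close when the last vertex neighbours v. Direction
  # canonicalized by requiring path[2] < path[n].
  extend <- function(path, inpath) {
    depth <- length(path)
    last <- path[depth]
    for (w in adj[[as.character(last)]]) {
      if (depth == n) break
      if (w <= path[1L] || inpath[w]) next
      if (depth + 1L == n) {
        if (path[2L] < w && path[1L] %in% adj[[as.character(w)]])
          rings[[length(rings) + 1L]] <<- c(path, w)
      } else {
        inpath[w] <- TRUE
        extend(c(path, w), inpath)
        inpath[w] <- FALSE
      }
    }
  }
  maxv <- max(verts)
  for (v in verts) {
    inpath <- logical(maxv)
    inpath[v] <- TRUE
    extend(v, inpath)
  }
  if (!length(rings)) return(list())
  ord <- order(vapply(rings, function(r)
    paste(sprintf("%09d", r), collapse = ""), ""))
  rings[ord]
}

#' Label mutually coordinated guests and their cage oxygens
#'
#' A guest pair is mutually coordinated iff at least `min_rings` rings lie
#' entirely within its coordinated-water set. The guests of such pairs and
#' the oxygens of their qualifying rings receive labels; label ids are
#' connected-component ids over qualifying pairs sharing a guest, numbered
#' from 1 in order of each component's smallest guest index (0 =
#' unlabelled).
#'
#' @param n_atoms Total number of atoms (length of the label vector).
#' @param pairs m x 2 guest pair matrix.
#' @param pair_waters Per-pair coordinated oxygen sets from
#'   [filter_waters()].
#' @param rings Ring list from [find_links()].
#' @param min_rings Minimum qualifying rings per pair (default 1, the
#'   MCG-1 criterion).
#' @return List with `labels` (per-atom numeric) and `mcg_count` (number of
#'   mutually coordinated pairs).
#' @export
register_hydrate <- function(n_atoms, pairs, pair_waters, rings,
                             min_rings = 1L) {
  labels <- numeric(n_atoms)
  np <- NROW(pairs)
  if (np == 0L) return(list(labels = labels, mcg_count = 0L))
  ring_sets <- lapply(rings, sort)
  pair_rings <- vector("list", np)
  for (p in seq_len(np)) {
    ws <- pair_waters[[p]]
    hits <- if (length(ws) && length(ring_sets))
      which(vapply(ring_sets, function(r) all(r %in% ws), TRUE)) else integer(0)
    pair_rings[[p]] <- hits
  }
  qual <- which(lengths(pair_rings) >= min_rings)
  if (!length(qual)) return(list(labels = labels, mcg_count = 0L))
  # component labels over qualifying pairs sharing a guest
  guests <- sort(unique(as.integer(pairs[qual, ])))
  gid <- function(g) match(g, guests)
  comp <- group_list(length(guests),
                     cbind(gid(pairs[qual, 1L]), gid(pairs[qual, 2L])))
  # renumber components by smallest guest index (group_list already orders
  # by smallest member, and `guests` is sorted, so comp ids are in order)
  for (k in seq_along(qual)) {
    p <- qual[k]
    lab <- comp[gid(pairs[p, 1L])]
    labels[pairs[p, ]] <- lab
    for (r in pair_rings[[p]]) labels[ring_sets[[r]]] <- lab
  }
  list(labels = labels, mcg_count = length(qual))
}

#' Number of classified molecules
#'
#' Counts distinct molecule ids owning at least one atom with a nonzero
#' label; this is the scalar fed to the plot node to locate the onset of
#' hydrate formation.
#'
#' @param labels Per-atom numeric labels.
#' @param molid Per-atom molecule ids.
#' @return Integer count.
#' @export
classified_count <- function(labels, molid) {
  if (length(labels) != length(molid))
    stop("labels and molecule ids must have equal length")
  length(unique(molid[labels != 0]))
}

register_hydrate_node_kinds <- function() {
  register_node_kind(
    "filter_guests", params = list(guests = NULL, cutoff = 9.0),
    outputs = list(pairs = port("int", 2)),
    check = function(p) c(
      if (!is.character(p$guests)) "filter_guests needs a 'guests' selection string",
      if (!is.numeric(p$cutoff) || p$cutoff <= 0) "cutoff must be positive"),
    fn = function(inputs, params, ctx) {
      gi <- select_atoms(ctx$traj, params$guests)
      list(pairs = filter_guests(ctx$frame$positions, ctx$box, gi,
                                 params$cutoff))
    })

  register_node_kind(
    "filter_waters",
    params = list(waters = "resname=SOL|HOH|WAT", cone_angle = 45,
                  max_dist = NULL),
    inputs = list(pairs = port("int", 2)),
    outputs = list(pair_waters = port("int", 2), selected = port("float", 1)),
    check = function(p) c(
      if (!is.numeric(p$cone_angle) || p$cone_angle <= 0 || p$cone_angle >= 90)
        "cone_angle must lie in (0, 90)"),
    fn = function(inputs, params, ctx) {
      wi <- intersect(select_atoms(ctx$traj, params$waters),
                      which(toupper(ctx$traj$atoms$element) == "O"))
      fw <- filter_waters(ctx$frame$positions, ctx$box, inputs$pairs, wi,
                          params$cone_angle, params$max_dist)
      sel <- numeric(ctx$n_atoms); sel[fw$selected] <- 1
      pw <- do.call(rbind, c(list(matrix(integer(0), 0L, 2L)),
                             lapply(seq_along(fw$pair_waters), function(p)
                               if (length(fw$pair_waters[[p]]))
                                 cbind(p, fw$pair_waters[[p]]))))
      colnames(pw) <- NULL
      list(pair_waters = pw, selected = sel)
    })

  register_node_kind(
    "hbonds_filtered",
    params = list(d_oo_max = 3.5, angle_max = 30),
    inputs = list(selected = port("float", 1)),
    outputs = list(hbonds = port("int", 2), oh = port("int", 2)),
    fn = function(inputs, params, ctx) {
      sel <- which(inputs$selected != 0)
      hb <- hbonds_filtered(ctx$frame$positions, ctx$box, ctx$traj$atoms,
                            sel, params$d_oo_max, params$angle_max)
      list(hbonds = hb, oh = oh_pairs(hb))
    })

  register_node_kind(
    "reconnect_water", inputs = list(hbonds = port("int", 2)),
    outputs = list(edges = port("int", 2)),
    fn = function(inputs, params, ctx)
      list(edges = reconnect_water(inputs$hbonds)))

  register_node_kind(
    "find_links", params = list(n = 5),
    inputs = list(edges = port("int", 2)),
    outputs = list(rings = port("int", 2)),
    check = function(p) if (!is.numeric(p$n) || p$n < 3)
      "ring size n must be at least 3" else character(0),
    fn = function(inputs, params, ctx) {
      rs <- find_links(inputs$edges, params$n)
      rings <- if (length(rs)) do.call(rbind, rs) else
        matrix(integer(0), 0L, as.integer(params$n))
      colnames(rings) <- NULL
      list(rings = rings)
    })

  register_node_kind(
    "register_hydrate", params = list(min_rings = 1),
    inputs = list(pairs = port("int", 2), pair_waters = port("int", 2),
                  rings = port("int", 2)),
    outputs = list(labels = port("float", 1), mcg_count = port("int", 0)),
    fn = function(inputs, params, ctx) {
      pw <- vector("list", NROW(inputs$pairs))
      for (p in seq_along(pw)) pw[[p]] <- integer(0)
      if (NROW(inputs$pair_waters))
        for (r in seq_len(nrow(inputs$pair_waters))) {
          p <- inputs$pair_waters[r, 1L]
          pw[[p]] <- c(pw[[p]], inputs$pair_waters[r, 2L])
        }
      rings <- if (NROW(inputs$rings))
        lapply(seq_len(nrow(inputs$rings)), function(i) inputs$rings[i, ]) else
          list()
      rh <- register_hydrate(ctx$n_atoms, inputs$pairs, pw, rings,
                             params$min_rings)
      list(labels = rh$labels, mcg_count = as.integer(rh$mcg_count))
    })

  register_node_kind(
    "classified_count", inputs = list(labels = port("float", 1)),
    outputs = list(count = port("int", 0)),
    fn = function(inputs, params, ctx)
      list(count = classified_count(inputs$labels, ctx$traj$atoms$molid)))
}
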