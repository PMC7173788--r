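# Synthetic fixture generators. These stand in for external simulations and
# give every pipeline stage a configuration with analytically known ground
# truth: a two-blob droplet trajectory with scripted nucleation, merge and
# join/leave events; an analytic guest pair caged by a water ring; the
# pentagonal-dodecahedron (5^12) cage; and a dilute bulk-water negative
# control. All generators are pure functions of their parameters (seed
# included).

# rigid 3-site water geometry (common convention, fixed for determinism)
OH_LEN <- 0.9572
HOH_DEG <- 104.52

# compact set of n cubic-grid sites (spacing s) around the origin, ordered
# by distance then lexicographically; connected at any cutoff >= s
blob_sites <- function(n, s) {
  r <- 1L
  repeat {
    g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
    if (nrow(g) >= n + 8L) break
    r <- r + 1L
  }
  ord <- order(rowSums(g * g), g[, 1L], g[, 2L], g[, 3L])
  g[ord[seq_len(n)], , drop = FALSE] * s
}

# distance from point p to the x-axis segment [x0, x1] (y = z = 0)
axis_seg_dist <- function(p, x0, x1) {
  dx <- if (p[1L] < x0) x0 - p[1L] else if (p[1L] > x1) p[1L] - x1 else 0
  sqrt(dx^2 + p[2L]^2 + p[3L]^2)
}

#' Synthetic droplet trajectory with known cluster ground truth
#'
#' Two compact blobs (intra-blob spacing below the cutoff) in a dilute gas
#' (every gas-gas and gas-blob distance well above the cutoff). The larger
#' blob nucleates from dispersed gas at `nucleation_frame`, both blobs
#' translate toward each other and merge into one connected component at
#' `merge_frame`, and a scripted set of gas atoms joins/leaves the main
#' blob at recorded events. The emitted ground truth is the per-frame
#' membership of the main cluster as recovered by backward tracking from
#' the final largest cluster: empty before nucleation (labels clear), the
#' large blob plus currently attached atoms before the merge, and both
#' blobs plus attached atoms from the merge on.
#'
#' @param n_atoms Total atom count (>= 20).
#' @param n_frames Number of frames.
#' @param merge_frame 1-based frame at which the blobs first connect
#'   (`nucleation_frame < merge_frame <= n_frames`).
#' @param cutoff Neighbour cutoff the ground truth is defined against,
#'   angstrom.
#' @param seed Integer seed; same seed, same trajectory.
#' @param nucleation_frame Frame at which the large blob assembles
#'   (default `max(2, merge_frame %/% 2)`).
#' @return List with `traj` (an [md_trajectory]) and `truth`: per-frame 0/1
#'   membership masks (list indexed by frame), `merge_frame`,
#'   `nucleation_frame`, `cutoff` and the join/leave `events`.
#' @export
gen_lj_droplet <- function(n_atoms = 60L, n_frames = 20L, merge_frame = 12L,
                           cutoff = 3.0, seed = 1L,
                           nucleation_frame = NULL) {
  n_atoms <- as.integer(n_atoms); n_frames <- as.integer(n_frames)
  merge_frame <- as.integer(merge_frame)
  if (n_atoms < 20L) stop("gen_lj_droplet needs at least 20 atoms")
  if (is.null(nucleation_frame)) nucleation_frame <- max(2L, merge_frame %/% 2L)
  nucleation_frame <- as.integer(nucleation_frame)
  if (!(nucleation_frame < merge_frame && merge_frame <= n_frames) ||
      nucleation_frame < 2L)
    stop("need 2 <= nucleation_frame < merge_frame <= n_frames")
  set.seed(seed)

  s <- 0.9 * cutoff
  nA <- max(8L, round(0.4 * n_atoms))
  nB <- max(4L, round(0.25 * n_atoms))
  if (nA <= nB) nA <- nB + 2L
  n_gas <- n_atoms - nA - nB
  if (n_gas < 3L) stop("too few atoms left for the gas phase; increase n_atoms")
  RA <- blob_sites(nA + 4L, s)            # extra sites = attachment points
  attach_rel <- RA[(nA + 1L):(nA + 4L), , drop = FALSE]
  RA <- RA[seq_len(nA), , drop = FALSE]
  RB <- blob_sites(nB, s)
  rA <- sqrt(max(rowSums(RA * RA))) + s
  rB <- sqrt(max(rowSums(RB * RB))) + s

  # center distance at which the nearest inter-blob atom pair sits at 0.8*cutoff
  min_gap <- function(t) {
    d <- 0
    best <- Inf
    for (i in seq_len(nA)) {
      dd <- sweep(RB, 2L, RA[i, ], "-")
      dd[, 1L] <- dd[, 1L] + t
      best <- min(best, min(rowSums(dd * dd)))
    }
    sqrt(best)
  }
  t_merge <- stats::uniroot(function(t) min_gap(t) - 0.8 * cutoff,
                            interval = c(0.1, rA + rB + 10 * cutoff))$root
  step <- 1.2 * cutoff
  center_dist <- function(f) {
    if (f >= merge_frame) t_merge else t_merge + (merge_frame - f) * step
  }
  t_start <- center_dist(nucleation_frame)
  cA <- function(f) c(-center_dist(max(f, nucleation_frame)) / 2, 0, 0)
  cB <- function(f) c(+center_dist(max(f, nucleation_frame)) / 2, 0, 0)

  # box: generous non-periodic region holding everything
  rmax <- max(rA, rB)
  X <- t_start / 2 + rmax + 8 * cutoff
  Y <- rmax + 8 * cutoff + (n_gas^(1 / 3)) * 2.5 * cutoff
  box <- md_box(2 * c(X, Y, Y), periodic = c(FALSE, FALSE, FALSE))

  # rejection-sample static positions for gas atoms and the dispersed
  # (pre-nucleation) positions of blob-A atoms: mutually > 2.2*cutoff and
  # clear of the blobs' swept region around the x axis
  n_scatter <- nA + n_gas
  scatter <- matrix(NA_real_, n_scatter, 3L)
  placed <- 0L; attempts <- 0L
  lim <- 4000L * n_scatter
  clearance <- 2.2 * cutoff
  while (placed < n_scatter) {
    attempts <- attempts + 1L
    if (attempts > lim)
      stop("gas placement failed; the implied density is too high - use fewer atoms (larger box)")
    p <- c(stats::runif(1, -X + cutoff, X - cutoff),
           stats::runif(1, -Y + cutoff, Y - cutoff),
           stats::runif(1, -Y + cutoff, Y - cutoff))
    if (axis_seg_dist(p, -t_start / 2 - rmax, t_start / 2 + rmax) <
        rmax + clearance) next
    if (placed > 0L) {
      d <- sweep(scatter[seq_len(placed), , drop = FALSE], 2L, p, "-")
      if (min(rowSums(d * d)) < clearance^2) next
    }
    placed <- placed + 1L
    scatter[placed, ] <- p
  }
  dispersedA <- scatter[seq_len(nA), , drop = FALSE]
  gas_pos <- scatter[(nA + 1L):n_scatter, , drop = FALSE]

  # scripted events among the gas atoms: two joiners and one leaver
  ev_lo <- nucleation_frame + 1L
  joiners <- integer(0); leavers <- integer(0)
  join_f <- integer(0); leave_f <- integer(0)
  pick <- function(from, to, size) {
    cand <- from:to
    cand[sample.int(length(cand), size, replace = TRUE)]
  }
  if (n_gas >= 3L && ev_lo <= n_frames) {
    joiners <- 1:2
    join_f <- sort(pick(ev_lo, n_frames, 2L))
    if (merge_frame - 1L >= ev_lo) {
      leavers <- 3L
      leave_f <- pick(ev_lo, merge_frame - 1L, 1L)
    }
  }
  # every attachment site must touch the blob at the generator's own cutoff
  for (slot in seq_len(nrow(attach_rel))) {
    dd <- sweep(RA, 2L, attach_rel[slot, ], "-")
    stopifnot(min(sqrt(rowSums(dd * dd))) <= cutoff)
  }

  # atom layout: A blob, B blob, then gas (joiners/leaver are the first gas)
  idxA <- seq_len(nA)
  idxB <- nA + seq_len(nB)
  idxG <- nA + nB + seq_len(n_gas)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  events <- list()
  for (k in seq_along(joiners))
    events[[length(events) + 1L]] <- list(atom = idxG[joiners[k]],
                                          type = "join", frame = join_f[k])
  for (k in seq_along(leavers))
    events[[length(events) + 1L]] <- list(atom = idxG[leavers[k]],
                                          type = "leave", frame = leave_f[k])

  for (f in seq_len(n_frames)) {
    pos <- matrix(0, n_atoms, 3L)
    pos[idxA, ] <- if (f < nucleation_frame) dispersedA else
      sweep(RA, 2L, cA(f), "+")
    pos[idxB, ] <- sweep(RB, 2L, cB(f), "+")
    pos[idxG, ] <- gas_pos
    attached <- integer(0)
    slot <- 1L
    for (k in seq_along(joiners)) {
      if (f >= join_f[k]) {
        a <- idxG[joiners[k]]
        pos[a, ] <- cA(f) + attach_rel[slot, ]
        attached <- c(attached, a)
      }
      slot <- slot + 1L
    }
    for (k in seq_along(leavers)) {
      if (f >= nucleation_frame && f < leave_f[k]) {
        a <- idxG[leavers[k]]
        pos[a, ] <- cA(f) + attach_rel[slot, ]
        attached <- c(attached, a)
      }
      slot <- slot + 1L
    }
    frames[[f]] <- md_frame(f, pos, box)
    mask <- numeric(n_atoms)
    if (f >= nucleation_frame) {
      mask[idxA] <- 1
      mask[attached] <- 1
      if (f >= merge_frame) mask[idxB] <- 1
    }
    truth[[f]] <- mask
  }
  atoms <- atom_table(name = rep("LJ", n_atoms), element = rep("Ar", n_atoms),
                      resname = rep("LJP", n_atoms),
                      resid = seq_len(n_atoms))
  traj <- md_trajectory(atoms, frames)
  # internal consistency: blobs really are single components at the cutoff
  stopifnot(max(group_list(list_neighbors(sweep(RA, 2L, c(0, 0, 0), "+"),
                                          box, cutoff))) == 1L)
  list(traj = traj,
       truth = list(mask = truth, merge_frame = merge_frame,
                    nucleation_frame = nucleation_frame, cutoff = cutoff,
                    events = events))
}

# unit vector
uv <- function(v) v / sqrt(sum(v * v))

#' Analytic guest pair caged by a ring of waters
#'
#' Two guest atoms on the z axis separated by `guest_sep`, with `n_ring`
#' water oxygens equally spaced on a circle of radius `ring_radius` in the
#' midplane. Each water donates one hydrogen straight at the next oxygen
#' around the ring (a linear hydrogen bond); the second hydrogen points out
#' of the ring plane at the rigid-water angle. The construction is
#' validated against the pipeline criteria: both cone angles at most 45
#' degrees and all ring O-O distances at most 3.5 angstrom.
#'
#' @param guest_sep Guest-guest distance, angstrom (default 8, below the
#'   9-angstrom pairing cutoff).
#' @param ring_radius Ring radius, angstrom (default 2.8).
#' @param n_ring Number of waters in the ring (default 5).
#' @return A single-frame [md_trajectory] (guests `resname=MET`, waters
#'   `resname=SOL`; large non-periodic box).
#' @export
gen_cage_pair <- function(guest_sep = 8.0, ring_radius = 2.8, n_ring = 5L) {
  n_ring <- as.integer(n_ring)
  if (n_ring < 3L) stop("n_ring must be at least 3")
  half <- guest_sep / 2
  cone <- atan2(ring_radius, half) * 180 / pi
  if (cone > 45)
    stop(sprintf("infeasible geometry: cone angle %.1f deg exceeds 45 deg (reduce ring_radius or guest_sep)", cone))
  oo <- 2 * ring_radius * sin(pi / n_ring)
  if (oo > 3.5)
    stop(sprintf("infeasible geometry: ring O-O distance %.2f A exceeds 3.5 A (reduce ring_radius or increase n_ring)", oo))
  gpos <- rbind(c(0, 0, -half), c(0, 0, half))
  th <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  opos <- cbind(ring_radius * cos(th), ring_radius * sin(th), 0)
  pos <- gpos; name <- c("C", "C"); elem <- c("C", "C")
  resname <- c("MET", "MET"); molid <- c(1L, 2L)
  a_hoh <- deg2rad(HOH_DEG)
  for (k in seq_len(n_ring)) {
    nxt <- if (k == n_ring) 1L else k + 1L
    u <- uv(opos[nxt, ] - opos[k, ])
    h1 <- opos[k, ] + OH_LEN * u
    h2 <- opos[k, ] + OH_LEN * (cos(a_hoh) * u + sin(a_hoh) * c(0, 0, 1))
    pos <- rbind(pos, opos[k, ], h1, h2)
    name <- c(name, "OW", "HW1", "HW2")
    elem <- c(elem, "O", "H", "H")
    resname <- c(resname, "SOL", "SOL", "SOL")
    molid <- c(molid, rep(2L + k, 3L))
  }
  ext <- apply(pos, 2L, function(v) diff(range(v)))
  box <- md_box(pmax(4 * ext, 4), periodic = c(FALSE, FALSE, FALSE))
  atoms <- atom_table(name = name, element = elem, resname = resname,
                      resid = molid, molid = molid)
  md_trajectory(atoms, list(md_frame(1L, pos, box)))
}

#' Pentagonal-dodecahedron (5^12) water cage
#'
#' Twenty water oxygens at the vertices of a regular pentagonal
#' dodecahedron (golden-ratio coordinates scaled to `radius`), hydrogens
#' directed along the polyhedron's 30 edges so that every edge carries
#' exactly one donated hydrogen (an Eulerian-circuit orientation keeps
#' every vertex's donations at one or two). The resulting hydrogen-bond
#' network is exactly the polyhedron's edge graph, whose 12 faces are the
#' canonical pentagonal rings.
#'
#' @param radius Circumradius (center-to-oxygen distance), angstrom. The
#'   default places neighbouring oxygens 2.8 angstrom apart.
#' @param guest_at_center Add a guest atom (resname `MET`) at the center?
#' @return A single-frame [md_trajectory].
#' @export
gen_dodecahedral_cage <- function(radius = NULL, guest_at_center = FALSE) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
             cbind(0, c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi)),
             cbind(c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi), 0),
             cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1) / phi))
  edge_unit <- 2 / phi                      # edge length at these coordinates
  if (is.null(radius)) radius <- 2.8 * sqrt(3) / edge_unit
  v <- v * (radius / sqrt(3))
  edge_len <- edge_unit * radius / sqrt(3)
  d2 <- as.matrix(stats::dist(v))
  edges <- which(upper.tri(d2) & abs(d2 - edge_len) < 1e-6 * edge_len,
                 arr.ind = TRUE)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  stopifnot(nrow(edges) == 30L)
  donors <- euler_orientation(20L, edges)   # per edge: which endpoint donates
  out_edges <- vector("list", 20L)
  for (e in seq_len(nrow(edges))) {
    d <- donors[e]
    a <- edges[e, d]; b <- edges[e, 3L - d]
    out_edges[[a]] <- c(out_edges[[a]], b)
  }
  pos <- NULL; name <- character(0); elem <- character(0)
  molid <- integer(0)
  o_index <- integer(20L)
  for (k in 1:20) {
    hs <- out_edges[[k]]
    stopifnot(length(hs) >= 1L, length(hs) <= 2L)
    h1 <- v[k, ] + OH_LEN * uv(v[hs[1L], ] - v[k, ])
    h2 <- if (length(hs) == 2L)
      v[k, ] + OH_LEN * uv(v[hs[2L], ] - v[k, ]) else
        v[k, ] + OH_LEN * uv(v[k, ])          # radially outward
    o_index[k] <- (if (is.null(pos)) 0L else nrow(pos)) + 1L
    pos <- rbind(pos, v[k, ], h1, h2)
    name <- c(name, "OW", "HW1", "HW2")
    elem <- c(elem, "O", "H", "H")
    molid <- c(molid, rep(k, 3L))
  }
  resname <- rep("SOL", length(name))
  if (guest_at_center) {
    pos <- rbind(pos, c(0, 0, 0))
    name <- c(name, "C"); elem <- c(elem, "C")
    resname <- c(resname, "MET"); molid <- c(molid, 21L)
  }
  box <- md_box(rep(8 * radius, 3L), periodic = c(FALSE, FALSE, FALSE))
  atoms <- atom_table(name = name, element = elem, resname = resname,
                      resid = molid, molid = molid)
  md_trajectory(atoms, list(md_frame(1L, pos, box)))
}

# orient the edges of a graph whose vertices all have odd degree so that
# every out-degree is at most ceil(degree/2): pair the odd vertices through
# a dummy vertex, walk an Eulerian circuit (Hierholzer), orient real edges
# along the walk. Returns, per edge row, 1 or 2 = the donating endpoint.
euler_orientation <- function(n, edges) {
  dummy <- n + 1L
  aug <- rbind(edges, cbind(seq_len(n), dummy))
  m <- nrow(aug)
  inc <- vector("list", dummy)
  for (e in seq_len(m)) {
    inc[[aug[e, 1L]]] <- c(inc[[aug[e, 1L]]], e)
    inc[[aug[e, 2L]]] <- c(inc[[aug[e, 2L]]], e)
  }
  used <- logical(m)
  ptr <- rep(1L, dummy)
  circuit <- integer(0)
  stack_v <- 1L
  stack_e <- integer(0)   # edge taken to reach stack_v[i] (0 for root)
  dir1 <- rep(NA_integer_, m)  # orientation: vertex we left the edge from
  while (length(stack_v)) {
    vtop <- stack_v[length(stack_v)]
    found <- 0L
    while (ptr[vtop] <= length(inc[[vtop]])) {
      e <- inc[[vtop]][ptr[vtop]]
      ptr[vtop] <- ptr[vtop] + 1L
      if (!used[e]) { found <- e; break }
    }
    if (found) {
      used[found] <- TRUE
      dir1[found] <- vtop
      w <- if (aug[found, 1L] == vtop) aug[found, 2L] else aug[found, 1L]
      stack_v <- c(stack_v, w)
    } else {
      stack_v <- stack_v[-length(stack_v)]
    }
  }
  stopifnot(all(used))
  ifelse(dir1[seq_len(nrow(edges))] == edges[, 1L], 1L, 2L)
}

#' Dilute bulk-water negative control
#'
#' Randomly placed and oriented rigid three-site waters in a periodic box,
#' with every oxygen-oxygen minimum-image separation kept above 3.7
#' angstrom so the geometric hydrogen-bond graph is empty and the MCG-1
#' pipeline classifies nothing.
#'
#' @param n_molecules Number of waters.
#' @param box_length Cubic box edge, angstrom.
#' @param seed Integer seed.
#' @return A single-frame [md_trajectory].
#' @export
gen_bulk_water <- function(n_molecules = 30L, box_length = 30, seed = 1L) {
  set.seed(seed)
  n_molecules <- as.integer(n_molecules)
  box <- md_box(rep(box_length, 3L))
  min_sep <- 3.7
  opos <- matrix(NA_real_, n_molecules, 3L)
  placed <- 0L; attempts <- 0L
  while (placed < n_molecules) {
    attempts <- attempts + 1L
    if (attempts > 4000L * n_molecules)
      stop("water placement failed; the density is too high for the minimum separation")
    p <- stats::runif(3L, 0, box_length)
    if (placed > 0L) {
      d <- wrap_disp(sweep(opos[seq_len(placed), , drop = FALSE], 2L, p, "-"),
                     box)
      if (min(rowSums(d * d)) < min_sep^2) next
    }
    placed <- placed + 1L
    opos[placed, ] <- p
  }
  a_hoh <- deg2rad(HOH_DEG)
  pos <- NULL; molid <- integer(0)
  for (k in seq_len(n_molecules)) {
    u <- uv(stats::rnorm(3L))
    w <- uv(stats::rnorm(3L))
    perp <- w - sum(w * u) * u
    while (sqrt(sum(perp * perp)) < 1e-6) {
      w <- uv(stats::rnorm(3L)); perp <- w - sum(w * u) * u
    }
    perp <- uv(perp)
    h1 <- opos[k, ] + OH_LEN * u
    h2 <- opos[k, ] + OH_LEN * (cos(a_hoh) * u + sin(a_hoh) * perp)
    pos <- rbind(pos, opos[k, ], h1, h2)
    molid <- c(molid, rep(k, 3L))
  }
  atoms <- atom_table(name = rep(c("OW", "HW1", "HW2"), n_molecules),
                      element = rep(c("O", "H", "H"), n_molecules),
                      resname = rep("SOL", 3L * n_molecules),
                      resid = molid, molid = molid)
  md_trajectory(atoms, list(md_frame(1L, pos, box)))
}
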