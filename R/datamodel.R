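# Core containers: simulation box, per-atom metadata, frames/trajectories and
# the mutable per-atom attribute store that graph executions read and write.
# Internal unit is the angstrom (velocities in angstrom/ps); indices are
# 1-based throughout, file formats keep native numbering at I/O boundaries.

#' Orthorhombic simulation box
#'
#' @param lengths Numeric length-3 vector of box edge lengths in angstrom.
#' @param periodic Logical length-3 vector; `TRUE` marks a periodic axis.
#'   Periodic axes must have strictly positive lengths. Triclinic cells are
#'   not supported.
#' @return An object of class `md_box`.
#' @export
md_box <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  lengths <- as.numeric(lengths)
  periodic <- as.logical(periodic)
  if (length(lengths) != 3L || length(periodic) != 3L)
    stop("box requires 3 lengths and 3 periodic flags")
  if (any(!is.finite(lengths)))
    stop("box lengths must be finite")
  if (any(is.na(periodic)))
    stop("box periodic flags must be TRUE/FALSE")
  if (any(periodic & lengths <= 0))
    stop("periodic box lengths must be > 0")
  structure(list(lengths = lengths, periodic = periodic), class = "md_box")
}

#' Per-atom metadata table
#'
#' @param name,element,resname Character vectors, one entry per atom.
#' @param resid,molid Integer vectors, one entry per atom; `molid` groups
#'   atoms into molecules and need not be contiguous.
#' @return A `data.frame` of class `md_atoms` with one row per atom.
#' @export
atom_table <- function(name, element = NULL, resname = NULL, resid = NULL,
                       molid = NULL) {
  n <- length(name)
  if (is.null(element)) element <- toupper(sub("[^A-Za-z].*$", "", name))
  if (is.null(resname)) resname <- rep("UNK", n)
  if (is.null(resid)) resid <- rep(1L, n)
  if (is.null(molid)) molid <- as.integer(resid)
  at <- data.frame(name = as.character(name),
                   element = as.character(element),
                   resname = as.character(resname),
                   resid = as.integer(resid),
                   molid = as.integer(molid),
                   stringsAsFactors = FALSE)
  if (any(lengths(list(element, resname, resid, molid)) != n))
    stop("all atom table columns must have one entry per atom")
  if (any(at$molid < 0L)) stop("molecule ids must be non-negative")
  class(at) <- c("md_atoms", "data.frame")
  at
}

#' Single trajectory frame
#'
#' @param index 1-based frame index, unique within a trajectory.
#' @param positions n_atoms x 3 numeric matrix, angstrom.
#' @param box An [md_box].
#' @param velocities Optional n_atoms x 3 matrix, angstrom/ps.
#' @param attrs Named list of per-atom numeric vectors imported with the
#'   frame (e.g. extra trajectory columns); refreshed into the attribute
#'   store at the start of each frame execution.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(index, positions, box, velocities = NULL, attrs = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (!inherits(box, "md_box")) stop("box must be an md_box")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions)))
      stop("velocities must match positions in shape")
  }
  if (length(attrs) && any(vapply(attrs, length, 0L) != nrow(positions)))
    stop("frame attributes must have one value per atom")
  structure(list(index = as.integer(index), positions = positions,
                 velocities = velocities, box = box, attrs = attrs),
            class = "md_frame")
}

#' Trajectory: shared atom table plus an ordered sequence of frames
#'
#' @param atoms An [atom_table].
#' @param frames List of [md_frame] objects sharing `nrow(atoms)` atoms.
#' @param bonds Optional m x 2 integer matrix of static bonds (1-based,
#'   i < j, deduplicated).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, frames, bonds = NULL) {
  if (!inherits(atoms, "md_atoms")) stop("atoms must be an atom_table")
  n <- nrow(atoms)
  if (!length(frames)) stop("trajectory needs at least one frame")
  for (fr in frames) {
    if (!inherits(fr, "md_frame")) stop("frames must be md_frame objects")
    if (nrow(fr$positions) != n)
      stop("all frames must share the trajectory's atom count")
  }
  idx <- vapply(frames, function(f) f$index, 0L)
  if (anyDuplicated(idx)) stop("frame indices must be unique")
  bonds <- normalize_pairs(bonds, n, what = "bond")
  structure(list(atoms = atoms, frames = frames, bonds = bonds),
            class = "md_trajectory")
}

# canonicalize an m x 2 index pair list: i < j, in range, unique, sorted
normalize_pairs <- function(pairs, n_atoms, what = "pair") {
  if (is.null(pairs) || NROW(pairs) == 0L)
    return(matrix(integer(0), 0L, 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs < 1L) || any(pairs > n_atoms))
    stop(sprintf("%s index out of range 1..%d", what, n_atoms))
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop(sprintf("%s cannot join an atom to itself", what))
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, %d static bonds\n",
              nrow(x$atoms), length(x$frames), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(traj) nrow(traj$atoms)
n_frames <- function(traj) length(traj$frames)

# ---------------------------------------------------------------------------
# Periodic geometry

#' Minimum-image displacement between two points
#'
#' Returns the displacement `q - p` with each periodic component wrapped into
#' `[-L/2, L/2)` (a tie at exactly `L/2` maps to `-L/2`); non-periodic axes
#' are left unwrapped.
#'
#' @param p,q Numeric length-3 coordinates in angstrom.
#' @param box An [md_box].
#' @return Numeric length-3 displacement.
#' @export
minimum_image <- function(p, q, box) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L || any(!is.finite(c(p, q))))
    stop("minimum_image requires finite length-3 coordinates")
  drop(wrap_disp(matrix(q - p, 1L, 3L), box))
}

# vectorized wrap of an m x 3 displacement matrix into the minimum image
wrap_disp <- function(d, box) {
  for (k in 1:3) {
    if (box$periodic[k]) {
      L <- box$lengths[k]
      d[, k] <- d[, k] - L * floor(d[, k] / L + 0.5)
    }
  }
  d
}

# minimum-image displacements from point p to each row of pos
disp_to_all <- function(p, pos, box) {
  d <- cbind(pos[, 1L] - p[1L], pos[, 2L] - p[2L], pos[, 3L] - p[3L])
  wrap_disp(d, box)
}

# ---------------------------------------------------------------------------
# Atom selection

#' Select atoms by a small metadata expression
#'
#' Grammar: clauses `name=X`, `resname=Y`, `element=Z`, combined with `&`
#' (and, binds tighter) and `|` (or). After a clause, a bare `|`-separated
#' token re-uses the previous key, so `resname=SOL|HOH|WAT` selects any of
#' the three residue names.
#'
#' @param x An [md_trajectory] or [atom_table].
#' @param expr Selection string.
#' @return Sorted unique 1-based atom indices (possibly empty).
#' @export
select_atoms <- function(x, expr) {
  atoms <- if (inherits(x, "md_trajectory")) x$atoms else x
  if (!inherits(atoms, "md_atoms")) stop("select_atoms needs a trajectory or atom table")
  toks <- selection_tokens(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$last_key <- NULL
  mask <- sel_parse_or(st, atoms)
  if (st$pos <= length(st$toks))
    stop(sprintf("selection parse error: unexpected token '%s'", st$toks[st$pos]))
  sort(which(mask))
}

selection_tokens <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr)))
    stop("selection expression must be a non-empty string")
  toks <- strsplit(expr, "(?=[&|=])|(?<=[&|=])", perl = TRUE)[[1]]
  toks <- trimws(toks)
  toks[nzchar(toks)]
}

sel_peek <- function(st, k = 0L) {
  i <- st$pos + k
  if (i <= length(st$toks)) st$toks[i] else NA_character_
}

sel_parse_or <- function(st, atoms) {
  mask <- sel_parse_and(st, atoms)
  while (identical(sel_peek(st), "|")) {
    st$pos <- st$pos + 1L
    mask <- mask | sel_parse_and(st, atoms)
  }
  mask
}

sel_parse_and <- function(st, atoms) {
  mask <- sel_parse_clause(st, atoms)
  while (identical(sel_peek(st), "&")) {
    st$pos <- st$pos + 1L
    mask <- mask & sel_parse_clause(st, atoms)
  }
  mask
}

sel_keys <- c(name = "name", resname = "resname", element = "element")

sel_parse_clause <- function(st, atoms) {
  key <- sel_peek(st)
  if (is.na(key)) stop("selection parse error: expected a clause, found end of input")
  if (identical(sel_peek(st, 1L), "=")) {
    if (!key %in% names(sel_keys))
      stop(sprintf("selection parse error: unknown key '%s'", key))
    val <- sel_peek(st, 2L)
    if (is.na(val) || val %in% c("&", "|", "="))
      stop(sprintf("selection parse error: missing value for key '%s'", key))
    st$pos <- st$pos + 3L
    st$last_key <- key
  } else if (!is.null(st$last_key) && !key %in% c("&", "|", "=")) {
    # bare token after `|`: alternative value for the previous key
    val <- key
    key <- st$last_key
    st$pos <- st$pos + 1L
  } else {
    stop(sprintf("selection parse error: unexpected token '%s'", key))
  }
  atoms[[sel_keys[[key]]]] == val
}

# ---------------------------------------------------------------------------
# Attribute store

#' Mutable per-atom attribute store
#'
#' Named per-atom numeric arrays that graph nodes may read and write at any
#' point during execution; values persist across frames, which is the
#' mechanism carrying state in recurrent graphs. Attributes marked recorded
#' get one history snapshot per executed frame.
#'
#' @param n_atoms Number of atoms each attribute array must match.
#' @return An environment of class `attribute_store`.
#' @export
attribute_store <- function(n_atoms) {
  st <- new.env(parent = emptyenv())
  st$n_atoms <- as.integer(n_atoms)
  st$values <- new.env(parent = emptyenv())
  st$recorded <- new.env(parent = emptyenv())
  st$history <- new.env(parent = emptyenv())
  class(st) <- "attribute_store"
  st
}

#' Declare an attribute with an initial value
#'
#' @param store An [attribute_store].
#' @param name Attribute name.
#' @param init Scalar (broadcast) or per-atom numeric initial value.
#' @param record If `TRUE`, [attr_snapshot()] keeps a per-frame history copy.
#' @export
attr_declare <- function(store, name, init = 0, record = FALSE) {
  init <- as.numeric(init)
  if (length(init) == 1L) init <- rep(init, store$n_atoms)
  if (length(init) != store$n_atoms)
    stop(sprintf("attribute '%s': initial value must be scalar or length %d",
                 name, store$n_atoms))
  store$values[[name]] <- init
  store$recorded[[name]] <- isTRUE(record)
  if (isTRUE(record) && is.null(store$history[[name]]))
    store$history[[name]] <- list()
  invisible(store)
}

#' Read a per-atom attribute
#'
#' Reading a name that was never declared implicitly declares it as all
#' zeros (recurrent graphs read their state attribute on the first frame
#' before anything has written it).
#'
#' @inheritParams attr_declare
#' @return Per-atom numeric vector.
#' @export
attr_get <- function(store, name) {
  if (is.null(store$values[[name]])) attr_declare(store, name, 0)
  store$values[[name]]
}

#' Write a per-atom attribute
#'
#' @inheritParams attr_declare
#' @param values Numeric vector of length `n_atoms`.
#' @export
attr_set <- function(store, name, values) {
  values <- as.numeric(values)
  if (length(values) != store$n_atoms)
    stop(sprintf("attribute '%s': expected %d values, got %d",
                 name, store$n_atoms, length(values)))
  if (is.null(store$recorded[[name]])) store$recorded[[name]] <- FALSE
  store$values[[name]] <- values
  invisible(store)
}

#' Snapshot the current value of a recorded attribute for one frame
#'
#' @inheritParams attr_declare
#' @param frame_index Frame index keying the history entry; re-snapshotting
#'   a frame overwrites its entry.
#' @export
attr_snapshot <- function(store, name, frame_index) {
  if (isTRUE(store$recorded[[name]])) {
    h <- store$history[[name]]
    if (is.null(h)) h <- list()
    h[[as.character(frame_index)]] <- attr_get(store, name)
    store$history[[name]] <- h
  }
  invisible(store)
}

#' Names of declared attributes
#' @inheritParams attr_declare
#' @export
attr_names <- function(store) sort(ls(store$values))

#' Recorded history of an attribute
#' @inheritParams attr_declare
#' @return Named list of per-atom vectors keyed by frame index (as written,
#'   in visit order).
#' @export
attr_history <- function(store, name) {
  h <- store$history[[name]]
  if (is.null(h)) list() else h
}
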