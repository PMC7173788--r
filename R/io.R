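# Trajectory readers/writers behind a pluggable registry. All parsing is
# strict: malformed input errors carry the offending line number. GRO files
# are in nm and converted to angstrom (x10) at read time.

.reader_registry <- new.env(parent = emptyenv())

reg_key <- function(name) tolower(sub("^\\.", "", name))

#' Register a trajectory reader for a format name / file extension
#'
#' @param name Format name or extension (case-insensitive, leading dot
#'   ignored). Registering an existing key replaces it.
#' @param fn Function `(path) -> md_trajectory`.
#' @export
register_reader <- function(name, fn) {
  if (!is.function(fn)) stop("reader must be a function(path)")
  assign(reg_key(name), fn, envir = .reader_registry)
  invisible(NULL)
}

supported_formats <- function() sort(ls(.reader_registry))

#' Detect the format of a trajectory file
#'
#' Extension lookup in the reader registry, with a content sniff fallback
#' for unknown extensions.
#'
#' @param path File path.
#' @return Format name (a registry key).
#' @export
detect_format <- function(path) {
  ext <- reg_key(tools::file_ext(path))
  if (nzchar(ext) && !is.null(.reader_registry[[ext]])) return(ext)
  if (file.exists(path)) {
    head <- readLines(path, n = 20L, warn = FALSE)
    if (any(grepl("^ITEM: TIMESTEP", head))) return("lammpstrj")
    if (any(grepl("^(ATOM  |HETATM|CRYST1|MODEL )", head))) return("pdb")
  }
  stop(sprintf("unknown trajectory format for '%s' (supported: %s)",
               path, paste(supported_formats(), collapse = ", ")))
}

#' Read a trajectory, dispatching on format
#'
#' @param path File path.
#' @param format Optional registry key; detected from the file when `NULL`.
#' @return An [md_trajectory].
#' @export
read_trajectory <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(format)) format <- detect_format(path)
  fn <- .reader_registry[[reg_key(format)]]
  if (is.null(fn))
    stop(sprintf("no reader registered for format '%s' (supported: %s)",
                 format, paste(supported_formats(), collapse = ", ")))
  fn(path)
}

io_stop <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

num_field <- function(s, path, line, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    io_stop(path, line, sprintf("non-numeric %s field '%s'", what, trimws(s[is.na(v)][1L])))
  v
}

# ---------------------------------------------------------------------------
# GRO (fixed-column GROMACS coordinate format, nm; frames concatenated)

#' Read a GROMACS GRO file (one or more concatenated frames)
#'
#' Coordinates (nm) and box vectors are converted to angstrom; velocities
#' (nm/ps) to angstrom/ps. Only orthorhombic boxes (first three box values)
#' are supported.
#'
#' @param path File path.
#' @return An [md_trajectory].
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); atoms <- NULL
  ln <- 1L; fidx <- 0L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    if (ln + 1L > length(lines)) io_stop(path, ln, "truncated frame header")
    nat <- suppressWarnings(as.integer(trimws(lines[ln + 1L])))
    if (is.na(nat) || nat < 1L) io_stop(path, ln + 1L, "invalid atom count line")
    if (ln + 1L + nat + 1L > length(lines))
      io_stop(path, min(length(lines), ln + 2L + nat),
              sprintf("expected %d atom lines plus a box line", nat))
    first <- ln + 2L
    rec <- lines[first:(first + nat - 1L)]
    short <- which(nchar(rec) < 44L)
    if (length(short))
      io_stop(path, first + short[1L] - 1L, "atom record shorter than 44 columns")
    bad <- which(!grepl("^[ 0-9.eE+-]+$", substr(rec, 21L, 44L)))
    if (length(bad))
      io_stop(path, first + bad[1L] - 1L, "non-numeric coordinate field")
    resid <- as.integer(num_field(substr(rec, 1L, 5L), path, first, "residue id"))
    resname <- trimws(substr(rec, 6L, 10L))
    name <- trimws(substr(rec, 11L, 15L))
    pos <- 10 * cbind(num_field(substr(rec, 21L, 28L), path, first, "x"),
                      num_field(substr(rec, 29L, 36L), path, first, "y"),
                      num_field(substr(rec, 37L, 44L), path, first, "z"))
    vel <- NULL
    if (all(nchar(rec) >= 68L)) {
      vel <- 10 * cbind(num_field(substr(rec, 45L, 52L), path, first, "vx"),
                        num_field(substr(rec, 53L, 60L), path, first, "vy"),
                        num_field(substr(rec, 61L, 68L), path, first, "vz"))
    }
    box_ln <- first + nat
    bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[box_ln]), "\\s+")[[1]]))
    if (length(bv) < 3L || any(is.na(bv[1:3])))
      io_stop(path, box_ln, "invalid box line")
    if (length(bv) >= 9L && any(bv[4:9] != 0))
      io_stop(path, box_ln, "triclinic boxes are not supported")
    L <- 10 * bv[1:3]
    box <- if (all(L > 0)) md_box(L) else
      md_box(pmax(L, 1), periodic = c(FALSE, FALSE, FALSE))
    fidx <- fidx + 1L
    if (is.null(atoms))
      atoms <- atom_table(name = name, resname = resname, resid = resid)
    else if (nat != nrow(atoms))
      io_stop(path, ln + 1L, "atom count differs between frames")
    frames[[fidx]] <- md_frame(fidx, pos, box, velocities = vel)
    ln <- box_ln + 1L
    while (ln <= length(lines) && !nzchar(trimws(lines[ln]))) ln <- ln + 1L
  }
  if (is.null(atoms)) stop(sprintf("%s: no frames found", path))
  md_trajectory(atoms, frames)
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Positions are written in nm at the format's fixed precision (3 decimals,
#' i.e. 0.01 angstrom); velocities, when present, in nm/ps.
#'
#' @param traj An [md_trajectory].
#' @param path Output path.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  at <- traj$atoms
  for (fr in traj$frames) {
    writeLines(sprintf("mdflow frame %d", fr$index), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    p <- fr$positions / 10
    if (is.null(fr$velocities)) {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         at$resid %% 100000L, at$resname, at$name,
                         seq_len(nrow(at)) %% 100000L,
                         p[, 1L], p[, 2L], p[, 3L]), con)
    } else {
      v <- fr$velocities / 10
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                         at$resid %% 100000L, at$resname, at$name,
                         seq_len(nrow(at)) %% 100000L,
                         p[, 1L], p[, 2L], p[, 3L],
                         v[, 1L], v[, 2L], v[, 3L]), con)
    }
    L <- if (all(fr$box$periodic)) fr$box$lengths / 10 else c(0, 0, 0)
    writeLines(sprintf("%10.5f%10.5f%10.5f", L[1L], L[2L], L[3L]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# PDB (ATOM/HETATM records; MODEL/ENDMDL frames; CRYST1 box; CONECT bonds)

#' Read a PDB file
#'
#' MODEL/ENDMDL blocks delimit frames (a file without MODEL records is a
#' single frame). CONECT records become deduplicated static bonds. A missing
#' CRYST1 record yields a non-periodic box. Blank element columns fall back
#' to the leading alphabetic characters of the atom name.
#'
#' @param path File path.
#' @return An [md_trajectory].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cryst <- NULL
  conect <- list()
  models <- list(); cur <- NULL
  meta <- NULL
  add_model <- function(cur) { if (!is.null(cur) && length(cur$rows)) models[[length(models) + 1L]] <<- cur }
  cur <- list(rows = list())
  for (i in seq_along(lines)) {
    l <- lines[i]
    tag <- substr(l, 1L, 6L)
    if (tag == "CRYST1") {
      abc <- num_field(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)),
                       path, i, "CRYST1")
      cryst <- abc
    } else if (tag == "MODEL ") {
      add_model(cur); cur <- list(rows = list())
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (nchar(l) < 54L) io_stop(path, i, "ATOM record shorter than coordinate columns")
      xyz <- num_field(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)),
                       path, i, "coordinate")
      name <- trimws(substr(l, 13, 16))
      elem <- if (nchar(l) >= 78L) trimws(substr(l, 77, 78)) else ""
      if (!nzchar(elem)) elem <- toupper(sub("[^A-Za-z].*$", "", sub("^[0-9]*", "", name)))
      cur$rows[[length(cur$rows) + 1L]] <- list(
        serial = suppressWarnings(as.integer(trimws(substr(l, 7, 11)))),
        name = name, elem = elem,
        resname = trimws(substr(l, 18, 20)),
        resid = suppressWarnings(as.integer(trimws(substr(l, 23, 26)))),
        xyz = xyz)
    } else if (tag == "CONECT") {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]]))
      f <- f[!is.na(f)]
      if (length(f) >= 2L)
        conect[[length(conect) + 1L]] <- cbind(f[1L], f[-1L])
    }
  }
  add_model(cur)
  if (!length(models)) stop(sprintf("%s: no ATOM/HETATM records found", path))
  n <- length(models[[1]]$rows)
  rows <- models[[1]]$rows
  resid <- vapply(rows, function(r) if (is.na(r$resid)) 1L else r$resid, 0L)
  atoms <- atom_table(name = vapply(rows, `[[`, "", "name"),
                      element = vapply(rows, `[[`, "", "elem"),
                      resname = vapply(rows, `[[`, "", "resname"),
                      resid = resid)
  serial <- vapply(rows, function(r) r$serial, 0L)
  frames <- vector("list", length(models))
  for (m in seq_along(models)) {
    rs <- models[[m]]$rows
    if (length(rs) != n)
      stop(sprintf("%s: MODEL %d has %d atoms, expected %d", path, m, length(rs), n))
    pos <- do.call(rbind, lapply(rs, `[[`, "xyz"))
    box <- if (!is.null(cryst) && all(cryst > 0)) md_box(cryst) else
      md_box(pmax(apply(pos, 2L, function(v) diff(range(v))), 1),
             periodic = c(FALSE, FALSE, FALSE))
    frames[[m]] <- md_frame(m, pos, box)
  }
  bonds <- NULL
  if (length(conect)) {
    cm <- do.call(rbind, conect)
    idx <- match(cm, serial)
    if (any(is.na(idx))) stop(sprintf("%s: CONECT references unknown atom serial", path))
    bonds <- matrix(idx, ncol = 2L)
  }
  md_trajectory(atoms, frames, bonds = bonds)
}

#' Write one frame of a trajectory as a PDB file with colors as B-factors
#'
#' Visualization-state export helper: the per-atom color scalar in `[0,1]`
#' is placed in the B-factor column so external viewers can map it.
#'
#' @param traj An [md_trajectory].
#' @param frame_index Which frame to write.
#' @param colors Per-atom numeric vector in `[0,1]` (default all 0).
#' @param path Output path.
#' @export
write_pdb_colored <- function(traj, frame_index, colors = NULL, path) {
  fr <- traj$frames[[frame_index]]
  at <- traj$atoms
  if (is.null(colors)) colors <- numeric(nrow(at))
  if (length(colors) != nrow(at)) stop("one color per atom required")
  con <- file(path, "w"); on.exit(close(con))
  if (all(fr$box$periodic))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       fr$box$lengths[1L], fr$box$lengths[2L], fr$box$lengths[3L]), con)
  writeLines(sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(at)) %% 100000L, substr(at$name, 1L, 4L),
                     substr(at$resname, 1L, 3L), at$resid %% 10000L,
                     fr$positions[, 1L], fr$positions[, 2L], fr$positions[, 3L],
                     1, pmin(pmax(colors, 0), 1), substr(at$element, 1L, 2L)), con)
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# LAMMPS text dump

#' Read a LAMMPS text dump file
#'
#' Requires `ITEM: ATOMS` column names including `id` and either `x y z` or
#' scaled `xs ys zs` (unscaled by the per-frame box). Atoms are sorted by id.
#' Columns beyond id/type/mol/positions are imported as per-frame recorded
#' attributes.
#'
#' @param path File path.
#' @return An [md_trajectory].
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; fidx <- 0L
  frames <- list(); atoms <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^ITEM: TIMESTEP", lines[i]))
      io_stop(path, i, "expected 'ITEM: TIMESTEP'")
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2L]))
      io_stop(path, i + 2L, "expected 'ITEM: NUMBER OF ATOMS'")
    nat <- as.integer(trimws(lines[i + 3L]))
    if (is.na(nat) || nat < 1L) io_stop(path, i + 3L, "invalid atom count")
    if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4L]))
      io_stop(path, i + 4L, "expected 'ITEM: BOX BOUNDS'")
    if (grepl("xy|xz|yz", lines[i + 4L]))
      io_stop(path, i + 4L, "triclinic boxes are not supported")
    bounds <- t(vapply(1:3, function(k) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 4L + k]), "\\s+")[[1]]))
      if (length(v) < 2L || any(is.na(v[1:2]))) io_stop(path, i + 4L + k, "invalid box bounds")
      v[1:2]
    }, numeric(2L)))
    periodic <- grepl("pp", lines[i + 4L])
    hdr_ln <- i + 8L
    if (!grepl("^ITEM: ATOMS", lines[hdr_ln]))
      io_stop(path, hdr_ln, "expected 'ITEM: ATOMS'")
    cols <- strsplit(trimws(sub("^ITEM: ATOMS", "", lines[hdr_ln])), "\\s+")[[1]]
    if (!"id" %in% cols) io_stop(path, hdr_ln, "missing required column 'id'")
    scaled <- all(c("xs", "ys", "zs") %in% cols)
    if (!scaled && !all(c("x", "y", "z") %in% cols))
      io_stop(path, hdr_ln, "missing required columns 'x y z' (or 'xs ys zs')")
    if (hdr_ln + nat > length(lines))
      io_stop(path, length(lines), sprintf("expected %d atom lines", nat))
    rec <- lines[(hdr_ln + 1L):(hdr_ln + nat)]
    fields <- strsplit(trimws(rec), "\\s+")
    widths <- lengths(fields)
    if (any(widths != length(cols)))
      io_stop(path, hdr_ln + which(widths != length(cols))[1L],
              sprintf("expected %d fields per atom line", length(cols)))
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))), nrow = nat,
                ncol = length(cols), byrow = TRUE)
    if (any(is.na(m)))
      io_stop(path, hdr_ln + which(apply(is.na(m), 1L, any))[1L], "non-numeric field")
    colnames(m) <- cols
    ord <- order(m[, "id"])
    m <- m[ord, , drop = FALSE]
    L <- bounds[, 2L] - bounds[, 1L]
    if (scaled) {
      pos <- cbind(bounds[1, 1] + m[, "xs"] * L[1],
                   bounds[2, 1] + m[, "ys"] * L[2],
                   bounds[3, 1] + m[, "zs"] * L[3])
    } else {
      pos <- m[, c("x", "y", "z"), drop = FALSE]
    }
    box <- md_box(pmax(L, 1), periodic = periodic & L > 0)
    known <- c("id", "type", "mol", "x", "y", "z", "xs", "ys", "zs",
               "vx", "vy", "vz")
    vel <- if (all(c("vx", "vy", "vz") %in% cols))
      m[, c("vx", "vy", "vz"), drop = FALSE] else NULL
    attrs <- list()
    for (cn in setdiff(cols, known)) attrs[[cn]] <- unname(m[, cn])
    fidx <- fidx + 1L
    if (is.null(atoms)) {
      type <- if ("type" %in% cols) as.character(as.integer(m[, "type"])) else rep("1", nat)
      molid <- if ("mol" %in% cols) as.integer(m[, "mol"]) else seq_len(nat)
      atoms <- atom_table(name = type, element = type,
                          resname = type, resid = molid, molid = molid)
    } else if (nat != nrow(atoms)) {
      io_stop(path, i + 3L, "atom count differs between frames")
    }
    frames[[fidx]] <- md_frame(fidx, pos, box, velocities = vel, attrs = attrs)
    i <- hdr_ln + nat + 1L
  }
  if (is.null(atoms)) stop(sprintf("%s: no frames found", path))
  md_trajectory(atoms, frames)
}

# ---------------------------------------------------------------------------
# SSV: generic space-separated values with a role-declaring header.
# Reserved column labels: x y z vx vy vz name resname resid; any other label
# is a per-atom attribute recorded per frame. Frames are blank-line-separated
# blocks under a single header line.

ssv_reserved <- c("x", "y", "z", "vx", "vy", "vz", "name", "resname", "resid")

#' Read a generic space-separated values (SSV) trajectory
#'
#' Line 1 declares one role per column (reserved: `x y z vx vy vz name
#' resname resid`; anything else becomes a recorded per-atom attribute, e.g.
#' orientation columns `rotx roty rotz`). Exactly one each of x/y/z is
#' required. Subsequent lines hold one atom each; blank lines separate
#' frames.
#'
#' @param path File path.
#' @return An [md_trajectory] (non-periodic box spanning the data extent).
#' @export
read_ssv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (anyDuplicated(header[!header %in% ssv_reserved]))
    io_stop(path, 1L, "duplicate attribute labels in header")
  for (ax in c("x", "y", "z"))
    if (sum(header == ax) != 1L)
      io_stop(path, 1L, sprintf("header must contain exactly one '%s' column", ax))
  ncol_h <- length(header)
  blocks <- list(); cur <- list(); cur_start <- NA_integer_
  flush <- function() {
    if (length(cur)) blocks[[length(blocks) + 1L]] <<- list(rows = cur, start = cur_start)
    cur <<- list(); cur_start <<- NA_integer_
  }
  for (i in seq_along(lines)[-1L]) {
    l <- trimws(lines[i])
    if (!nzchar(l)) { flush(); next }
    f <- strsplit(l, "\\s+")[[1]]
    if (length(f) != ncol_h)
      io_stop(path, i, sprintf("row has %d fields, header declares %d",
                               length(f), ncol_h))
    if (!length(cur)) cur_start <- i
    cur[[length(cur) + 1L]] <- f
  }
  flush()
  if (!length(blocks)) stop(sprintf("%s: no atom rows found", path))
  nat <- length(blocks[[1]]$rows)
  frames <- vector("list", length(blocks))
  atoms <- NULL
  attr_cols <- setdiff(header, ssv_reserved)
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]$rows
    if (length(rows) != nat)
      io_stop(path, blocks[[b]]$start,
              sprintf("frame %d has %d atoms, expected %d", b, length(rows), nat))
    m <- matrix(unlist(rows), nrow = nat, ncol = ncol_h, byrow = TRUE)
    colnames(m) <- make.unique(header)
    numcol <- function(lbl) num_field(m[, lbl], path, blocks[[b]]$start, lbl)
    pos <- cbind(numcol("x"), numcol("y"), numcol("z"))
    vel <- if (all(c("vx", "vy", "vz") %in% header))
      cbind(numcol("vx"), numcol("vy"), numcol("vz")) else NULL
    attrs <- list()
    for (a in attr_cols) attrs[[a]] <- numcol(a)
    box <- md_box(pmax(apply(pos, 2L, function(v) diff(range(v))), 1),
                  periodic = c(FALSE, FALSE, FALSE))
    frames[[b]] <- md_frame(b, pos, box, velocities = vel, attrs = attrs)
    if (is.null(atoms)) {
      atoms <- atom_table(
        name = if ("name" %in% header) m[, "name"] else paste0("A", seq_len(nat)),
        resname = if ("resname" %in% header) m[, "resname"] else NULL,
        resid = if ("resid" %in% header)
          as.integer(numcol("resid")) else NULL)
    }
  }
  md_trajectory(atoms, frames)
}

#' Write a trajectory in SSV format
#'
#' Canonical formatting (`%.6f` for all numeric columns), so a
#' write/read/write cycle is byte-identical and positions round-trip to
#' better than 1e-4 angstrom.
#'
#' @param traj An [md_trajectory].
#' @param attr_names Character vector of per-frame attribute names to export
#'   as extra columns (must be present in every frame's `attrs`, or in
#'   `history` a caller merged into the frames).
#' @param path Output path.
#' @export
write_ssv <- function(traj, attr_names = character(0), path) {
  at <- traj$atoms
  for (a in attr_names) {
    if (a %in% ssv_reserved)
      stop(sprintf("attribute name '%s' collides with a reserved SSV column", a))
    for (fr in traj$frames)
      if (is.null(fr$attrs[[a]]))
        stop(sprintf("unknown attribute '%s' (frame %d has no such column)",
                     a, fr$index))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("name", "resname", "resid", "x", "y", "z", attr_names),
                   collapse = " "), con)
  first <- TRUE
  for (fr in traj$frames) {
    if (!first) writeLines("", con)
    first <- FALSE
    cols <- list(at$name, at$resname, sprintf("%d", at$resid),
                 sprintf("%.6f", fr$positions[, 1L]),
                 sprintf("%.6f", fr$positions[, 2L]),
                 sprintf("%.6f", fr$positions[, 3L]))
    for (a in attr_names) cols[[length(cols) + 1L]] <- sprintf("%.6f", fr$attrs[[a]])
    writeLines(do.call(paste, cols), con)
  }
  invisible(path)
}

register_builtin_readers <- function() {
  register_reader("gro", read_gro)
  register_reader("pdb", read_pdb)
  register_reader("ssv", read_ssv)
  register_reader("lammpstrj", read_lammps_dump)
  register_reader("dump", read_lammps_dump)
}
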