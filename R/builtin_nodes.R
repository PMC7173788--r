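# Built-in operation nodes: trajectory inputs, attribute access, and
# visualization-state modification. Visualization here is data, not pixels:
# a per-atom color scalar in [0,1] (consumers map it blue -> red), a radius
# scale, a visibility mask, extra bonds and a camera center, all exportable.

#' Element-wise combination of two per-atom attributes
#'
#' @param a,b Numeric vectors of equal length.
#' @param mode One of `"max"`, `"min"`, `"sum"`, `"mean"`.
#' @return Combined numeric vector.
#' @export
combine_attributes <- function(a, b, mode = c("max", "min", "sum", "mean")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("attribute lengths differ")
  switch(mode,
         max = pmax(a, b),
         min = pmin(a, b),
         sum = a + b,
         mean = (a + b) / 2)
}

#' Visibility mask from an attribute range
#'
#' Closed interval: values equal to either bound stay visible.
#'
#' @param values Per-atom numeric vector.
#' @param lo,hi Range bounds, `lo <= hi` (infinite bounds allowed).
#' @return Logical per-atom vector.
#' @export
show_range_mask <- function(values, lo = -Inf, hi = Inf) {
  if (lo > hi) stop("show range requires lo <= hi")
  values >= lo & values <= hi
}

#' Centroid of masked atoms
#'
#' Arithmetic mean of the positions where `mask != 0`; no periodic
#' unwrapping is attempted, so the masked set should not straddle a
#' periodic boundary.
#'
#' @param positions n x 3 matrix.
#' @param mask Per-atom numeric/logical mask with at least one nonzero.
#' @return Length-3 centroid.
#' @export
mask_centroid <- function(positions, mask) {
  sel <- which(mask != 0)
  if (!length(sel)) stop("mask selects no atoms")
  colMeans(positions[sel, , drop = FALSE])
}

register_builtin_node_kinds <- function() {
  register_node_kind(
    "positions", outputs = list(positions = port("float", 2)),
    fn = function(inputs, params, ctx) list(positions = ctx$frame$positions))

  register_node_kind(
    "velocities", outputs = list(velocities = port("float", 2)),
    fn = function(inputs, params, ctx) {
      if (is.null(ctx$frame$velocities)) stop("trajectory has no velocities")
      list(velocities = ctx$frame$velocities)
    })

  register_node_kind(
    "box",
    outputs = list(lengths = port("float", 1), periodic = port("int", 1)),
    fn = function(inputs, params, ctx)
      list(lengths = ctx$box$lengths, periodic = as.integer(ctx$box$periodic)))

  register_node_kind(
    "get_attribute", params = list(name = NULL),
    outputs = list(value = port("float", 1)),
    check = function(p) if (is.null(p$name)) "get_attribute needs a 'name' parameter" else character(0),
    fn = function(inputs, params, ctx) list(value = attr_get(ctx$store, params$name)))

  register_node_kind(
    "set_attribute", params = list(name = NULL),
    inputs = list(value = port("float", 1)),
    check = function(p) if (is.null(p$name)) "set_attribute needs a 'name' parameter" else character(0),
    fn = function(inputs, params, ctx) {
      attr_set(ctx$store, params$name, inputs$value)
      list()
    })

  register_node_kind(
    "combine_attributes", params = list(mode = "max"),
    inputs = list(a = port("float", 1), b = port("float", 1)),
    outputs = list(value = port("float", 1)),
    check = function(p) if (!p$mode %in% c("max", "min", "sum", "mean"))
      sprintf("unknown combine mode '%s'", p$mode) else character(0),
    fn = function(inputs, params, ctx)
      list(value = combine_attributes(inputs$a, inputs$b, params$mode)))

  register_node_kind(
    "extra_bonds", inputs = list(pairs = port("int", 2)),
    fn = function(inputs, params, ctx) {
      ctx$vis$extra_bonds <- normalize_pairs(inputs$pairs, ctx$n_atoms,
                                             what = "extra bond")
      list()
    })

  register_node_kind(
    "show_range", params = list(lo = -Inf, hi = Inf),
    inputs = list(values = port("float", 1)),
    check = function(p) if (p$lo > p$hi) "show_range requires lo <= hi" else character(0),
    fn = function(inputs, params, ctx) {
      ctx$vis$visible <- show_range_mask(inputs$values, params$lo, params$hi)
      list()
    })

  register_node_kind(
    "set_radius_scale", params = list(value = 1),
    inputs = list(values = port("float", 1)), optional = "values",
    fn = function(inputs, params, ctx) {
      v <- if (!is.null(inputs$values)) inputs$values else
        rep(params$value, ctx$n_atoms)
      if (length(v) == 1L) v <- rep(v, ctx$n_atoms)
      if (length(v) != ctx$n_atoms) stop("one radius scale per atom required")
      if (any(v <= 0)) stop("radius scale must be positive")
      ctx$vis$radius_scale <- v
      list()
    })

  register_node_kind(
    "set_camera_center", inputs = list(point = port("float", 1)),
    fn = function(inputs, params, ctx) {
      p <- as.numeric(inputs$point)
      if (length(p) != 3L || any(!is.finite(p)))
        stop("camera center must be a finite 3-vector")
      ctx$vis$camera_center <- p
      list()
    })

  register_node_kind(
    "plot_data", params = list(mode = "lines_accumulate"),
    inputs = list(y = port("float", 0)),
    check = function(p) if (!identical(p$mode, "lines_accumulate"))
      sprintf("unknown plot mode '%s'", p$mode) else character(0),
    fn = function(inputs, params, ctx) {
      y <- inputs$y
      if (length(y) != 1L) stop("plot_data takes a scalar input")
      id <- ctx$.node_id
      pe <- ctx$plots[[id]]
      if (is.null(pe)) {
        pe <- new.env(parent = emptyenv())
        assign(id, pe, envir = ctx$plots)
      }
      pe[[as.character(ctx$frame_index)]] <- as.numeric(y)
      list()
    })

  register_node_kind(
    "mask_centroid",
    inputs = list(positions = port("float", 2), mask = port("float", 1)),
    outputs = list(center = port("float", 1)),
    fn = function(inputs, params, ctx)
      list(center = mask_centroid(inputs$positions, inputs$mask)))
}

#' Export a plot-node series as CSV
#'
#' @param run An `mdflow_run`.
#' @param node_id Id of the plot node.
#' @param path Output path; header is `frame,value`, rows in visit order.
#' @export
write_plot_csv <- function(run, node_id, path) {
  s <- run$plots[[node_id]]
  if (is.null(s)) stop(sprintf("run has no plot series for node '%s'", node_id))
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export per-frame visualization state as JSON
#'
#' One file per visited frame (`vis_<frame>.json`) holding colors, radius
#' scales, visibility, extra bonds and the camera center.
#'
#' @param run An `mdflow_run`.
#' @param dir Output directory (created if needed).
#' @export
write_vis_state <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(run$vis_history)) {
    jsonlite::write_json(run$vis_history[[f]],
                         file.path(dir, sprintf("vis_%s.json", f)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
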