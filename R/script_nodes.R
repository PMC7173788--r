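# Script nodes: a plain R script becomes a graph node with no framework
# code in it. Variables exposed to the graph are declared by a comment
# annotation immediately preceding the variable's first assignment or use:
#
#   # @in xs : float[1]
#   # @out n : int[0]
#
# Everything else in the script stays invisible to the graph. Errors raised
# inside a script are reported with the original file's line numbers.

ann_re <- "^\\s*#\\s*@(in|out)\\s+([A-Za-z.][A-Za-z0-9._]*)\\s*:\\s*([A-Za-z]+)\\s*\\[\\s*([0-9]+)\\s*\\]\\s*$"
ann_like_re <- "^\\s*#\\s*@(in|out)\\b"

#' Parse the I/O annotations of a script
#'
#' @param path Path to an R script (or a character vector of source lines
#'   via `text`).
#' @param text Optional script text, overriding `path`.
#' @return A list of class `script_node_spec` with `inputs` and `outputs`
#'   (named lists of [port()]), `path` and `lines`.
#' @export
parse_annotations <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (!file.exists(path)) stop(sprintf("script not found: %s", path))
    readLines(path, warn = FALSE)
  }
  where <- if (is.null(path)) "<script>" else path
  inputs <- list(); outputs <- list()
  bases <- c("int", "float", "string")
  is_code <- function(l) nzchar(trimws(l)) && !grepl("^\\s*#", l)
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!grepl(ann_like_re, l)) next
    m <- regmatches(l, regexec(ann_re, l))[[1]]
    if (!length(m))
      stop(sprintf("%s:%d: malformed annotation (expected '@in|@out name : base[rank]')",
                   where, i))
    dir <- m[2]; nm <- m[3]; base <- m[4]; rank <- as.integer(m[5])
    if (!base %in% bases)
      stop(sprintf("%s:%d: unknown base type '%s' (expected int, float or string)",
                   where, i, base))
    if (nm %in% c(names(inputs), names(outputs)))
      stop(sprintf("%s:%d: duplicate annotation for variable '%s'", where, i, nm))
    # the annotation must sit directly above a statement (further annotation
    # lines may stack in between)
    j <- i + 1L
    while (j <= length(lines) && grepl(ann_like_re, lines[j])) j <- j + 1L
    if (j > length(lines) || !is_code(lines[j]))
      stop(sprintf("%s:%d: annotation for '%s' is not adjacent to a statement",
                   where, i, nm))
    p <- port(base, rank)
    if (dir == "in") inputs[[nm]] <- p else outputs[[nm]] <- p
  }
  if (!length(outputs))
    stop(sprintf("%s: node exposes no outputs", where))
  structure(list(inputs = inputs, outputs = outputs, path = path,
                 lines = lines),
            class = "script_node_spec")
}

# run a parsed script with the given input bindings; returns output bindings
run_script <- function(spec, input_values) {
  env <- new.env(parent = globalenv())
  for (nm in names(input_values))
    if (!is.null(input_values[[nm]])) assign(nm, input_values[[nm]], envir = env)
  exprs <- parse(text = spec$lines, keep.source = TRUE)
  refs <- attr(exprs, "srcref")
  for (k in seq_along(exprs)) {
    ln <- if (!is.null(refs) && k <= length(refs)) refs[[k]][1L] else NA_integer_
    tryCatch(eval(exprs[[k]], envir = env), error = function(e) {
      stop(sprintf("script error at line %s: %s",
                   ifelse(is.na(ln), "?", ln), conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- list()
  for (nm in names(spec$outputs)) {
    if (!exists(nm, envir = env, inherits = FALSE))
      stop(sprintf("script did not assign declared output '%s'", nm))
    out[[nm]] <- get(nm, envir = env, inherits = FALSE)
  }
  out
}

#' Create a graph node from an annotated script
#'
#' The node binds wired inputs into the script's namespace, runs the whole
#' script top to bottom, and reads the declared outputs back. Arrays are
#' copied in and out, so a script mutating an input never changes another
#' node's cached output.
#'
#' @param id Node id.
#' @param path Path to the annotated R script.
#' @return A graph node usable in [md_graph()].
#' @export
make_script_node <- function(id, path) {
  graph_node(id, "script", params = list(path = path))
}

register_script_kind <- function() {
  register_node_kind(
    "script",
    inputs = list(), outputs = list(),   # instance ports come from annotations
    params = list(path = NULL),
    fn = function(inputs, params, ctx) {
      spec <- parse_annotations(params$path)
      run_script(spec, inputs)
    })
}
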