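# Typed dataflow graph engine. A graph is a set of nodes with typed ports
# joined by connections (a DAG); recurrence is carried exclusively by the
# attribute store, which nodes read and write immediately, in topological
# order. Execution walks the trajectory forward or backward, caching every
# output port of every node at every frame.

# ---------------------------------------------------------------------------
# Port types

#' Port type: base type plus array rank
#'
#' @param base One of `"int"`, `"float"`, `"string"`.
#' @param rank Non-negative integer; 0 is a scalar, r >= 1 a variable-length
#'   array of that rank.
#' @return An object of class `mdflow_port`.
#' @export
port <- function(base = c("float", "int", "string"), rank = 0L) {
  base <- match.arg(base)
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 0L) stop("port rank must be a non-negative integer")
  structure(list(base = base, rank = rank), class = "mdflow_port")
}

#' Are two port types compatible (from -> to)?
#'
#' Identical types are compatible; `int` promotes to `float` at any rank;
#' rank mismatches are incompatible.
#'
#' @param from,to [port()] objects.
#' @export
port_compatible <- function(from, to) {
  if (from$rank != to$rank) return(FALSE)
  if (from$base == to$base) return(TRUE)
  from$base == "int" && to$base == "float"
}

port_str <- function(p) sprintf("%s[%d]", p$base, p$rank)

# ---------------------------------------------------------------------------
# Node kind registry

.node_kinds <- new.env(parent = emptyenv())

#' Register a node kind
#'
#' @param kind Kind name used by graphs.
#' @param inputs,outputs Named lists of [port()] declarations (order defines
#'   port order).
#' @param params Named list of default parameter values; a graph node's
#'   `params` override these.
#' @param fn Execution function `function(inputs, params, ctx)` returning a
#'   named list with one entry per output port (may be empty for pure state
#'   nodes). `ctx` carries `traj`, `frame`, `frame_index`, `n_atoms`,
#'   `store` (attribute store), `vis` (visualization state) and `plots`.
#' @param optional Character vector of input names that may stay unwired.
#' @param check Optional `function(params)` returning character diagnostics
#'   for invalid parameter values (used at validation time).
#' @export
register_node_kind <- function(kind, inputs = list(), outputs = list(),
                               params = list(), fn, optional = character(0),
                               check = NULL) {
  stopifnot(is.function(fn))
  for (p in c(inputs, outputs))
    if (!inherits(p, "mdflow_port")) stop("ports must be created with port()")
  if (anyDuplicated(names(inputs)) || anyDuplicated(names(outputs)))
    stop("port names must be unique per side")
  assign(kind, list(kind = kind, inputs = inputs, outputs = outputs,
                    params = params, fn = fn, optional = optional,
                    check = check),
         envir = .node_kinds)
  invisible(NULL)
}

node_kind <- function(kind) {
  k <- .node_kinds[[kind]]
  if (is.null(k)) stop(sprintf("unknown node kind '%s'", kind))
  k
}

node_kind_exists <- function(kind) !is.null(.node_kinds[[kind]])

#' Names of all registered node kinds
#' @export
node_kinds <- function() sort(ls(.node_kinds))

# ---------------------------------------------------------------------------
# Graph construction

#' Create a graph node
#'
#' @param id Unique node id within the graph.
#' @param kind Registered node kind (or `"script"` with a `path` parameter).
#' @param params Named list of parameter overrides.
#' @return A `list` describing the node. Script nodes derive their ports
#'   from the script's annotations at creation time.
#' @export
graph_node <- function(id, kind, params = list()) {
  nd <- list(id = as.character(id), kind = as.character(kind), params = params)
  if (identical(kind, "script")) {
    if (is.null(params$path)) stop("script nodes require a 'path' parameter")
    spec <- parse_annotations(params$path)
    nd$inputs <- spec$inputs
    nd$outputs <- spec$outputs
  }
  nd
}

#' Create a connection between two node ports
#'
#' @param from_id,from_port Source node id and output port name.
#' @param to_id,to_port Destination node id and input port name.
#' @export
connection <- function(from_id, from_port, to_id, to_port) {
  list(from = c(as.character(from_id), as.character(from_port)),
       to = c(as.character(to_id), as.character(to_port)))
}

#' Declare a graph-managed attribute
#'
#' @param name Attribute name.
#' @param init Initial value (scalar broadcast or per-atom vector).
#' @param record Snapshot the value after every executed frame?
#' @export
attr_decl <- function(name, init = 0, record = FALSE) {
  list(name = as.character(name), init = init, record = isTRUE(record))
}

#' Assemble a dataflow graph
#'
#' @param nodes List of [graph_node()] objects.
#' @param connections List of [connection()] objects.
#' @param attributes List of [attr_decl()] declarations.
#' @param direction `"forward"` (ascending frames) or `"backward"`.
#' @param frames Optional `c(first, last)` 1-based inclusive frame range.
#' @return An object of class `mdflow_graph`.
#' @export
md_graph <- function(nodes = list(), connections = list(),
                     attributes = list(), direction = "forward",
                     frames = NULL) {
  structure(list(nodes = nodes, connections = connections,
                 attributes = attributes,
                 execution = list(direction = direction, frames = frames)),
            class = "mdflow_graph")
}

node_ports <- function(nd, side) {
  if (!is.null(nd[[side]])) return(nd[[side]])   # instance ports (script nodes)
  if (!node_kind_exists(nd$kind)) return(list())
  node_kind(nd$kind)[[side]]
}

node_ids <- function(graph) vapply(graph$nodes, `[[`, "", "id")

find_node <- function(graph, id) {
  for (nd in graph$nodes) if (nd$id == id) return(nd)
  NULL
}

# ---------------------------------------------------------------------------
# Validation

#' Validate a graph
#'
#' Returns a character vector of diagnostics; an executable graph yields an
#' empty vector. Covers unknown node kinds, duplicate ids, dangling
#' connection endpoints, port-type mismatches, multiply-wired inputs,
#' connection cycles, unsatisfied required inputs and invalid parameters.
#'
#' @param graph An [md_graph()].
#' @param traj Optional trajectory, enabling checks that need the data (a
#'   wired velocities node on a velocity-less trajectory).
#' @return Character vector of diagnostics (empty when valid).
#' @export
validate_graph <- function(graph, traj = NULL) {
  diags <- character(0)
  say <- function(...) diags <<- c(diags, sprintf(...))
  ids <- node_ids(graph)
  if (anyDuplicated(ids))
    say("duplicate node id '%s'", ids[duplicated(ids)][1L])
  for (nd in graph$nodes) {
    if (!node_kind_exists(nd$kind) && is.null(nd$outputs))
      say("unknown node kind '%s' (node '%s')", nd$kind, nd$id)
    else if (node_kind_exists(nd$kind)) {
      chk <- node_kind(nd$kind)$check
      if (!is.null(chk)) {
        pr <- utils::modifyList(node_kind(nd$kind)$params, nd$params)
        diags <- c(diags, vapply(chk(pr), function(m)
          sprintf("node '%s': %s", nd$id, m), ""))
      }
    }
  }
  seen_to <- character(0)
  for (cn in graph$connections) {
    fnode <- find_node(graph, cn$from[1L]); tnode <- find_node(graph, cn$to[1L])
    if (is.null(fnode)) { say("connection from unknown node '%s'", cn$from[1L]); next }
    if (is.null(tnode)) { say("connection to unknown node '%s'", cn$to[1L]); next }
    fp <- node_ports(fnode, "outputs")[[cn$from[2L]]]
    tp <- node_ports(tnode, "inputs")[[cn$to[2L]]]
    if (is.null(fp)) { say("node '%s' has no output port '%s'", cn$from[1L], cn$from[2L]); next }
    if (is.null(tp)) { say("node '%s' has no input port '%s'", cn$to[1L], cn$to[2L]); next }
    if (!port_compatible(fp, tp))
      say("type mismatch: %s.%s (%s) -> %s.%s (%s)",
          cn$from[1L], cn$from[2L], port_str(fp),
          cn$to[1L], cn$to[2L], port_str(tp))
    key <- paste(cn$to[1L], cn$to[2L], sep = ".")
    if (key %in% seen_to)
      say("input port %s has more than one incoming connection", key)
    seen_to <- c(seen_to, key)
  }
  cyc <- connection_cycle(graph)
  if (!is.null(cyc))
    say("connection cycle through nodes: %s", paste(cyc, collapse = " -> "))
  # required inputs must be wired
  wired <- vapply(graph$connections, function(cn)
    paste(cn$to[1L], cn$to[2L], sep = "."), "")
  for (nd in graph$nodes) {
    ins <- node_ports(nd, "inputs")
    opt <- if (!is.null(nd$outputs)) character(0) else
      if (node_kind_exists(nd$kind)) node_kind(nd$kind)$optional else character(0)
    for (pn in setdiff(names(ins), opt)) {
      if (!paste(nd$id, pn, sep = ".") %in% wired)
        say("required input %s.%s is not connected", nd$id, pn)
    }
  }
  if (!is.null(traj)) {
    for (nd in graph$nodes) {
      if (identical(nd$kind, "velocities")) {
        has_v <- all(vapply(traj$frames, function(f) !is.null(f$velocities), TRUE))
        if (!has_v)
          say("node '%s' requires velocities, which the trajectory lacks", nd$id)
      }
    }
  }
  diags
}

# returns NULL or a vector of node ids forming a cycle
connection_cycle <- function(graph) {
  ids <- node_ids(graph)
  adj <- stats::setNames(lapply(ids, function(i) character(0)), ids)
  for (cn in graph$connections) {
    f <- cn$from[1L]; t <- cn$to[1L]
    if (f %in% ids && t %in% ids) adj[[f]] <- c(adj[[f]], t)
  }
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  path <- character(0); found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[v] <<- 1L; path <<- c(path, v)
    for (w in adj[[v]]) {
      if (state[w] == 1L) { found <<- c(path[which(path == w)[1L]:length(path)], w); return() }
      if (state[w] == 0L) visit(w)
      if (!is.null(found)) return()
    }
    state[v] <<- 2L; path <<- path[-length(path)]
  }
  for (v in ids) if (state[v] == 0L) visit(v)
  found
}

#' Topological order of a graph's nodes
#'
#' Every connection goes from an earlier to a later node; ties between
#' unordered nodes are broken by lexicographic node id, making the schedule
#' (and therefore attribute read/write interleaving) deterministic.
#'
#' @param graph An [md_graph()].
#' @return Character vector of node ids.
#' @export
topo_order <- function(graph) {
  ids <- sort(node_ids(graph))
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  adj <- stats::setNames(lapply(ids, function(i) character(0)), ids)
  for (cn in graph$connections) {
    f <- cn$from[1L]; t <- cn$to[1L]
    if (!f %in% ids || !t %in% ids) next
    adj[[f]] <- c(adj[[f]], t)
    indeg[t] <- indeg[t] + 1L
  }
  out <- character(0)
  avail <- ids[indeg[ids] == 0L]
  while (length(avail)) {
    v <- sort(avail)[1L]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    for (w in unique(adj[[v]])) {
      indeg[w] <- indeg[w] - sum(adj[[v]] == w)
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != length(ids)) stop("graph has a connection cycle")
  out
}

# ---------------------------------------------------------------------------
# Execution

new_vis_state <- function(n) {
  v <- new.env(parent = emptyenv())
  v$color <- numeric(n)
  v$radius_scale <- rep(1, n)
  v$visible <- rep(TRUE, n)
  v$extra_bonds <- matrix(integer(0), 0L, 2L)
  v$camera_center <- c(0, 0, 0)
  v
}

vis_as_list <- function(v) {
  list(color = v$color, radius_scale = v$radius_scale,
       visible = v$visible,
       extra_bonds = if (nrow(v$extra_bonds)) unname(v$extra_bonds) else
         matrix(integer(0), 0L, 2L),
       camera_center = v$camera_center)
}

node_error <- function(id, frame_index, msg) {
  structure(class = c("mdflow_node_error", "error", "condition"),
            list(message = sprintf("node '%s' failed at frame %d: %s",
                                   id, frame_index, msg),
                 call = NULL, node_id = id, frame_index = frame_index))
}

#' Execute a graph for one frame
#'
#' Input nodes see this frame's data; nodes run in [topo_order()]; attribute
#' reads and writes take effect immediately in that order; recorded
#' attributes are snapshotted after the last node.
#'
#' @param graph An [md_graph()] (assumed validated).
#' @param traj An [md_trajectory].
#' @param frame_index 1-based frame index.
#' @param store An [attribute_store()].
#' @param vis Optional visualization state environment (a fresh default one
#'   is created when `NULL`).
#' @param plots Optional environment collecting plot-node series.
#' @param order Optional precomputed [topo_order()].
#' @return Named list `cache[[node_id]][[port]]` of every output value, plus
#'   the visualization state under the attribute `"vis"`.
#' @export
execute_frame <- function(graph, traj, frame_index, store, vis = NULL,
                          plots = NULL, order = NULL) {
  n <- n_atoms(traj)
  frame <- traj$frames[[frame_index]]
  if (is.null(frame)) stop(sprintf("frame index %d out of range", frame_index))
  if (is.null(vis)) vis <- new_vis_state(n)
  if (is.null(plots)) plots <- new.env(parent = emptyenv())
  if (is.null(order)) order <- topo_order(graph)
  # refresh trajectory-imported attributes for this frame
  for (a in names(frame$attrs)) {
    attr_set(store, a, frame$attrs[[a]])
    if (is.null(store$recorded[[a]]) || !isTRUE(store$recorded[[a]])) {
      store$recorded[[a]] <- TRUE
      if (is.null(store$history[[a]])) store$history[[a]] <- list()
    }
  }
  ctx <- list(traj = traj, frame = frame, frame_index = frame_index,
              n_atoms = n, box = frame$box, store = store, vis = vis,
              plots = plots)
  # incoming connection lookup: to "id.port" -> from c(id, port)
  incoming <- list()
  for (cn in graph$connections)
    incoming[[paste(cn$to[1L], cn$to[2L], sep = ".")]] <- cn$from
  cache <- list()
  by_id <- stats::setNames(graph$nodes, node_ids(graph))
  for (id in order) {
    nd <- by_id[[id]]
    kind <- node_kind(nd$kind)
    params <- utils::modifyList(kind$params, nd$params)
    ins <- node_ports(nd, "inputs")
    vals <- stats::setNames(vector("list", length(ins)), names(ins))
    for (pn in names(ins)) {
      src <- incoming[[paste(id, pn, sep = ".")]]
      if (!is.null(src)) vals[[pn]] <- cache[[src[1L]]][[src[2L]]]
    }
    ctx$.node_id <- id
    out <- tryCatch(kind$fn(vals, params, ctx), error = function(e)
      stop(node_error(id, frame_index, conditionMessage(e))))
    outs <- node_ports(nd, "outputs")
    stored <- stats::setNames(vector("list", length(outs)), names(outs))
    for (pn in names(outs)) {
      if (is.null(out[[pn]]))
        stop(node_error(id, frame_index,
                        sprintf("did not produce output '%s'", pn)))
      stored[[pn]] <- out[[pn]]
    }
    cache[[id]] <- stored
  }
  for (a in ls(store$recorded))
    attr_snapshot(store, a, frame_index)
  attr(cache, "vis") <- vis_as_list(vis)
  cache
}

#' Execute a graph over a trajectory
#'
#' Frames are visited in ascending order (`"forward"`) or descending order
#' (`"backward"`). Attribute values persist across frames, which is what
#' makes recurrent graphs (an attribute set as both input and output of a
#' node) carry state through time.
#'
#' @param graph An [md_graph()].
#' @param traj An [md_trajectory].
#' @param direction,frames Optional overrides of the graph's execution
#'   config.
#' @return An object of class `mdflow_run` with components `cache`
#'   (per-frame per-node per-port values), `attr_history`, `vis_history`,
#'   `plots` (per plot node, a data.frame `frame,value` in visit order),
#'   `visited` (frame visit order) and `direction`.
#' @export
execute_trajectory <- function(graph, traj, direction = NULL, frames = NULL) {
  diags <- validate_graph(graph, traj)
  if (length(diags))
    stop(paste(c("graph is not executable:", diags), collapse = "\n  "))
  if (is.null(direction)) direction <- graph$execution$direction
  if (is.null(direction)) direction <- "forward"
  if (!direction %in% c("forward", "backward"))
    stop("direction must be 'forward' or 'backward'")
  if (is.null(frames)) frames <- graph$execution$frames
  nf <- n_frames(traj)
  if (is.null(frames)) frames <- c(1L, nf)
  frames <- as.integer(frames)
  if (length(frames) != 2L || frames[1L] < 1L || frames[2L] > nf ||
      frames[1L] > frames[2L])
    stop(sprintf("frame range must lie within 1..%d", nf))
  visit <- if (direction == "forward") frames[1L]:frames[2L] else
    frames[2L]:frames[1L]
  store <- attribute_store(n_atoms(traj))
  for (ad in graph$attributes)
    attr_declare(store, ad$name, init = ad$init, record = isTRUE(ad$record))
  plots <- new.env(parent = emptyenv())
  order <- topo_order(graph)
  cache <- list(); vis_history <- list()
  for (f in visit) {
    fc <- execute_frame(graph, traj, f, store, vis = NULL, plots = plots,
                        order = order)
    vis_history[[as.character(f)]] <- attr(fc, "vis")
    attr(fc, "vis") <- NULL
    cache[[as.character(f)]] <- fc
  }
  plot_series <- list()
  for (pid in sort(ls(plots))) {
    pe <- plots[[pid]]
    fs <- visit[as.character(visit) %in% ls(pe)]
    plot_series[[pid]] <- data.frame(
      frame = fs, value = vapply(as.character(fs), function(k) pe[[k]], 0))
  }
  hist <- list()
  for (a in attr_names(store))
    if (isTRUE(store$recorded[[a]])) hist[[a]] <- attr_history(store, a)
  structure(list(cache = cache, attr_history = hist,
                 vis_history = vis_history, plots = plot_series,
                 visited = visit, direction = direction,
                 store = store),
            class = "mdflow_run")
}

#' Serialize a run result to canonical JSON
#'
#' Deterministic: identical graph + trajectory give byte-identical output.
#'
#' @param run An `mdflow_run`.
#' @return A JSON string.
#' @export
serialize_run <- function(run) {
  x <- list(direction = run$direction, visited = run$visited,
            cache = run$cache, attr_history = run$attr_history,
            vis_history = run$vis_history, plots = run$plots)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"))
}

# ---------------------------------------------------------------------------
# Graph JSON persistence
# Schema: {"nodes":[{"id","kind","params"}],
#          "connections":[{"from":["id","port"],"to":["id","port"]}],
#          "attributes":[{"name","init","record"}],
#          "execution":{"direction","frames"}}

#' Save a graph as JSON
#'
#' @param graph An [md_graph()].
#' @param path Output path.
#' @export
save_graph <- function(graph, path) {
  enc <- list(
    nodes = lapply(graph$nodes, function(nd)
      list(id = nd$id, kind = nd$kind,
           params = if (length(nd$params)) nd$params else structure(list(), names = character(0)))),
    connections = lapply(graph$connections, function(cn)
      list(from = as.list(cn$from), to = as.list(cn$to))),
    attributes = lapply(graph$attributes, function(ad)
      list(name = ad$name, init = ad$init, record = ad$record)),
    execution = list(direction = graph$execution$direction,
                     frames = graph$execution$frames))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a graph from JSON
#'
#' Missing `execution.direction` defaults to `"forward"`. Unknown node kinds
#' and schema violations raise errors naming the offending JSON path.
#'
#' @param path JSON file path.
#' @return An [md_graph()].
#' @export
load_graph <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop(sprintf("graph schema violation at %s: missing '%s'", where, field))
    x[[field]]
  }
  nodes <- lapply(seq_along(js$nodes), function(i) {
    nd <- js$nodes[[i]]
    where <- sprintf("$.nodes[%d]", i)
    id <- need(nd, "id", where); kind <- need(nd, "kind", where)
    params <- if (is.null(nd$params)) list() else nd$params
    params <- lapply(params, function(v) if (is.list(v)) unlist(v) else v)
    if (!identical(kind, "script") && !node_kind_exists(kind))
      stop(sprintf("graph schema violation at %s: unknown node kind '%s'",
                   where, kind))
    graph_node(id, kind, params)
  })
  conns <- lapply(seq_along(js$connections), function(i) {
    cn <- js$connections[[i]]
    where <- sprintf("$.connections[%d]", i)
    f <- need(cn, "from", where); t <- need(cn, "to", where)
    if (length(f) != 2L || length(t) != 2L)
      stop(sprintf("graph schema violation at %s: endpoints must be [id, port]", where))
    connection(f[[1]], f[[2]], t[[1]], t[[2]])
  })
  attrs <- lapply(seq_along(js$attributes), function(i) {
    ad <- js$attributes[[i]]
    where <- sprintf("$.attributes[%d]", i)
    attr_decl(need(ad, "name", where),
              init = if (is.null(ad$init)) 0 else unlist(ad$init),
              record = isTRUE(ad$record))
  })
  direction <- js$execution$direction
  if (is.null(direction)) direction <- "forward"
  frames <- if (is.null(js$execution$frames)) NULL else
    as.integer(unlist(js$execution$frames))
  md_graph(nodes, conns, attrs, direction = direction, frames = frames)
}
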