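# Extra node kinds registered only for the tests. `affine` is the minimal
# stateless transform used to build random recurrent graphs, and also
# demonstrates user extension of the node registry.

register_node_kind(
  "affine", params = list(a = 1, b = 0),
  inputs = list(x = port("float", 1)),
  outputs = list(y = port("float", 1)),
  fn = function(inputs, params, ctx) list(y = params$a * inputs$x + params$b))

# a recurrent graph applying a chain of affine maps to one attribute
affine_feedback_graph <- function(coeffs, attr_name = "state", init = 0,
                                  direction = "forward") {
  nodes <- list(graph_node("a_read", "get_attribute", list(name = attr_name)))
  conns <- list()
  prev <- c("a_read", "value")
  for (k in seq_len(nrow(coeffs))) {
    id <- sprintf("f%02d", k)
    nodes[[length(nodes) + 1L]] <- graph_node(id, "affine",
                                              list(a = coeffs[k, 1L],
                                                   b = coeffs[k, 2L]))
    conns[[length(conns) + 1L]] <- connection(prev[1L], prev[2L], id, "x")
    prev <- c(id, "y")
  }
  nodes[[length(nodes) + 1L]] <- graph_node("z_write", "set_attribute",
                                            list(name = attr_name))
  conns[[length(conns) + 1L]] <- connection(prev[1L], prev[2L], "z_write", "value")
  md_graph(nodes, conns,
           attributes = list(attr_decl(attr_name, init = init, record = TRUE)),
           direction = direction)
}

# evaluate a CLI call, swallowing its printed output, returning the code
capture_code <- function(expr) {
  utils::capture.output(res <- expr)
  as.integer(res)
}

# tiny trajectory with arbitrary still positions, for engine-only tests
still_trajectory <- function(n_atoms = 3L, n_frames = 5L, velocities = FALSE) {
  box <- md_box(c(20, 20, 20), periodic = c(FALSE, FALSE, FALSE))
  pos <- cbind(seq_len(n_atoms), 0, 0)
  frames <- lapply(seq_len(n_frames), function(f)
    md_frame(f, pos, box,
             velocities = if (velocities) matrix(0.1, n_atoms, 3L) else NULL))
  md_trajectory(atom_table(name = rep("A", n_atoms),
                           resid = seq_len(n_atoms)), frames)
}
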