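test_that("port compatibility allows int->float promotion, rejects rank mismatch", {
  expect_true(port_compatible(port("float", 1), port("float", 1)))
  expect_true(port_compatible(port("int", 2), port("float", 2)))
  expect_false(port_compatible(port("float", 0), port("int", 0)))
  expect_false(port_compatible(port("float", 1), port("float", 2)))
  expect_false(port_compatible(port("string", 0), port("float", 0)))
})

test_that("validation reports type mismatches, cycles, unknown kinds, unwired inputs", {
  g_bad <- md_graph(
    nodes = list(graph_node("c", "classified_count"),
                 graph_node("p", "plot_data")),
    connections = list(connection("c", "count", "p", "y")))
  # classified_count requires a wired labels input
  expect_match(validate_graph(g_bad), "required input c.labels", all = FALSE)

  g_type <- md_graph(
    nodes = list(graph_node("pos", "positions"),
                 graph_node("p", "plot_data")),
    connections = list(connection("pos", "positions", "p", "y")))
  expect_match(validate_graph(g_type), "type mismatch", all = FALSE)

  # int output into float input is fine (promotion)
  g_ok <- md_graph(
    nodes = list(graph_node("pos", "positions"),
                 graph_node("nbr", "list_neighbors", list(cutoff = 2)),
                 graph_node("sv", "set_attribute", list(name = "n"))),
    connections = list(connection("pos", "positions", "nbr", "positions"),
                       connection("nbr", "counts", "sv", "value")))
  expect_length(validate_graph(g_ok), 0L)

  g_cycle <- md_graph(
    nodes = list(graph_node("a", "affine"), graph_node("b", "affine")),
    connections = list(connection("a", "y", "b", "x"),
                       connection("b", "y", "a", "x")))
  d <- validate_graph(g_cycle)
  expect_match(d, "cycle", all = FALSE)
  expect_match(d[grepl("cycle", d)], "a")
  expect_match(d[grepl("cycle", d)], "b")

  g_unknown <- md_graph(nodes = list(graph_node("x", "no_such_kind")))
  expect_match(validate_graph(g_unknown), "unknown node kind 'no_such_kind'",
               all = FALSE)

  g_dangling <- md_graph(
    nodes = list(graph_node("pos", "positions")),
    connections = list(connection("pos", "positions", "ghost", "x")))
  expect_match(validate_graph(g_dangling), "unknown node 'ghost'", all = FALSE)
})

test_that("topological order respects connections and breaks ties lexicographically", {
  chain <- md_graph(
    nodes = list(graph_node("C", "affine"), graph_node("A", "affine"),
                 graph_node("B", "affine")),
    connections = list(connection("A", "y", "B", "x"),
                       connection("B", "y", "C", "x")))
  expect_identical(topo_order(chain), c("A", "B", "C"))
  indep <- md_graph(nodes = list(graph_node("zz", "positions"),
                                 graph_node("aa", "positions")))
  expect_identical(topo_order(indep), c("aa", "zz"))
  diamond <- md_graph(
    nodes = list(graph_node("d", "combine_attributes"),
                 graph_node("a", "get_attribute", list(name = "x")),
                 graph_node("b", "affine"), graph_node("c", "affine")),
    connections = list(connection("a", "value", "b", "x"),
                       connection("a", "value", "c", "x"),
                       connection("b", "y", "d", "a"),
                       connection("c", "y", "d", "b")))
  ord <- topo_order(diamond)
  expect_identical(ord[1], "a")
  expect_identical(ord[4], "d")
})

test_that("attribute reads see writes according to schedule position", {
  traj <- still_trajectory(n_atoms = 2L, n_frames = 1L)
  # reader id sorts before the writer chain: sees the pre-frame value
  g1 <- md_graph(
    nodes = list(graph_node("a_read", "get_attribute", list(name = "v")),
                 graph_node("a_save", "set_attribute", list(name = "seen")),
                 graph_node("w1", "get_attribute", list(name = "init")),
                 graph_node("w2", "set_attribute", list(name = "v"))),
    connections = list(connection("a_read", "value", "a_save", "value"),
                       connection("w1", "value", "w2", "value")),
    attributes = list(attr_decl("v", init = 1, record = TRUE),
                      attr_decl("init", init = 9),
                      attr_decl("seen", record = TRUE)))
  r1 <- execute_trajectory(g1, traj)
  expect_equal(r1$attr_history$seen[["1"]], c(1, 1))
  # reader scheduled after the writer: sees the new value
  g2 <- md_graph(
    nodes = list(graph_node("z_read", "get_attribute", list(name = "v")),
                 graph_node("z_save", "set_attribute", list(name = "seen")),
                 graph_node("w1", "get_attribute", list(name = "init")),
                 graph_node("w2", "set_attribute", list(name = "v"))),
    connections = list(connection("z_read", "value", "z_save", "value"),
                       connection("w1", "value", "w2", "value")),
    attributes = list(attr_decl("v", init = 1, record = TRUE),
                      attr_decl("init", init = 9),
                      attr_decl("seen", record = TRUE)))
  r2 <- execute_trajectory(g2, traj)
  expect_equal(r2$attr_history$seen[["1"]], c(9, 9))
})

test_that("node failures carry the node id and frame index", {
  traj <- still_trajectory(n_atoms = 2L, n_frames = 5L)
  sc <- tempfile(fileext = ".R")
  writeLines(c("# @in f : float[0]",
               "stopifnot(f < 3)",
               "# @out y : float[0]",
               "y <- f"), sc)
  g <- md_graph(
    nodes = list(graph_node("fidx", "get_attribute", list(name = "counter")),
                 graph_node("bump", "affine", list(b = 1)),
                 graph_node("keep", "set_attribute", list(name = "counter"))),
    connections = list(connection("fidx", "value", "bump", "x"),
                       connection("bump", "y", "keep", "value")),
    attributes = list(attr_decl("counter")))
  # direct frame failure: an invalid camera point
  g_bad <- md_graph(
    nodes = list(graph_node("cam", "set_camera_center"),
                 graph_node("bad", "get_attribute", list(name = "nanattr"))),
    connections = list(connection("bad", "value", "cam", "point")),
    attributes = list(attr_decl("nanattr", init = NaN)))
  err <- tryCatch(execute_trajectory(g_bad, traj, frames = c(3, 5)),
                  error = function(e) e)
  expect_s3_class(err, "mdflow_node_error")
  expect_identical(err$node_id, "cam")
  expect_identical(err$frame_index, 3L)
  expect_match(conditionMessage(err), "node 'cam' failed at frame 3")
})

test_that("attributes persist across frames in both directions", {
  traj <- still_trajectory(n_atoms = 4L, n_frames = 3L)
  g <- affine_feedback_graph(cbind(1, 1), init = 0)     # state <- state + 1
  fwd <- execute_trajectory(g, traj, direction = "forward")
  bwd <- execute_trajectory(g, traj, direction = "backward")
  expect_equal(fwd$attr_history$state[["3"]], rep(3, 4))
  expect_equal(bwd$attr_history$state[["1"]], rep(3, 4))
  expect_identical(bwd$visited, 3:1)
  expect_identical(names(bwd$attr_history$state), c("3", "2", "1"))
})

test_that("the frame cache holds every output port of every frame", {
  traj <- still_trajectory(n_atoms = 3L, n_frames = 4L)
  g <- md_graph(
    nodes = list(graph_node("pos", "positions"),
                 graph_node("nbr", "list_neighbors", list(cutoff = 1.5)),
                 graph_node("grp", "group_list"),
                 graph_node("sv", "set_attribute", list(name = "g"))),
    connections = list(connection("pos", "positions", "nbr", "positions"),
                       connection("nbr", "edges", "grp", "edges"),
                       connection("grp", "labels", "sv", "value")))
  run <- execute_trajectory(g, traj)
  n_ports <- sum(vapply(run$cache, function(fc)
    sum(lengths(lapply(fc, names))), 0L))
  expect_identical(n_ports, 4L * 4L)   # 4 frames x (positions, edges, counts, labels)
  expect_equal(run$cache[["2"]][["grp"]][["labels"]], c(1L, 1L, 1L))
})

test_that("graph JSON round trip preserves structure and defaults direction", {
  g <- mcg_graph()
  p <- tempfile(fileext = ".json")
  save_graph(g, p)
  g2 <- load_graph(p)
  expect_identical(node_ids_of <- vapply(g2$nodes, `[[`, "", "id"),
                   vapply(g$nodes, `[[`, "", "id"))
  expect_identical(vapply(g2$nodes, `[[`, "", "kind"),
                   vapply(g$nodes, `[[`, "", "kind"))
  expect_identical(length(g2$connections), length(g$connections))
  for (k in seq_along(g$connections))
    expect_identical(g2$connections[[k]], g$connections[[k]])
  expect_length(validate_graph(g2), 0L)
  expect_identical(topo_order(g2), topo_order(g))
  # missing execution.direction defaults to forward
  js <- jsonlite::read_json(p, simplifyVector = FALSE)
  js$execution$direction <- NULL
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(js, p2, auto_unbox = TRUE)
  expect_identical(load_graph(p2)$execution$direction, "forward")
  # unknown node kind is named
  js$nodes[[1]]$kind <- "warp_drive"
  jsonlite::write_json(js, p2, auto_unbox = TRUE)
  expect_error(load_graph(p2), "warp_drive")
})

test_that("wired velocities node on a velocity-less trajectory is caught before running", {
  g <- md_graph(
    nodes = list(graph_node("vel", "velocities"),
                 graph_node("sv", "set_attribute", list(name = "vx"))),
    connections = list(connection("vel", "velocities", "sv", "value")))
  g$nodes[[2]] <- graph_node("cen", "mask_centroid")  # keep vel wired somewhere
  g <- md_graph(
    nodes = list(graph_node("vel", "velocities"),
                 graph_node("cen", "mask_centroid"),
                 graph_node("msk", "get_attribute", list(name = "m")),
                 graph_node("cam", "set_camera_center")),
    connections = list(connection("vel", "velocities", "cen", "positions"),
                       connection("msk", "value", "cen", "mask"),
                       connection("cen", "center", "cam", "point")),
    attributes = list(attr_decl("m", init = 1)))
  no_vel <- still_trajectory(velocities = FALSE)
  with_vel <- still_trajectory(velocities = TRUE)
  expect_match(validate_graph(g, no_vel), "velocities", all = FALSE)
  expect_error(execute_trajectory(g, no_vel), "velocities")
  expect_silent(execute_trajectory(g, with_vel))
})
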