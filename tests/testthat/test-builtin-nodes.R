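test_that("attribute combination modes behave element-wise", {
  expect_equal(combine_attributes(c(0, 1), c(1, 0), "max"), c(1, 1))
  expect_equal(combine_attributes(c(0, 1), c(1, 0), "mean"), c(0.5, 0.5))
  expect_equal(combine_attributes(c(0, 1), c(1, 0), "min"), c(0, 0))
  expect_equal(combine_attributes(c(0, 1), c(1, 0), "sum"), c(1, 1))
  x <- runif(5)
  expect_identical(combine_attributes(x, x, "max"), x)
  expect_error(combine_attributes(1:3, 1:2), "lengths differ")
})

test_that("show range uses a closed interval", {
  v <- c(0, 1, 2)
  expect_identical(show_range_mask(v, 1, 2), c(FALSE, TRUE, TRUE))
  expect_identical(show_range_mask(v), c(TRUE, TRUE, TRUE))
  expect_identical(show_range_mask(v, 2, 2), c(FALSE, FALSE, TRUE))
  expect_error(show_range_mask(v, 2, 1), "lo <= hi")
})

test_that("mask centroid averages masked positions only", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(100, 100, 100))
  expect_equal(mask_centroid(pos, c(1, 1, 0)), c(1, 0, 0))
  expect_equal(mask_centroid(pos, c(0, 0, 1)), c(100, 100, 100))
  expect_error(mask_centroid(pos, c(0, 0, 0)), "no atoms")
})

test_that("visualization-state nodes write state without touching attributes", {
  traj <- still_trajectory(n_atoms = 4L, n_frames = 2L)
  g <- md_graph(
    nodes = list(
      graph_node("lab", "get_attribute", list(name = "lab")),
      graph_node("rng", "show_range", list(lo = 0.5, hi = Inf)),
      graph_node("rad", "set_radius_scale", list(value = 2)),
      graph_node("pos", "positions"),
      graph_node("cen", "mask_centroid"),
      graph_node("cam", "set_camera_center")),
    connections = list(connection("lab", "value", "rng", "values"),
                       connection("pos", "positions", "cen", "positions"),
                       connection("lab", "value", "cen", "mask"),
                       connection("cen", "center", "cam", "point")),
    attributes = list(attr_decl("lab", init = c(1, 1, 0, 0))))
  run <- execute_trajectory(g, traj)
  vs <- run$vis_history[["1"]]
  expect_identical(vs$visible, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(vs$radius_scale, rep(2, 4))
  expect_equal(vs$camera_center, c(1.5, 0, 0))
  # attribute store untouched by state nodes
  expect_identical(sort(attr_names(run$store)), "lab")
})

test_that("extra bonds deduplicate and validate indices", {
  traj <- still_trajectory(n_atoms = 3L, n_frames = 1L)
  # feed pairs through a script node
  sc <- tempfile(fileext = ".R")
  writeLines(c("# @out pairs : int[2]",
               "pairs <- rbind(c(1L, 2L), c(2L, 1L))"), sc)
  g <- md_graph(
    nodes = list(graph_node("gen", "script", list(path = sc)),
                 graph_node("eb", "extra_bonds")),
    connections = list(connection("gen", "pairs", "eb", "pairs")))
  run <- execute_trajectory(g, traj)
  expect_identical(unname(run$vis_history[["1"]]$extra_bonds),
                   matrix(c(1L, 2L), 1L))
  sc2 <- tempfile(fileext = ".R")
  writeLines(c("# @out pairs : int[2]",
               "pairs <- rbind(c(1L, 9L))"), sc2)
  g2 <- md_graph(
    nodes = list(graph_node("gen", "script", list(path = sc2)),
                 graph_node("eb", "extra_bonds")),
    connections = list(connection("gen", "pairs", "eb", "pairs")))
  expect_error(execute_trajectory(g2, traj), "out of range")
})

test_that("plot node accumulates one point per visited frame in visit order", {
  traj <- still_trajectory(n_atoms = 2L, n_frames = 5L)
  g <- md_graph(
    nodes = list(graph_node("st", "get_attribute", list(name = "s")),
                 graph_node("bump", "affine", list(b = 1)),
                 graph_node("keep", "set_attribute", list(name = "s")),
                 graph_node("cnt", "classified_count"),
                 graph_node("plt", "plot_data")),
    connections = list(connection("st", "value", "bump", "x"),
                       connection("bump", "y", "keep", "value"),
                       connection("bump", "y", "cnt", "labels"),
                       connection("cnt", "count", "plt", "y")),
    attributes = list(attr_decl("s", init = 0)))
  fwd <- execute_trajectory(g, traj, direction = "forward")
  expect_equal(fwd$plots$plt$frame, 1:5)
  expect_equal(fwd$plots$plt$value, rep(2, 5))   # both atoms always counted
  bwd <- execute_trajectory(g, traj, direction = "backward")
  expect_equal(bwd$plots$plt$frame, 5:1)
  p <- tempfile(fileext = ".csv")
  write_plot_csv(fwd, "plt", p)
  expect_identical(readLines(p)[1], "frame,value")
  expect_length(readLines(p), 6L)
})

test_that("radius scale rejects non-positive values", {
  traj <- still_trajectory(n_atoms = 2L, n_frames = 1L)
  g <- md_graph(nodes = list(graph_node("rad", "set_radius_scale",
                                        list(value = 0))))
  expect_error(execute_trajectory(g, traj), "positive")
})
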