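test_that("droplet generator is deterministic and structured as scripted", {
  d1 <- gen_lj_droplet(n_atoms = 60, n_frames = 20, merge_frame = 10, seed = 7)
  d2 <- gen_lj_droplet(n_atoms = 60, n_frames = 20, merge_frame = 10, seed = 7)
  expect_identical(d1$traj$frames[[13]]$positions, d2$traj$frames[[13]]$positions)
  expect_identical(d1$truth, d2$truth)
  cutoff <- d1$truth$cutoff
  f1 <- d1$traj$frames[[1]]
  g1 <- group_list(list_neighbors(f1$positions, f1$box, cutoff))
  expect_gte(max(g1), 3L)
  fN <- d1$traj$frames[[20]]
  gN <- group_list(list_neighbors(fN$positions, fN$box, cutoff))
  # final frame: both blobs share one component, which is the largest
  big <- which(mode_mask(gN) == 1)
  expect_true(all(which(d1$truth$mask[[20]] == 1) %in% big))
  # pre-nucleation frames hold no clusters containing future members
  f_pre <- d1$traj$frames[[d1$truth$nucleation_frame - 1L]]
  g_pre <- group_list(list_neighbors(f_pre$positions, f_pre$box, cutoff))
  sizes <- tabulate(g_pre)
  blobA <- which(d1$truth$mask[[d1$truth$nucleation_frame]] == 1)
  expect_true(all(sizes[g_pre[blobA]] == 1L))
})

test_that("droplet ground truth is exactly recovered by backward tracking", {
  d <- gen_lj_droplet(seed = 12)
  fN <- d$traj$frames[[n_frames_d <- length(d$traj$frames)]]
  init <- mode_mask(group_list(list_neighbors(fN$positions, fN$box,
                                              d$truth$cutoff)))
  run <- execute_trajectory(tracking_graph(d$truth$cutoff, init = init),
                            d$traj)
  for (f in seq_len(n_frames_d))
    expect_identical(run$attr_history$cluster_label[[as.character(f)]],
                     d$truth$mask[[f]])
})

test_that("cage pair satisfies each pipeline criterion analytically", {
  cp <- gen_cage_pair()
  fr <- cp$frames[[1]]
  gi <- select_atoms(cp, "resname=MET")
  expect_length(gi, 2L)
  d_guest <- sqrt(sum((fr$positions[gi[1], ] - fr$positions[gi[2], ])^2))
  expect_equal(d_guest, 8)
  oi <- intersect(select_atoms(cp, "resname=SOL"),
                  which(cp$atoms$element == "O"))
  expect_length(oi, 5L)
  # cone angles at both guests within 45 degrees, by direct computation
  for (o in oi) {
    for (g in seq_along(gi)) {
      other <- gi[if (g == 1) 2 else 1]
      u <- fr$positions[o, ] - fr$positions[gi[g], ]
      v <- fr$positions[other, ] - fr$positions[gi[g], ]
      ang <- acos(sum(u * v) / sqrt(sum(u * u) * sum(v * v))) * 180 / pi
      expect_lte(ang, 45)
    }
  }
  # consecutive ring O-O within 3.5 A
  ring <- fr$positions[oi, ]
  for (k in seq_len(5)) {
    nk <- if (k == 5) 1 else k + 1
    expect_lte(sqrt(sum((ring[k, ] - ring[nk, ])^2)), 3.5)
  }
  expect_error(gen_cage_pair(ring_radius = 5), "cone angle")
  expect_error(gen_cage_pair(ring_radius = 3.4, guest_sep = 9 * 0.77),
               "O-O distance")
})

test_that("cage pair outputs are invariant under rigid motion", {
  cp <- gen_cage_pair()
  run0 <- execute_trajectory(mcg_graph(), cp)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fr <- cp$frames[[1]]
  pos2 <- fr$positions %*% t(R)
  pos2 <- sweep(pos2, 2L, c(5, -3, 2), "+")
  cp2 <- md_trajectory(cp$atoms, list(md_frame(1L, pos2, fr$box)))
  run1 <- execute_trajectory(mcg_graph(), cp2)
  expect_identical(run0$attr_history$mcg_label, run1$attr_history$mcg_label)
  expect_identical(run0$plots$order_param, run1$plots$order_param)
})

test_that("over-cutoff guest separation empties the pipeline", {
  cp <- gen_cage_pair(guest_sep = 9.5, ring_radius = 2.8)
  fr <- cp$frames[[1]]
  expect_identical(nrow(filter_guests(fr$positions, fr$box,
                                      select_atoms(cp, "resname=MET"))), 0L)
  run <- execute_trajectory(mcg_graph(), cp)
  expect_equal(run$plots$order_param$value, 0)
  expect_equal(sum(run$attr_history$mcg_label[["1"]]), 0)
})

test_that("dodecahedral cage has 30 hydrogen-bond edges, 12 pentagons, no hexagons", {
  dd <- gen_dodecahedral_cage()
  fr <- dd$frames[[1]]
  oi <- which(dd$atoms$element == "O")
  expect_length(oi, 20L)
  hb <- hbonds_filtered(fr$positions, fr$box, dd$atoms, oi)
  oo <- reconnect_water(hb)
  expect_identical(nrow(oo), 30L)
  expect_length(find_links(oo, 5), 12L)
  expect_length(find_links(oo, 6), 0L)
  # oracle agreement on the polyhedron graph
  expect_identical(ring_strings(find_links(oo, 5)),
                   ring_strings(exhaustive_rings(oo, 5)))
})

test_that("bulk water control has no hydrogen bonds and classifies nothing", {
  bw <- gen_bulk_water(n_molecules = 25, box_length = 28, seed = 5)
  fr <- bw$frames[[1]]
  oi <- which(bw$atoms$element == "O")
  # minimum-image O-O separations all above the H-bond cutoff
  for (k in seq_along(oi)[-1]) {
    d <- minimum_image(fr$positions[oi[1], ], fr$positions[oi[k], ], fr$box)
    expect_gt(sqrt(sum(d * d)), 3.5)
  }
  hb <- hbonds_filtered(fr$positions, fr$box, bw$atoms, oi)
  expect_identical(nrow(hb), 0L)
  bw2 <- gen_bulk_water(n_molecules = 25, box_length = 28, seed = 5)
  expect_identical(bw$frames[[1]]$positions, bw2$frames[[1]]$positions)
})

test_that("generated trajectories round-trip through SSV", {
  for (traj in list(gen_cage_pair(), gen_dodecahedral_cage(),
                    gen_bulk_water(10, 25, 3))) {
    p <- tempfile(fileext = ".ssv")
    write_ssv(traj, path = p)
    t2 <- read_ssv(p)
    expect_equal(t2$frames[[1]]$positions, unname(traj$frames[[1]]$positions),
                 tolerance = 1e-6)
    expect_identical(t2$atoms$resname, traj$atoms$resname)
  }
})
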