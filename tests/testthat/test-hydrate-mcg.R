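open_box <- md_box(c(100, 100, 100), periodic = c(FALSE, FALSE, FALSE))

test_that("guest pairing respects the 9 angstrom default and pair counting", {
  pos <- rbind(c(0, 0, 0), c(8, 0, 0))
  expect_identical(unname(filter_guests(pos, open_box, 1:2)),
                   matrix(c(1L, 2L), 1L))
  pos2 <- rbind(c(0, 0, 0), c(9.5, 0, 0))
  expect_identical(nrow(filter_guests(pos2, open_box, 1:2)), 0L)
  k <- 5L
  posk <- matrix(runif(3 * k, 0, 3), ncol = 3)
  expect_identical(nrow(filter_guests(posk, open_box, 1:k)), k * (k - 1L) %/% 2L)
})

test_that("the double-cone water criterion accepts the lens and straddles 45 deg", {
  g <- rbind(c(0, 0, -4), c(0, 0, 4))
  mk <- function(w) rbind(g, w)
  pairs <- matrix(c(1L, 2L), 1L)
  hit <- function(w, angle = 45) {
    fw <- filter_waters(mk(w), open_box, pairs, 3L, cone_angle = angle)
    length(fw$pair_waters[[1]]) == 1L
  }
  expect_true(hit(c(0, 0, 0)))                 # midpoint: both angles 0
  expect_false(hit(c(0, 0, 6)))                # on axis beyond g2
  r44 <- 4 * tan(44 * pi / 180)
  r46 <- 4 * tan(46 * pi / 180)
  expect_true(hit(c(r44, 0, 0)))               # 44 deg at both guests: in
  expect_false(hit(c(r46, 0, 0)))              # 46 deg: out
  # degenerate pair is skipped with a warning
  expect_warning(
    fw <- filter_waters(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), open_box,
                        pairs, 3L),
    "zero separation")
  expect_length(fw$selected, 0L)
})

two_waters <- function(o2_x, h1_angle_deg = 0) {
  # water 1 donates toward water 2 along +x, with the donor H rotated
  # h1_angle_deg away from the O-O axis
  a <- h1_angle_deg * pi / 180
  h1 <- c(cos(a), sin(a), 0) * 0.9572
  pos <- rbind(c(0, 0, 0), h1, c(-0.24, -0.93, 0),
               c(o2_x, 0, 0), c(o2_x + 0.24, 0.93, 0), c(o2_x + 0.24, -0.93, 0))
  atoms <- atom_table(name = rep(c("OW", "HW1", "HW2"), 2),
                      element = rep(c("O", "H", "H"), 2),
                      resname = rep("SOL", 6),
                      resid = rep(1:2, each = 3), molid = rep(1:2, each = 3))
  list(pos = pos, atoms = atoms)
}

test_that("hydrogen bonds apply the distance and angle cuts", {
  w <- two_waters(2.8)
  hb <- hbonds_filtered(w$pos, open_box, w$atoms, c(1L, 4L))
  expect_identical(unname(hb), matrix(c(1L, 2L, 4L), 1L))  # linear, accepted
  w2 <- two_waters(3.6)
  expect_identical(nrow(hbonds_filtered(w2$pos, open_box, w2$atoms, c(1L, 4L))), 0L)
  w3 <- two_waters(2.8, h1_angle_deg = 35)
  expect_identical(nrow(hbonds_filtered(w3$pos, open_box, w3$atoms, c(1L, 4L))), 0L)
  # role antisymmetry: no (Oa, ., Od) for the same hydrogen
  expect_false(any(hb[, 1L] == 4L))
  # malformed water is named
  atoms_bad <- w$atoms
  atoms_bad$element[2] <- "X"
  expect_error(hbonds_filtered(w$pos, open_box, atoms_bad, c(1L, 4L)),
               "exactly 2 hydrogens")
})

test_that("O-H bonds reconnect to deduplicated O-O edges", {
  hb <- rbind(c(1L, 2L, 4L), c(4L, 5L, 1L))
  expect_identical(unname(reconnect_water(hb)), matrix(c(1L, 4L), 1L))
  expect_identical(nrow(reconnect_water(matrix(integer(0), 0, 3))), 0L)
  expect_identical(unname(oh_pairs(hb)), rbind(c(1L, 5L), c(2L, 4L)))
})

test_that("ring perception finds exactly the simple n-cycles", {
  ring5 <- cbind(1:5, c(2:5, 1))
  expect_length(find_links(ring5, 5), 1L)
  expect_identical(find_links(ring5, 5)[[1]], c(1L, 2L, 3L, 4L, 5L))
  ring6 <- cbind(1:6, c(2:6, 1))
  expect_length(find_links(ring6, 5), 0L)
  expect_length(find_links(ring6, 6), 1L)
  expect_error(find_links(ring5, 2), "at least 3")
})

test_that("ring perception equals exhaustive enumeration on random graphs", {
  set.seed(303)
  for (rep in 1:10) {
    nv <- sample(8:16, 1)
    e <- random_graph_edges(nv, sample(nv:(2 * nv), 1))
    n <- sample(3:6, 1)
    got <- find_links(e, n)
    want <- exhaustive_rings(e, n)
    expect_identical(ring_strings(got), ring_strings(want))
    expect_false(anyDuplicated(ring_strings(got)) > 0)
  }
})

test_that("hydrate registration labels caged guests and rings, counts pairs", {
  # synthetic: guests 1,2 and 3,4; rings on waters 10..14 and 20..24
  pairs <- rbind(c(1L, 2L), c(3L, 4L))
  pair_waters <- list(10:14, 20:24)
  rings <- list(10:14, 20:24)
  rh <- register_hydrate(30, pairs, pair_waters, rings)
  expect_identical(rh$mcg_count, 2L)
  expect_equal(rh$labels[c(1, 2, 10:14)], rep(1, 7))
  expect_equal(rh$labels[c(3, 4, 20:24)], rep(2, 7))
  expect_equal(sum(rh$labels != 0), 14)
  # shared guest merges the component
  pairs2 <- rbind(c(1L, 2L), c(2L, 6L))
  rh2 <- register_hydrate(30, pairs2, list(10:14, 20:24), rings)
  expect_equal(unique(rh2$labels[rh2$labels != 0]), 1)
  # no rings -> nothing labelled
  rh3 <- register_hydrate(30, pairs, pair_waters, list())
  expect_identical(rh3$mcg_count, 0L)
  expect_equal(sum(rh3$labels), 0)
  # min_rings above availability disqualifies
  rh4 <- register_hydrate(30, pairs, pair_waters, rings, min_rings = 2)
  expect_identical(rh4$mcg_count, 0L)
})

test_that("classified_count counts molecules, not atoms, and grows monotonically", {
  molid <- c(1, 1, 1, 2, 2, 2, 3)
  expect_identical(classified_count(c(1, 0, 0, 0, 0, 0, 0), molid), 1L)
  expect_identical(classified_count(numeric(7), molid), 0L)
  l1 <- c(1, 0, 0, 0, 0, 0, 0)
  l2 <- c(1, 0, 0, 1, 0, 0, 0)
  expect_lte(classified_count(l1, molid), classified_count(l2, molid))
})

test_that("switching the extra-bonds source between O-H and O-O lists flips state", {
  cp <- gen_cage_pair()
  base <- mcg_graph()
  run_oo <- execute_trajectory(base, cp)
  g_oh <- base
  # rewire the bonds node input from the O-O edges to the O-H pairs
  for (k in seq_along(g_oh$connections)) {
    cn <- g_oh$connections[[k]]
    if (identical(cn$to, c("bonds", "pairs")))
      g_oh$connections[[k]] <- connection("hbonds", "oh", "bonds", "pairs")
  }
  run_oh <- execute_trajectory(g_oh, cp)
  eb_oo <- run_oo$vis_history[["1"]]$extra_bonds
  eb_oh <- run_oh$vis_history[["1"]]$extra_bonds
  expect_identical(nrow(eb_oo), 5L)
  expect_identical(nrow(eb_oh), 5L)
  expect_false(identical(eb_oo, eb_oh))
  # everything else in the run agrees
  expect_identical(run_oo$attr_history, run_oh$attr_history)
  expect_identical(run_oo$plots, run_oh$plots)
})
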