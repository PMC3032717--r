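test_that("default zone areas realise the 1000:200:5000 volume ratios", {
  zs <- zone_spec()
  expect_identical(zs$area, c(12321L, 2500L, 62500L))
  # ratios approximate 1000:200:5000 with zone 2 fixed at 50x50
  expect_equal(zs$area / zs$area[2], c(1000, 200, 5000) / 200,
               tolerance = 0.015)
})

test_that("Moore neighbourhoods have the right sizes and truncate at edges", {
  expect_equal(nrow(moore_neighborhood(c(5, 5), 1, side = 11)), 8)
  expect_equal(nrow(moore_neighborhood(c(5, 5), 2, side = 11)), 24)
  expect_equal(nrow(moore_neighborhood(c(0, 0), 1, side = 11)), 3)
  expect_equal(nrow(moore_neighborhood(c(0, 5), 1, side = 11)), 5)
  expect_equal(nrow(moore_neighborhood(c(10, 10), 2, side = 11)), 8)
  nb <- moore_neighborhood(c(3, 3), 1, side = 11)
  expect_false(any(nb[, 1] == 3 & nb[, 2] == 3))  # centre excluded
  expect_error(moore_neighborhood(c(11, 0), 1, side = 11), "out of bounds")
})

test_that("the built world has the fixed layout and four infection sites", {
  w <- build_world(default_config(seed = 5L))
  expect_identical(w$zones$area, c(12321L, 2500L, 62500L))
  expect_equal(sum(w$agents$state == "PC_Infected"), 4)
  expect_equal(w$n_pc_init, 71L^2)
  expect_equal(sum(w$agents$type == "Parenchymal"), 71^2)
  # portals: 4 in the tissue, 8 each in lymphoid tissue and blood
  expect_equal(as.integer(table(w$portals$zone)), c(4L, 8L, 8L))
  # the infection sites form the centre 2x2 of the block
  inf <- w$agents[w$agents$state == "PC_Infected", ]
  expect_equal(sort(unique(inf$x)), sort(unique(inf$y)))
  expect_equal(diff(range(inf$x)), 1)
  # all coordinates within their zone bounds
  side <- w$zones$side[w$agents$zone]
  expect_true(all(w$agents$x >= 0 & w$agents$x < side))
  expect_true(all(w$agents$y >= 0 & w$agents$y < side))
})

test_that("world construction is deterministic under a fixed seed", {
  w1 <- build_world(default_config(seed = 77L))
  w2 <- build_world(default_config(seed = 77L))
  expect_identical(w1$agents, w2$agents)
  w3 <- build_world(default_config(seed = 78L))
  expect_false(identical(w1$agents, w3$agents))
})

test_that("mobile agents and tissue cells occupy separate layers", {
  w <- build_world(small_config())
  mob <- w$agents[w$agents$type %in% c("Dendritic", "Macrophage",
                                       "NaturalKiller", "Granulocyte",
                                       "TCell", "BCell", "CTL"), ]
  key <- paste(mob$zone, mob$x, mob$y)
  expect_false(any(duplicated(key)))  # one mobile agent per cell
})

test_that("signal fields validate their constants", {
  expect_error(signal_field("Virus", 1, matrix(0, 5, 5), D = 0), "\\(0, 1\\]")
  expect_error(signal_field("Virus", 1, matrix(0, 5, 5), e = 1.2), "\\(0, 1\\]")
  expect_error(signal_field("Virus", 1, matrix(-1, 5, 5)), "grid")
})

test_that("diffusion keeps uniform fields unchanged at e = 1", {
  f <- signal_field("PK1", 1, matrix(2.5, 9, 9), D = 0.7, e = 1)
  out <- diffuse_step(f)
  expect_equal(out$grid, f$grid, tolerance = 1e-12)
})

test_that("diffusion conserves mass on a periodic lattice at e = 1", {
  g <- matrix(0, 15, 15); g[8, 8] <- 1
  f <- signal_field("Virus", 1, g, D = 0.6, e = 1)
  for (k in 1:4) f <- diffuse_step(f, periodic = TRUE)
  expect_equal(sum(f$grid), 1, tolerance = 1e-9)
})

test_that("a point mass spreads to its eight neighbours and the centre drops", {
  g <- matrix(0, 9, 9); g[5, 5] <- 1
  f <- diffuse_step(signal_field("Virus", 1, g, D = 0.6, e = 1))
  expect_true(all(f$grid[4:6, 4:6][-5] > 0))
  expect_lt(f$grid[5, 5], 1)
  expect_equal(sum(f$grid > 0), 9)
})

test_that("concentrations below the floor are zeroed", {
  g <- matrix(0, 9, 9); g[5, 5] <- 1e-5
  f <- diffuse_step(signal_field("Virus", 1, g, D = 0.6, e = 0.9, eps = 1e-6))
  # the spread puts every neighbour below the 1e-6 floor
  expect_true(all(f$grid[f$grid > 0] >= 1e-6))
})

test_that("gradient targets follow the maximal neighbour above threshold", {
  g <- matrix(0, 9, 9); g[5, 6] <- 5  # row 5, col 6 -> x = 5, y = 4 (0-based)
  f <- signal_field("CH_tissue", 1, g)
  expect_equal(gradient_target(f, c(4, 4), threshold = 1), c(5L, 4L))
  expect_null(gradient_target(f, c(4, 4), threshold = 10))
  # centre holding the maximum is not a gradient
  g2 <- matrix(0, 9, 9); g2[5, 5] <- 5
  expect_null(gradient_target(signal_field("X", 1, g2), c(4, 4), 1))
})

test_that("gradient tie-breaking is uniform at random", {
  g <- matrix(0, 9, 9)
  g[5, 4] <- 3; g[5, 6] <- 3  # two tied maxima at (3,4) and (5,4)
  f <- signal_field("CH_tissue", 1, g)
  set.seed(1234)
  picks <- replicate(4000, gradient_target(f, c(4, 4), 1)[1])
  frac <- mean(picks == 3)
  expect_gt(frac, 0.46)  # 0.5 +- sampling error at n = 4000
  expect_lt(frac, 0.54)
})
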