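test_that("live-live contact totals are symmetric across type pairs", {
  r <- traced_small_run()
  expect_identical(r$pair_live, t(r$pair_live))
})

test_that("portals never appear in any checkpoint", {
  ck <- traced_small_run()$checkpoints
  expect_false(any(ck$agent_type == "Portal"))
  expect_false(any(ck$partner_type == "Portal"))
})

test_that("cumulative counts never decrease across checkpoints", {
  ck <- traced_small_run()$checkpoints
  ck <- ck[ck$partner_type != "none", ]
  key <- paste(ck$agent_id, ck$partner_type, ck$zone)
  for (k in unique(key)) {
    rows <- ck[key == k, ]
    rows <- rows[order(rows$tick), ]
    expect_true(all(diff(rows$count) >= 0), info = k)
  }
})

test_that("zero-contact agents appear so denominators are computable", {
  ck <- traced_small_run()$checkpoints
  t0 <- ck[ck$tick == 0, ]
  expect_true(all(t0$partner_type == "none"))
  expect_true(all(t0$count == 0))
  # every non-portal agent present exactly once at tick 0
  expect_false(any(duplicated(t0$agent_id)))
})

test_that("engagement fractions follow the present/engaged definition", {
  tab <- data.frame(
    tick = 100L, agent_id = 1:10, agent_type = "Macrophage",
    alive = TRUE,
    partner_type = c(rep("Parenchymal", 3), rep("none", 7)),
    zone = c(rep(1L, 3), rep(0L, 7)),
    count = c(5L, 1L, 2L, rep(0L, 7)))
  expect_equal(engagement_fraction(tab, "Macrophage"), 30)
  # five unengaged newcomers dilute the denominator
  extra <- tab[4:8, ]; extra$agent_id <- 11:15
  expect_equal(engagement_fraction(rbind(tab, extra), "Macrophage"), 20)
  expect_true(is.na(engagement_fraction(tab, "NaturalKiller")))
})

test_that("engagement is zero at the start of every run", {
  ck <- traced_small_run()$checkpoints
  t0 <- ck[ck$tick == 0, ]
  for (type in immunet:::immune_types())
    expect_equal(engagement_fraction(t0, type), 0, info = type)
})

test_that("pairwise contact quartiles use linear interpolation", {
  tab <- data.frame(
    tick = 100L, agent_id = 1:3, agent_type = "Dendritic", alive = TRUE,
    partner_type = "TCell", zone = 2L, count = c(1L, 2L, 3L))
  st <- pairwise_contact_stats(tab, "Dendritic", "TCell", zone = 2)
  expect_equal(st$median, 2)
  expect_equal(st$q25, 1.5)
  expect_equal(st$q75, 2.5)
  single <- tab[1, ]; single$count <- 7L
  expect_equal(pairwise_contact_stats(single, "Dendritic", "TCell", 2)$median,
               7)
  # all-zero counts vanish under the engaged restriction
  zero <- tab; zero$count <- 0L
  expect_true(is.na(pairwise_contact_stats(zero, "Dendritic", "TCell",
                                           2)$median))
})

test_that("zone-2 ledgers carry zone-1 history without reset", {
  # an agent with contacts in both zones keeps separate, cumulative rows
  ck <- traced_small_run()$checkpoints
  dc <- ck[ck$agent_type == "Dendritic" & ck$partner_type == "Parenchymal", ]
  expect_true(all(dc$zone == 1))  # activation happened in the tissue
  last <- dc[dc$tick == max(ck$tick), ]
  expect_true(all(last$count >= 1))
})

test_that("checkpoint tables round-trip losslessly through CSV", {
  r <- traced_small_run()
  path <- file.path(tempdir(), "checkpoints.csv")
  write_checkpoints(r, path)
  back <- read_checkpoints(path)
  expect_equal(back, r$checkpoints, ignore_attr = TRUE)
  first <- readLines(path, n = 1)
  expect_match(first, "tick,agent_id,agent_type,alive,partner_type,zone,count")
  unlink(path)

  cpath <- file.path(tempdir(), "census.csv")
  write_census(r, cpath)
  cback <- read_census(cpath)
  expect_equal(dim(cback), dim(r$census))
  expect_equal(cback$pc_infected, r$census$pc_infected)
  unlink(cpath)
})

test_that("links per node counts repeats, with a distinct-partner variant", {
  tab <- data.frame(
    tick = 100L, agent_id = c(1L, 1L, 2L), agent_type = "Dendritic",
    alive = TRUE, partner_type = c("TCell", "BCell", "TCell"),
    zone = 2L, count = c(4L, 2L, 1L))
  deg <- links_per_node(tab, "Dendritic")
  expect_equal(sort(unname(deg)), c(1, 6))
  dis <- links_per_node(tab, "Dendritic", distinct_partners = TRUE)
  expect_equal(sort(unname(dis)), c(1, 2))
})
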