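test_that("identical seeds give bit-identical runs", {
  cfg <- small_config(seed = 31L, stop_tick = 120L, checkpoint_interval = 60L)
  r1 <- run(cfg); r2 <- run(cfg)
  expect_identical(r1$census, r2$census)
  expect_identical(r1$checkpoints, r2$checkpoints)
  expect_identical(r1$outcome, r2$outcome)
})

test_that("the infection starts at the same four sites every run", {
  r <- traced_small_run()
  expect_equal(r$census$pc_infected[1], 4)
  r2 <- run(small_config(seed = 99L, stop_tick = 60L,
                         checkpoint_interval = 60L))
  expect_equal(r2$census$pc_infected[1], 4)
})

test_that("checkpoints land at every interval multiple", {
  r <- run(small_config(seed = 41L, stop_tick = 200L,
                        checkpoint_interval = 50L))
  expect_equal(r$checkpoint_ticks, c(50L, 100L, 150L, 200L))
  expect_equal(length(r$checkpoint_ticks),
               r$config$stop_tick %/% r$config$checkpoint_interval)
})

test_that("outcomes follow the conjunctive win definition", {
  census <- function(inf, healthy, stressed = 0) {
    data.frame(pc_infected = inf, pc_healthy = healthy,
               pc_stressed = stressed)
  }
  expect_equal(classify_outcome(census(0, 70), n_pc_init = 100), "win")
  expect_equal(classify_outcome(census(3, 90), n_pc_init = 100), "loss")
  expect_equal(classify_outcome(census(0, 40), n_pc_init = 100), "loss")
  expect_equal(classify_outcome(census(0, 0), n_pc_init = 100), "loss")
  # exactly half surviving is not a win
  expect_equal(classify_outcome(census(0, 50), n_pc_init = 100), "loss")
  # stressed survivors count as alive
  expect_equal(classify_outcome(census(0, 40, 20), n_pc_init = 100), "win")
})

test_that("batches classify every run exactly once and pool checkpoints", {
  b <- small_batch()
  expect_equal(b$n_win + b$n_loss, b$n_runs)
  expect_true(all(b$outcomes %in% c("win", "loss")))
  expect_setequal(unique(b$pooled_checkpoints$run), seq_len(b$n_runs))
  seeds <- vapply(b$runs, `[[`, 0L, "seed")
  expect_equal(seeds, 21:23)
})

test_that("census bands are mean +- 1.96 sd / sqrt(n)", {
  b <- small_batch()
  oc <- if (b$n_win > 0) "win" else "loss"
  cb <- census_band(b, "pc_infected", oc)
  sel <- which(b$outcomes == oc)
  m <- sapply(b$runs[sel], function(r) r$census$pc_infected)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(sel))
  i <- 50
  expect_equal(cb$mean[i], mean(m[i, ]))
  expect_equal(cb$upper[i] - cb$mean[i],
               1.96 * stats::sd(m[i, ]) / sqrt(length(sel)))
  # a missing outcome class yields an empty band, not an error
  other <- setdiff(c("win", "loss"), oc)
  if (!any(b$outcomes == other))
    expect_equal(nrow(census_band(b, "pc_infected", other)), 0)
})

test_that("every win run ends with zero infected tissue cells", {
  b <- small_batch()
  for (r in b$runs[b$outcomes == "win"])
    expect_equal(r$census$pc_infected[nrow(r$census)], 0)
})

test_that("sweeps reuse the batch machinery with disjoint seed blocks", {
  cfg <- small_config(stop_tick = 100L, checkpoint_interval = 50L)
  sw <- sweep_parameter(cfg, "Dendritic", values = c(10L, 40L),
                        n_per_value = 2, seed_base = 5L)
  expect_equal(nrow(sw$table), 2)
  expect_equal(sw$table$n_win + (sw$table$n_runs - sw$table$n_win),
               rep(2, 2))
  s1 <- vapply(sw$batches[[1]]$runs, `[[`, 0L, "seed")
  s2 <- vapply(sw$batches[[2]]$runs, `[[`, 0L, "seed")
  expect_length(intersect(s1, s2), 0)
  expect_equal(sw$batches[[2]]$config$counts[["Dendritic"]], 40L)
  # a single-value sweep is just a batch
  sw1 <- sweep_parameter(cfg, "Dendritic", values = 40L, n_per_value = 2,
                         seed_base = 5L)
  b <- batch(modify_config(cfg, counts = c(Dendritic = 40L)), 2, 5L)
  expect_equal(sw1$batches[[1]]$outcomes, b$outcomes)
  expect_error(sweep_parameter(cfg, "not_a_parameter", 1, 1),
               "unknown parameter")
})

test_that("portal queues neither lose nor duplicate agents", {
  r <- traced_small_run()
  au <- r$portal_audit
  fin <- r$final_agents
  # the engine's queue audit agrees with the per-agent waiting flags
  expect_equal(au$still_queued, sum(fin$alive & fin$in_queue))
  # queued agents were at most those that ever asked to migrate
  expect_lte(au$still_queued, au$enqueued)
  expect_false(any(duplicated(fin$id)))  # no agent lost or duplicated
})
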