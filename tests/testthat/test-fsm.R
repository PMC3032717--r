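test_that("declared automata cover all nine agent types", {
  fsm <- agent_fsms()
  expect_setequal(names(fsm), c("Parenchymal", "Portal", "Dendritic",
                                "Macrophage", "NaturalKiller", "Granulocyte",
                                "TCell", "BCell", "CTL"))
  for (nm in names(fsm)) {
    e <- fsm[[nm]]$edges
    expect_true(all(e$from %in% fsm[[nm]]$states), info = nm)
    expect_true(all(e$to %in% fsm[[nm]]$states), info = nm)
  }
  expect_equal(nrow(fsm$Portal$edges), 0)  # portals never change state
})

test_that("automata round-trip through plain-text files", {
  dir <- file.path(tempdir(), "fsm-roundtrip")
  write_fsms(agent_fsms(), dir)
  expect_length(list.files(dir, pattern = "\\.fsm$"), 9)
  back <- read_fsms(dir)
  expect_equal(back, agent_fsms())
  unlink(dir, recursive = TRUE)
})

test_that("the trace validator flags undeclared edges and double steps", {
  good <- data.frame(tick = c(3L, 9L), agent_id = c(1L, 1L),
                     agent_type = "TCell",
                     from = c("T_Naive", "T_Activated"),
                     to = c("T_Activated", "T_Effector"),
                     trigger = c("antigen_presented", "division_complete"))
  expect_true(validate_trace(good)$valid)

  bad_edge <- good
  bad_edge$to[1] <- "T_Memory"  # naive cells cannot jump to memory
  v <- validate_trace(bad_edge)
  expect_false(v$valid)
  expect_true("undeclared_edge" %in% names(v$violations) ||
                "broken_chain" %in% names(v$violations))

  double <- good
  double$tick <- c(3L, 3L)  # two edges in one tick
  v2 <- validate_trace(double)
  expect_false(v2$valid)
  expect_true("multiple_edges_per_tick" %in% names(v2$violations))

  chain <- good
  chain$from[2] <- "T_Naive"  # does not chain from the previous to-state
  expect_false(validate_trace(chain)$valid)
})
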