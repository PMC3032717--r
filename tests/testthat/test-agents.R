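test_that("every transition in a full trace is a declared automaton edge", {
  r <- traced_small_run()
  expect_gt(nrow(r$trace), 100)
  v <- validate_trace(r$trace)
  expect_true(v$valid)
})

test_that("no agent follows more than one edge per tick", {
  tr <- traced_small_run()$trace
  expect_false(any(duplicated(tr[, c("agent_id", "tick")])))
})

test_that("dead agents make no further transitions", {
  tr <- traced_small_run()$trace
  dead_states <- grep("Dead", cpp_state_names(), value = TRUE)
  expect_false(any(tr$from %in% dead_states))
})

test_that("only antigen-specific lymphocytes ever become activated", {
  fin <- traced_small_run()$final_agents
  act <- fin[fin$type %in% c("TCell", "BCell", "CTL") &
               !grepl("Naive|Dead", fin$state), ]
  expect_gt(nrow(act), 0)       # the response did fire
  expect_true(all(act$specific))
})

test_that("dendritic activation precedes specific T-cell activation", {
  tr <- traced_small_run()$trace
  dc_act <- tr$tick[tr$agent_type == "Dendritic" & tr$to == "DC_Activated"]
  t_act <- tr$tick[tr$agent_type == "TCell" & tr$to == "T_Activated"]
  expect_gt(length(dc_act), 0)
  expect_gt(length(t_act), 0)
  # antigen presentation strictly precedes T activation; recruitment keeps
  # activating fresh dendritic agents all run, so compare onsets
  expect_lt(min(dc_act), min(t_act))
  expect_lt(median(sort(dc_act)[seq_along(t_act)]), median(t_act))
})

test_that("dendritic agents are activated by infected tissue with danger signal", {
  tr <- traced_small_run()$trace
  expect_true("activation_infected_pc" %in%
                tr$trigger[tr$agent_type == "Dendritic"])
})

test_that("infected parenchymal cells stress neighbours and die by lysis", {
  tr <- traced_small_run()$trace
  pc <- tr[tr$agent_type == "Parenchymal", ]
  expect_true("adjacent_infected" %in% pc$trigger)
  expect_true("viral_lysis" %in% pc$trigger)
  expect_true("virus_threshold" %in% pc$trigger)
})

test_that("innate killing fires and leukocyte helpers complete the loop", {
  tr <- traced_small_run()$trace
  expect_true(any(tr$trigger %in% c("killed_nk", "killed_mac",
                                    "killed_gran", "killed_ctl")))
  expect_true("tcell_help" %in% tr$trigger)       # B -> plasma via T help
  expect_true("arrived_zone2" %in% tr$trigger)    # DC migration completed
})

test_that("macrophages record one-sided contacts with dead agents", {
  r <- traced_small_run()
  expect_gt(sum(r$pair_onesided["Macrophage", ]), 0)
})

test_that("crowded presenting dendritic agents register mutual contacts", {
  r <- run(dc_crowd_config(4L, seed = 2L))
  ck <- r$checkpoints
  dd <- ck[ck$agent_type == "Dendritic" & ck$partner_type == "Dendritic" &
             ck$zone == 2 & ck$tick == max(ck$tick), ]
  expect_gte(nrow(dd), 2)          # at least two DCs hold DC-DC contacts
  expect_true(all(dd$count > 0))
  expect_gt(r$pair_live["Dendritic", "Dendritic"], 0)
})

test_that("an empty lymphoid zone produces no dendritic self-contacts", {
  r <- run(dc_crowd_config(1L, seed = 3L))
  expect_equal(r$pair_live["Dendritic", "Dendritic"], 0L)
})

test_that("no cell ever holds two mobile agents", {
  r <- traced_small_run()
  expect_equal(r$occ_violations, 0)
  fin <- r$final_agents
  mob <- fin[fin$type != "Parenchymal" & !fin$removed, ]
  expect_false(any(duplicated(mob[, c("zone", "x", "y")])))
})
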