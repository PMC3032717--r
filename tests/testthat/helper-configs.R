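# shared fixtures: reduced worlds so unit tests run in milliseconds, plus a
# memoised traced run reused by several test files

small_config <- function(seed = 11L, stop_tick = 200L,
                         checkpoint_interval = 50L) {
  default_config(
    zones = list(side = c(41L, 21L, 31L), pc_block_side = 25L),
    counts = c(Dendritic = 40L, Macrophage = 20L, NaturalKiller = 10L,
               Granulocyte = 20L, TCell = 40L, BCell = 40L, CTL = 15L),
    specific = c(TCell = 3L, BCell = 3L, CTL = 3L),
    stop_tick = stop_tick, checkpoint_interval = checkpoint_interval,
    seed = seed)
}

# a Zone-2-only scenario: presenting dendritic agents in a 5x5 lymphoid zone
dc_crowd_config <- function(n_dc, seed = 2L, stop_tick = 60L) {
  default_config(
    zones = list(side = c(15L, 5L, 9L), pc_block_side = 5L),
    counts = c(Dendritic = 0L, Macrophage = 0L, NaturalKiller = 0L,
               Granulocyte = 0L, TCell = 0L, BCell = 0L, CTL = 0L),
    specific = c(TCell = 0L, BCell = 0L, CTL = 0L),
    dc_presenting_z2 = n_dc,
    pars = c(dc_influx = 0),  # no recruitment: only the staged agents act
    stop_tick = stop_tick, checkpoint_interval = stop_tick, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

traced_small_run <- function() {
  if (is.null(.fixture_env$traced)) {
    .fixture_env$traced <- run(small_config(), trace = TRUE)
  }
  .fixture_env$traced
}

small_batch <- function() {
  if (is.null(.fixture_env$batch3)) {
    .fixture_env$batch3 <- batch(small_config(stop_tick = 150L,
                                              checkpoint_interval = 50L),
                                 n_runs = 3, seed_base = 21L)
  }
  .fixture_env$batch3
}
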