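#' Run one simulation
#'
#' Executes a complete simulation run.  Each tick: (1) the agent activation
#' order is reshuffled (emulating concurrency), (2) every agent senses its
#' local environment and follows at most one state-machine edge, (3) all
#' signal fields diffuse, (4) portals transfer signals and process their
#' migration queues in FIFO order, (5) a census row is appended, and (6) a
#' contact-ledger checkpoint is written when the tick is a multiple of the
#' checkpoint interval.  A fixed seed and configuration give a bit-identical
#' trajectory.
#'
#' @param config an `immunet_config` (see [default_config()]).
#' @param trace record every state transition (tick, agent, edge, trigger)
#'   for validation with [validate_trace()]; memory-heavy on full runs.
#' @return an `immune_run` with elements
#'   \describe{
#'     \item{census}{data.frame, one row per tick: live agent counts by
#'       type and zone, parenchymal state counts, activated-DC phenotype
#'       counts in Zone 2, lymphocyte state counts, and per-signal zone
#'       totals.}
#'     \item{checkpoints}{data.frame of cumulative meaningful-contact
#'       counts per agent, partner type and zone at tick 0 and at every
#'       checkpoint interval; unengaged agents appear with partner
#'       `"none"` and count 0 so engagement denominators are computable.}
#'     \item{outcome}{`"win"` (infection cleared with more than half of the
#'       tissue agents surviving or regenerated) or `"loss"`.}
#'     \item{pair_live, pair_onesided}{type-by-type contact totals for
#'       live-live and live-dead recordings.}
#'     \item{final_agents}{snapshot of every agent ever created (state,
#'       position, flags) at the final tick.}
#'     \item{trace}{transition log when `trace = TRUE`.}
#'   }
#' @examples
#' \donttest{
#' r <- run(default_config(seed = 7L))
#' r$outcome
#' }
#' @export
run <- function(config = default_config(), trace = FALSE) {
  config <- validate_config(config)
  if (config$scenario == "bacterial")
    stop("the bacterial scenario is not implemented; supply rule tables ",
         "to enable it")
  set.seed(config$seed)
  raw <- cpp_run(config, trace)

  census <- as.data.frame(raw$census)
  census$tick <- seq_len(nrow(census))

  ck <- as.data.frame(raw$checkpoints)
  tn <- cpp_type_names()
  ck$agent_type <- tn[ck$agent_type + 1L]
  ck$partner_type <- ifelse(ck$partner_type < 0, "none",
                            tn[pmax(ck$partner_type, 0L) + 1L])
  ck$alive <- ck$alive == 1L

  pl <- raw$pair_live; po <- raw$pair_onesided
  dimnames(pl) <- dimnames(po) <- list(tn, tn)

  fin <- as.data.frame(raw$agents_final)
  sn <- cpp_state_names()
  fin$type <- tn[fin$type + 1L]
  fin$state <- sn[fin$state + 1L]
  fin$phenotype <- c("none", "DC1", "DC2", "Th1", "Treg")[fin$phenotype + 1L]

  res <- structure(list(
    census = census,
    checkpoints = ck,
    checkpoint_ticks = sort(unique(ck$tick[ck$tick > 0L])),
    pair_live = pl,
    pair_onesided = po,
    final_agents = fin,
    n_pc_init = raw$n_pc_init,
    portal_audit = raw$portal_audit,
    occ_violations = raw$occ_violations,
    seed = config$seed,
    config = config), class = "immune_run")
  if (trace) {
    tr <- as.data.frame(raw$trace)
    sn <- cpp_state_names(); gn <- cpp_trigger_names()
    tr$agent_type <- tn[tr$agent_type + 1L]
    tr$from <- sn[tr$from + 1L]
    tr$to <- sn[tr$to + 1L]
    tr$trigger <- gn[tr$trigger + 1L]
    res$trace <- tr
  }
  res$outcome <- classify_outcome(res)
  res
}

#' Classify the outcome of a completed run
#'
#' A *win* requires the infection to be cleared (zero infected parenchymal
#' agents at the final tick) **and** more than half of the initial tissue
#' layout to be alive (healthy or stressed, including regenerated cells).
#' Everything else — persisting infection, total tissue death, or clearance
#' with half or fewer survivors — is a *loss*.
#'
#' @param x an `immune_run`, or a census data.frame (then `n_pc_init` must
#'   be given).
#' @param n_pc_init initial number of parenchymal agents.
#' @return `"win"` or `"loss"`.
#' @export
classify_outcome <- function(x, n_pc_init = NULL) {
  if (inherits(x, "immune_run")) {
    census <- x$census
    n_pc_init <- x$n_pc_init
  } else {
    census <- x
    stopifnot(!is.null(n_pc_init))
  }
  fin <- census[nrow(census), ]
  cleared <- fin$pc_infected == 0
  alive <- fin$pc_healthy + fin$pc_stressed
  if (cleared && alive > 0.5 * n_pc_init) "win" else "loss"
}

#' @export
print.immune_run <- function(x, ...) {
  fin <- x$census[nrow(x$census), ]
  cat("<immune_run>", nrow(x$census), "ticks, outcome:", x$outcome, "\n")
  cat("  final: infected =", fin$pc_infected,
      "healthy =", fin$pc_healthy,
      "(of", x$n_pc_init, "initial parenchymal agents)\n")
  cat("  checkpoints at:", paste(x$checkpoint_ticks, collapse = " "), "\n")
  invisible(x)
}

#' Census and checkpoint CSV files
#'
#' Plain comma-separated text with a header row, UTF-8, LF line endings.
#' The checkpoint schema is `tick, agent_id, agent_type, alive,
#' partner_type, zone, count`; files round-trip losslessly through
#' `read_checkpoints()`.
#'
#' @param run an `immune_run`.
#' @param path output file.
#' @export
write_census <- function(run, path) {
  data.table::fwrite(run$census, path, eol = "\n")
  invisible(path)
}

#' @rdname write_census
#' @export
write_checkpoints <- function(run, path) {
  ck <- if (inherits(run, "immune_run")) run$checkpoints else run
  data.table::fwrite(ck, path, eol = "\n")
  invisible(path)
}

#' @rdname write_census
#' @export
read_checkpoints <- function(path) {
  as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                  logical01 = FALSE))
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  as.data.frame(data.table::fread(path, sep = ",", header = TRUE))
}
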