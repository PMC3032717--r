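#' Replicate batches of simulation runs
#'
#' Runs `n_runs` simulations with sequential seeds `seed_base, seed_base +
#' 1, ...`, classifies each outcome, and pools the contact checkpoints with
#' run and outcome labels for the network analyses.
#'
#' @param config an `immunet_config`.
#' @param n_runs number of replicate runs (>= 1).
#' @param seed_base first seed; run `i` uses `seed_base + i - 1`.
#' @param progress print one line per finished run.
#' @return an `immune_batch`: `runs` (list of `immune_run`s), `outcomes`,
#'   `n_win`, `n_loss`, and `pooled_checkpoints` (all runs' checkpoint
#'   tables with `run` and `outcome` columns).
#' @seealso [census_band()] for per-outcome mean time courses with 95%
#'   confidence bands, [engagement_timecourse()], [hub_table()],
#'   [degree_distribution()].
#' @export
batch <- function(config = default_config(), n_runs, seed_base = 1L,
                  progress = FALSE) {
  stopifnot(n_runs >= 1)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(seed_base + i - 1L)
    runs[[i]] <- run(cfg)
    if (progress)
      message(sprintf("run %d/%d (seed %d): %s", i, n_runs, cfg$seed,
                      runs[[i]]$outcome))
  }
  outcomes <- vapply(runs, `[[`, "", "outcome")
  pooled <- data.table::rbindlist(lapply(seq_len(n_runs), function(i) {
    ck <- runs[[i]]$checkpoints
    ck$run <- i
    ck$outcome <- outcomes[i]
    ck
  }))
  structure(list(
    runs = runs, n_runs = n_runs, seed_base = seed_base,
    outcomes = outcomes,
    n_win = sum(outcomes == "win"), n_loss = sum(outcomes == "loss"),
    pooled_checkpoints = as.data.frame(pooled),
    config = config), class = "immune_batch")
}

#' @export
print.immune_batch <- function(x, ...) {
  cat("<immune_batch>", x$n_runs, "runs:", x$n_win, "win /", x$n_loss,
      "loss\n")
  invisible(x)
}

#' Per-outcome census time course with confidence band
#'
#' Mean of a census column at every tick within an outcome class, with the
#' normal-approximation 95% confidence interval (mean +- 1.96 sd / sqrt(n)).
#'
#' @param batch an `immune_batch`.
#' @param column census column name, e.g. `"pc_infected"` or `"dc1_z2"`.
#' @param outcome `"win"` or `"loss"`.
#' @return data.frame `tick`, `mean`, `lower`, `upper`, `n`.
#' @export
census_band <- function(batch, column = "pc_infected",
                        outcome = c("win", "loss")) {
  outcome <- match.arg(outcome)
  sel <- which(batch$outcomes == outcome)
  if (!length(sel))
    return(data.frame(tick = integer(0), mean = numeric(0),
                      lower = numeric(0), upper = numeric(0), n = integer(0)))
  m <- sapply(batch$runs[sel], function(r) r$census[[column]])
  if (is.null(dim(m))) m <- matrix(m, ncol = length(sel))
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  half <- 1.96 * sdv / sqrt(length(sel))
  data.frame(tick = seq_along(mu), mean = mu, lower = mu - half,
             upper = mu + half, n = length(sel))
}

#' Parameter sweeps
#'
#' Runs one batch per parameter value (e.g. the number of Dendritic Agents
#' in \{20, 100, 200, 300\}) and tabulates the win percentage against the
#' value.  Each value gets a disjoint block of sequential seeds.
#'
#' @param config an `immunet_config`.
#' @param parameter name of an initial-count entry (`"Dendritic"`, ...), a
#'   rule constant in `config$pars`, or a numeric top-level entry.
#' @param values vector of values to sweep.
#' @param n_per_value replicate runs per value.
#' @param seed_base seeds for value `j` are
#'   `seed_base + (j-1) * n_per_value + 0:(n_per_value-1)`.
#' @return an `immune_sweep`: list of batches plus a `table` of win
#'   fractions per value.
#' @export
sweep_parameter <- function(config = default_config(), parameter, values,
                            n_per_value, seed_base = 1L, progress = FALSE) {
  set_par <- function(cfg, value) {
    if (parameter %in% names(cfg$counts)) {
      cfg$counts[[parameter]] <- as.integer(value)
    } else if (parameter %in% names(cfg$pars)) {
      cfg$pars[[parameter]] <- value
    } else if (parameter %in% names(cfg) && is.numeric(cfg[[parameter]])) {
      cfg[[parameter]] <- value
    } else {
      stop("unknown parameter: ", parameter)
    }
    validate_config(cfg)
  }
  batches <- vector("list", length(values))
  for (j in seq_along(values)) {
    cfg <- set_par(config, values[j])
    batches[[j]] <- batch(cfg, n_per_value,
                          seed_base + (j - 1L) * n_per_value,
                          progress = progress)
  }
  tab <- data.frame(
    value = values,
    n_runs = n_per_value,
    n_win = vapply(batches, `[[`, 0L, "n_win"),
    win_pct = 100 * vapply(batches, `[[`, 0L, "n_win") / n_per_value)
  structure(list(parameter = parameter, values = values, batches = batches,
                 table = tab), class = "immune_sweep")
}

#' @export
print.immune_sweep <- function(x, ...) {
  cat("<immune_sweep> over", x$parameter, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
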