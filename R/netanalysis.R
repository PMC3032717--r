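#' Two-tailed Mann-Whitney U test with Bonferroni correction
#'
#' Nonparametric comparison of two samples as used for all win-vs-loss
#' contrasts: the U statistic and two-tailed p-value (exact when the
#' combined sample size is at most 12 and tie-free, normal approximation
#' with tie and continuity correction otherwise), declared significant at
#' the Bonferroni-adjusted level `0.05 / m` for `m` comparisons.
#'
#' @param x,y numeric samples (nonempty).
#' @param m number of comparisons in the family.
#' @return a `group_comparison`: `U`, `p`, `m`, `alpha_adj`, `significant`.
#' @examples
#' mann_whitney_bonferroni(c(1, 2, 3), c(4, 5, 6), m = 1)  # U = 0, p = 0.1
#' @export
mann_whitney_bonferroni <- function(x, y, m = 1L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  stopifnot(m >= 1)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  p <- min(1, wt$p.value)
  if (is.nan(p)) p <- 1  # degenerate case: every pooled value identical
  structure(list(U = unname(wt$statistic), p = p, m = as.integer(m),
                 alpha_adj = 0.05 / m, significant = p <= 0.05 / m),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-tailed p = %.4g (alpha_adj = %.4g%s)\n",
              x$U, x$p, x$alpha_adj,
              if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Engagement time course per agent type and outcome
#'
#' For every checkpoint tick (including tick 0, where engagement is zero by
#' definition) and every immune agent type: the median and quartiles, over
#' runs of each outcome class, of the percentage of agents engaged, with a
#' win-vs-loss Mann-Whitney comparison per tick (Bonferroni-corrected over
#' the ticks compared for that type).
#'
#' @param batch an `immune_batch`.
#' @param types agent types (default: the seven leukocyte types).
#' @return data.frame with columns `agent_type`, `tick`, `outcome`,
#'   `median`, `q25`, `q75`, `n_runs`, `p`, `significant` (`p` is `NA`
#'   when an outcome class is empty).
#' @export
engagement_timecourse <- function(batch, types = immune_types()) {
  ticks <- c(0L, batch$runs[[1]]$checkpoint_ticks)
  per_run <- function(r, type, tk)
    engagement_fraction(r$checkpoints[r$checkpoints$tick == tk, ], type)
  out <- list()
  for (type in types) {
    vals <- lapply(ticks, function(tk)
      vapply(batch$runs, per_run, 0, type = type, tk = tk))
    both <- batch$n_win > 0 && batch$n_loss > 0
    m <- if (both) sum(ticks > 0L) else 1L
    for (k in seq_along(ticks)) {
      v <- vals[[k]]
      for (oc in c("win", "loss")) {
        sel <- v[batch$outcomes == oc]
        sel <- sel[!is.na(sel)]
        if (!length(sel)) next
        q <- stats::quantile(sel, c(0.25, 0.5, 0.75), names = FALSE)
        p <- NA_real_; sig <- NA
        if (both && ticks[k] > 0L) {
          w <- v[batch$outcomes == "win"]; l <- v[batch$outcomes == "loss"]
          w <- w[!is.na(w)]; l <- l[!is.na(l)]
          if (length(w) && length(l)) {
            cmp <- mann_whitney_bonferroni(w, l, m = m)
            p <- cmp$p; sig <- cmp$significant
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          agent_type = type, tick = ticks[k], outcome = oc,
          median = q[2], q25 = q[1], q75 = q[3], n_runs = length(sel),
          p = p, significant = sig)
      }
    }
  }
  do.call(rbind, out)
}

#' Degree (links-per-node) frequency distribution and power-law check
#'
#' Pools the cumulative links per node of engaged agents across runs (of
#' one outcome class if requested), histograms them, and tests the
#' scale-free signature the way the study's figures do: a Spearman
#' correlation on the raw (links-per-node, node-count) pairs and a linear
#' regression on the log10-log10 points.  With fewer than three distinct
#' degree values the fit is reported as undetermined.
#'
#' @param tables pooled checkpoint rows (e.g.
#'   `batch$pooled_checkpoints`).
#' @param agent_type one type name, or `"combined"` for all leukocyte
#'   types together.
#' @param outcome restrict to `"win"` or `"loss"` runs (requires an
#'   `outcome` column); `NULL` pools everything.
#' @param at_tick checkpoint tick (default latest).
#' @return a `distribution_fit`: histogram points (raw and log10),
#'   `n_agents`, `spearman_r`, `spearman_p`, regression `slope` and
#'   `intercept`, and `determined`.
#' @export
degree_distribution <- function(tables, agent_type = "combined",
                                outcome = NULL, at_tick = NULL) {
  if (!is.null(outcome)) {
    stopifnot("outcome" %in% names(tables))
    tables <- tables[tables$outcome == outcome, , drop = FALSE]
  }
  types <- if (identical(agent_type, "combined")) immune_types() else
    agent_type
  deg <- links_per_node(tables, types, at_tick = at_tick,
                        engaged_only = TRUE)
  tab <- table(deg)
  links <- as.numeric(names(tab))
  nodes <- as.numeric(tab)
  fit <- list(points = data.frame(links = links, nodes = nodes,
                                  log10_links = log10(links),
                                  log10_nodes = log10(nodes)),
              n_agents = length(deg),
              agent_type = agent_type, outcome = outcome,
              spearman_r = NA_real_, spearman_p = NA_real_,
              slope = NA_real_, intercept = NA_real_,
              determined = length(links) >= 3L)
  if (fit$determined) {
    ct <- suppressWarnings(
      stats::cor.test(nodes, links, method = "spearman"))
    lm0 <- stats::lm(log10(nodes) ~ log10(links))
    fit$spearman_r <- unname(ct$estimate)
    fit$spearman_p <- ct$p.value
    fit$slope <- unname(stats::coef(lm0)[2])
    fit$intercept <- unname(stats::coef(lm0)[1])
  }
  structure(fit, class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat("<distribution_fit>", x$agent_type,
      if (!is.null(x$outcome)) paste0("(", x$outcome, ")"), "\n")
  cat("  ", x$n_agents, "engaged agents,", nrow(x$points),
      "distinct degrees\n")
  if (x$determined) {
    cat(sprintf("  Spearman r = %.4f (p = %.3g); log-log slope = %.3f\n",
                x$spearman_r, x$spearman_p, x$slope))
  } else {
    cat("  fit undetermined (fewer than 3 distinct degree values)\n")
  }
  invisible(x)
}

#' Log-log degree-frequency plot
#'
#' @param fit a `distribution_fit`.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics abline
#' @export
plot_degree_fit <- function(fit, ...) {
  p <- fit$points
  graphics::plot(p$log10_links, p$log10_nodes,
       xlab = "log10 links per node", ylab = "log10 number of nodes", ...)
  if (fit$determined)
    graphics::abline(fit$intercept, fit$slope, lty = 2)
  invisible(fit)
}

#' Median links per node per type, and hub identification
#'
#' For every checkpoint tick, the median cumulative links per node of each
#' agent type, pooled across the batch's runs; the *hub* at a tick is the
#' leukocyte type with the greatest median.  Medians are computed over
#' engaged agents (at least one link) by default, with an over-all-agents
#' variant.
#'
#' @param batch an `immune_batch` (or pooled checkpoint rows).
#' @param types agent types (default: the seven leukocyte types).
#' @param engaged_only restrict to engaged agents.
#' @return list: `medians` (types x ticks matrix), `hub` (named character
#'   vector, hub type per tick).
#' @export
hub_table <- function(batch, types = immune_types(), engaged_only = TRUE) {
  tables <- if (inherits(batch, "immune_batch")) batch$pooled_checkpoints
            else batch
  ticks <- sort(unique(tables$tick[tables$tick > 0]))
  med <- matrix(NA_real_, length(types), length(ticks),
                dimnames = list(types, ticks))
  for (type in types)
    for (k in seq_along(ticks)) {
      deg <- links_per_node(tables, type, at_tick = ticks[k],
                            engaged_only = engaged_only)
      if (!engaged_only) {
        # include currently present zero-contact agents
        t0 <- tables[tables$tick == ticks[k] &
                       tables$agent_type == type, , drop = FALSE]
        id <- if ("run" %in% names(t0)) paste(t0$run, t0$agent_id) else
          as.character(t0$agent_id)
        deg <- rowsum(t0$count, id)[, 1]
      }
      if (length(deg)) med[type, k] <- stats::median(deg)
    }
  hub <- apply(med, 2, function(col)
    if (all(is.na(col))) NA_character_ else names(which.max(col)))
  list(medians = med, hub = hub)
}

#' Synthetic power-law degree sample
#'
#' Draws `n` degrees from a discrete power law `P(k) ~ k^-alpha` on
#' `kmin..kmax` by inverse-CDF sampling — a fixture for validating the
#' log-log fitting machinery against a known exponent.
#'
#' @param n sample size.
#' @param alpha exponent (> 1).
#' @param kmin,kmax support bounds.
#' @return integer vector of degrees.
#' @export
rpowerlaw_degrees <- function(n, alpha = 2, kmin = 1L, kmax = 100L) {
  stopifnot(alpha > 1, kmin >= 1, kmax > kmin)
  k <- seq.int(kmin, kmax)
  p <- k^(-alpha)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}
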