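#' Engagement fraction at a checkpoint
#'
#' An agent is *engaged* once it has made at least one meaningful contact
#' since the start of the run.  The engagement fraction of a type is
#' `100 * engaged / present` over the agents of that type alive at the
#' checkpoint; it can decrease between checkpoints when new (unengaged)
#' agents enter the world.
#'
#' @param table checkpoint rows for a single tick (optionally pooled over
#'   runs; a `run` column, if present, disambiguates agent ids).
#' @param agent_type one of the agent type names (see `cpp_type_names()`).
#' @return percentage in `[0, 100]`, or `NA` if no agent of the type is
#'   present.
#' @export
engagement_fraction <- function(table, agent_type) {
  t0 <- table[table$agent_type == agent_type & table$alive, , drop = FALSE]
  if (nrow(t0) == 0L) return(NA_real_)
  id <- if ("run" %in% names(t0)) paste(t0$run, t0$agent_id) else
    as.character(t0$agent_id)
  eng <- rowsum(t0$count, id)
  100 * sum(eng[, 1] > 0) / nrow(eng)
}

#' Per-agent pairwise contact distributions
#'
#' The distribution, over recorder agents of one type, of their cumulative
#' meaningful-contact count with a partner type in a zone (the first type
#' *records* the contact; counts are never reset when an agent changes
#' zone, so Zone-2 values carry Zone-1 history).  Quartiles use linear
#' interpolation between order statistics.
#'
#' @param tables pooled checkpoint rows (a `run` column disambiguates ids).
#' @param recorder_type,partner_type agent type names.
#' @param zone zone of the interaction (1, 2 or 3).
#' @param at_tick checkpoint tick to evaluate (default: the latest in
#'   `tables`).
#' @param engaged_on `"pair"` restricts to recorders with at least one
#'   contact with this partner/zone (agents without any are excluded);
#'   `"any"` restricts to recorders engaged with anyone and keeps their
#'   zeros for this pair.
#' @return list with `median`, `q25`, `q75`, `n` and the per-agent
#'   `counts`; all-`NA` summary when no eligible recorder exists.
#' @export
pairwise_contact_stats <- function(tables, recorder_type, partner_type,
                                   zone, at_tick = NULL,
                                   engaged_on = c("pair", "any")) {
  engaged_on <- match.arg(engaged_on)
  if (is.null(at_tick)) at_tick <- max(tables$tick)
  t0 <- tables[tables$tick == at_tick & tables$agent_type == recorder_type, ,
               drop = FALSE]
  empty <- list(median = NA_real_, q25 = NA_real_, q75 = NA_real_, n = 0L,
                counts = numeric(0))
  if (nrow(t0) == 0L) return(empty)
  id <- if ("run" %in% names(t0)) paste(t0$run, t0$agent_id) else
    as.character(t0$agent_id)
  sel <- t0$partner_type == partner_type & t0$zone == zone
  if (engaged_on == "pair") {
    counts <- rowsum(t0$count[sel], id[sel])
    counts <- counts[counts[, 1] > 0, 1]
  } else {
    tot <- rowsum(t0$count, id)
    engaged <- rownames(tot)[tot[, 1] > 0]
    pair <- rowsum(t0$count[sel], id[sel])
    counts <- stats::setNames(rep(0, length(engaged)), engaged)
    hit <- intersect(engaged, rownames(pair))
    counts[hit] <- pair[hit, 1]
  }
  if (length(counts) == 0L) return(empty)
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(counts),
       counts = unname(counts))
}

#' Per-agent total links (degree) at a checkpoint
#'
#' Cumulative meaningful-contact count per agent — the "links per node" of
#' the contact network (repeat contacts included).
#'
#' @param tables pooled checkpoint rows.
#' @param types agent types to include.
#' @param at_tick checkpoint tick.
#' @param engaged_only drop zero-contact agents.
#' @param distinct_partners count distinct (partner type, zone) categories
#'   instead of cumulative contacts (a non-default variant).
#' @return named numeric vector of degrees (names are `run:agent` keys).
#' @export
links_per_node <- function(tables, types, at_tick = NULL,
                           engaged_only = TRUE, distinct_partners = FALSE) {
  if (is.null(at_tick)) at_tick <- max(tables$tick)
  t0 <- tables[tables$tick == at_tick & tables$agent_type %in% types, ,
               drop = FALSE]
  if (nrow(t0) == 0L) return(numeric(0))
  id <- if ("run" %in% names(t0)) paste(t0$run, t0$agent_id) else
    as.character(t0$agent_id)
  v <- if (distinct_partners) as.numeric(t0$count > 0) else t0$count
  deg <- rowsum(v, id)[, 1]
  if (engaged_only) deg <- deg[deg > 0]
  deg
}

# immune (leukocyte) agent types: everything but tissue cells and portals
immune_types <- function() {
  setdiff(cpp_type_names(), c("Parenchymal", "Portal"))
}
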