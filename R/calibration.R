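#' Tick of the peak of a time series
#'
#' 1-based tick of the maximum; the earliest tick wins on ties.
#'
#' @param series nonempty numeric per-tick series.
#' @return integer tick.
#' @examples
#' peak_tick(c(0, 2, 5, 3))  # 3
#' peak_tick(c(5, 5, 1))     # 1
#' @export
peak_tick <- function(series) {
  if (length(series) == 0L) stop("empty series")
  which.max(series)
}

#' Minutes of physical time represented by one tick
#'
#' Maps simulation ticks to physical time through an immune-response
#' hallmark: if a hallmark (say, the serum IgM peak) occurs at `peak_tick`
#' ticks in the simulation and at `human_day` days in humans, then one tick
#' represents `1440 * human_day / peak_tick` minutes.  The display value is
#' rounded half-away-from-zero to the nearest minute.
#'
#' @param peak_tick tick of the simulated hallmark peak (> 0).
#' @param human_day literature day of the human hallmark peak (> 0).
#' @return list: `ticks_per_day`, `minutes_per_tick` (unrounded) and
#'   `minutes_per_tick_rounded`.
#' @examples
#' minutes_per_tick(159, 8.5)  # 18.7 ticks/day, 77 minutes/tick
#' @export
minutes_per_tick <- function(peak_tick, human_day) {
  if (peak_tick <= 0 || human_day <= 0)
    stop("peak_tick and human_day must be positive")
  mpt <- 1440 * human_day / peak_tick
  list(ticks_per_day = peak_tick / human_day,
       minutes_per_tick = mpt,
       minutes_per_tick_rounded = sign(mpt) * floor(abs(mpt) + 0.5))
}

#' Convert a tick to days of physical time
#'
#' @param tick tick number (> 0).
#' @param minutes_per_tick calibration factor in minutes (> 0).
#' @return days.
#' @examples
#' ticks_to_days(96.75, 64)  # ~4.3 days
#' @export
ticks_to_days <- function(tick, minutes_per_tick) {
  if (any(tick <= 0) || minutes_per_tick <= 0)
    stop("tick and minutes_per_tick must be positive")
  tick * minutes_per_tick / 1440
}

#' Hallmark registry for tick calibration
#'
#' Immune-response hallmarks usable for the tick-to-time calibration: the
#' serum IgM/IgG peaks (Zone 3 antibody signals) and mucosal virus/IgM/IgA
#' peaks (Zone 1 signals).  Only the serum IgM day (8.5, the midpoint of
#' the 7-10 day literature window) ships with a value; the others are
#' supplied by the user from their preferred literature source.
#'
#' @return data.frame: `name`, `zone_id`, `signals` (comma-separated;
#'   averaged when several), `human_day`.
#' @export
hallmarks <- function() {
  data.frame(
    name = c("serum_IgM", "serum_IgG", "mucosal_virus", "mucosal_IgM",
             "mucosal_IgA"),
    zone_id = c(3L, 3L, 1L, 1L, 1L),
    signals = c("Ab5", "Ab1,Ab2", "Virus", "Ab5", "Ab1,Ab2"),
    human_day = c(8.5, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Calibrate ticks to physical time from simulated hallmark peaks
#'
#' For each hallmark with a literature day, averages the named signal
#' series (within their zone) over the supplied censuses, finds the peak
#' tick, and converts to minutes per tick; reports the per-hallmark values
#' plus their mean and range.
#'
#' @param censuses a census data.frame or a list of them (typically the
#'   win-class runs of a batch).
#' @param hallmark_table as [hallmarks()], rows with `NA` days are skipped.
#' @return a `calibration_result`: data.frame of per-hallmark results with
#'   attributes `mean_minutes_per_tick` and `range`.
#' @export
calibrate <- function(censuses, hallmark_table = hallmarks()) {
  if (is.data.frame(censuses)) censuses <- list(censuses)
  hm <- hallmark_table[!is.na(hallmark_table$human_day), , drop = FALSE]
  if (nrow(hm) == 0L) stop("no hallmark has a literature day")
  rows <- lapply(seq_len(nrow(hm)), function(i) {
    sigs <- strsplit(hm$signals[i], ",")[[1]]
    cols <- paste0("sig_", trimws(sigs), "_z", hm$zone_id[i])
    series <- Reduce(`+`, lapply(censuses, function(cen) {
      miss <- setdiff(cols, names(cen))
      if (length(miss)) stop("census lacks columns: ",
                             paste(miss, collapse = ", "))
      rowMeans(as.matrix(cen[, cols, drop = FALSE]))
    })) / length(censuses)
    pk <- peak_tick(series)
    cal <- minutes_per_tick(pk, hm$human_day[i])
    data.frame(name = hm$name[i], peak_tick = pk,
               human_day = hm$human_day[i],
               ticks_per_day = cal$ticks_per_day,
               minutes_per_tick = cal$minutes_per_tick,
               minutes_per_tick_rounded = cal$minutes_per_tick_rounded)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_minutes_per_tick") <- mean(out$minutes_per_tick)
  attr(out, "range") <- range(out$minutes_per_tick)
  class(out) <- c("calibration_result", "data.frame")
  out
}
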