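#' Intracellular / free water split from a bi-exponential fit
#'
#' The long-T2 component of a two-component fit is read as intracellular
#' water (ICW, vacuole + cytoplasm) and the short-T2 component as free water
#' (FW, intercellular spaces). The percentages are amplitude fractions,
#' \eqn{ICW\% = 100 M_{long} / (M_{long} + M_{short})}, and sum to 100
#' exactly. One- or three-component fits have no defined ICW/FW reading and
#' raise an error (tightly bound cell-wall water is never fitted here).
#'
#' @param fit a `t2_fit` with exactly two (non-collapsed) components.
#' @return named numeric vector `c(icw_pct = , fw_pct = )`.
#' @export
assign_compartments <- function(fit) {
  if (!inherits(fit, "t2_fit")) stop("`fit` must be a t2_fit", call. = FALSE)
  if (isTRUE(fit$collapsed))
    stop("fit collapsed to fewer components; ICW/FW split undefined",
         call. = FALSE)
  m <- fit$model
  if (n_components(m) != 2)
    stop("ICW/FW assignment requires exactly 2 components, got ",
         n_components(m), call. = FALSE)
  tot <- sum(m$amplitudes)
  if (tot <= 0)
    stop("total amplitude is zero; fractions undefined", call. = FALSE)
  icw <- 100 * m$amplitudes[1] / tot
  c(icw_pct = icw, fw_pct = 100 - icw)
}

#' Compartment fraction series over drying time
#'
#' ICW%/FW% against drying time at one drying temperature. Total water at
#' each point is 100% by construction, so only the ICW percentage is stored;
#' FW% is derived.
#'
#' @param times drying times in minutes, strictly increasing.
#' @param icw_pct ICW percentages in `[0, 100]`, same length.
#' @param temperature_c drying temperature in Celsius.
#' @return object of class `compartment_series`: data.frame with columns
#'   `time_min`, `icw_pct`, `fw_pct` and attribute `temperature_c`.
#' @export
compartment_series <- function(times, icw_pct, temperature_c = NA_real_) {
  times <- as.numeric(times); icw_pct <- as.numeric(icw_pct)
  if (length(times) != length(icw_pct))
    stop("`times` and `icw_pct` must have the same length", call. = FALSE)
  if (anyNA(times) || anyNA(icw_pct))
    stop("series values must not be missing", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("drying times must be strictly increasing", call. = FALSE)
  if (any(icw_pct < 0 | icw_pct > 100))
    stop("ICW percentages must lie in [0, 100]", call. = FALSE)
  out <- data.frame(time_min = times, icw_pct = icw_pct,
                    fw_pct = 100 - icw_pct)
  attr(out, "temperature_c") <- temperature_c
  class(out) <- c("compartment_series", "data.frame")
  out
}

#' Assemble a compartment series from gated fits
#'
#' Converts a time-ordered collection of accepted bi-exponential fits into a
#' [compartment_series()]. Fits rejected by the SNR gate are excluded (and
#' reported via the `n_rejected`/`rejected_times` attributes) rather than
#' interpolated, so a low-quality measurement can neither fabricate nor hide
#' a rupture.
#'
#' @param fits list of `t2_fit` objects that have been through
#'   [gate_by_snr()].
#' @param times drying times in minutes, one per fit.
#' @param temperature_c drying temperature of the protocol.
#' @return a [compartment_series()] over the accepted time points.
#' @export
build_series <- function(fits, times, temperature_c = NA_real_) {
  if (length(fits) != length(times))
    stop("`fits` and `times` must have the same length", call. = FALSE)
  gated <- vapply(fits, function(f) !is.na(f$accepted), logical(1))
  if (!all(gated))
    stop("all fits must be gated (run gate_by_snr) before series assembly",
         call. = FALSE)
  keep <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  if (sum(keep) < 2)
    stop("fewer than 2 accepted fits; cannot build a series", call. = FALSE)
  o <- order(times[keep])
  icw <- vapply(fits[keep], function(f) assign_compartments(f)[["icw_pct"]],
                numeric(1))
  out <- compartment_series(times[keep][o], icw[o], temperature_c)
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "rejected_times") <- sort(times[!keep])
  out
}

#' Detect cell-rupture events in an ICW series
#'
#' A rupture shows as an abrupt drop of the intracellular-water percentage:
#' when cell membranes collapse, intracellular water is released to the
#' intercellular spaces and is re-labelled free water, so ICW% falls by tens
#' of percentage points within one sampling interval. An event is recorded at
#' every time point whose ICW% sits at least `min_drop_pp` percentage points
#' below the previous retained point; the preceding point is the "peak" of
#' the sawtooth. Events are timestamped at the post-drop measurement, the
#' first time the rupture is observable on the discrete sampling grid.
#'
#' @param series a [compartment_series()] with at least 3 points.
#' @param min_drop_pp detection threshold in percentage points. The default
#'   15 separates genuine rupture drops (>= ~22 pp in the reference data at
#'   60-70 degC) from the minor fluctuations (<= ~6 pp) of non-rupturing
#'   low-temperature drying.
#' @return data.frame of class `rupture_events` with columns `time_min` and
#'   `drop_pp`, time-ordered; zero rows when nothing is detected.
#' @examples
#' s <- compartment_series(c(30, 60, 90, 120), c(88, 87, 45, 69))
#' detect_rupture_events(s)   # one event at 90 min, drop 42 pp
#' @export
detect_rupture_events <- function(series, min_drop_pp = 15) {
  if (!inherits(series, "compartment_series"))
    stop("`series` must be a compartment_series", call. = FALSE)
  if (nrow(series) < 3)
    stop("need at least 3 points to scan for ruptures", call. = FALSE)
  if (!is.numeric(min_drop_pp) || length(min_drop_pp) != 1 ||
      is.na(min_drop_pp))
    stop("`min_drop_pp` must be a single number", call. = FALSE)
  drops <- -diff(series$icw_pct)
  hit <- which(drops >= min_drop_pp) + 1L
  out <- data.frame(time_min = series$time_min[hit],
                    drop_pp = drops[hit - 1L])
  class(out) <- c("rupture_events", "data.frame")
  out
}

#' Compare rupture behaviour across drying protocols
#'
#' Per-series summary used to contrast drying temperatures: number of
#' detected rupture events, time of the first event (NA when none), and the
#' final ICW percentage. Higher drying temperatures rupture earlier and end
#' with less intracellular water; gentle drying shows no events at all.
#'
#' @param series_list list of >= 2 [compartment_series()] objects.
#' @param min_drop_pp threshold passed to [detect_rupture_events()].
#' @return data.frame with one row per series: `temperature_c`, `n_events`,
#'   `first_event_min`, `final_icw_pct`.
#' @export
compare_series <- function(series_list, min_drop_pp = 15) {
  if (!is.list(series_list) || length(series_list) < 2)
    stop("need a list of at least 2 series", call. = FALSE)
  rows <- lapply(series_list, function(s) {
    ev <- detect_rupture_events(s, min_drop_pp)
    data.frame(temperature_c = attr(s, "temperature_c") %||% NA_real_,
               n_events = nrow(ev),
               first_event_min = if (nrow(ev)) ev$time_min[1] else NA_real_,
               final_icw_pct = s$icw_pct[nrow(s)])
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference bi-exponential T2 components for apple drying
#'
#' The published reference decomposition of apple-tissue T2 decays during
#' convective drying at 45, 60 and 70 degC: long/short T2 constants (ms) and
#' relative contributions (%) at each 30-min drying step, each value the mean
#' of 3 tests. Row `drying_time_min == 0` is the fresh sample. Used as the
#' fixture for round-trip fitting checks and as the sawtooth ICW series on
#' which rupture detection is validated.
#'
#' @return data.frame with columns `temperature_c`, `drying_time_min`,
#'   `t2_long_ms`, `sd_t2_long`, `pct_long`, `sd_pct_long`, `t2_short_ms`,
#'   `sd_t2_short`, `pct_short`, `sd_pct_short`, `r_squared`.
#' @export
apple_t2_reference <- function() {
  path <- system.file("extdata", "apple_t2_components.csv",
                      package = "relaxdry", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Reference ICW series at one drying temperature
#'
#' Convenience view of [apple_t2_reference()]: the long-component percentage
#' against drying time at the requested temperature, as a
#' [compartment_series()]. The fresh row (time 0) belongs to no particular
#' protocol and is excluded by default.
#'
#' @param temperature_c one of 45, 60, 70.
#' @param include_fresh prepend the fresh-sample row at time 0? Note time 0
#'   is only present in the 45 degC table.
#' @return a [compartment_series()].
#' @export
reference_icw_series <- function(temperature_c, include_fresh = FALSE) {
  tab <- apple_t2_reference()
  tab <- tab[tab$temperature_c == temperature_c, ]
  if (!nrow(tab))
    stop("no reference data at ", temperature_c, " degC", call. = FALSE)
  if (!include_fresh) tab <- tab[tab$drying_time_min > 0, ]
  compartment_series(tab$drying_time_min, tab$pct_long, temperature_c)
}
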