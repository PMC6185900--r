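#' Decay curve: a sampled T2 relaxation signal
#'
#' Container for a magnitude decay sampled on an echo-time grid, the raw input
#' of the relaxometry pipeline. Echo times are in milliseconds and must be
#' strictly increasing and positive; at least 4 samples are required for any
#' downstream fit. Signal values are in arbitrary units. Magnitude data are
#' ordinarily non-negative, but synthetic curves with additive Gaussian noise
#' may dip below zero at the noise floor, so negative samples are allowed here
#' and handled at the points of use ([log_signal()] drops or rejects them;
#' nonlinear fitting keeps them, since it operates on the linear scale).
#'
#' @param times numeric vector of echo times in ms, strictly increasing, > 0.
#' @param signal numeric vector of magnitudes (a.u.), same length as `times`.
#' @param meta named list of acquisition/sample metadata. Recognised entries:
#'   `temperature_c` (drying temperature), `drying_time_min`, `sample_id`,
#'   plus anything a generator or reader wants to attach (e.g. `noise_roi`).
#' @return an object of class `decay_curve`.
#' @seealso [read_decay_csv()], [generate_decay()]
#' @export
decay_curve <- function(times, signal, meta = list()) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop("`times` and `signal` must have the same length", call. = FALSE)
  if (length(times) < 4)
    stop("a decay curve needs at least 4 samples, got ", length(times),
         call. = FALSE)
  if (anyNA(times) || anyNA(signal) || any(!is.finite(times)) ||
      any(!is.finite(signal)))
    stop("`times` and `signal` must be finite and non-missing", call. = FALSE)
  if (any(times <= 0))
    stop("all echo times must be positive", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("echo times must be strictly increasing", call. = FALSE)
  if (!is.list(meta)) stop("`meta` must be a list", call. = FALSE)
  structure(list(times = times, signal = signal, meta = meta),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d echoes, t = [%g, %g] ms\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  if (!is.null(x$meta$temperature_c) || !is.null(x$meta$drying_time_min))
    cat(sprintf("  %s%s\n",
                if (!is.null(x$meta$temperature_c))
                  sprintf("T = %g degC  ", x$meta$temperature_c) else "",
                if (!is.null(x$meta$drying_time_min))
                  sprintf("drying time = %g min", x$meta$drying_time_min)
                else ""))
  invisible(x)
}

#' @export
length.decay_curve <- function(x) length(x$times)

#' Multi-exponential relaxation model
#'
#' A discrete multi-component transverse relaxation model,
#' \deqn{Z(t) = \sum_i M_i \exp(-t / T_2^i),}
#' with 1 to 3 components. Components are stored in canonical order, sorted by
#' descending T2, so index 1 is always the "long" component; the
#' intracellular/free water labels used elsewhere rely on this ordering.
#'
#' @param amplitudes non-negative relative contributions (a.u. or %).
#' @param t2 relaxation time constants in ms, all > 0, pairwise distinct,
#'   same length as `amplitudes` (1 to 3 components).
#' @return an object of class `multiexp_model`: a list with numeric fields
#'   `amplitudes` and `t2` in descending-T2 order.
#' @examples
#' m <- multiexp_model(c(11.97, 88.10), c(32.76, 90.67))
#' m$t2[1]   # 90.67 -- long component is always first
#' evaluate_model(m, c(0, 10, 100))
#' @export
multiexp_model <- function(amplitudes, t2) {
  amplitudes <- as.numeric(amplitudes)
  t2 <- as.numeric(t2)
  n <- length(t2)
  if (length(amplitudes) != n)
    stop("`amplitudes` and `t2` must have the same length", call. = FALSE)
  if (n < 1 || n > 3)
    stop("between 1 and 3 components supported, got ", n, call. = FALSE)
  if (anyNA(amplitudes) || anyNA(t2))
    stop("model parameters must not be missing", call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(t2 <= 0)) stop("T2 values must be > 0", call. = FALSE)
  if (anyDuplicated(t2))
    stop("components must have distinct T2 values", call. = FALSE)
  o <- order(t2, decreasing = TRUE)
  structure(list(amplitudes = amplitudes[o], t2 = t2[o]),
            class = "multiexp_model")
}

#' @export
print.multiexp_model <- function(x, ...) {
  lab <- c("long", "mid", "short")[seq_along(x$t2)]
  if (length(x$t2) == 2) lab <- c("long", "short")
  if (length(x$t2) == 1) lab <- "single"
  cat("<multiexp_model>\n")
  for (i in seq_along(x$t2))
    cat(sprintf("  %-6s M = %g, T2 = %g ms\n", lab[i], x$amplitudes[i],
                x$t2[i]))
  invisible(x)
}

n_components <- function(model) length(model$t2)

#' Evaluate a multi-exponential decay model
#'
#' Computes \eqn{Z(t) = \sum_i M_i \exp(-t/T_2^i)} on a time grid. At t = 0
#' this equals the sum of the amplitudes exactly; for all-positive amplitudes
#' the curve is strictly decreasing.
#'
#' @param model a [multiexp_model()].
#' @param times numeric vector of times in ms, all >= 0.
#' @return numeric vector of model values, one per time.
#' @export
evaluate_model <- function(model, times) {
  if (!inherits(model, "multiexp_model"))
    stop("`model` must be a multiexp_model", call. = FALSE)
  times <- as.numeric(times)
  if (anyNA(times) || any(times < 0))
    stop("`times` must be non-negative and non-missing", call. = FALSE)
  drop(exp(-outer(times, model$t2, "/")) %*% model$amplitudes)
}

#' Natural logarithm of a decay signal
#'
#' Returns the (time, ln signal) pairs used for visual/piecewise model-order
#' assessment: a mono-exponential decay is an exact line of slope -1/T2 on
#' this scale, and each additional well-separated component adds a distinct
#' linear regime. Non-positive samples (noise floor) carry no information on
#' the log scale and are either dropped or rejected.
#'
#' @param curve a [decay_curve()].
#' @param on_nonpositive `"drop"` (default) silently removes non-positive
#'   samples; `"error"` fails if any are present.
#' @return data.frame with columns `time_ms` and `log_signal`.
#' @export
log_signal <- function(curve, on_nonpositive = c("drop", "error")) {
  if (!inherits(curve, "decay_curve"))
    stop("`curve` must be a decay_curve", call. = FALSE)
  on_nonpositive <- match.arg(on_nonpositive)
  pos <- curve$signal > 0
  if (!any(pos))
    stop("no positive signal samples; cannot take logarithm", call. = FALSE)
  if (on_nonpositive == "error" && !all(pos))
    stop(sum(!pos), " non-positive signal sample(s) present", call. = FALSE)
  data.frame(time_ms = curve$times[pos], log_signal = log(curve$signal[pos]))
}
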