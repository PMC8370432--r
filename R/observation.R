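#' Observation model: from depolarisation to event-related field
#'
#' Source ERFs are a gain-scaled weighted sum of the population
#' depolarisations within each source. The contribution weights `j` are
#' fixed prior means shared across sources (pyramidal populations dominate
#' the measurable field); a free log-gain parameter (`obs:gain`) absorbs
#' overall scale, so ERF units are arbitrary. Observation noise is additive
#' Gaussian with one log-precision hyperparameter per source.
#'
#' @param j named contribution weights per population.
#' @param gain prior-mean observation gain.
#' @param lambda_prior Gaussian prior (mean, var) on the per-source noise
#'   log-precision.
#' @export
observation_spec <- function(j = c(ss = 0.2, sp = 0.8, si = 0, dp = 0.4,
                                   di = 0, tp = 0.2),
                             gain = 1,
                             lambda_prior = c(mean = 4, var = 1)) {
  pops <- cmm_populations()
  if (!all(pops %in% names(j))) abort("`j` must name all six populations")
  if (j[["sp"]] == 0 && j[["dp"]] == 0 && j[["tp"]] == 0)
    abort("at least one pyramidal population must contribute to the ERF")
  structure(list(j = j[pops], gain = gain, lambda_prior = lambda_prior),
            class = "observation_spec")
}

#' Project hidden-state trajectories to source ERFs
#'
#' Linear map from population depolarisations to the measured field:
#' `erf_s(t) = gain * sum_p j_p * (V_{s,p}(t) - VL)`.
#'
#' @param trajectories a `cmm_trajectory` from [integrate_network()].
#' @param obs an [observation_spec()].
#' @param gain_theta log-gain deviation (the `obs:gain` parameter);
#'   effective gain is `gain * exp(gain_theta)`.
#' @return sources x time matrix of ERF values.
#' @export
project_erf <- function(trajectories, obs = observation_spec(),
                        gain_theta = 0) {
  if (!inherits(trajectories, "cmm_trajectory"))
    abort("`trajectories` must come from integrate_network()")
  v <- trajectories$v
  sources <- trajectories$model$net$sources
  if (ncol(v) != 6 * length(sources)) abort("trajectory shape mismatch")
  vl <- trajectories$model$consts$VL
  jn <- matrix(0, length(sources), ncol(v))
  for (s in seq_along(sources))
    jn[s, (s - 1L) * 6L + seq_len(6L)] <- obs$j
  out <- obs$gain * exp(gain_theta) * (jn %*% t(v - vl))
  rownames(out) <- sources
  out
}

# Tukey-style window: exactly 1 on [flat1, flat2], cosine tapers to the
# epoch edges, evaluated on the given time axis (ms)
tukey_window <- function(time_ms, flat = c(50, 350)) {
  t0 <- min(time_ms); t1 <- max(time_ms)
  if (flat[1] <= t0 || flat[2] >= t1)
    abort("window flat region must lie strictly inside the epoch")
  w <- rep(1, length(time_ms))
  left <- time_ms < flat[1]
  right <- time_ms > flat[2]
  w[left] <- 0.5 * (1 - cos(pi * (time_ms[left] - t0) / (flat[1] - t0)))
  w[right] <- 0.5 * (1 + cos(pi * (time_ms[right] - flat[2]) / (t1 - flat[2])))
  w
}

# zero-phase low-pass by FFT mask: retains DC up to `hz`, removes all
# higher frequencies exactly; idempotent, zero group delay
lowpass_fft <- function(x, time_ms, hz) {
  dt <- diff(time_ms[1:2]) / 1000     # s
  fs <- 1 / dt
  if (fs < 2 * hz) abort("sampling rate must be at least twice the low-pass edge")
  one_row <- is.null(dim(x))
  m <- if (one_row) matrix(x, 1) else x
  T <- ncol(m)
  f <- (seq_len(T) - 1) / T * fs
  f <- pmin(f, fs - f)                # two-sided frequency magnitude
  xf <- stats::mvfft(t(m))            # columns = channels
  xf[f > hz, ] <- 0
  out <- t(Re(stats::mvfft(xf, inverse = TRUE)) / T)
  if (one_row) drop(out) else out
}

# core conditioning on a channels x time matrix
condition_matrix <- function(m, time_ms, lowpass_hz = 48, window = c(50, 350)) {
  w <- tukey_window(time_ms, window)
  filtered <- lowpass_fft(m, time_ms, lowpass_hz)
  if (is.null(dim(filtered))) filtered * w
  else sweep(filtered, 2, w, `*`)
}

#' Condition an event-related field
#'
#' Applies the ERF conditioning used identically for simulated and recorded
#' data: a zero-phase low-pass at `lowpass_hz` (DC retained, all content
#' above the edge removed) followed by a Tukey window that is exactly 1
#' between `window[1]` and `window[2]` ms and cosine-tapers to the epoch
#' edges.
#'
#' @param erf a long ERF tibble (columns `source`, `time_ms`, `value`, plus
#'   any identifier columns such as `subject`, `session`, `condition`) or a
#'   channels x time matrix.
#' @param lowpass_hz low-pass edge in Hz (default 48).
#' @param window flat (unattenuated) interval in ms (default 50-350).
#' @param time_ms time axis; required when `erf` is a matrix.
#' @return object of the same type with conditioned values; the time axis
#'   is unchanged.
#' @export
condition_erf <- function(erf, lowpass_hz = 48, window = c(50, 350),
                          time_ms = NULL) {
  if (is.matrix(erf)) {
    if (is.null(time_ms)) abort("`time_ms` is required for matrix input")
    return(condition_matrix(erf, time_ms, lowpass_hz, window))
  }
  stopifnot(all(c("source", "time_ms", "value") %in% names(erf)))
  keys <- intersect(c("subject", "group", "session", "condition", "source"),
                    names(erf))
  erf |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(value = {
      o <- order(.data$time_ms)
      v <- numeric(length(.data$value))
      v[o] <- condition_matrix(matrix(.data$value[o], nrow = 1),
                               .data$time_ms[o], lowpass_hz, window)[1, ]
      v
    }) |>
    dplyr::ungroup()
}

#' Goodness of fit between observed and predicted ERFs
#'
#' Pearson correlation per trace (source within subject/session/condition)
#' plus the pooled median and interquartile range across traces. Traces
#' with zero variance yield a missing correlation rather than NaN.
#'
#' @param observed,predicted long ERF tibbles with matching identifier
#'   columns and time axes, or sources x time matrices.
#' @return a list of class `erf_fit_stats`: `by_trace` tibble (identifier
#'   columns + `r`) and `summary` tibble (`median_r`, `iqr_r`, `n`).
#' @export
erf_fit_statistics <- function(observed, predicted) {
  if (is.matrix(observed)) {
    observed <- erf_matrix_to_tibble(observed,
                                     seq_len(ncol(observed)))
    predicted <- erf_matrix_to_tibble(predicted,
                                      seq_len(ncol(predicted)))
  }
  keys <- intersect(c("subject", "group", "session", "condition", "source"),
                    names(observed))
  joined <- dplyr::inner_join(observed, predicted,
                              by = c(keys, "time_ms"),
                              suffix = c("_obs", "_pred"))
  if (nrow(joined) != nrow(observed))
    abort("observed and predicted ERFs do not share shape/time axes")
  by_trace <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(r = {
      o <- .data$value_obs; p <- .data$value_pred
      if (sd(o) == 0 || sd(p) == 0) NA_real_ else cor(o, p)
    }, .groups = "drop")
  ok <- !is.na(by_trace$r)
  summary <- tibble::tibble(
    median_r = median(by_trace$r[ok]),
    iqr_r = unname(diff(quantile(by_trace$r[ok], c(0.25, 0.75)))),
    n = sum(ok)
  )
  structure(list(by_trace = by_trace, summary = summary),
            class = "erf_fit_stats")
}

#' @export
print.erf_fit_stats <- function(x, ...) {
  cat(sprintf("<erf_fit_stats> %d traces, median r = %.3f (IQR %.3f)\n",
              x$summary$n, x$summary$median_r, x$summary$iqr_r))
  invisible(x)
}

#' Convert between ERF matrices and tidy tibbles
#'
#' @param m sources x time matrix with source row names.
#' @param time_ms time axis.
#' @export
erf_matrix_to_tibble <- function(m, time_ms) {
  src <- rownames(m) %||% paste0("ch", seq_len(nrow(m)))
  tibble::tibble(
    source = rep(src, each = ncol(m)),
    time_ms = rep(time_ms, nrow(m)),
    value = as.numeric(t(m))
  )
}

#' @rdname erf_matrix_to_tibble
#' @param erf long ERF tibble for a single trace set (one row per
#'   source/time).
#' @export
erf_tibble_to_matrix <- function(erf) {
  wide <- erf |>
    dplyr::select("source", "time_ms", "value") |>
    tidyr::pivot_wider(names_from = "time_ms", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$source
  ord <- intersect(cmm_sources(), rownames(m))
  if (length(ord) == nrow(m)) m <- m[ord, , drop = FALSE]
  m
}
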