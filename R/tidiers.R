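#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gaussian belief
#'
#' @param x a [gaussian_belief()].
#' @param ... unused.
#' @return tibble with `parameter`, `estimate`, `std.error`.
#' @export
tidy.gaussian_belief <- function(x, ...) {
  tibble::tibble(parameter = names(x$mean), estimate = unname(x$mean),
                 std.error = sqrt(diag(x$cov)))
}

#' @rdname tidy.gaussian_belief
#' @export
glance.gaussian_belief <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy, n_parameters = length(x$mean),
                 converged = x$converged)
}

#' Tidy a single-subject fit
#'
#' @param x a `cmm_fit` from [invert_erf()].
#' @param ... unused.
#' @export
tidy.cmm_fit <- function(x, ...) tidy(x$posterior)

#' @rdname tidy.cmm_fit
#' @export
glance.cmm_fit <- function(x, ...) {
  tibble::tibble(
    free_energy = x$posterior$free_energy,
    converged = x$converged,
    iterations = x$iterations,
    median_r = if (is.null(x$stats)) NA_real_ else x$stats$summary$median_r)
}

#' Tidy a PEB model
#'
#' One row per (effect column, parameter): posterior mean, standard error,
#' posterior probability of the effect and its sign.
#'
#' @param x a `peb_model`.
#' @param ... unused.
#' @export
tidy.peb_model <- function(x, ...) {
  se <- matrix(sqrt(diag(x$belief$cov)), nrow(x$beta), ncol(x$beta))
  tibble::tibble(
    effect = rep(colnames(x$beta), each = nrow(x$beta)),
    parameter = rep(rownames(x$beta), ncol(x$beta)),
    estimate = as.numeric(x$beta),
    std.error = as.numeric(se),
    pp = as.numeric(x$pp),
    sign = sign(as.numeric(x$beta)))
}

#' @rdname tidy.peb_model
#' @export
glance.peb_model <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 n_parameters = nrow(x$beta),
                 n_effects = ncol(x$beta),
                 max_pp = max(x$pp))
}

#' Plot observed against predicted ERFs of a fit
#'
#' @param object a `cmm_fit`.
#' @param ... unused.
#' @return a ggplot faceted by source.
#' @export
autoplot.cmm_fit <- function(object, ...) {
  t_grid <- object$model$t_grid
  obs <- erf_matrix_to_tibble(object$data, t_grid)
  obs$kind <- "observed"
  pred <- erf_matrix_to_tibble(object$predicted, t_grid)
  pred$kind <- "predicted"
  df <- dplyr::bind_rows(obs, pred)
  df$source <- factor(df$source, cmm_sources())
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~source, scales = "free_y") +
    ggplot2::labs(x = "peristimulus time (ms)", y = "field (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior-probability map of a PEB model
#'
#' Heatmap of effect posterior probabilities by (effect, parameter), with
#' the sign of the posterior mean as the fill direction.
#'
#' @param object a `peb_model`.
#' @param pp_threshold draw a tile border where `pp` exceeds this value.
#' @param ... unused.
#' @export
autoplot.peb_model <- function(object, pp_threshold = 0.95, ...) {
  df <- tidy(object)
  df$signed_pp <- df$pp * df$sign
  ggplot2::ggplot(df, ggplot2::aes(.data$effect, .data$parameter,
                                   fill = .data$signed_pp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$pp > pp_threshold, ],
                       colour = "black", linewidth = 0.6, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "signed Pp") +
    ggplot2::theme_minimal()
}

#' Kernel-density summary of fit correlations
#'
#' @param fit_table the `table` component of [fit_cohort()].
#' @export
plot_fit_density <- function(fit_table) {
  ggplot2::ggplot(fit_table, ggplot2::aes(.data$r_median)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = median(fit_table$r_median,
                                            na.rm = TRUE),
                        colour = "red") +
    ggplot2::labs(x = "observed-predicted correlation (median per fit)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Tidy a network trajectory
#'
#' @param x a `cmm_trajectory` from [integrate_network()].
#' @param ... unused.
#' @return long tibble with `time_ms`, `source`, `population`, `state`
#'   (`v`, `g_ampa`, `g_nmda`, `g_gabaa`) and `value` — the flat-text
#'   interchange form of the hidden states.
#' @export
tidy.cmm_trajectory <- function(x, ...) {
  blocks <- c("v", "g_ampa", "g_nmda", "g_gabaa")
  purrr::map_dfr(blocks, function(b) {
    m <- x[[b]]
    lab <- strsplit(colnames(m), ".", fixed = TRUE)
    tibble::tibble(
      time_ms = rep(x$time, ncol(m)),
      source = rep(vapply(lab, `[[`, "", 1), each = nrow(m)),
      population = rep(vapply(lab, `[[`, "", 2), each = nrow(m)),
      state = b,
      value = as.numeric(m))
  })
}
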