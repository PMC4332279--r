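#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PCM
#'
#' One row per free parameter: estimate, confidence bounds (when computed),
#' interval method and boundary flag.
#'
#' @param x A [fit_pcm()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pcm_fit
#' @export
tidy.pcm_fit <- function(x, ...) {
  if (x$model$S == 0) {
    return(tibble::tibble(parameter = character(), estimate = numeric(),
                          lower = numeric(), upper = numeric(),
                          boundary = logical()))
  }
  out <- tibble::tibble(parameter = names(x$theta), estimate = unname(x$theta),
                        boundary = unname(x$boundary))
  if (nrow(x$ci) == length(x$theta)) {
    out$lower <- x$ci$lower
    out$upper <- x$ci$upper
    out$ci_method <- x$ci$method
  }
  out
}

#' Glance at a fitted PCM
#'
#' @param x A [fit_pcm()] result.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `S`, `gsq`, `df`, `p_value`,
#'   `AIC`, `BIC`, `N`, `converged`, `n_starts_agreeing`.
#' @method glance pcm_fit
#' @export
glance.pcm_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(logLik = x$logLik, S = x$model$S, gsq = x$gsq, df = x$df,
                   p_value = x$p_value),
    aic_bic(x),
    tibble::tibble(N = x$N, converged = x$converged,
                   n_starts_agreeing = x$n_starts_agreeing)
  )
}

#' Tidy a recovery study
#'
#' @param x A [recovery_study()] result.
#' @param ... Unused.
#' @return The per-parameter summary tibble.
#' @method tidy pcm_recovery
#' @export
tidy.pcm_recovery <- function(x, ...) x$parameters

#' Serial-position plot of a fitted PCM
#'
#' Observed (solid) and model-expected (dashed) final-preference frequencies
#' by serial position, one panel per set size, coloured by factor level —
#' the standard visual check that the model captures primacy and recency.
#'
#' @param object A [fit_pcm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcm_fit
#' @export
autoplot.pcm_fit <- function(object, ...) {
  oe <- pcm_expected(object$model, unname(object$theta)) |>
    dplyr::left_join(dplyr::rename(object$data, observed = "count"),
                     by = c("level", "set_size", "position")) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "source", values_to = "frequency")
  ggplot2::ggplot(oe, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   colour = .data$level,
                                   linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$source == "observed")) +
    ggplot2::facet_wrap(~set_size, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_linetype_manual(values = c(observed = "solid",
                                              expected = "dashed")) +
    ggplot2::labs(x = "serial position", y = "final-preference frequency",
                  colour = "level", linetype = NULL,
                  title = paste("Observed vs expected:", object$model$name)) +
    ggplot2::theme_minimal()
}

#' Model-weight plot of a selection table
#'
#' @param object A [select_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcm_selection
#' @export
autoplot.pcm_selection <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$model, y = .data$w_FIA)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "FIA model weight") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Parameter-estimate plot of a fitted PCM
#'
#' Point estimates with confidence intervals, in parameter order — the
#' usual display for comparing inertia across steps and factor levels.
#'
#' @param fit A [fit_pcm()] result.
#' @return A ggplot object.
#' @export
plot_estimates <- function(fit) {
  td <- tidy(fit)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$parameter, y = .data$estimate))
  if ("lower" %in% names(td)) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                                 ymax = .data$upper),
                                    width = 0.15)
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}
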