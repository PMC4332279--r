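#' Simulate a final-preference frequency table
#'
#' Draws one independent multinomial sample per design group, with category
#' probabilities given by the model's forward map — the product-multinomial
#' sampling scheme of a between-subjects tasting study. Reproducible given
#' the seed; the caller's RNG state is untouched.
#'
#' @param design A [pcm_design()] (must equal the model's design).
#' @param model A [pcm_model()].
#' @param theta_true True free-parameter values for the model.
#' @param seed Integer seed.
#' @return A frequency table tibble (`level`, `set_size`, `position`,
#'   `count`) whose group totals equal the design's `n`.
#' @examples
#' d <- mantonakis_design()
#' generate_dataset(d, pcm3_model(d), theta_true = 0.51, seed = 42)
#' @export
generate_dataset <- function(design, model, theta_true, seed) {
  stopifnot(inherits(model, "pcm_model"))
  design <- pcm_design(design)
  if (!identical(dplyr::arrange(design, .data$level, .data$set_size),
                 dplyr::arrange(model$design, .data$level, .data$set_size))) {
    stop("design does not match the model's design", call. = FALSE)
  }
  theta_true <- check_theta(model, theta_true)
  local_seed(seed, {
    purrr::map_dfr(model$group_index, function(g) {
      sw <- step_survival_win(model, theta_true, g)
      p <- probs_from_sw(sw$s, sw$w)
      counts <- as.integer(stats::rmultinom(1, g$n, p))
      tibble::tibble(level = g$level, set_size = g$m,
                     position = seq_len(g$m), count = counts)
    })
  })
}

# per-replicate seeds derived deterministically from one master seed
derive_seeds <- function(master_seed, n) {
  local_seed(master_seed, sample.int(2147483646L, n))
}

#' Parameter- and model-recovery simulation study
#'
#' Generates `replicates` datasets from a known truth, refits, and
#' summarises estimation quality (bias, RMSE, confidence-interval coverage)
#' per parameter. When several candidate models are supplied the study also
#' records how often each candidate wins under FIA, AIC and BIC (model
#' recovery); FIA complexity integrals are computed once per candidate since
#' they do not depend on the data.
#'
#' @param design The data-generating [pcm_design()].
#' @param model_truth The generating [pcm_model()].
#' @param theta_true True parameter values for `model_truth`.
#' @param model_fit Model to fit for parameter recovery; defaults to
#'   `model_truth` (must share its parameter vector for bias/coverage to be
#'   meaningful).
#' @param candidates Optional named list of `pcm_model`s for model recovery.
#' @param replicates Number of simulated datasets (at least 2).
#' @param seed Master seed; one seed per replicate is derived from it, so
#'   results are reproducible and independent of evaluation order.
#' @param ci_level Nominal coverage of the intervals scored.
#' @param fia_draws,fia_seed Monte-Carlo settings for candidate complexity.
#' @param n_starts Optimisation starts per fit (see [fit_pcm()]).
#'
#' @return An object of class `pcm_recovery`: list with `parameters`
#'   (tibble: `parameter`, `true`, `mean_estimate`, `bias`, `rmse`,
#'   `coverage`), `selection` (tibble of winner frequencies, or `NULL`),
#'   `replicates`, `failures`, `seed`.
#' @examples
#' d <- mantonakis_design()
#' recovery_study(d, pcm3_model(d), 0.51, replicates = 5, seed = 3)
#' @export
recovery_study <- function(design, model_truth, theta_true, model_fit = NULL,
                           candidates = NULL, replicates = 100, seed = 1,
                           ci_level = 0.95, fia_draws = 200000,
                           fia_seed = 20150218, n_starts = 10) {
  stopifnot(replicates >= 2)
  if (is.null(model_fit)) model_fit <- model_truth
  theta_true <- check_theta(model_truth, theta_true)
  seeds <- derive_seeds(seed, replicates)

  complexities <- NULL
  if (!is.null(candidates)) {
    if (is.null(names(candidates)) || any(names(candidates) == "")) {
      names(candidates) <- vapply(candidates, function(m) m$name, "")
    }
    complexities <- lapply(candidates, model_complexity,
                           draws = fia_draws, seed = fia_seed)
  }

  est <- matrix(NA_real_, replicates, model_fit$S)
  covered <- matrix(NA, replicates, model_fit$S)
  winners <- if (!is.null(candidates)) {
    tibble::tibble(fia = character(replicates), aic = character(replicates),
                   bic = character(replicates))
  } else NULL
  failures <- 0L

  for (r in seq_len(replicates)) {
    x <- generate_dataset(design, model_truth, theta_true, seed = seeds[r])
    ok <- tryCatch({
      f <- fit_pcm(x, model_fit, n_starts = n_starts, seed = seeds[r],
                   ci_level = ci_level)
      est[r, ] <- unname(f$theta)
      if (nrow(f$ci) == model_fit$S && model_fit$S > 0) {
        covered[r, ] <- f$ci$lower <= theta_true & theta_true <= f$ci$upper
      }
      if (!is.null(candidates)) {
        sel <- select_models(x, candidates, complexities = complexities,
                             n_starts = n_starts, fit_seed = seeds[r],
                             ci_level = NA)
        winners$fia[r] <- sel$model[which.min(sel$FIA)]
        winners$aic[r] <- sel$model[which.min(sel$AIC)]
        winners$bic[r] <- sel$model[which.min(sel$BIC)]
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failures <- failures + 1L
  }

  done <- stats::complete.cases(est)
  params <- tibble::tibble(
    parameter = model_fit$parameters,
    true = theta_true,
    mean_estimate = colMeans(est[done, , drop = FALSE]),
    bias = colMeans(est[done, , drop = FALSE]) - theta_true,
    rmse = sqrt(colMeans((est[done, , drop = FALSE] -
                            matrix(theta_true, sum(done), model_fit$S,
                                   byrow = TRUE))^2)),
    coverage = colMeans(covered[done, , drop = FALSE])
  )
  selection <- NULL
  if (!is.null(candidates)) {
    win_rows <- winners[done & winners$fia != "", , drop = FALSE]
    selection <- purrr::map_dfr(names(candidates), function(nm) {
      tibble::tibble(model = nm,
                     fia_share = mean(win_rows$fia == nm),
                     aic_share = mean(win_rows$aic == nm),
                     bic_share = mean(win_rows$bic == nm))
    })
  }
  structure(
    list(parameters = params, selection = selection, estimates = est,
         replicates = replicates, failures = failures, seed = seed,
         ci_level = ci_level, truth = model_truth$name),
    class = "pcm_recovery"
  )
}

#' @export
print.pcm_recovery <- function(x, ...) {
  cat("Recovery study: truth ", x$truth, ", ", x$replicates, " replicates",
      if (x$failures > 0) paste0(" (", x$failures, " fit failures)"),
      "\n", sep = "")
  print(x$parameters)
  if (!is.null(x$selection)) {
    cat("model-recovery winner shares:\n")
    print(x$selection)
  }
  invisible(x)
}
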