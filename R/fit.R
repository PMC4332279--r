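#' Product-multinomial log-likelihood kernel
#'
#' `sum over groups and positions of f * log p(theta)`, dropping the
#' multinomial coefficients (they do not depend on theta and cancel in all
#' likelihood ratios). Returns `-Inf` when any cell with a positive count
#' has probability zero; cells with zero counts contribute zero regardless.
#'
#' @param data A frequency table (see [read_frequency_table()]).
#' @param model A [pcm_model()].
#' @param theta Free-parameter vector of length `model$S`.
#' @return A single number.
#' @export
log_likelihood <- function(data, model, theta) {
  data <- validate_frequency_table(data, model$design)
  theta <- check_theta(model, theta)
  ll <- 0
  for (g in model$group_index) {
    f <- group_counts(data, g)
    sw <- step_survival_win(model, theta, g)
    p <- probs_from_sw(sw$s, sw$w)
    pos <- f > 0
    if (any(pos & p <= 0)) return(-Inf)
    ll <- ll + sum(f[pos] * log(p[pos]))
  }
  ll
}

# log-likelihood and analytic gradient, no validation (hot path).
# Uses the factorisation log L = sum_j [K_j log s_j + f_j log w_j], where
# K_j counts participants whose favorite entered step j from an earlier
# position (K_j = f_1 + ... + f_{j-1}).
ll_and_grad <- function(model, theta, counts_by_group) {
  v <- model$slots$constant
  free <- is.na(v)
  v[free] <- theta[model$slots$theta_index[free]]
  ll <- 0
  grad <- numeric(model$S)
  for (gi in seq_along(model$group_index)) {
    g <- model$group_index[[gi]]
    f <- counts_by_group[[gi]]
    pi_j <- v[g$pi_rows]
    p_j <- v[g$pnew_rows]
    s <- pi_j + (1 - pi_j) * (1 - p_j)
    w <- (1 - pi_j) * p_j
    K <- cumsum(f)[-g$m]           # K_j for steps j = 2..m
    fj <- f[-1]                    # f_j for steps j = 2..m
    if (any((K > 0 & s <= 0) | (fj > 0 & w <= 0))) {
      return(list(ll = -Inf, grad = grad))
    }
    ll <- ll + sum(ifelse(K > 0, K * log(s), 0)) +
      sum(ifelse(fj > 0, fj * log(w), 0))
    dlds <- ifelse(K > 0, K / s, 0)
    dldw <- ifelse(fj > 0, fj / w, 0)
    dpi <- p_j * dlds - p_j * dldw
    dpn <- -(1 - pi_j) * dlds + (1 - pi_j) * dldw
    ti_pi <- model$slots$theta_index[g$pi_rows]
    ti_pn <- model$slots$theta_index[g$pnew_rows]
    ok <- !is.na(ti_pi)
    if (any(ok)) {
      acc <- rowsum(dpi[ok], ti_pi[ok])
      grad[as.integer(rownames(acc))] <- grad[as.integer(rownames(acc))] + acc[, 1]
    }
    ok <- !is.na(ti_pn)
    if (any(ok)) {
      acc <- rowsum(dpn[ok], ti_pn[ok])
      grad[as.integer(rownames(acc))] <- grad[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  list(ll = ll, grad = grad)
}

#' Fit a PCM by maximum likelihood
#'
#' Maximises the product-multinomial likelihood over the unit hypercube with
#' bound-constrained quasi-Newton optimisation (`L-BFGS-B` with analytic
#' gradients) from multiple seeded starting points, and reports goodness of
#' fit and parameter confidence intervals. Estimates within `1e-4` of the
#' box bounds are flagged as boundary estimates and get profile-likelihood
#' intervals instead of Wald intervals.
#'
#' @param data A frequency table (columns `level`, `set_size`, `position`,
#'   `count`) covering exactly the model's design.
#' @param model A [pcm_model()].
#' @param n_starts Number of optimisation starts: the midpoint `0.5` vector
#'   plus `n_starts - 1` uniform draws.
#' @param seed Seed for the start draws (local; the global RNG state is
#'   untouched).
#' @param ci_level Confidence level for parameter intervals, or `NA` to skip.
#' @param reltol Relative convergence tolerance passed to the optimiser
#'   (`factr = reltol / .Machine$double.eps`).
#'
#' @return An object of class `pcm_fit`: a list with `theta` (named
#'   estimates), `logLik`, `gsq`, `df`, `p_value`, `ci` (tibble), `converged`,
#'   `n_starts_agreeing`, `boundary` (logical per parameter), plus the model
#'   and data. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#'
#' @examples
#' d <- mantonakis_design()
#' truth <- pcm3_model(d)
#' x <- generate_dataset(d, truth, 0.51, seed = 7)
#' fit <- fit_pcm(x, truth)
#' glance(fit)
#' @export
fit_pcm <- function(data, model, n_starts = 10, seed = 1, ci_level = 0.95,
                    reltol = 1e-10) {
  stopifnot(inherits(model, "pcm_model"))
  data <- validate_frequency_table(data, model$design)
  counts <- lapply(model$group_index, function(g) group_counts(data, g))
  S <- model$S
  eps <- 1e-6

  if (S == 0) {
    theta <- numeric(0)
    ll <- ll_and_grad(model, theta, counts)$ll
    fit <- new_pcm_fit(model, data, theta, ll, converged = TRUE,
                       n_starts_agreeing = n_starts, boundary = logical(0),
                       start_values = numeric(0))
    return(finish_fit(fit, counts, ci_level))
  }

  nll <- function(th) -ll_and_grad(model, th, counts)$ll
  ngr <- function(th) -ll_and_grad(model, th, counts)$grad
  starts <- rbind(
    rep(0.5, S),
    local_seed(seed, matrix(stats::runif((n_starts - 1) * S), ncol = S))
  )[seq_len(n_starts), , drop = FALSE]

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(starts[i, ], nll, ngr, method = "L-BFGS-B",
                 lower = eps, upper = 1 - eps,
                 control = list(factr = reltol / .Machine$double.eps,
                                maxit = 500))
  })
  values <- -vapply(runs, `[[`, 0, "value")
  best <- which.max(values)
  conv_codes <- vapply(runs, `[[`, 0L, "convergence")
  if (all(conv_codes != 0L)) {
    stop("optimisation failed to converge from any of ", n_starts, " starts",
         call. = FALSE)
  }
  theta <- runs[[best]]$par
  boundary <- theta <= eps + 1e-4 | theta >= 1 - eps - 1e-4
  # snap boundary estimates to the true bound for reporting
  theta_rep <- ifelse(theta <= eps + 1e-4, 0, ifelse(theta >= 1 - eps - 1e-4, 1, theta))
  ll <- ll_and_grad(model, theta_rep, counts)$ll
  if (!is.finite(ll)) {  # snapping hit a log(0); keep the interior optimum
    theta_rep <- theta
    ll <- values[best]
  }
  fit <- new_pcm_fit(model, data, theta_rep, ll,
                     converged = conv_codes[best] == 0L,
                     n_starts_agreeing = sum(values >= values[best] - 1e-6),
                     boundary = boundary, start_values = values)
  finish_fit(fit, counts, ci_level)
}

new_pcm_fit <- function(model, data, theta, ll, converged, n_starts_agreeing,
                        boundary, start_values) {
  names(theta) <- model$parameters
  names(boundary) <- model$parameters
  structure(
    list(model = model, data = data, theta = theta, logLik = ll,
         converged = converged, n_starts_agreeing = n_starts_agreeing,
         boundary = boundary, start_values = start_values,
         N = sum(model$design$n)),
    class = "pcm_fit"
  )
}

finish_fit <- function(fit, counts, ci_level) {
  gof <- compute_gsq(fit$model, fit$theta, counts)
  fit$gsq <- gof$gsq
  fit$df <- gof$df
  fit$p_value <- gof$p_value
  fit$ci <- if (!is.na(ci_level) && fit$model$S > 0) {
    tryCatch(compute_ci(fit, level = ci_level),
             error = function(e) {
               warning("confidence intervals unavailable: ", conditionMessage(e),
                       call. = FALSE)
               tibble::tibble(parameter = fit$model$parameters,
                              estimate = unname(fit$theta),
                              lower = NA_real_, upper = NA_real_,
                              level = ci_level, method = NA_character_)
             })
  } else {
    tibble::tibble(parameter = character(), estimate = numeric(),
                   lower = numeric(), upper = numeric(),
                   level = numeric(), method = character())
  }
  fit
}

compute_gsq <- function(model, theta, counts_by_group) {
  gsq <- 0
  for (gi in seq_along(model$group_index)) {
    g <- model$group_index[[gi]]
    f <- counts_by_group[[gi]]
    sw <- step_survival_win(model, theta, g)
    e <- g$n * probs_from_sw(sw$s, sw$w)
    pos <- f > 0
    if (any(pos & e <= 0)) {
      stop("expected count zero with observed count ", f[pos & e <= 0][1],
           " in group level '", g$level, "', set size ", g$m,
           ", position ", which(pos & e <= 0)[1], call. = FALSE)
    }
    gsq <- gsq + 2 * sum(f[pos] * log(f[pos] / e[pos]))
  }
  gsq <- max(0, gsq)  # guard tiny negative rounding at the saturated optimum
  df <- model$df
  tibble::tibble(gsq = gsq, df = df,
                 p_value = stats::pchisq(gsq, df, lower.tail = FALSE))
}

#' Goodness-of-fit test of a fitted PCM
#'
#' The likelihood-ratio statistic `G^2 = 2 sum f log(f / e)` against the
#' saturated model, with `e = n * p(theta_hat)` and the convention that
#' cells with `f = 0` contribute zero. Asymptotically central chi-square
#' with `df = n_categories - S` under the model.
#'
#' @param fit A [fit_pcm()] result.
#' @return A one-row tibble with `gsq`, `df` and `p_value`.
#' @export
gsq_test <- function(fit) {
  stopifnot(inherits(fit, "pcm_fit"))
  counts <- lapply(fit$model$group_index, function(g) group_counts(fit$data, g))
  compute_gsq(fit$model, fit$theta, counts)
}

#' Likelihood-ratio test between nested fitted models
#'
#' `Delta G^2 = G^2(restricted) - G^2(general)` referred to a central
#' chi-square with `Delta df` degrees of freedom. The nesting is verified
#' structurally on the constraint maps and both fits must use identical
#' data.
#'
#' @param fit_restricted,fit_general [fit_pcm()] results, the restricted
#'   model nested in the general one.
#' @return A one-row tibble with `delta_gsq`, `delta_df` and `p_value`.
#' @export
lr_test <- function(fit_restricted, fit_general) {
  stopifnot(inherits(fit_restricted, "pcm_fit"), inherits(fit_general, "pcm_fit"))
  if (!is_nested(fit_restricted$model, fit_general$model)) {
    stop("the first model is not nested in the second", call. = FALSE)
  }
  if (!identical(tibble::as_tibble(fit_restricted$data),
                 tibble::as_tibble(fit_general$data))) {
    stop("the two fits use different data", call. = FALSE)
  }
  delta_gsq <- max(0, fit_restricted$gsq - fit_general$gsq)
  delta_df <- fit_restricted$df - fit_general$df
  p <- if (delta_df == 0) {
    if (delta_gsq <= 1e-12) 1 else NA_real_
  } else {
    stats::pchisq(delta_gsq, delta_df, lower.tail = FALSE)
  }
  tibble::tibble(delta_gsq = delta_gsq, delta_df = delta_df, p_value = p)
}

#' Confidence intervals for PCM parameters
#'
#' Wald intervals `theta_hat +/- z * SE` from the inverse of the observed
#' information (numerical Hessian of the negative log-likelihood at the
#' maximum), truncated to `[0, 1]`. Parameters estimated at the boundary of
#' the unit interval get profile-likelihood intervals instead, since the
#' quadratic approximation fails there.
#'
#' @param fit A [fit_pcm()] result.
#' @param level Confidence level.
#' @return A tibble with columns `parameter`, `estimate`, `lower`, `upper`,
#'   `level`, `method` (`"wald"` or `"profile"`).
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "pcm_fit"), level > 0, level < 1)
  compute_ci(fit, level)
}

compute_ci <- function(fit, level) {
  model <- fit$model
  S <- model$S
  if (S == 0) {
    return(tibble::tibble(parameter = character(), estimate = numeric(),
                          lower = numeric(), upper = numeric(),
                          level = numeric(), method = character()))
  }
  counts <- lapply(model$group_index, function(g) group_counts(fit$data, g))
  theta <- unname(fit$theta)
  z <- stats::qnorm(1 - (1 - level) / 2)

  need_profile <- fit$boundary
  se <- rep(NA_real_, S)
  if (!all(need_profile)) {
    th_int <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    H <- pracma::hessian(function(th) -ll_and_grad(model, th, counts)$ll, th_int)
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    if (min(ev$values) <= max(ev$values) * 1e-7) {
      dir <- ev$vectors[, which.min(ev$values)]
      worst <- model$parameters[which.max(abs(dir))]
      stop("observed information matrix is singular; the direction loading ",
           "mostly on '", worst, "' is not identified from these data",
           call. = FALSE)
    }
    se <- sqrt(diag(solve(H)))
  }

  lower <- upper <- numeric(S)
  method <- character(S)
  for (i in seq_len(S)) {
    if (need_profile[i]) {
      pl <- profile_ci_one(model, counts, theta, fit$logLik, i, level)
      lower[i] <- pl[1]; upper[i] <- pl[2]
      method[i] <- "profile"
    } else {
      lower[i] <- max(0, theta[i] - z * se[i])
      upper[i] <- min(1, theta[i] + z * se[i])
      method[i] <- "wald"
    }
  }
  tibble::tibble(parameter = model$parameters, estimate = theta,
                 lower = lower, upper = upper, level = level, method = method)
}

# profile-likelihood interval for parameter i: theta_i with profile deviance
# 2 * (llmax - pl(theta_i)) <= qchisq(level, 1)
profile_ci_one <- function(model, counts, theta, llmax, i, level) {
  eps <- 1e-6
  target <- llmax - stats::qchisq(level, 1) / 2
  S <- model$S
  prof <- function(x) {
    if (S == 1) return(ll_and_grad(model, x, counts)$ll)
    nll <- function(th_rest) {
      th <- numeric(S); th[i] <- x; th[-i] <- th_rest
      -ll_and_grad(model, th, counts)$ll
    }
    ngr <- function(th_rest) {
      th <- numeric(S); th[i] <- x; th[-i] <- th_rest
      -ll_and_grad(model, th, counts)$grad[-i]
    }
    -stats::optim(pmin(pmax(theta[-i], eps), 1 - eps), nll, ngr,
                  method = "L-BFGS-B", lower = eps, upper = 1 - eps)$value
  }
  edge <- function(lo, hi) {
    # profile ll - target changes sign between lo (below) and hi (at optimum)
    stats::uniroot(function(x) prof(x) - target, c(lo, hi), tol = 1e-6)$root
  }
  est <- theta[i]
  lower <- if (est <= eps) 0
           else if (prof(eps) >= target) 0
           else edge(eps, est)
  upper <- if (est >= 1 - eps) 1
           else if (prof(1 - eps) >= target) 1
           else edge(est, 1 - eps)
  c(lower, upper)
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("ML fit of ", x$model$name, " (N = ", x$N, ")\n", sep = "")
  est <- format(round(x$theta, 4))
  if (length(est) > 0) {
    flag <- ifelse(x$boundary, " (boundary)", "")
    cat(paste0("  ", names(x$theta), " = ", est, flag, collapse = "\n"), "\n")
  } else {
    cat("  (no free parameters)\n")
  }
  cat(sprintf("  log-likelihood kernel: %.4f\n", x$logLik))
  cat(sprintf("  G^2(%d) = %.3f, p = %.3f\n", x$df, x$gsq, x$p_value))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

# evaluate code under a temporary RNG state, restoring the caller's
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
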