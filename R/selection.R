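#' Expected Fisher information of a PCM
#'
#' Per-observation expected information for the product-multinomial design:
#' `I(theta) = sum_g (n_g / N) sum_j (dp_j/dtheta)(dp_j/dtheta)' / p_j`,
#' groups weighted by their share of the total sample. Symmetric positive
#' semi-definite; positive definite at interior points of identifiable
#' models.
#'
#' @param model A [pcm_model()].
#' @param theta Interior parameter vector (all entries strictly in `(0, 1)`).
#' @return An `S x S` matrix.
#' @export
fisher_information <- function(model, theta) {
  theta <- check_theta(model, theta)
  if (model$S == 0) return(matrix(0, 0, 0))
  if (any(theta <= 0 | theta >= 1)) {
    stop("Fisher information requires an interior theta (components in (0,1))",
         call. = FALSE)
  }
  N <- sum(model$design$n)
  info <- matrix(0, model$S, model$S)
  for (g in model$group_index) {
    sw <- step_survival_win(model, theta, g)
    p <- probs_from_sw(sw$s, sw$w)
    J <- group_jacobian(model, theta, g)
    keep <- p > 0
    info <- info + (g$n / N) *
      crossprod(J[keep, , drop = FALSE] / sqrt(p[keep]))
  }
  (info + t(info)) / 2
}

#' Monte-Carlo estimate of the FIA complexity term
#'
#' The functional-form complexity of the Fisher information approximation is
#' `C = log integral over [0,1]^S of sqrt(det I(theta)) dtheta`, with `I` the
#' per-observation expected information of [fisher_information()]. The
#' integral is estimated by plain uniform Monte-Carlo over the unit
#' hypercube (the natural parameter space of an MPT), which is accurate for
#' the low dimensions involved here; the Monte-Carlo standard error of `C`
#' is reported via the delta method.
#'
#' @param model A [pcm_model()].
#' @param draws Number of uniform draws.
#' @param seed Seed for the draws (local RNG).
#' @param chunk Draws processed per block (memory control).
#' @return A list with `C`, `mc_se`, `draws` and `seed`.
#' @export
model_complexity <- function(model, draws = 200000, seed = 20150218,
                             chunk = 20000) {
  stopifnot(inherits(model, "pcm_model"), draws >= 10)
  S <- model$S
  if (S == 0) return(list(C = 0, mc_se = 0, draws = draws, seed = seed))
  total <- 0; total2 <- 0; n_done <- 0
  local_seed(seed, {
    while (n_done < draws) {
      nb <- min(chunk, draws - n_done)
      TH <- matrix(stats::runif(nb * S), nb, S)
      h <- sqrt(pmax(sqrt_det_info_vec(model, TH), 0))
      if (any(!is.finite(h))) {
        stop("non-finite integrand in ", sum(!is.finite(h)), " of ", nb,
             " draws; the information determinant diverges near the boundary",
             call. = FALSE)
      }
      total <- total + sum(h)
      total2 <- total2 + sum(h^2)
      n_done <- n_done + nb
    }
  })
  mean_h <- total / n_done
  var_h <- max(0, total2 / n_done - mean_h^2) * n_done / (n_done - 1)
  if (mean_h <= 0) stop("complexity integral estimated as zero", call. = FALSE)
  list(C = log(mean_h), mc_se = sqrt(var_h / n_done) / mean_h,
       draws = draws, seed = seed)
}

# det I(theta) for many theta at once; TH is draws x S. Builds, per group,
# the category-probability Jacobian columns as vectors across draws, then
# accumulates I and reduces to a determinant by vectorised symmetric
# Gaussian elimination.
sqrt_det_info_vec <- function(model, TH) {
  nb <- nrow(TH); S <- ncol(TH)
  N <- sum(model$design$n)
  M <- array(0, c(nb, S, S))
  slots <- model$slots
  for (g in model$group_index) {
    k <- g$m - 1L
    slot_val <- function(rows) {
      out <- matrix(0, nb, k)
      for (j in seq_len(k)) {
        r <- rows[j]
        out[, j] <- if (is.na(slots$constant[r])) TH[, slots$theta_index[r]]
                    else slots$constant[r]
      }
      out
    }
    Pi <- slot_val(g$pi_rows)
    Pn <- slot_val(g$pnew_rows)
    s <- Pi + (1 - Pi) * (1 - Pn)
    w <- (1 - Pi) * Pn
    # prefix/suffix products of s across step columns
    pre <- matrix(1, nb, k + 1L)  # pre[, j] = prod s over columns < j
    for (j in seq_len(k)) pre[, j + 1L] <- pre[, j] * s[, j]
    suf <- matrix(1, nb, k + 1L)  # suf[, j] = prod s over columns > j - 1
    for (j in k:1) suf[, j] <- suf[, j + 1L] * s[, j]
    P <- cbind(suf[, 1L], w * suf[, -1L, drop = FALSE])  # nb x m

    ti_pi <- slots$theta_index[g$pi_rows]
    ti_pn <- slots$theta_index[g$pnew_rows]
    wgt <- g$n / N
    # Jacobian of category c wrt theta, one nb-vector per (c, t)
    Jc <- matrix(0, nb, S)
    for (c in seq_len(g$m)) {
      Jc[] <- 0
      for (j in seq_len(k)) {
        # dP_c / ds_j and dP_c / dw_j
        if (c == 1L) {
          dPds <- pre[, j] * suf[, j + 1L]
          dPdw <- 0
        } else {
          jc <- c - 1L
          if (j < jc) next
          if (j == jc) {
            dPds <- 0
            dPdw <- suf[, jc + 1L]
          } else {
            dPds <- w[, jc] * (pre[, j] / pmax(pre[, jc + 1L], 1e-300)) * suf[, j + 1L]
            dPdw <- 0
          }
        }
        dpi <- Pn[, j] * (dPds - dPdw)
        dpn <- (1 - Pi[, j]) * (dPdw - dPds)
        if (!is.na(ti_pi[j])) Jc[, ti_pi[j]] <- Jc[, ti_pi[j]] + dpi
        if (!is.na(ti_pn[j])) Jc[, ti_pn[j]] <- Jc[, ti_pn[j]] + dpn
      }
      invp <- wgt / pmax(P[, c], 1e-300)
      for (r in seq_len(S)) {
        for (t in r:S) {
          M[, r, t] <- M[, r, t] + invp * Jc[, r] * Jc[, t]
        }
      }
    }
  }
  for (r in seq_len(S)) for (t in seq_len(S)) if (t < r) M[, r, t] <- M[, t, r]
  det_spd_vec(M)
}

# determinants of many small SPD matrices: Gaussian elimination without
# pivoting, vectorised across the first array dimension
det_spd_vec <- function(A) {
  nb <- dim(A)[1]; S <- dim(A)[2]
  if (S == 1) return(A[, 1, 1])
  det <- rep(1, nb)
  for (kk in seq_len(S)) {
    piv <- A[, kk, kk]
    det <- det * piv
    if (kk < S) {
      for (i in (kk + 1):S) {
        f <- A[, i, kk] / piv
        for (j in kk:S) A[, i, j] <- A[, i, j] - f * A[, kk, j]
      }
    }
  }
  det
}

#' Fisher information approximation (FIA) of a fitted model
#'
#' The minimum-description-length criterion
#' `FIA = -log L(theta_hat) + (S/2) log(N / 2 pi) + C`, where `N` is the
#' total number of participants and `C` is the functional-form complexity of
#' [model_complexity()]. Unlike AIC/BIC, FIA penalises the functional form
#' of a model beyond its parameter count. Smaller is better.
#'
#' @param fit A [fit_pcm()] result.
#' @param draws,seed Monte-Carlo settings for the complexity integral.
#' @param complexity Optional precomputed [model_complexity()] result, e.g.
#'   when the same model is scored against many datasets.
#' @return A one-row tibble with the penalty decomposition: `minus_log_lik`,
#'   `dimension_term`, `complexity`, `complexity_mc_se` and `fia`.
#' @export
fia <- function(fit, draws = 200000, seed = 20150218, complexity = NULL) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (is.null(complexity)) {
    complexity <- model_complexity(fit$model, draws = draws, seed = seed)
  }
  S <- fit$model$S
  N <- fit$N
  dim_term <- if (S == 0) 0 else (S / 2) * log(N / (2 * pi))
  cx <- complexity
  tibble::tibble(
    minus_log_lik = -fit$logLik,
    dimension_term = dim_term,
    complexity = cx$C,
    complexity_mc_se = cx$mc_se,
    fia = -fit$logLik + dim_term + cx$C
  )
}

#' Model weights from FIA values
#'
#' `w_i = exp(-(FIA_i - min FIA)) / sum_k exp(-(FIA_k - min FIA))` —
#' normalised evidence weights, interpretable as the probability of each
#' model being the best of the candidate set. FIA lives on the `-log L`
#' scale, so no factor one-half enters the exponent (unlike Akaike weights
#' on the `-2 log L` scale).
#'
#' @param fia_values Numeric vector of FIA values (at least one, all finite).
#' @return Numeric vector of weights summing to one.
#' @examples
#' round(fia_weights(c(166.4, 165.4, 163.8)), 3)  # 0.058 0.158 0.784
#' @export
fia_weights <- function(fia_values) {
  fia_values <- as.numeric(fia_values)
  if (length(fia_values) == 0) stop("no FIA values supplied", call. = FALSE)
  if (anyNA(fia_values) || any(!is.finite(fia_values))) {
    stop("FIA values must be finite", call. = FALSE)
  }
  e <- exp(-(fia_values - min(fia_values)))
  e / sum(e)
}

#' AIC and BIC of a fitted PCM
#'
#' `AIC = -2 log L + 2 S` and `BIC = -2 log L + S log N`, on the
#' multinomial likelihood kernel, with `N` the total participant count.
#'
#' @param fit A [fit_pcm()] result.
#' @param N Sample size for BIC; defaults to the design total.
#' @return A one-row tibble with `AIC` and `BIC`.
#' @export
aic_bic <- function(fit, N = NULL) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (is.null(N)) N <- fit$N
  tibble::tibble(AIC = -2 * fit$logLik + 2 * fit$model$S,
                 BIC = -2 * fit$logLik + fit$model$S * log(N))
}

#' Lower sample-size bound for FIA model comparison
#'
#' Below `N' = 2 pi exp(2 (C_s - C_c) / (S_c - S_s))` the FIA penalty of the
#' higher-dimensional model can drop below the simpler model's, making the
#' criterion inconsistent for small samples; FIA comparisons are safe when
#' the total sample size exceeds `N'`. `C` terms are the Monte-Carlo
#' complexity integrals; for more than two candidate models take the maximum
#' of the bound over all nested pairs.
#'
#' @param model_simple,model_complex Two `pcm_model`s with
#'   `S_simple < S_complex`.
#' @param draws,seed Monte-Carlo settings for [model_complexity()].
#' @param C_simple,C_complex Optional precomputed complexity values.
#' @return The bound `N'` (a single number).
#' @export
heck_lower_bound <- function(model_simple, model_complex,
                             draws = 200000, seed = 20150218,
                             C_simple = NULL, C_complex = NULL) {
  S_s <- model_simple$S
  S_c <- model_complex$S
  if (S_s >= S_c) {
    stop("the first model must have fewer free parameters than the second",
         call. = FALSE)
  }
  if (is.null(C_simple)) C_simple <- model_complexity(model_simple, draws, seed)$C
  if (is.null(C_complex)) C_complex <- model_complexity(model_complex, draws, seed)$C
  2 * pi * exp(2 * (C_simple - C_complex) / (S_c - S_s))
}

#' Fit and compare a set of candidate PCMs
#'
#' Fits every candidate model to the same frequency table and assembles the
#' full selection table: log-likelihood, parameter count, goodness of fit,
#' AIC, BIC, FIA with its Monte-Carlo error, and FIA weights.
#'
#' @param data A frequency table.
#' @param models A named list of `pcm_model`s (names label the output rows).
#' @param draws,seed Monte-Carlo settings for the FIA complexity integrals.
#' @param complexities Optional named list of precomputed
#'   [model_complexity()] results (names matching `models`).
#' @param fit_seed Seed for the optimiser's multistart draws.
#' @param ... Passed to [fit_pcm()].
#' @return A tibble of class `pcm_selection` with one row per model and
#'   columns `model`, `lnL`, `S`, `df`, `gsq`, `p`, `AIC`, `BIC`, `FIA`,
#'   `FIA_mc_se`, `w_FIA`; fitted objects are attached as attribute `fits`.
#' @examples
#' d <- mantonakis_design()
#' x <- generate_dataset(d, pcm3_model(d), 0.51, seed = 11)
#' sel <- select_models(x, list(`PCM(2)` = pcm2_model(d), `PCM(3)` = pcm3_model(d)),
#'                      draws = 5000)
#' sel
#' @export
select_models <- function(data, models, draws = 200000, seed = 20150218,
                          complexities = NULL, fit_seed = 1, ...) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, function(m) m$name, "")
  }
  fits <- lapply(models, function(m) fit_pcm(data, m, seed = fit_seed, ...))
  if (is.null(complexities)) {
    complexities <- lapply(models, model_complexity, draws = draws, seed = seed)
  }
  rows <- purrr::map2_dfr(fits, complexities, function(f, cx) {
    fi <- fia(f, complexity = cx)
    dplyr::bind_cols(
      tibble::tibble(lnL = f$logLik, S = f$model$S, df = f$df,
                     gsq = f$gsq, p = f$p_value),
      aic_bic(f),
      tibble::tibble(FIA = fi$fia, FIA_mc_se = fi$complexity_mc_se)
    )
  })
  out <- dplyr::bind_cols(tibble::tibble(model = names(models)), rows)
  out$w_FIA <- fia_weights(out$FIA)
  attr(out, "fits") <- fits
  class(out) <- c("pcm_selection", class(out))
  out
}
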