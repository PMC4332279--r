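#' Serial-position choice probabilities of a PCM
#'
#' Evaluates the forward map of the pairwise-competition model for one group:
#' the probability that each serial position `1..m` holds the finally
#' preferred object. With step survival `s_j = pi_j + (1 - pi_j)(1 - pnew_j)`
#' and step win `w_j = (1 - pi_j) pnew_j`, position 1 is chosen when the
#' first object survives every later step, `P(1) = prod_{j=2..m} s_j`, and
#' position `k >= 2` when the object at step `k` wins its competition and
#' then survives, `P(k) = w_k * prod_{j=k+1..m} s_j`. The probabilities sum
#' to one by telescoping.
#'
#' @param model A [pcm_model()].
#' @param theta Numeric vector of free-parameter values in `[0, 1]`, length
#'   `model$S`, ordered as `model$parameters` (names are checked if present).
#' @param level,set_size Identify the group.
#' @return Named numeric vector of length `m` (`pos1` ... `posm`).
#' @examples
#' d <- pcm_design(level = "a", set_size = 2, n = 10)
#' m <- pcm_model(d, dplyr::mutate(pcm_slots(d),
#'   parameter = ifelse(kind == "pi", "pi", NA),
#'   constant = ifelse(kind == "pnew", 0.5, NA)), check_identifiability = FALSE)
#' category_probabilities(m, 0.3, "a", 2)  # (0.65, 0.35)
#' @export
category_probabilities <- function(model, theta, level, set_size) {
  g <- find_group(model, level, set_size)
  sw <- step_survival_win(model, check_theta(model, theta), g)
  probs_from_sw(sw$s, sw$w)
}

#' @keywords internal
find_group <- function(model, level, set_size) {
  hit <- which(model$design$level == level & model$design$set_size == set_size)
  if (length(hit) != 1) {
    stop("no group with level '", level, "' and set size ", set_size,
         " in the design", call. = FALSE)
  }
  model$group_index[[hit]]
}

check_theta <- function(model, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != model$S) {
    stop("theta has length ", length(theta), " but the model has S = ",
         model$S, " free parameters", call. = FALSE)
  }
  if (anyNA(theta) || any(theta < 0 | theta > 1)) {
    stop("theta entries must lie in [0, 1]", call. = FALSE)
  }
  theta
}

# slot values: constants where fixed, theta elsewhere
expand_slots <- function(model, theta) {
  v <- model$slots$constant
  free <- is.na(v)
  v[free] <- theta[model$slots$theta_index[free]]
  v
}

step_survival_win <- function(model, theta, g) {
  v <- expand_slots(model, theta)
  pi_j <- v[g$pi_rows]
  p_j <- v[g$pnew_rows]
  list(pi = pi_j, pnew = p_j,
       s = pi_j + (1 - pi_j) * (1 - p_j),
       w = (1 - pi_j) * p_j)
}

# probabilities (pos 1..m) from survival/win vectors for steps 2..m
probs_from_sw <- function(s, w) {
  m <- length(s) + 1L
  suf <- rev(cumprod(rev(c(s, 1))))  # suf[k] = prod s over steps > k
  p <- c(suf[1], w * suf[-1])
  names(p) <- paste0("pos", seq_len(m))
  p
}

#' Choice probabilities by exhaustive path enumeration
#'
#' Independent reference implementation of [category_probabilities()]: walks
#' all `3^(m-1)` branches of the processing tree (inertia-keep, compete-keep,
#' compete-new at each step), multiplies branch probabilities, and sums them
#' by final choice. Exponential in `m`; intended as a test oracle for small
#' set sizes.
#'
#' @inheritParams category_probabilities
#' @param max_m Largest set size accepted (enumeration is exponential).
#' @return Named numeric vector of length `m`.
#' @export
path_enumeration_probabilities <- function(model, theta, level, set_size,
                                           max_m = 8) {
  g <- find_group(model, level, set_size)
  if (g$m > max_m) {
    stop("set size ", g$m, " too large for path enumeration (max ", max_m, ")",
         call. = FALSE)
  }
  sw <- step_survival_win(model, check_theta(model, theta), g)
  m <- g$m
  probs <- numeric(m)
  outcomes <- expand.grid(rep(list(1:3), m - 1))  # per step: 1 inertia, 2 keep, 3 new
  for (r in seq_len(nrow(outcomes))) {
    branch <- as.integer(outcomes[r, ])
    favorite <- 1L
    prob <- 1
    for (j in 2:m) {
      o <- branch[j - 1]
      step_prob <- switch(o,
        sw$pi[j - 1],                        # inertia: keep without comparison
        (1 - sw$pi[j - 1]) * (1 - sw$pnew[j - 1]),  # compete, favorite wins
        (1 - sw$pi[j - 1]) * sw$pnew[j - 1]  # compete, new object wins
      )
      prob <- prob * step_prob
      if (o == 3L) favorite <- j
    }
    probs[favorite] <- probs[favorite] + prob
  }
  names(probs) <- paste0("pos", seq_len(m))
  probs
}

#' Expected choice probabilities and counts for every group
#'
#' Tidy view of the forward map across the whole design, optionally scaled
#' by group sizes to expected frequencies.
#'
#' @inheritParams category_probabilities
#' @return A tibble with columns `level`, `set_size`, `position`, `prob`
#'   and `expected` (`n * prob`).
#' @export
pcm_expected <- function(model, theta) {
  theta <- check_theta(model, theta)
  purrr::map_dfr(model$group_index, function(g) {
    sw <- step_survival_win(model, theta, g)
    p <- probs_from_sw(sw$s, sw$w)
    tibble::tibble(level = g$level, set_size = g$m,
                   position = seq_len(g$m), prob = unname(p),
                   expected = g$n * unname(p))
  })
}

# Jacobian dP/dtheta for one group: m x S. Uses the product structure:
# dP1/ds_j and dPk/ds_j (j > k), dPk/dw_k, chained through
# ds/dpi = pnew, dw/dpi = -pnew, ds/dpnew = -(1-pi), dw/dpnew = (1-pi).
group_jacobian <- function(model, theta, g) {
  sw <- step_survival_win(model, theta, g)
  m <- g$m
  s <- sw$s; w <- sw$w
  nsteps <- m - 1L
  # dP[k, j]: derivative of P(position k) wrt s_j (steps indexed 1..m-1 for j=2..m)
  dPds <- matrix(0, m, nsteps)
  dPdw <- matrix(0, m, nsteps)
  # products of s over step index ranges, excluding one step
  for (j in seq_len(nsteps)) {
    others <- s[-j]
    dPds[1, j] <- prod(others)
  }
  for (k in 2:m) {
    kk <- k - 1L  # step index at which the position-k object wins
    later <- if (kk < nsteps) (kk + 1L):nsteps else integer(0)
    dPdw[k, kk] <- prod(s[later])
    for (j in later) {
      dPds[k, j] <- w[kk] * prod(s[setdiff(later, j)])
    }
  }
  dPdpi <- sweep(dPds, 2, sw$pnew, `*`) - sweep(dPdw, 2, sw$pnew, `*`)
  dPdpn <- sweep(dPdw - dPds, 2, 1 - sw$pi, `*`)
  J <- matrix(0, m, model$S)
  ti_pi <- model$slots$theta_index[g$pi_rows]
  ti_pn <- model$slots$theta_index[g$pnew_rows]
  for (j in seq_len(nsteps)) {
    if (!is.na(ti_pi[j])) J[, ti_pi[j]] <- J[, ti_pi[j]] + dPdpi[, j]
    if (!is.na(ti_pn[j])) J[, ti_pn[j]] <- J[, ti_pn[j]] + dPdpn[, j]
  }
  J
}

# stacked Jacobian over all groups (sum(m) rows x S cols)
model_jacobian <- function(model, theta) {
  theta <- check_theta(model, theta)
  do.call(rbind, lapply(model$group_index, function(g) {
    group_jacobian(model, theta, g)
  }))
}
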