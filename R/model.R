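#' Constrained pairwise-competition models
#'
#' The pairwise-competition model (PCM) describes sequential preference
#' construction: the object tasted first is the initial favorite; at each
#' subsequent step `j = 2, ..., m` the taster either keeps the current
#' favorite without comparison ("choice inertia", probability `pi_j`) or
#' compares the new object against the favorite, which the new object wins
#' with probability `pnew_j`. The final favorite is the preferred object.
#' As a multinomial processing tree this yields, with step survival
#' `s_j = pi_j + (1 - pi_j)(1 - pnew_j)` and step win `w_j = (1 - pi_j) pnew_j`,
#' the serial-position choice probabilities
#' `P(1) = prod_{j=2..m} s_j` and `P(k) = w_k * prod_{j=k+1..m} s_j` for
#' `k >= 2`.
#'
#' A model is the design plus a constraint map assigning every parameter slot
#' `(kind, step, level)` — kind is `"pi"` or `"pnew"` — either to a free
#' parameter (an equivalence class named by a label) or to a fixed constant
#' in `[0, 1]`. Step-`j` parameters are shared across all set-size groups
#' with `m >= j` within a factor level. Order constraints are not supported.
#'
#' @param design A [pcm_design()].
#' @param constraints A data frame with columns `kind`, `step`, `level`,
#'   `parameter` (character label of the free-parameter class, `NA` if fixed)
#'   and `constant` (numeric in `[0, 1]`, `NA` if free), covering every slot
#'   of the design exactly once. [pcm_slots()] returns the slot skeleton.
#' @param check_identifiability Probe the parameter-to-probability map for
#'   local identifiability (numerical Jacobian rank) at model build time?
#' @param name Optional display name for the model.
#'
#' @return An object of class `pcm_model`: a list with elements `design`,
#'   `slots` (the resolved constraint map), `parameters` (free-parameter
#'   names in class order), `S` (number of free parameters),
#'   `n_categories` (independent category probabilities, `sum(m - 1)`),
#'   `df` (`n_categories - S`) and `identifiable` (logical or `NA`).
#'
#' @seealso [pcm1_model()], [pcm2_model()], [pcm3_model()] for the standard
#'   nested family; [category_probabilities()] for the forward map.
#' @examples
#' d <- mantonakis_design()
#' m1 <- pcm1_model(d)
#' m1$S   # 8 free inertia parameters
#' m1$df  # 20 - 8 = 12
#' @export
pcm_model <- function(design, constraints, check_identifiability = TRUE,
                      name = "PCM") {
  design <- pcm_design(design)
  skeleton <- pcm_slots(design)

  req <- c("kind", "step", "level", "parameter", "constant")
  missing_cols <- setdiff(req, names(constraints))
  if (length(missing_cols) > 0) {
    stop("constraints must have columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  constraints <- tibble::as_tibble(constraints[req])
  key <- function(x) paste(x$kind, x$step, x$level, sep = "\r")
  if (anyDuplicated(key(constraints))) {
    stop("constraint map assigns a parameter slot more than once", call. = FALSE)
  }
  idx <- match(key(skeleton), key(constraints))
  if (anyNA(idx)) {
    bad <- skeleton[is.na(idx), ]
    stop("constraint map leaves slots unassigned: ",
         paste(bad$kind, bad$step, bad$level, collapse = "; "), call. = FALSE)
  }
  slots <- skeleton
  slots$parameter <- as.character(constraints$parameter[idx])
  slots$constant <- as.numeric(constraints$constant[idx])

  free <- is.na(slots$constant)
  if (any(free & is.na(slots$parameter))) {
    stop("each slot needs either a parameter label or a constant", call. = FALSE)
  }
  if (any(!free & !is.na(slots$parameter))) {
    stop("a slot cannot have both a parameter label and a constant", call. = FALSE)
  }
  if (any(!free & (slots$constant < 0 | slots$constant > 1))) {
    stop("fixed constants must lie in [0, 1]", call. = FALSE)
  }

  parameters <- unique(slots$parameter[free])
  slots$theta_index <- match(slots$parameter, parameters)

  n_categories <- sum(design$set_size - 1L)
  S <- length(parameters)
  df <- n_categories - S
  if (df < 0) {
    warning("model has more free parameters (", S, ") than independent ",
            "categories (", n_categories, "): it cannot be identified or ",
            "tested", call. = FALSE)
  }

  model <- structure(
    list(design = design, slots = slots, parameters = parameters,
         S = S, n_categories = n_categories, df = as.integer(df),
         identifiable = NA, name = name),
    class = "pcm_model"
  )
  model$group_index <- build_group_index(model)
  if (check_identifiability && S > 0) {
    ident <- check_identifiability(model)
    model$identifiable <- ident$identifiable
    if (!isTRUE(ident$identifiable)) {
      warning("model is not locally identifiable (Jacobian rank ",
              max(ident$probes$rank), " < S = ", S, "); ",
              "freeing both pi and pnew at a step usually causes this",
              call. = FALSE)
    }
  }
  model
}

#' Parameter-slot skeleton of a design
#'
#' Lists every parameter slot `(kind, step, level)` of a design: for each
#' factor level, steps `j = 2` up to the largest set size at that level,
#' for both the inertia (`pi`) and competition-win (`pnew`) parameters.
#' Fill in the `parameter`/`constant` columns to build a constraint map for
#' [pcm_model()].
#'
#' @inheritParams pcm_model
#' @return A tibble with columns `kind`, `step`, `level`, `parameter` (`NA`),
#'   `constant` (`NA`).
#' @export
pcm_slots <- function(design) {
  design <- pcm_design(design)
  levels <- unique(design$level)
  purrr::map_dfr(levels, function(lv) {
    m_max <- max(design$set_size[design$level == lv])
    tidyr::expand_grid(kind = c("pi", "pnew"), step = 2:m_max) |>
      dplyr::mutate(level = lv, parameter = NA_character_, constant = NA_real_)
  }) |>
    dplyr::arrange(.data$level, .data$kind, .data$step) |>
    dplyr::select("kind", "step", "level", "parameter", "constant")
}

# Per-group lookup from slots into theta: for group g with set size m, the
# slot rows for pi_j and pnew_j, j = 2..m, in step order.
build_group_index <- function(model) {
  slots <- model$slots
  purrr::pmap(model$design, function(level, set_size, n) {
    steps <- 2:set_size
    pi_rows <- match(paste("pi", steps, level), paste(slots$kind, slots$step, slots$level))
    pnew_rows <- match(paste("pnew", steps, level), paste(slots$kind, slots$step, slots$level))
    list(level = level, m = set_size, n = n,
         pi_rows = pi_rows, pnew_rows = pnew_rows)
  })
}

default_parameter_name <- function(kind, step, level) {
  paste0(kind, step, "_", level)
}

#' The standard nested PCM family
#'
#' Three nested model versions for a design with a between-subjects factor,
#' all fixing the competition-win probability at `pnew = 0.5` (appropriate
#' when the objects are physically identical, so neither competitor has an
#' advantage):
#'
#' * `pcm1_model()` — PCM(1): one free inertia parameter per step and factor
#'   level, shared across set-size groups (8 parameters on a 2-level design
#'   with set sizes 2–5).
#' * `pcm2_model()` — PCM(2): inertia equated across steps within each level
#'   (one parameter per level).
#' * `pcm3_model()` — PCM(3): a single inertia parameter overall.
#'
#' @inheritParams pcm_model
#' @param pnew Fixed competition-win constant, default `0.5`.
#' @return A [pcm_model()].
#' @examples
#' d <- mantonakis_design()
#' vapply(list(pcm1_model(d), pcm2_model(d), pcm3_model(d)), `[[`, 0L, "df")
#' @export
pcm1_model <- function(design, pnew = 0.5) {
  cm <- pcm_slots(design) |>
    dplyr::mutate(
      parameter = dplyr::if_else(.data$kind == "pi",
                                 default_parameter_name(.data$kind, .data$step, .data$level),
                                 NA_character_),
      constant = dplyr::if_else(.data$kind == "pnew", pnew, NA_real_)
    )
  pcm_model(design, cm, name = "PCM(1)")
}

#' @rdname pcm1_model
#' @export
pcm2_model <- function(design, pnew = 0.5) {
  cm <- pcm_slots(design) |>
    dplyr::mutate(
      parameter = dplyr::if_else(.data$kind == "pi",
                                 paste0("pi_", .data$level), NA_character_),
      constant = dplyr::if_else(.data$kind == "pnew", pnew, NA_real_)
    )
  pcm_model(design, cm, name = "PCM(2)")
}

#' @rdname pcm1_model
#' @export
pcm3_model <- function(design, pnew = 0.5) {
  cm <- pcm_slots(design) |>
    dplyr::mutate(
      parameter = dplyr::if_else(.data$kind == "pi", "pi", NA_character_),
      constant = dplyr::if_else(.data$kind == "pnew", pnew, NA_real_)
    )
  pcm_model(design, cm, name = "PCM(3)")
}

#' @export
print.pcm_model <- function(x, ...) {
  cat(x$name, ": pairwise-competition model\n", sep = "")
  cat("  groups: ", nrow(x$design),
      " (levels: ", paste(unique(x$design$level), collapse = ", "),
      "; set sizes: ", paste(sort(unique(x$design$set_size)), collapse = ", "),
      ")\n", sep = "")
  cat("  free parameters (S): ", x$S,
      if (x$S > 0) paste0(" [", paste(x$parameters, collapse = ", "), "]"),
      "\n", sep = "")
  cat("  independent categories: ", x$n_categories, "; df: ", x$df, "\n", sep = "")
  if (!is.na(x$identifiable)) {
    cat("  locally identifiable: ", x$identifiable, "\n", sep = "")
  }
  invisible(x)
}

#' Check whether a model is nested in another
#'
#' A restricted model is nested in a general model when every constraint of
#' the general model also holds in the restricted model: slots sharing a free
#' parameter in the general model share one (or share a constant) in the
#' restricted model, and slots fixed in the general model are fixed to the
#' same constant in the restricted one. Checked structurally on the
#' constraint maps; both models must share the same design.
#'
#' @param restricted,general `pcm_model` objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_nested <- function(restricted, general) {
  stopifnot(inherits(restricted, "pcm_model"), inherits(general, "pcm_model"))
  if (!identical(dplyr::arrange(restricted$design, .data$level, .data$set_size),
                 dplyr::arrange(general$design, .data$level, .data$set_size))) {
    return(FALSE)
  }
  key <- function(s) paste(s$kind, s$step, s$level)
  rs <- restricted$slots[match(key(general$slots), key(restricted$slots)), ]
  gs <- general$slots
  # restricted assignment of each slot, as a comparable token
  token <- function(s) ifelse(is.na(s$constant),
                              paste0("p:", s$parameter),
                              paste0("c:", format(s$constant, digits = 15)))
  rtok <- token(rs)
  gtok <- token(gs)
  # general constants must be identical constants in the restricted model
  gconst <- !is.na(gs$constant)
  if (any(gconst & (gtok != rtok))) return(FALSE)
  # each general free class must map to a single restricted token
  for (cls in unique(gs$parameter[!gconst])) {
    if (length(unique(rtok[!gconst & gs$parameter == cls])) > 1) return(FALSE)
  }
  TRUE
}

#' Probe local identifiability of a model
#'
#' Computes the rank of the Jacobian of the category-probability map with
#' respect to the free parameters at several interior probe points
#' (deterministic low-discrepancy points in `(0.05, 0.95)^S`). The model is
#' locally identifiable when the rank equals `S` at every probe.
#'
#' @param model A `pcm_model`.
#' @param n_probes Number of interior probe points (at least 5 recommended).
#' @return A list with `identifiable` (logical) and `probes` (tibble of
#'   per-probe Jacobian ranks).
#' @export
check_identifiability <- function(model, n_probes = 5) {
  stopifnot(inherits(model, "pcm_model"))
  S <- model$S
  if (S == 0) {
    return(list(identifiable = TRUE,
                probes = tibble::tibble(probe = integer(), rank = integer())))
  }
  # deterministic low-discrepancy (Kronecker) points in (0.05, 0.95)^S
  irr <- sqrt(utils::head(c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37,
                            41, 43, 47, 53, 59, 61, 67, 71), S))
  pts <- outer(seq_len(n_probes), irr) %% 1
  pts <- 0.05 + 0.9 * matrix(pts, nrow = n_probes, ncol = S)
  ranks <- vapply(seq_len(n_probes), function(i) {
    J <- model_jacobian(model, pts[i, ])
    qr(J)$rank
  }, integer(1))
  list(identifiable = all(ranks == S),
       probes = tibble::tibble(probe = seq_len(n_probes), rank = ranks))
}
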