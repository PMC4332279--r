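#' Define a product-multinomial tasting design
#'
#' A design describes the experimental layout of a sequential tasting study:
#' independent groups defined by a between-subjects factor level (e.g. high
#' vs. low product knowledge) crossed with the choice-set size `m` (number of
#' objects tasted in sequence), each with its own participant count.
#'
#' @param data A data frame with columns `level`, `set_size` and `n`
#'   (one row per group), or `NULL` to supply the columns directly.
#' @param level,set_size,n Vectors used when `data` is `NULL`.
#'
#' @return A tibble of class `pcm_design` with columns `level` (character),
#'   `set_size` (integer, at least 2) and `n` (non-negative integer).
#'
#' @examples
#' pcm_design(level = c("high", "low"), set_size = c(3, 3), n = c(20, 25))
#' @export
pcm_design <- function(data = NULL, level = NULL, set_size = NULL, n = NULL) {
  if (is.null(data)) {
    data <- tibble::tibble(level = level, set_size = set_size, n = n)
  }
  req <- c("level", "set_size", "n")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("design must have columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data[req])
  out$level <- as.character(out$level)
  out$set_size <- as.integer(out$set_size)
  out$n <- as.integer(out$n)
  validate_design(out)
  class(out) <- c("pcm_design", class(tibble::tibble()))
  out
}

validate_design <- function(design) {
  if (nrow(design) == 0) stop("design has no groups", call. = FALSE)
  if (anyNA(design)) stop("design contains missing values", call. = FALSE)
  if (any(design$set_size < 2)) {
    stop("set_size must be at least 2: a single object admits no competition step",
         call. = FALSE)
  }
  if (any(design$n < 0)) stop("participant counts must be non-negative", call. = FALSE)
  key <- paste(design$level, design$set_size)
  if (anyDuplicated(key)) {
    stop("duplicate (level, set_size) group in design", call. = FALSE)
  }
  invisible(design)
}

#' Two-factor wine-tasting design: knowledge level by choice-set size
#'
#' Builds the 2 x 4 product-multinomial layout of the wine-tasting study the
#' package emulates: 142 participants (69 with high and 73 with low knowledge
#' about wines) randomised across choice sets of 2 to 5 wine samples. The
#' per-cell allocation was not published; participants are split across set
#' sizes as evenly as possible (69 -> 18, 17, 17, 17 and 73 -> 19, 18, 18, 18),
#' with the larger cells at the smaller set sizes. The split is deterministic.
#'
#' @param scale Positive integer multiplier on every cell count; `scale = 1`
#'   gives the original total of 142 participants.
#'
#' @return A [pcm_design()] with 8 groups.
#' @examples
#' mantonakis_design()
#' sum(mantonakis_design(scale = 10)$n)  # 1420
#' @export
mantonakis_design <- function(scale = 1) {
  stopifnot(length(scale) == 1, scale >= 1, scale == as.integer(scale))
  split_even <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + (seq_len(k) <= extra)  # larger cells first (smallest set size)
  }
  sizes <- 2:5
  pcm_design(
    level = rep(c("high", "low"), each = 4),
    set_size = rep(sizes, 2),
    n = as.integer(scale) * c(split_even(69, 4), split_even(73, 4))
  )
}
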