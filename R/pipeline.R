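#' Run the full model-fitting analysis pipeline
#'
#' Orchestrates the complete analysis on observed or simulated data: fit a
#' chain of candidate models, run the nested likelihood-ratio tests,
#' assemble the model-selection table (AIC, BIC, FIA, weights), tabulate
#' observed versus expected serial-position frequencies for the preferred
#' model, and evaluate any power queries. All randomness is controlled by
#' seeds recorded in the report, so every number is regenerable.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{data}{path to a frequency-table CSV, *or*}
#'     \item{synthetic}{list with `scale` (design multiplier), `model`
#'       (`"pcm1"|"pcm2"|"pcm3"`), `theta` (true values) and `seed`}
#'     \item{models}{character vector of candidates among
#'       `"pcm1"`, `"pcm2"`, `"pcm3"` (default all three)}
#'     \item{ci_level}{confidence level (default 0.95)}
#'     \item{fia}{list with `draws` (default 200000) and `seed`
#'       (default 20150218)}
#'     \item{power}{data-frame-like list of power queries (see
#'       [power_table()])}
#'     \item{out_dir}{optional output directory for the TSV/EQN bundle}
#'     \item{fit}{optional list with `n_starts`, `seed` for the optimiser}
#'   }
#'
#' @return An object of class `pcm_report`: list with `data`, `design`,
#'   `fits`, `fit_table`, `lr_table` (nested pairs in decreasing S),
#'   `selection`, `observed_expected` (for the FIA-preferred model),
#'   `power`, `config`.
#' @examples
#' rep <- run_analysis(list(
#'   synthetic = list(scale = 1, model = "pcm3", theta = 0.51, seed = 9),
#'   fia = list(draws = 2000)
#' ))
#' rep$selection
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  # --- data -----------------------------------------------------------
  if (!is.null(config$data)) {
    data <- read_frequency_table(config$data)
    design <- data |>
      dplyr::group_by(.data$level, .data$set_size) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
      pcm_design()
  } else if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    scale <- syn$scale %||% 1
    design <- mantonakis_design(scale)
    gen_model <- standard_model(syn$model %||% "pcm3", design)
    if (is.null(syn$seed)) stop("synthetic data requires a seed", call. = FALSE)
    data <- generate_dataset(design, gen_model, syn$theta, seed = syn$seed)
  } else {
    stop("config needs either 'data' (CSV path) or 'synthetic'", call. = FALSE)
  }

  model_names <- config$models %||% c("pcm1", "pcm2", "pcm3")
  if (length(model_names) < 1) stop("at least one model required", call. = FALSE)
  models <- lapply(model_names, standard_model, design = design)
  names(models) <- vapply(models, function(m) m$name, "")

  fia_cfg <- config$fia %||% list()
  fit_cfg <- config$fit %||% list()
  ci_level <- config$ci_level %||% 0.95

  selection <- select_models(
    data, models,
    draws = fia_cfg$draws %||% 200000,
    seed = fia_cfg$seed %||% 20150218,
    n_starts = fit_cfg$n_starts %||% 10,
    fit_seed = fit_cfg$seed %||% 1,
    ci_level = ci_level
  )
  fits <- attr(selection, "fits")

  fit_table <- purrr::map_dfr(fits, glance.pcm_fit)
  fit_table <- dplyr::bind_cols(tibble::tibble(model = names(fits)), fit_table)

  # nested LR tests along decreasing dimension
  ord <- order(vapply(fits, function(f) f$model$S, 0), decreasing = TRUE)
  lr_table <- NULL
  if (length(ord) >= 2) {
    lr_table <- purrr::map_dfr(seq_len(length(ord) - 1), function(i) {
      gen <- fits[[ord[i]]]; res <- fits[[ord[i + 1]]]
      if (!is_nested(res$model, gen$model)) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(restricted = names(fits)[ord[i + 1]],
                       general = names(fits)[ord[i]]),
        lr_test(res, gen)
      )
    })
  }

  best <- fits[[which.max(selection$w_FIA)]]
  observed_expected <- pcm_expected(best$model, unname(best$theta)) |>
    dplyr::left_join(
      dplyr::rename(best$data, observed = "count"),
      by = c("level", "set_size", "position")
    ) |>
    dplyr::select("level", "set_size", "position", "observed",
                  expected = "expected", prob = "prob")

  power <- NULL
  if (!is.null(config$power)) {
    q <- config$power
    if (!is.data.frame(q)) q <- dplyr::bind_rows(lapply(q, tibble::as_tibble))
    power <- power_table(q)
  }

  report <- structure(
    list(data = data, design = design, fits = fits, fit_table = fit_table,
         lr_table = lr_table, selection = selection,
         observed_expected = observed_expected, power = power,
         best_model = names(fits)[which.max(selection$w_FIA)],
         config = config),
    class = "pcm_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

standard_model <- function(name, design) {
  switch(tolower(name),
         pcm1 = pcm1_model(design),
         pcm2 = pcm2_model(design),
         pcm3 = pcm3_model(design),
         stop("unknown model '", name, "' (expected pcm1/pcm2/pcm3)",
              call. = FALSE))
}

#' Write a report bundle to disk
#'
#' Plain-text output: TSV tables (`fits.tsv`, `lr_tests.tsv`,
#' `selection.tsv`, `observed_expected.tsv`, `power.tsv`, `data.csv`), one
#' EQN model file per candidate, and a human-readable `summary.txt`.
#'
#' @param report A [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pcm_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frequency_table(report$data, file.path(dir, "data.csv"))
  readr::write_tsv(report$fit_table, file.path(dir, "fits.tsv"))
  if (!is.null(report$lr_table) && nrow(report$lr_table) > 0) {
    readr::write_tsv(report$lr_table, file.path(dir, "lr_tests.tsv"))
  }
  write_selection_tsv(report$selection, file.path(dir, "selection.tsv"))
  readr::write_tsv(report$observed_expected,
                   file.path(dir, "observed_expected.tsv"))
  if (!is.null(report$power)) {
    readr::write_tsv(report$power, file.path(dir, "power.tsv"))
  }
  for (nm in names(report$fits)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_eqn(report$fits[[nm]]$model, file.path(dir, paste0(safe, ".eqn")))
  }
  writeLines(utils::capture.output(print(report)), file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.pcm_report <- function(x, ...) {
  cat("PCM analysis report\n")
  cat("  design: ", nrow(x$design), " groups, N = ", sum(x$design$n), "\n", sep = "")
  cat("\nGoodness of fit:\n")
  print(x$fit_table)
  if (!is.null(x$lr_table) && nrow(x$lr_table) > 0) {
    cat("\nNested likelihood-ratio tests:\n")
    print(x$lr_table)
  }
  cat("\nModel selection:\n")
  print(tibble::as_tibble(x$selection))
  cat("\nFIA-preferred model: ", x$best_model, "\n", sep = "")
  if (!is.null(x$power)) {
    cat("\nPower analysis:\n")
    print(x$power)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
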