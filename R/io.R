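#' Read and write final-preference frequency tables
#'
#' A frequency table records, for every group of a design, the number of
#' participants whose finally preferred object sat at each serial position:
#' columns `level` (factor level), `set_size` (m), `position` (1..m) and
#' `count` (non-negative integer). Each group must be complete (every
#' position present exactly once).
#'
#' @param path File path of a CSV with exactly those four columns.
#' @return A validated tibble.
#' @export
read_frequency_table <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    level = readr::col_character(),
    set_size = readr::col_integer(),
    position = readr::col_integer(),
    count = readr::col_integer()
  ))
  extra <- setdiff(names(data), c("level", "set_size", "position", "count"))
  if (length(extra) > 0) {
    stop("unexpected columns in frequency table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  validate_frequency_table(data)
}

#' @rdname read_frequency_table
#' @param data A frequency table.
#' @export
write_frequency_table <- function(data, path) {
  data <- validate_frequency_table(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Validate a frequency table, optionally against a design
#'
#' @param data A data frame with columns `level`, `set_size`, `position`,
#'   `count`.
#' @param design Optional [pcm_design()]; when given, the table must contain
#'   exactly the design's groups with matching totals.
#' @return The table as a tibble, sorted by group and position, invisibly
#'   usable downstream.
#' @export
validate_frequency_table <- function(data, design = NULL) {
  req <- c("level", "set_size", "position", "count")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("frequency table must have columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data[req])
  data$level <- as.character(data$level)
  for (col in c("set_size", "position", "count")) {
    v <- data[[col]]
    if (anyNA(v) || any(v != as.integer(v))) {
      stop("column '", col, "' must be integer-valued with no missing entries",
           call. = FALSE)
    }
    data[[col]] <- as.integer(v)
  }
  if (any(data$count < 0)) stop("counts must be non-negative", call. = FALSE)
  data <- dplyr::arrange(data, .data$level, .data$set_size, .data$position)
  bad <- data |>
    dplyr::group_by(.data$level, .data$set_size) |>
    dplyr::summarise(
      ok = identical(.data$position, seq_len(.data$set_size[1])),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("incomplete or duplicated positions for group(s): ",
         paste(bad$level, bad$set_size, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(design)) {
    totals <- data |>
      dplyr::group_by(.data$level, .data$set_size) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
      dplyr::arrange(.data$level, .data$set_size)
    dd <- dplyr::arrange(tibble::as_tibble(design), .data$level, .data$set_size)
    if (!identical(totals$level, dd$level) ||
        !identical(totals$set_size, dd$set_size)) {
      stop("frequency-table groups do not match the design", call. = FALSE)
    }
    if (!identical(as.integer(totals$n), as.integer(dd$n))) {
      stop("group totals do not match the design's participant counts",
           call. = FALSE)
    }
  }
  data
}

# counts for one group, as a vector over positions 1..m
group_counts <- function(data, g) {
  rows <- data$level == g$level & data$set_size == g$m
  counts <- data$count[rows][order(data$position[rows])]
  if (length(counts) != g$m) {
    stop("data lacks group level '", g$level, "', set size ", g$m, call. = FALSE)
  }
  counts
}

#' Write a model-selection table as TSV
#'
#' @param selection A [select_models()] result.
#' @param path Output file path.
#' @export
write_selection_tsv <- function(selection, path) {
  readr::write_tsv(tibble::as_tibble(selection), path)
  invisible(path)
}
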