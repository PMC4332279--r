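#' Export a model as an EQN processing-tree file
#'
#' Writes the standard plain-text MPT model format read by common MPT tools:
#' an optional first line giving the number of branch lines, then one line
#' per processing-tree branch with fields `tree category term`, where the
#' term is a `*`-separated product of parameter names, complements
#' `(1-name)` and numeric constants. Each group of the design is one tree
#' with `3^(m-1)` branches (inertia-keep, compete-keep, compete-new at each
#' step); categories are numbered contiguously within each tree. Free
#' parameters are named `pi{j}_{level}` / `pnew{j}_{level}` after the first
#' slot of their equivalence class.
#'
#' @param model A [pcm_model()].
#' @param path Optional output file; when `NULL` the text is returned only.
#' @param header Prepend the branch-count header line?
#' @return Invisibly, the lines of the file as a character vector.
#' @export
write_eqn <- function(model, path = NULL, header = TRUE) {
  stopifnot(inherits(model, "pcm_model"))
  slots <- model$slots
  # display name per slot: class representative name or the constant
  class_name <- character(nrow(slots))
  for (i in seq_len(nrow(slots))) {
    if (!is.na(slots$constant[i])) {
      class_name[i] <- format(slots$constant[i], digits = 15)
    } else {
      first <- which(slots$parameter == slots$parameter[i])[1]
      class_name[i] <- default_parameter_name(slots$kind[first], slots$step[first],
                                              slots$level[first])
    }
  }
  is_const <- !is.na(slots$constant)

  term_of <- function(slot_row, complement) {
    nm <- class_name[slot_row]
    if (is_const[slot_row]) {
      format(if (complement) 1 - slots$constant[slot_row] else slots$constant[slot_row],
             digits = 15)
    } else if (complement) paste0("(1-", nm, ")") else nm
  }

  lines <- character(0)
  cat_offset <- 0L
  for (tree in seq_along(model$group_index)) {
    g <- model$group_index[[tree]]
    m <- g$m
    outcomes <- expand.grid(rep(list(1:3), m - 1))
    for (r in seq_len(nrow(outcomes))) {
      branch <- as.integer(outcomes[r, ])
      favorite <- 1L
      terms <- character(0)
      for (j in 2:m) {
        o <- branch[j - 1]
        pi_row <- g$pi_rows[j - 1]
        pn_row <- g$pnew_rows[j - 1]
        terms <- c(terms, switch(o,
          term_of(pi_row, FALSE),
          c(term_of(pi_row, TRUE), term_of(pn_row, TRUE)),
          c(term_of(pi_row, TRUE), term_of(pn_row, FALSE))
        ))
        if (o == 3L) favorite <- j
      }
      lines <- c(lines,
                 paste(tree, cat_offset + favorite, paste(terms, collapse = "*")))
    }
    cat_offset <- cat_offset + m
  }
  if (header) lines <- c(as.character(length(lines)), lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
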