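# small single-group models used across tests

# one group of size m with a single shared inertia parameter, pnew fixed
single_pi_model <- function(m, n = 10, pnew = 0.5, level = "a") {
  d <- pcm_design(level = level, set_size = m, n = n)
  cm <- dplyr::mutate(
    pcm_slots(d),
    parameter = ifelse(kind == "pi", "pi", NA_character_),
    constant = ifelse(kind == "pnew", pnew, NA_real_)
  )
  pcm_model(d, cm, check_identifiability = FALSE, name = "single-pi")
}

# one group of size m, every pi_j and pnew_j its own free parameter
# (over-parameterised for small m: suppress the df warning)
fully_free_model <- function(m, n = 10, level = "a") {
  d <- pcm_design(level = level, set_size = m, n = n)
  cm <- dplyr::mutate(
    pcm_slots(d),
    parameter = paste0(kind, step, "_", level),
    constant = NA_real_
  )
  suppressWarnings(
    pcm_model(d, cm, check_identifiability = FALSE, name = "fully-free")
  )
}

# binomial in MPT clothing: m = 2, inertia fixed at 0, free success probability
free_pnew_binomial <- function(n = 10) {
  d <- pcm_design(level = "a", set_size = 2, n = n)
  cm <- dplyr::mutate(
    pcm_slots(d),
    parameter = ifelse(kind == "pnew", "p", NA_character_),
    constant = ifelse(kind == "pi", 0, NA_real_)
  )
  pcm_model(d, cm, check_identifiability = FALSE, name = "binomial")
}

derive_seeds_for_test <- function(seed, n) {
  withr::with_seed(seed, sample.int(2147483646L, n))
}

freq_table <- function(counts, level = "a") {
  tibble::tibble(level = level, set_size = length(counts),
                 position = seq_along(counts), count = as.integer(counts))
}
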