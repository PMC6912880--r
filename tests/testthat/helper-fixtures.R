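# Small in-code fixtures shared across test files.

make_cm <- function(covers, fertility = "fertile", subregion = "MB",
                    survey_year = 1970, label = "old") {
  meta <- data.frame(plot_id = rownames(covers),
                     fertility = rep_len(fertility, nrow(covers)),
                     subregion = rep_len(subregion, nrow(covers)),
                     survey_year = rep_len(survey_year, nrow(covers)),
                     stringsAsFactors = FALSE)
  cover_matrix(covers, meta, label)
}

# a tiny paired survey: same plots, covers supplied for both periods
make_ps <- function(old_covers, new_covers, fertility = "fertile",
                    subregion = "MB", year_old = 1970, year_new = 2014) {
  old <- make_cm(old_covers, fertility, subregion, year_old, "old")
  new <- make_cm(new_covers, fertility, subregion, year_new, "new")
  pair_surveys(old, new)
}

# minimal vascular trait table; csr is a list of c(C, S, R) rows
make_traits <- function(species, csr = NULL, morph = "forbs",
                        vascular = TRUE, csr_class = NA_character_) {
  n <- length(species)
  if (is.null(csr)) csr <- replicate(n, c(100 / 3, 100 / 3, 100 / 3),
                                     simplify = FALSE)
  m <- do.call(rbind, csr)
  vascular <- rep_len(vascular, n)
  trait_table(data.frame(
    species = species,
    C = ifelse(vascular, m[, 1], NA_real_),
    S = ifelse(vascular, m[, 2], NA_real_),
    R = ifelse(vascular, m[, 3], NA_real_),
    morph_group = rep_len(morph, n),
    is_vascular = vascular,
    csr_class = rep_len(csr_class, n),
    stringsAsFactors = FALSE))
}

# long-format community CSV on disk
write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

random_community <- function(n_species, zero_frac = 0.3) {
  x <- stats::rexp(n_species)
  x[stats::runif(n_species) < zero_frac] <- 0
  if (sum(x) == 0) x[1] <- 1
  x
}
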