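#' Community cover matrix for one survey period
#'
#' A `cover_matrix` holds percent covers of species in a set of vegetation
#' plots sampled in a single survey period, together with per-plot site
#' metadata (fertility class, subregion, survey year). Covers are percentages
#' in \[0, 100\] per species; per-plot totals may exceed 100 because
#' vegetation layers overlap.
#'
#' @param covers numeric matrix, plots in rows and species in columns, with
#'   dimnames giving plot and species identifiers.
#' @param site_meta data frame with one row per plot and columns `plot_id`,
#'   `fertility` (`"fertile"` or `"infertile"`), `subregion`, `survey_year`.
#' @param survey_label character tag for the survey period (e.g. `"old"`,
#'   `"new"`).
#'
#' @return An object of class `cover_matrix`: a list with elements
#'   `covers`, `plot_ids`, `species_ids`, `site_meta`, `survey_label`.
#' @export
cover_matrix <- function(covers, site_meta, survey_label = "survey") {
  if (!is.matrix(covers) || !is.numeric(covers))
    stop("`covers` must be a numeric matrix (plots x species)", call. = FALSE)
  if (is.null(rownames(covers)) || is.null(colnames(covers)))
    stop("`covers` must have plot and species dimnames", call. = FALSE)
  if (anyNA(covers))
    stop("cover values must not be missing", call. = FALSE)
  if (any(covers < 0)) {
    bad <- which(covers < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative cover for plot '%s', species '%s'",
                 rownames(covers)[bad[1]], colnames(covers)[bad[2]]),
         call. = FALSE)
  }
  empty <- rowSums(covers) <= 0
  if (any(empty))
    stop(sprintf("empty plot(s) with no positive cover: %s",
                 paste(rownames(covers)[empty], collapse = ", ")),
         call. = FALSE)
  req <- c("plot_id", "fertility", "subregion", "survey_year")
  miss <- setdiff(req, names(site_meta))
  if (length(miss))
    stop("site_meta missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  site_meta <- as.data.frame(site_meta, stringsAsFactors = FALSE)
  if (!setequal(site_meta$plot_id, rownames(covers)) ||
      nrow(site_meta) != nrow(covers))
    stop("site_meta plot_id must match the rows of `covers` exactly",
         call. = FALSE)
  site_meta <- site_meta[match(rownames(covers), site_meta$plot_id), , drop = FALSE]
  rownames(site_meta) <- NULL
  bad_fert <- !site_meta$fertility %in% c("fertile", "infertile")
  if (any(bad_fert))
    stop("fertility must be 'fertile' or 'infertile' (plot ",
         site_meta$plot_id[bad_fert][1], ")", call. = FALSE)
  structure(
    list(covers = covers,
         plot_ids = rownames(covers),
         species_ids = colnames(covers),
         site_meta = site_meta,
         survey_label = survey_label),
    class = "cover_matrix")
}

#' @export
print.cover_matrix <- function(x, ...) {
  cat(sprintf("<cover_matrix '%s'> %d plots x %d species\n",
              x$survey_label, length(x$plot_ids), length(x$species_ids)))
  cat("  fertility:", paste(sprintf("%s=%d", names(table(x$site_meta$fertility)),
                                    table(x$site_meta$fertility)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cover_matrix <- function(x) dim(x$covers)

#' Read a long-format community table
#'
#' Reads a comma-delimited long-format community file with header
#' `plot_id,species,cover,fertility,subregion,survey_year` and returns a
#' validated [cover_matrix()]. Duplicate `(plot_id, species)` rows are an
#' error (resurvey data should arrive taxonomically harmonised; silently
#' summing duplicates would hide harmonisation mistakes).
#'
#' @param path path to a CSV file.
#' @param survey_label character tag for the survey period.
#' @return A [cover_matrix()].
#' @export
read_community <- function(path, survey_label = "survey") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plot_id", "species", "cover", "fertility", "subregion", "survey_year")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("community file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(df$cover) || !is.numeric(df$cover))
    stop("non-numeric or missing cover values in ", path, call. = FALSE)
  neg <- which(df$cover < 0)
  if (length(neg))
    stop(sprintf("negative cover in %s at row %d (plot '%s', species '%s')",
                 path, neg[1], df$plot_id[neg[1]], df$species[neg[1]]),
         call. = FALSE)
  key <- paste(df$plot_id, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (plot, species) entry: ('%s', '%s')",
                 d$plot_id, d$species), call. = FALSE)
  }
  plots <- unique(df$plot_id)
  species <- sort(unique(df$species))
  covers <- matrix(0, length(plots), length(species),
                   dimnames = list(plots, species))
  covers[cbind(match(df$plot_id, plots), match(df$species, species))] <- df$cover
  meta <- unique(df[, c("plot_id", "fertility", "subregion", "survey_year")])
  if (anyDuplicated(meta$plot_id))
    stop("inconsistent metadata within a plot in ", path, call. = FALSE)
  cover_matrix(covers, meta, survey_label)
}

#' Write a cover matrix as a long-format community table
#'
#' Writes every plot x species cell (including zeros) so that
#' `read_community()` reproduces the matrix exactly.
#'
#' @param cm a [cover_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_community <- function(cm, path) {
  stopifnot(inherits(cm, "cover_matrix"))
  idx <- expand.grid(plot = seq_along(cm$plot_ids),
                     sp = seq_along(cm$species_ids))
  meta <- cm$site_meta[idx$plot, ]
  df <- data.frame(plot_id = cm$plot_ids[idx$plot],
                   species = cm$species_ids[idx$sp],
                   cover = cm$covers[cbind(idx$plot, idx$sp)],
                   fertility = meta$fertility,
                   subregion = meta$subregion,
                   survey_year = meta$survey_year,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair an original and a resurveyed cover matrix
#'
#' Aligns two surveys of the same quasi-permanent plots: the species axes are
#' harmonised to their union (zero-filled where a species was absent) and the
#' plots are matched one-to-one via `pairing`. Metadata (fertility,
#' subregion) must agree within each pair.
#'
#' @param old,new [cover_matrix()] objects for the original survey and the
#'   resurvey.
#' @param pairing named character vector mapping old plot ids (names) to new
#'   plot ids (values). Defaults to identity pairing on shared plot ids.
#' @return An object of class `paired_survey`: list with elements `old`,
#'   `new` (both on the union species axis, new rows ordered to match old)
#'   and `plot_pairs` (data frame `old_plot`, `new_plot`).
#' @export
pair_surveys <- function(old, new, pairing = NULL) {
  stopifnot(inherits(old, "cover_matrix"), inherits(new, "cover_matrix"))
  if (is.null(pairing)) {
    if (!setequal(old$plot_ids, new$plot_ids))
      stop("plot ids differ between surveys; supply an explicit `pairing`",
           call. = FALSE)
    pairing <- stats::setNames(old$plot_ids, old$plot_ids)
  }
  if (!setequal(names(pairing), old$plot_ids))
    stop("pairing must map every old plot exactly once (unmatched: ",
         paste(setdiff(old$plot_ids, names(pairing)), collapse = ", "), ")",
         call. = FALSE)
  if (!setequal(unname(pairing), new$plot_ids) || anyDuplicated(pairing))
    stop("pairing must be a bijection onto the new survey's plots",
         call. = FALSE)
  species <- sort(union(old$species_ids, new$species_ids))
  expand <- function(cm) {
    m <- matrix(0, length(cm$plot_ids), length(species),
                dimnames = list(cm$plot_ids, species))
    m[, cm$species_ids] <- cm$covers
    m
  }
  old_m <- expand(old)
  new_m <- expand(new)[unname(pairing[old$plot_ids]), , drop = FALSE]
  new_meta <- new$site_meta[match(rownames(new_m), new$site_meta$plot_id), ]
  rownames(new_meta) <- NULL
  mism <- old$site_meta$fertility != new_meta$fertility |
    old$site_meta$subregion != new_meta$subregion
  if (any(mism))
    stop("fertility/subregion mismatch within pair(s): ",
         paste(old$plot_ids[mism], collapse = ", "), call. = FALSE)
  structure(
    list(old = cover_matrix(old_m, old$site_meta, old$survey_label),
         new = cover_matrix(new_m, new_meta, new$survey_label),
         plot_pairs = data.frame(old_plot = old$plot_ids,
                                 new_plot = rownames(new_m),
                                 stringsAsFactors = FALSE)),
    class = "paired_survey")
}

#' @export
print.paired_survey <- function(x, ...) {
  cat(sprintf("<paired_survey> %d plot pairs, %d species (union axis)\n",
              nrow(x$plot_pairs), length(x$old$species_ids)))
  invisible(x)
}

#' Years elapsed between the paired surveys, per plot
#'
#' @param ps a [pair_surveys()] result.
#' @return Integer vector, one value per plot pair.
#' @export
sampling_time <- function(ps) {
  stopifnot(inherits(ps, "paired_survey"))
  ps$new$site_meta$survey_year - ps$old$site_meta$survey_year
}
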