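#' Relative abundances from raw covers
#'
#' @param covers non-negative numeric vector of covers for one plot.
#' @return Numeric vector summing to 1.
#' @export
relative_abundance <- function(covers) {
  if (any(covers < 0)) stop("covers must be non-negative", call. = FALSE)
  tot <- sum(covers)
  if (tot <= 0) stop("empty community: all covers are zero", call. = FALSE)
  covers / tot
}

#' Morisita-Horn similarity between two communities
#'
#' Abundance-based similarity
#' \deqn{C_{MH} = \frac{2 \sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}}
#' computed on within-plot relative abundances, so the index is insensitive
#' to plot size and dominated by abundant species. Raw covers are accepted
#' and normalised internally.
#'
#' @param p,q non-negative abundance vectors on the same species axis.
#' @return Similarity in \[0, 1\]: 1 iff the relative abundances are equal,
#'   0 iff the species supports are disjoint.
#' @export
morisita_horn <- function(p, q) {
  if (length(p) != length(q))
    stop("species axes differ in length", call. = FALSE)
  p <- relative_abundance(p)
  q <- relative_abundance(q)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Temporal turnover of each plot pair
#'
#' Turnover of a quasi-permanent plot between surveys is the Morisita-Horn
#' dissimilarity `1 - morisita_horn(old, new)` of its two records, carrying
#' site metadata and the sampling interval through.
#'
#' @param ps a [pair_surveys()] result.
#' @return Data frame with columns `plot_id`, `d` (dissimilarity in
#'   \[0, 1\]), `fertility`, `subregion`, `sampling_time` (years).
#' @export
pairwise_turnover <- function(ps) {
  stopifnot(inherits(ps, "paired_survey"))
  d <- vapply(seq_len(nrow(ps$plot_pairs)), function(i) {
    sim <- tryCatch(
      morisita_horn(ps$old$covers[i, ], ps$new$covers[i, ]),
      error = function(e) stop("plot '", ps$plot_pairs$old_plot[i], "': ",
                               conditionMessage(e), call. = FALSE))
    1 - sim
  }, numeric(1))
  data.frame(plot_id = ps$plot_pairs$old_plot,
             d = pmin(pmax(d, 0), 1),
             fertility = ps$old$site_meta$fertility,
             subregion = ps$old$site_meta$subregion,
             sampling_time = sampling_time(ps),
             stringsAsFactors = FALSE)
}

#' Effective number of species (Hill number of order 2)
#'
#' The inverse Simpson concentration \eqn{D = 1 / \sum_i p_i^2}: the number
#' of equally abundant species that would give the observed Simpson
#' diversity.
#'
#' @param p non-negative abundance vector (normalised internally).
#' @return Effective species number in \[1, S\]; equals the species count S
#'   iff abundances are uniform.
#' @export
hill_simpson <- function(p) {
  p <- relative_abundance(p)
  1 / sum(p^2)
}

#' Per-plot effective species numbers by taxonomic group
#'
#' Computes Hill-Simpson effective species numbers per plot for vascular
#' plants, bryophytes, lichens, and all species pooled. Group membership
#' comes from the trait table; species without trait records are excluded
#' from the group-specific numbers (with one warning per species) but always
#' count towards the total. A group absent from a plot yields `NA`, not zero.
#'
#' @param cm a [cover_matrix()].
#' @param traits a [trait_table()].
#' @return Data frame `plot_id`, `group` (one of `vascular`, `bryophyte`,
#'   `lichen`, `total`), `effective_species`.
#' @export
diversity_by_group <- function(cm, traits) {
  stopifnot(inherits(cm, "cover_matrix"))
  traits <- trait_table(traits)
  sp <- cm$species_ids
  known <- sp %in% traits$species
  if (any(!known))
    warning("species without trait records excluded from group diversity: ",
            paste(sp[!known], collapse = ", "), call. = FALSE)
  tr <- traits[match(sp, traits$species), ]
  members <- list(
    vascular  = known & tr$is_vascular %in% TRUE,
    bryophyte = known & tr$morph_group %in% "bryophytes",
    lichen    = known & tr$morph_group %in% "lichens",
    total     = rep(TRUE, length(sp)))
  out <- lapply(names(members), function(g) {
    D <- vapply(seq_along(cm$plot_ids), function(i) {
      x <- cm$covers[i, members[[g]]]
      if (sum(x) <= 0) NA_real_ else hill_simpson(x)
    }, numeric(1))
    data.frame(plot_id = cm$plot_ids, group = g, effective_species = D,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Multiple-assemblage turnover of a set of plots (order 2)
#'
#' Generalises Morisita-Horn dissimilarity to N assemblages through the
#' gamma/alpha Hill-number decomposition at order q = 2 with equal plot
#' weights: \eqn{D_\gamma} is the Hill-Simpson number of the equal-weight
#' pooled relative abundances, \eqn{D_\alpha = 1 / \mathrm{mean}_j \sum_i
#' p_{ij}^2}, \eqn{D_\beta = D_\gamma / D_\alpha}, the overlap is
#' \eqn{C = (1/D_\beta - 1/N)/(1 - 1/N)} and the turnover is \eqn{1 - C}.
#'
#' @param cm a [cover_matrix()] (or a plain plots x species matrix) holding
#'   the assemblages of one site in one period.
#' @return Turnover in \[0, 1\]: 0 iff all plots share identical relative
#'   abundances, 1 iff all plots are pairwise disjoint.
#' @export
multi_assemblage_turnover <- function(cm) {
  m <- if (inherits(cm, "cover_matrix")) cm$covers else as.matrix(cm)
  n <- nrow(m)
  if (n < 2)
    stop("multiple-assemblage turnover is undefined for fewer than 2 plots",
         call. = FALSE)
  p <- t(apply(m, 1, relative_abundance))
  pooled <- colMeans(p)
  d_gamma <- 1 / sum(pooled^2)
  d_alpha <- 1 / mean(rowSums(p^2))
  d_beta <- d_gamma / d_alpha
  overlap <- (1 / d_beta - 1 / n) / (1 - 1 / n)
  min(max(1 - overlap, 0), 1)
}

#' Bootstrap standard error of multiple-assemblage turnover
#'
#' Plot-level nonparametric bootstrap: plots are resampled with replacement
#' (resamples with fewer than 2 distinct plots are redrawn) and the standard
#' deviation of the turnover over resamples is returned.
#'
#' @param cm a [cover_matrix()] with at least 2 plots.
#' @param reps number of bootstrap resamples (default 2000).
#' @param seed integer RNG seed for reproducibility.
#' @return Bootstrap standard error (numeric scalar).
#' @export
bootstrap_se_beta <- function(cm, reps = 2000, seed = NULL) {
  m <- if (inherits(cm, "cover_matrix")) cm$covers else as.matrix(cm)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 plots", call. = FALSE)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 2) break
    }
    multi_assemblage_turnover(m[idx, , drop = FALSE])
  }, numeric(1))
  stats::sd(vals)
}

#' Within-site beta-diversity change between surveys
#'
#' Computes the multiple-assemblage turnover of a site's plots in the
#' original survey and the resurvey and their difference
#' `delta_beta = beta_new - beta_old`. A positive difference indicates
#' heterogenisation (plots grew more dissimilar), a negative one
#' homogenisation.
#'
#' @param ps a [pair_surveys()] result holding one site's plots, or a
#'   numeric vector of `beta_old` values (with `beta_new` supplied) for
#'   direct arithmetic on precomputed turnover rates.
#' @param ... passed on to methods.
#' @return Data frame with `beta_old`, `se_old`, `beta_new`, `se_new`,
#'   `delta_beta` (SE columns `NA` when betas are supplied directly or
#'   `reps` is `NULL`).
#' @export
beta_change <- function(ps, ...) UseMethod("beta_change")

#' @rdname beta_change
#' @param site label for the site (carried through to the output).
#' @param reps bootstrap replicates for the standard errors; `NULL` skips
#'   the bootstrap.
#' @param seed integer RNG seed for the bootstrap.
#' @export
beta_change.paired_survey <- function(ps, site = NA_character_,
                                      reps = 2000, seed = NULL, ...) {
  if (nrow(ps$plot_pairs) < 2)
    stop("beta-diversity change needs at least 2 plot pairs", call. = FALSE)
  beta_old <- multi_assemblage_turnover(ps$old)
  beta_new <- multi_assemblage_turnover(ps$new)
  se_old <- se_new <- NA_real_
  if (!is.null(reps)) {
    se_old <- bootstrap_se_beta(ps$old, reps = reps,
                                seed = if (is.null(seed)) NULL else seed)
    se_new <- bootstrap_se_beta(ps$new, reps = reps,
                                seed = if (is.null(seed)) NULL else seed + 1L)
  }
  data.frame(site = site, beta_old = beta_old, se_old = se_old,
             beta_new = beta_new, se_new = se_new,
             delta_beta = beta_new - beta_old, stringsAsFactors = FALSE)
}

#' @rdname beta_change
#' @param beta_new turnover rates at the resurvey, matching `ps` (the
#'   `beta_old` rates) element-wise.
#' @export
beta_change.numeric <- function(ps, beta_new, site = NA_character_, ...) {
  beta_old <- ps
  stopifnot(length(beta_old) == length(beta_new),
            all(beta_old >= 0 & beta_old <= 1),
            all(beta_new >= 0 & beta_new <= 1))
  data.frame(site = if (length(site) == length(beta_old)) site else
               rep(site, length(beta_old)),
             beta_old = beta_old, se_old = NA_real_,
             beta_new = beta_new, se_new = NA_real_,
             delta_beta = beta_new - beta_old, stringsAsFactors = FALSE)
}

#' Split a paired survey into per-site paired surveys
#'
#' Sites are the subregion x fertility combinations of the plot metadata.
#'
#' @param ps a [pair_surveys()] result.
#' @return Named list of `paired_survey` objects, one per site, named
#'   `"<subregion>.<fertility>"`.
#' @export
split_sites <- function(ps) {
  stopifnot(inherits(ps, "paired_survey"))
  key <- paste(ps$old$site_meta$subregion, ps$old$site_meta$fertility, sep = ".")
  lapply(split(seq_along(key), key), function(idx) {
    subset_pairs(ps, idx)
  })
}

subset_pairs <- function(ps, idx) {
  sub_cm <- function(cm, idx) {
    cover_matrix(cm$covers[idx, , drop = FALSE],
                 cm$site_meta[idx, , drop = FALSE], cm$survey_label)
  }
  structure(list(old = sub_cm(ps$old, idx), new = sub_cm(ps$new, idx),
                 plot_pairs = ps$plot_pairs[idx, , drop = FALSE]),
            class = "paired_survey")
}
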