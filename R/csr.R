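#' Cover-weighted CSR strategy proportions of one plot
#'
#' Each vascular species carries CSR coordinates (percent competitor,
#' stress-tolerator, ruderal summing to 100). The plot-level profile weights
#' each species' coordinates by its percent cover and divides by the summed
#' cover of the contributing species, yielding relative strategy-class
#' proportions that again sum to 100.
#'
#' By default only vascular species with strategy data enter both the
#' numerator and the denominator, which keeps the proportions well-defined
#' when cryptogams dominate a plot; `denominator = "total"` divides by the
#' whole-plot cover instead (the remaining share is renormalised away).
#'
#' @param covers named numeric vector of percent covers (names = species).
#' @param traits a [trait_table()].
#' @param denominator `"vascular"` (default) or `"total"`.
#' @param warn warn once per species found in the community but absent from
#'   the trait table.
#' @return Named numeric vector `c(propC, propS, propR)` summing to 100.
#' @export
cwm_csr <- function(covers, traits, denominator = c("vascular", "total"),
                    warn = TRUE) {
  denominator <- match.arg(denominator)
  traits <- trait_table(traits)
  sp <- names(covers)
  if (is.null(sp)) stop("`covers` must be named by species", call. = FALSE)
  idx <- match(sp, traits$species)
  unknown <- is.na(idx) & covers > 0
  if (any(unknown) && warn)
    warning("species without trait records excluded from CSR profile: ",
            paste(sp[unknown], collapse = ", "), call. = FALSE)
  has_csr <- !is.na(idx) & !is.na(traits$C[idx])
  eligible <- has_csr & covers > 0
  if (!any(eligible))
    stop("undefined CSR profile: no vascular species with strategy data and positive cover",
         call. = FALSE)
  w <- covers[eligible]
  num <- c(propC = sum(w * traits$C[idx][eligible]),
           propS = sum(w * traits$S[idx][eligible]),
           propR = sum(w * traits$R[idx][eligible]))
  prop <- num / sum(w)
  if (denominator == "total") {
    # weighted sums over the whole-plot cover; renormalise so the three
    # classes still describe relative shares among themselves
    prop_tot <- num / sum(covers)
    prop <- 100 * prop_tot / sum(prop_tot)
  }
  prop
}

#' Logit transform of a proportion with boundary clamping
#'
#' `log(x'/(1 - x'))` with `x' = min(max(x, epsilon), 1 - epsilon)`, used
#' before Gaussian modelling of proportions so that boundary values do not
#' map to infinities.
#'
#' @param x fraction(s) in \[0, 1\].
#' @param epsilon clamping constant in (0, 0.5); default 0.001.
#' @return Logit value(s); strictly increasing on \[epsilon, 1 - epsilon\].
#' @export
logit_fraction <- function(x, epsilon = 0.001) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("x must lie in [0, 1]", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  xp <- pmin(pmax(x, epsilon), 1 - epsilon)
  log(xp / (1 - xp))
}

#' Inverse logit
#' @param z real value(s).
#' @return `exp(z) / (1 + exp(z))`, computed stably.
#' @export
inv_logit <- function(z) 1 / (1 + exp(-z))

#' CSR strategy profiles for both survey periods
#'
#' Applies [cwm_csr()] to every plot in both periods of a paired survey.
#' Plots with no eligible vascular species are dropped with a warning.
#'
#' @param ps a [pair_surveys()] result.
#' @param traits a [trait_table()].
#' @param epsilon logit clamping constant (see [logit_fraction()]).
#' @param denominator passed to [cwm_csr()].
#' @return Data frame with `plot_id`, `period` (`"old"`/`"new"`),
#'   `fertility`, `subregion`, `propC`, `propS`, `propR`, `logitC`,
#'   `logitS`.
#' @export
strategy_profiles <- function(ps, traits, epsilon = 0.001,
                              denominator = "vascular") {
  stopifnot(inherits(ps, "paired_survey"))
  traits <- trait_table(traits)
  one_period <- function(cm, period) {
    rows <- lapply(seq_along(cm$plot_ids), function(i) {
      prof <- tryCatch(
        cwm_csr(cm$covers[i, ], traits, denominator = denominator,
                warn = FALSE),
        error = function(e) NULL)
      if (is.null(prof)) return(NULL)
      data.frame(plot_id = cm$plot_ids[i], period = period,
                 fertility = cm$site_meta$fertility[i],
                 subregion = cm$site_meta$subregion[i],
                 propC = prof[["propC"]], propS = prof[["propS"]],
                 propR = prof[["propR"]],
                 logitC = logit_fraction(prof[["propC"]] / 100, epsilon),
                 logitS = logit_fraction(prof[["propS"]] / 100, epsilon),
                 stringsAsFactors = FALSE)
    })
    dropped <- vapply(rows, is.null, logical(1))
    if (any(dropped))
      warning("plots without CSR-eligible species dropped (", period, "): ",
              paste(cm$plot_ids[dropped], collapse = ", "), call. = FALSE)
    do.call(rbind, rows[!dropped])
  }
  out <- rbind(one_period(ps$old, "old"), one_period(ps$new, "new"))
  rownames(out) <- NULL
  out
}

#' Mean absolute cover change of plant groups with bootstrap CIs
#'
#' For each group (morphological plant group, or specified CSR strategy
#' class), computes the mean over plots of the change in summed percent
#' cover between surveys, with a percentile 95% confidence interval from a
#' plot-level nonparametric bootstrap.
#'
#' @param ps a [pair_surveys()] result (typically one site's plots).
#' @param traits a [trait_table()]; for `grouping = "csr"` it must carry a
#'   `csr_class` column.
#' @param grouping `"morphological"` or `"csr"`.
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return Data frame with `group`, `mean_change` (percent-cover units),
#'   `ci_low`, `ci_high`, `present` (FALSE when the group occurs in neither
#'   period).
#' @export
group_cover_change <- function(ps, traits, grouping = c("morphological", "csr"),
                               reps = 2000, seed = NULL, conf = 0.95) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(ps, "paired_survey"))
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  traits <- trait_table(traits)
  sp <- ps$old$species_ids
  if (grouping == "morphological") {
    lab <- traits$morph_group[match(sp, traits$species)]
    levels_all <- c("shrubs", "dwarf shrubs", "forbs", "graminoids",
                    "pteridophytes", "bryophytes", "lichens")
  } else {
    if (!"csr_class" %in% names(traits))
      stop("trait table has no `csr_class` column", call. = FALSE)
    lab <- traits$csr_class[match(sp, traits$species)]
    levels_all <- c("C", "CR", "R", "SR", "S", "CS", "CSR")
  }
  # per-plot summed cover of each group, in each period
  group_tot <- function(m) {
    vapply(levels_all, function(g) {
      cols <- which(lab %in% g)
      if (!length(cols)) rep(0, nrow(m)) else rowSums(m[, cols, drop = FALSE])
    }, numeric(nrow(ps$old$covers)))
  }
  old_t <- matrix(group_tot(ps$old$covers), ncol = length(levels_all),
                  dimnames = list(NULL, levels_all))
  new_t <- matrix(group_tot(ps$new$covers), ncol = length(levels_all),
                  dimnames = list(NULL, levels_all))
  change <- new_t - old_t
  n <- nrow(change)
  if (!is.null(seed)) set.seed(seed)
  boot_means <- matrix(NA_real_, reps, length(levels_all))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_means[r, ] <- colMeans(change[idx, , drop = FALSE])
  }
  alpha <- (1 - conf) / 2
  present <- colSums(old_t) > 0 | colSums(new_t) > 0
  ci <- apply(boot_means, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  # degenerate cases: a single plot, or a single replicate, collapse the
  # interval onto the point estimate
  if (n == 1 || reps == 1) ci <- rbind(colMeans(change), colMeans(change))
  data.frame(group = levels_all,
             mean_change = colMeans(change),
             ci_low = ci[1, ], ci_high = ci[2, ],
             present = present,
             row.names = NULL, stringsAsFactors = FALSE)
}
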