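#' Analysis configuration
#'
#' Collects file paths, bootstrap and MCMC settings, the RNG seed and
#' numeric options for a full pipeline run.
#'
#' @param community_old,community_new,traits,climate,site_years input CSV
#'   paths (see [read_community()], [read_traits()], [read_climate()];
#'   `site_years` has columns `site,year0,year1`). Leave `NULL` with
#'   `simulate = TRUE` to run on a synthetic bundle instead.
#' @param simulate generate the inputs with [simulate_resurvey()] instead of
#'   reading files.
#' @param truth [simulation_truth()] used when `simulate = TRUE` (its seed
#'   is overridden by `rng_seed`).
#' @param out_dir directory for the output tables; `NULL` skips writing.
#' @param bootstrap_reps bootstrap replicates for standard errors and CIs
#'   (default 2000).
#' @param chains,draws,warmup MCMC settings (defaults 4 chains x 1000
#'   post-warmup draws, 1000 warmup).
#' @param rng_seed integer master seed; every stochastic stage derives its
#'   seed from it, so identical config + inputs give identical outputs.
#' @param logit_epsilon clamping constant for [logit_fraction()].
#' @param gdd_base,gdd_window,gdd_mode growing-season and thermal-sum
#'   settings (see [growing_season()] and [thermal_sum()]).
#' @param csr_denominator passed to [cwm_csr()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(community_old = NULL, community_new = NULL,
                            traits = NULL, climate = NULL, site_years = NULL,
                            simulate = is.null(community_old),
                            truth = simulation_truth(),
                            out_dir = NULL,
                            bootstrap_reps = 2000,
                            chains = 4, draws = 1000, warmup = 1000,
                            rng_seed = 1,
                            logit_epsilon = 0.001,
                            gdd_base = 5, gdd_window = 10,
                            gdd_mode = "excess",
                            csr_denominator = "vascular") {
  stopifnot(bootstrap_reps >= 1, chains >= 1, draws >= 1,
            logit_epsilon > 0, logit_epsilon < 0.5)
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [analysis_config()]; unknown
#' keys are an error.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(analysis_config, cfg)
}

#' Fit the per-group diversity models
#'
#' Normal-error Bayesian regressions on `log(x + 1)`-transformed effective
#' species numbers, one per group: total, vascular and bryophyte diversity
#' get time, fertility and their interaction as fixed effects; lichen
#' diversity (absent from fertile sites) gets time only. Plot identity is a
#' random intercept everywhere.
#'
#' @param div data frame with columns `plot_id`, `period` (factor with
#'   levels `old`, `new`), `fertility`, `group`, `effective_species`
#'   (e.g. stacked [diversity_by_group()] results for both periods).
#' @param chains,draws,warmup,seed MCMC settings as in [bayes_lm()].
#' @return Named list of [bayes_lm()] fits (groups with fewer than 2 plots
#'   of data are skipped with a warning).
#' @export
fit_diversity_models <- function(div, chains = 4, draws = 1000,
                                 warmup = 1000, seed = 1) {
  div <- div[!is.na(div$effective_species), , drop = FALSE]
  if (any(div$effective_species < 1))
    stop("effective species numbers below 1", call. = FALSE)
  div$period <- factor(div$period, c("old", "new"))
  div$fertility <- factor(div$fertility, c("fertile", "infertile"))
  div$log_div <- log1p(div$effective_species)
  fits <- list()
  for (g in unique(div$group)) {
    dg <- div[div$group == g, , drop = FALSE]
    if (length(unique(dg$plot_id)) < 2) {
      warning("group '", g, "' has fewer than 2 plots; skipped", call. = FALSE)
      next
    }
    form <- if (length(unique(dg$fertility)) > 1)
      log_div ~ period * fertility else log_div ~ period
    fits[[g]] <- bayes_lm(form, dg, random = ~ plot_id, chains = chains,
                          draws = draws, warmup = warmup, seed = seed)
  }
  fits
}

log_stage <- function(stage, detail, t0) {
  message(sprintf("[resurvey] %-16s %s (%.2fs)", stage, detail,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

run_stage <- function(stage, detail_fn, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  log_stage(stage, detail_fn(res), t0)
  res
}

#' Run the full resurvey analysis pipeline
#'
#' Orchestrates every stage: data loading (or synthetic generation),
#' per-plot turnover, per-site beta diversity with bootstrap SEs, CSR
#' strategy profiles and group cover changes, per-group effective species
#' numbers, climate trend deltas, and the Bayesian model layer (turnover
#' model set ranked by PSIS-LOO, bivariate CSR model, diversity models).
#' With `out_dir` set, writes `turnover.csv`, `site_beta.csv`,
#' `csr_profiles.csv`, `group_changes.csv`, `diversity.csv`,
#' `climate_deltas.csv`, `posterior_summary.csv`, `loo_compare.csv` and a
#' JSON run manifest. Identical inputs and config (including
#' `rng_seed`) produce byte-identical outputs.
#'
#' @param config an [analysis_config()].
#' @return (Invisibly) a list with every stage result: `turnover`,
#'   `site_beta`, `csr_profiles`, `group_changes`, `diversity`,
#'   `climate_deltas`, `turnover_fits`, `loo_compare`, `csr_fit`,
#'   `diversity_fits`, `bayes_r2`, `manifest`.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- as.integer(config$rng_seed)

  inputs <- run_stage("load", function(r)
    sprintf("%d plot pairs, %d species, %d climate rows",
            nrow(r$ps$plot_pairs), length(r$ps$old$species_ids),
            nrow(r$climate)), {
    if (config$simulate) {
      truth <- config$truth
      truth$seed <- seed
      sim <- simulate_resurvey(truth)
      list(ps = sim$paired_survey, traits = sim$traits,
           climate = sim$climate, site_years = sim$site_years,
           truth_manifest = sim$manifest)
    } else {
      old <- read_community(config$community_old, "old")
      new <- read_community(config$community_new, "new")
      list(ps = pair_surveys(old, new),
           traits = read_traits(config$traits),
           climate = read_climate(config$climate),
           site_years = utils::read.csv(config$site_years,
                                        stringsAsFactors = FALSE),
           truth_manifest = NULL)
    }
  })
  ps <- inputs$ps

  turnover <- run_stage("turnover", function(r)
    sprintf("%d plots, mean d = %.3f", nrow(r), mean(r$d)),
    pairwise_turnover(ps))

  sites <- split_sites(ps)
  site_beta <- run_stage("site_beta", function(r)
    sprintf("%d sites, reps = %d", nrow(r), config$bootstrap_reps), {
    reps_beta <- if (config$bootstrap_reps >= 2) config$bootstrap_reps else NULL
    rows <- lapply(seq_along(sites), function(i)
      beta_change(sites[[i]], site = names(sites)[i],
                  reps = reps_beta, seed = seed + 100L + 2L * i))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  csr_profiles <- run_stage("csr_profiles", function(r)
    sprintf("%d plot x period profiles", nrow(r)),
    strategy_profiles(ps, inputs$traits, epsilon = config$logit_epsilon,
                      denominator = config$csr_denominator))

  group_changes <- run_stage("group_changes", function(r)
    sprintf("%d site x group rows", nrow(r)), {
    rows <- list()
    for (i in seq_along(sites)) {
      for (gr in c("morphological", "csr")) {
        gc <- group_cover_change(sites[[i]], inputs$traits, grouping = gr,
                                 reps = config$bootstrap_reps,
                                 seed = seed + 200L + 10L * i +
                                   (gr == "csr"))
        gc <- cbind(site = names(sites)[i], grouping = gr, gc)
        rows[[length(rows) + 1L]] <- gc
      }
    }
    do.call(rbind, rows)
  })

  diversity <- run_stage("diversity", function(r)
    sprintf("%d plot x group rows", nrow(r)), {
    d_old <- cbind(period = "old", diversity_by_group(ps$old, inputs$traits))
    d_new <- cbind(period = "new", diversity_by_group(ps$new, inputs$traits))
    d <- rbind(d_old, d_new)
    d$fertility <- ps$old$site_meta$fertility[
      match(d$plot_id, ps$old$site_meta$plot_id)]
    d
  })

  clim_deltas <- run_stage("climate", function(r)
    sprintf("%d sites, mean dGDD = %.1f", nrow(r), mean(r$delta_gdd)),
    climate_deltas(inputs$climate, inputs$site_years,
                   base = config$gdd_base, window = config$gdd_window,
                   mode = config$gdd_mode))

  fits <- run_stage("turnover_models", function(r)
    sprintf("%d candidate models", length(r)), {
    td <- turnover
    td$fertility <- factor(td$fertility, c("fertile", "infertile"))
    mcmc <- list(chains = config$chains, draws = config$draws,
                 warmup = config$warmup)
    list(
      fertility = bayes_lm(d ~ fertility, td, chains = mcmc$chains,
                           draws = mcmc$draws, warmup = mcmc$warmup,
                           seed = seed + 300L),
      fertility_time = bayes_lm(d ~ fertility + sampling_time, td,
                                chains = mcmc$chains, draws = mcmc$draws,
                                warmup = mcmc$warmup, seed = seed + 310L),
      fertility_time2 = bayes_lm(d ~ fertility + poly(sampling_time, 2), td,
                                 chains = mcmc$chains, draws = mcmc$draws,
                                 warmup = mcmc$warmup, seed = seed + 320L),
      fertility_x_time = bayes_lm(d ~ fertility * sampling_time, td,
                                  chains = mcmc$chains, draws = mcmc$draws,
                                  warmup = mcmc$warmup, seed = seed + 330L))
  })

  loo_cmp <- run_stage("loo_compare", function(r)
    sprintf("best: %s", r$model[1]),
    compare_models(lapply(fits, psis_loo)))

  r2 <- bayes_r2(fits$fertility)

  csr_fit <- run_stage("csr_model", function(r)
    sprintf("%d rows", nrow(r$Y)), {
    pr <- csr_profiles
    pr$period <- factor(pr$period, c("old", "new"))
    pr$fertility <- factor(pr$fertility, c("fertile", "infertile"))
    bayes_mv_lm(cbind(logitC, logitS) ~ period * fertility, pr,
                random = ~ plot_id, chains = config$chains,
                draws = config$draws, warmup = config$warmup,
                seed = seed + 400L)
  })

  div_fits <- run_stage("diversity_models", function(r)
    sprintf("%d groups fitted", length(r)),
    fit_diversity_models(diversity, chains = config$chains,
                         draws = config$draws, warmup = config$warmup,
                         seed = seed + 500L))

  fert_sum <- summary(fits$fertility)
  fert_row <- fert_sum[fert_sum$parameter == "fertilityinfertile", ]
  manifest <- list(
    rng_seed = seed,
    settings = list(bootstrap_reps = config$bootstrap_reps,
                    chains = config$chains, draws = config$draws,
                    warmup = config$warmup,
                    logit_epsilon = config$logit_epsilon,
                    gdd = list(base = config$gdd_base,
                               window = config$gdd_window,
                               mode = config$gdd_mode)),
    n_plots = nrow(ps$plot_pairs),
    fertility_effect = list(mean = fert_row$mean,
                            ci_low = fert_row[[4]],
                            ci_high = fert_row[[5]]),
    bayes_r2_median = stats::median(r2),
    best_turnover_model = loo_cmp$model[1],
    truth = inputs$truth_manifest)

  result <- list(turnover = turnover, site_beta = site_beta,
                 csr_profiles = csr_profiles, group_changes = group_changes,
                 diversity = diversity, climate_deltas = clim_deltas,
                 turnover_fits = fits, loo_compare = loo_cmp,
                 csr_fit = csr_fit, diversity_fits = div_fits,
                 bayes_r2 = r2, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(config$out_dir, name),
                       row.names = FALSE)
    wr(turnover, "turnover.csv")
    wr(site_beta, "site_beta.csv")
    wr(csr_profiles, "csr_profiles.csv")
    wr(group_changes, "group_changes.csv")
    wr(diversity, "diversity.csv")
    wr(clim_deltas, "climate_deltas.csv")
    post <- do.call(rbind, c(
      lapply(names(fits), function(nm)
        cbind(model = paste0("turnover_", nm), summary(fits[[nm]]))),
      list(cbind(model = "csr_mv", summary(csr_fit))),
      lapply(names(div_fits), function(nm)
        cbind(model = paste0("diversity_", nm), summary(div_fits[[nm]])))))
    wr(post, "posterior_summary.csv")
    wr(loo_cmp, "loo_compare.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
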