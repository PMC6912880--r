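# Synthetic paired-survey generator with known ground truth.
#
# The generator emulates the study design of a boreal resurvey: four
# subregions, each with one fertile (herb-rich) and one infertile (heath)
# site of ~8-11 quasi-permanent plots, resurveyed 33-57 years after the
# original survey. Fertile communities are built from a guild of
# competitor/ruderal-leaning vascular species, infertile ones from
# stress-tolerator-leaning species plus bryophytes and lichens. Temporal
# turnover is induced by mixing each plot towards an independent community
# draw, with the mixing weight calibrated per fertility class so the
# realised mean Morisita-Horn dissimilarity hits the class target.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Ground-truth settings for the synthetic resurvey generator
#'
#' @param turnover_mean_fertile,turnover_mean_infertile target mean plot
#'   turnover (Morisita-Horn dissimilarity) per fertility class, in (0, 1).
#' @param csr_time_effects list with elements `fertile` and `infertile`,
#'   each a vector `c(C =, S =)` of species-weight tilts applied to the
#'   resurvey target communities (negative C shifts cover away from
#'   competitors).
#' @param evenness_shift named multiplier (`fertile`, `infertile`) on the
#'   Dirichlet concentration of the resurvey draws; values > 1 make
#'   resurveyed communities more even (higher effective diversity).
#' @param n_vascular,n_bryophyte,n_lichen species pool sizes per guild
#'   (lichens only occur in the infertile guild).
#' @param plots_fertile,plots_infertile plots per subregion.
#' @param subregions subregion labels, south to north.
#' @param sampling_time_fertile,sampling_time_infertile years between the
#'   surveys per subregion.
#' @param resurvey_year calendar year of the resurvey.
#' @param turnover_dispersion Beta precision of the per-plot turnover
#'   targets around the class mean; smaller values spread plot turnovers
#'   more widely (default 8, giving a within-class SD of roughly 0.12-0.16).
#' @param concentration Dirichlet concentration of plot draws around the
#'   site mean community; lower values give more heterogeneous plots.
#' @param dominance_sd standard deviation of the log-normal species weights
#'   that shape the site mean community (larger = fewer dominants, more
#'   rare species).
#' @param replacement_rate fraction of resurvey target weight moved onto
#'   species absent from the site's original pool (species-swap turnover on
#'   top of abundance mixing).
#' @param climate list of climate-generator settings: `base_temp` (named
#'   per subregion, deg C), `amplitude` (seasonal half-range, deg C),
#'   `warming_slope` (deg C / yr), `noise_sd` (deg C), `prec_mean` (mm/day),
#'   `prec_shape` (gamma shape), `prec_slope` (mm/day/yr).
#' @param seed integer RNG seed recorded in every manifest.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(turnover_mean_fertile = 0.35,
                             turnover_mean_infertile = 0.15,
                             csr_time_effects = list(
                               fertile = c(C = -2, S = 2),
                               infertile = c(C = 0, S = 0)),
                             evenness_shift = c(fertile = 1, infertile = 1),
                             n_vascular = c(fertile = 60, infertile = 40),
                             n_bryophyte = c(fertile = 20, infertile = 15),
                             n_lichen = c(fertile = 0, infertile = 15),
                             plots_fertile = c(MB = 8, NBs = 10, NBm = 10, NBn = 10),
                             plots_infertile = c(MB = 9, NBs = 10, NBm = 10, NBn = 11),
                             subregions = c("MB", "NBs", "NBm", "NBn"),
                             sampling_time_fertile = c(MB = 44, NBs = 42, NBm = 39, NBn = 55),
                             sampling_time_infertile = c(MB = 33, NBs = 34, NBm = 34, NBn = 55),
                             resurvey_year = 2014,
                             turnover_dispersion = 8,
                             concentration = 30,
                             dominance_sd = 1.6,
                             replacement_rate = 0,
                             climate = list(
                               base_temp = c(MB = 2.5, NBs = 1.2, NBm = 0.0, NBn = -1.0),
                               amplitude = 12, warming_slope = 0.03,
                               noise_sd = 2, prec_mean = 1.6,
                               prec_shape = 0.6, prec_slope = 0.005),
                             seed = 1) {
  stopifnot(turnover_mean_fertile > 0, turnover_mean_fertile < 1,
            turnover_mean_infertile > 0, turnover_mean_infertile < 1,
            all(plots_fertile >= 2), all(plots_infertile >= 2))
  structure(as.list(environment()), class = "simulation_truth")
}

#' Generate a species trait table for the synthetic guilds
#'
#' Vascular CSR coordinates are Dirichlet draws with guild-specific
#' concentration: the fertile guild skews towards competitor/ruderal
#' strategies, the infertile guild towards stress-tolerators. Coordinates
#' are rounded so C + S + R = 100 exactly; the specified discrete class is
#' the nearest of the seven class centroids.
#'
#' @param truth a [simulation_truth()].
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return A [trait_table()] with a `guild` attribute mapping species to
#'   their fertility guild.
#' @export
gen_traits <- function(truth = simulation_truth(), seed = truth$seed) {
  set.seed(seed)
  centroids <- rbind(C = c(100, 0, 0), CR = c(50, 0, 50), R = c(0, 0, 100),
                     SR = c(0, 50, 50), S = c(0, 100, 0), CS = c(50, 50, 0),
                     CSR = c(100, 100, 100) / 3)
  alpha_guild <- list(fertile = c(C = 4, S = 1.5, R = 3),
                      infertile = c(C = 1, S = 6, R = 1.5))
  morph_prob <- list(
    fertile = c(shrubs = .06, `dwarf shrubs` = .04, forbs = .5,
                graminoids = .25, pteridophytes = .15),
    infertile = c(shrubs = .04, `dwarf shrubs` = .45, forbs = .15,
                  graminoids = .3, pteridophytes = .06))
  rows <- list(); guild_of <- character(0); k <- 0
  for (g in c("fertile", "infertile")) {
    nv <- truth$n_vascular[[g]]; nb <- truth$n_bryophyte[[g]]
    nl <- truth$n_lichen[[g]]
    for (i in seq_len(nv)) {
      k <- k + 1
      csr <- 100 * rdirichlet1(alpha_guild[[g]])
      csr <- round(csr, 6); csr[3] <- 100 - csr[1] - csr[2]
      cls <- rownames(centroids)[which.min(colSums((t(centroids) - csr)^2))]
      rows[[k]] <- data.frame(
        species = sprintf("sp%03d", k), C = csr[1], S = csr[2], R = csr[3],
        morph_group = sample(names(morph_prob[[g]]), 1,
                             prob = morph_prob[[g]]),
        is_vascular = TRUE, csr_class = cls, stringsAsFactors = FALSE)
      guild_of[k] <- g
    }
    for (i in seq_len(nb + nl)) {
      k <- k + 1
      rows[[k]] <- data.frame(
        species = sprintf("sp%03d", k), C = NA_real_, S = NA_real_,
        R = NA_real_, morph_group = if (i <= nb) "bryophytes" else "lichens",
        is_vascular = FALSE, csr_class = NA_character_,
        stringsAsFactors = FALSE)
      guild_of[k] <- g
    }
  }
  tr <- trait_table(do.call(rbind, rows))
  attr(tr, "guild") <- stats::setNames(guild_of, tr$species)
  tr
}

# Morisita-Horn dissimilarity of one plot mixed with weight w
mixing_dissim <- function(p, q, w) 1 - morisita_horn(p, (1 - w) * p + w * q)

# per-plot bisection of the mixing weight against the Morisita-Horn formula
calibrate_mixing <- function(p, q, target, tol = 1e-6) {
  if (target <= 0) return(0)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mixing_dissim(p, q, mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a paired synthetic survey
#'
#' Old-plot relative abundances are Dirichlet draws around a site mean
#' community shaped by log-normal species weights (few dominants, many rare
#' species). Resurvey abundances mix each plot towards an independent draw
#' from a resurvey target community (strategy-tilted for the resurvey CSR
#' effects); the mixing weight is calibrated per fertility class by
#' bisection against the Morisita-Horn formula so the realised class mean
#' turnover hits the targets.
#'
#' @param truth a [simulation_truth()].
#' @param traits optional [gen_traits()] table (regenerated from `truth`
#'   when missing).
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return A list with `paired_survey`, `traits`, and `manifest` (realised
#'   mixing weights and class mean turnovers plus the seed).
#' @export
gen_paired_survey <- function(truth = simulation_truth(), traits = NULL,
                              seed = truth$seed) {
  if (is.null(traits)) traits <- gen_traits(truth, seed = seed)
  set.seed(seed + 1000L)
  guild <- attr(traits, "guild")
  species_all <- traits$species
  P_class <- list(fertile = list(), infertile = list())
  Q_class <- list(fertile = list(), infertile = list())
  meta_class <- list(fertile = list(), infertile = list())
  for (sr in truth$subregions) {
    for (g in c("fertile", "infertile")) {
      n_plots <- if (g == "fertile") truth$plots_fertile[[sr]] else
        truth$plots_infertile[[sr]]
      pool <- species_all[guild == g]
      idx <- match(pool, species_all)
      # site mean community: log-normal dominance weights
      w_old <- exp(stats::rnorm(length(pool), 0, truth$dominance_sd))
      m_old <- w_old / sum(w_old)
      # resurvey target community: fresh dominance weights, strategy tilt
      eff <- truth$csr_time_effects[[g]]
      tilt <- exp(ifelse(is.na(traits$C[idx]), 0,
                         eff[["C"]] * traits$C[idx] / 100 +
                           eff[["S"]] * traits$S[idx] / 100))
      w_new <- exp(stats::rnorm(length(pool), 0, truth$dominance_sd)) * tilt
      if (truth$replacement_rate > 0) {
        swap <- stats::runif(length(pool)) < truth$replacement_rate
        w_new[swap] <- 0
      }
      m_new <- w_new / sum(w_new)
      conc_new <- truth$concentration * truth$evenness_shift[[g]]
      for (j in seq_len(n_plots)) {
        p_full <- q_full <- stats::setNames(numeric(length(species_all)),
                                            species_all)
        p_full[idx] <- rdirichlet1(truth$concentration * m_old +
                                     1e-8)
        q_full[idx] <- rdirichlet1(conc_new * m_new + 1e-8)
        P_class[[g]] <- c(P_class[[g]], list(p_full))
        Q_class[[g]] <- c(Q_class[[g]], list(q_full))
        st <- if (g == "fertile") truth$sampling_time_fertile[[sr]] else
          truth$sampling_time_infertile[[sr]]
        meta_class[[g]] <- c(meta_class[[g]], list(data.frame(
          subregion = sr, fertility = g, sampling_time = st,
          stringsAsFactors = FALSE)))
      }
    }
  }
  targets <- c(fertile = truth$turnover_mean_fertile,
               infertile = truth$turnover_mean_infertile)
  w_mix <- realized <- list(fertile = NA_real_, infertile = NA_real_)
  rows_old <- list(); rows_new <- list(); meta <- list(); pid <- 0
  for (g in c("fertile", "infertile")) {
    mu <- targets[[g]]
    phi <- truth$turnover_dispersion
    dmax <- vapply(seq_along(P_class[[g]]), function(j)
      mixing_dissim(P_class[[g]][[j]], Q_class[[g]][[j]], 1), numeric(1))
    if (mean(dmax) < mu)
      stop(sprintf(
        "unattainable turnover target %.3f for %s plots (maximum attainable mean %.3f); raise dominance_sd or replacement_rate",
        mu, g, mean(dmax)), call. = FALSE)
    # per-plot turnover targets around the class mean; clamping to each
    # plot's attainable range keeps the realised class mean close to target
    d_j <- stats::rbeta(length(dmax), mu * phi, (1 - mu) * phi)
    d_j <- pmin(pmax(d_j, 0.002), 0.98 * dmax)
    w_j <- vapply(seq_along(d_j), function(j)
      calibrate_mixing(P_class[[g]][[j]], Q_class[[g]][[j]], d_j[j]),
      numeric(1))
    realized[[g]] <- mean(vapply(seq_along(d_j), function(j)
      mixing_dissim(P_class[[g]][[j]], Q_class[[g]][[j]], w_j[j]),
      numeric(1)))
    w_mix[[g]] <- mean(w_j)
    for (j in seq_along(P_class[[g]])) {
      pid <- pid + 1
      p <- P_class[[g]][[j]]
      q <- (1 - w_j[j]) * p + w_j[j] * Q_class[[g]][[j]]
      tot_old <- stats::runif(1, 60, 140)
      tot_new <- stats::runif(1, 60, 140)
      rows_old[[pid]] <- p * tot_old
      rows_new[[pid]] <- q * tot_new
      m <- meta_class[[g]][[j]]
      meta[[pid]] <- data.frame(
        plot_id = sprintf("p%02d", pid), fertility = m$fertility,
        subregion = m$subregion,
        year_old = truth$resurvey_year - m$sampling_time,
        year_new = truth$resurvey_year, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  old_m <- do.call(rbind, rows_old)
  new_m <- do.call(rbind, rows_new)
  rownames(old_m) <- rownames(new_m) <- meta$plot_id
  mk_meta <- function(yr_col) data.frame(
    plot_id = meta$plot_id, fertility = meta$fertility,
    subregion = meta$subregion, survey_year = meta[[yr_col]],
    stringsAsFactors = FALSE)
  ps <- pair_surveys(cover_matrix(old_m, mk_meta("year_old"), "old"),
                     cover_matrix(new_m, mk_meta("year_new"), "new"))
  list(paired_survey = ps, traits = traits,
       manifest = list(seed = seed,
                       mean_mixing_weight = w_mix,
                       realized_mean_turnover = realized,
                       targets = as.list(targets)))
}

#' Generate a daily climate series for one site
#'
#' Daily mean temperature is a seasonal sine cycle plus a linear warming
#' trend and Gaussian noise; daily precipitation is gamma-distributed with
#' a slow linear trend in its mean. The series is gap-free over whole
#' calendar years.
#'
#' @param truth a [simulation_truth()].
#' @param site site label (used to pick the subregion base temperature:
#'   labels look like `"MB.fertile"`).
#' @param year0,year1 first and last calendar year (inclusive).
#' @param seed RNG seed.
#' @return Data frame `site`, `date`, `tmean_c`, `prec_mm`.
#' @export
gen_climate <- function(truth, site, year0, year1, seed = truth$seed) {
  set.seed(seed)
  if (year1 - year0 < 2) stop("need at least 3 years", call. = FALSE)
  sr <- strsplit(site, ".", fixed = TRUE)[[1]][1]
  cl <- truth$climate
  base <- if (sr %in% names(cl$base_temp)) cl$base_temp[[sr]] else
    mean(unlist(cl$base_temp))
  dates <- seq(as.Date(sprintf("%d-01-01", year0)),
               as.Date(sprintf("%d-12-31", year1)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr_frac <- as.integer(format(dates, "%Y")) - year0 + doy / 366
  tmean <- base + cl$amplitude * sin(2 * pi * (doy - 110) / 365.25) +
    cl$warming_slope * yr_frac + stats::rnorm(length(dates), 0, cl$noise_sd)
  prec_mu <- pmax(cl$prec_mean + cl$prec_slope * yr_frac, 0.05)
  prec <- stats::rgamma(length(dates), shape = cl$prec_shape,
                        rate = cl$prec_shape / prec_mu)
  data.frame(site = site, date = dates, tmean_c = tmean, prec_mm = prec,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic study bundle
#'
#' Traits, paired community surveys for all sites, and per-site daily
#' climate spanning each site's survey interval.
#'
#' @param truth a [simulation_truth()].
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return List with `paired_survey`, `traits`, `climate` (multi-site data
#'   frame), `site_years` (site, year0, year1), `manifest`.
#' @export
simulate_resurvey <- function(truth = simulation_truth(), seed = truth$seed) {
  sim <- gen_paired_survey(truth, seed = seed)
  meta <- sim$paired_survey$old$site_meta
  meta_new <- sim$paired_survey$new$site_meta
  site <- paste(meta$subregion, meta$fertility, sep = ".")
  site_years <- unique(data.frame(site = site, year0 = meta$survey_year,
                                  year1 = meta_new$survey_year,
                                  stringsAsFactors = FALSE))
  clim <- do.call(rbind, lapply(seq_len(nrow(site_years)), function(i)
    gen_climate(truth, site_years$site[i], site_years$year0[i],
                site_years$year1[i], seed = seed + 2000L + i)))
  c(sim, list(climate = clim, site_years = site_years))
}

#' Write a simulated bundle to CSV files plus a truth manifest
#'
#' @param sim a [simulate_resurvey()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `community_old.csv`,
#'   `community_new.csv`, `traits.csv`, `climate.csv`, `site_years.csv`,
#'   `truth_manifest.json`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_community(sim$paired_survey$old, file.path(dir, "community_old.csv"))
  write_community(sim$paired_survey$new, file.path(dir, "community_new.csv"))
  write_traits(sim$traits, file.path(dir, "traits.csv"))
  utils::write.csv(sim$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$site_years, file.path(dir, "site_years.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
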