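test_that("noiseless linear data is recovered tightly", {
  set.seed(2)
  d <- data.frame(x = seq(-2, 2, length.out = 40))
  d$y <- 1.5 - 0.7 * d$x + rnorm(40, 0, 0.01)
  fit <- bayes_lm(y ~ x, d, chains = 2, draws = 400, warmup = 400, seed = 4)
  s <- summary(fit)
  slope <- s[s$parameter == "x", ]
  expect_lt(abs(slope$mean - (-0.7)), 3 * slope$sd)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 1.5), 0.02)
  expect_equal(unname(fitted(fit) + residuals(fit)), d$y)
})

test_that("intercept-only posterior matches the conjugate closed form", {
  set.seed(9)
  y <- rnorm(120, 3, 1)
  d <- data.frame(y = y)
  fit <- bayes_lm(y ~ 1, d, chains = 2, draws = 1000, warmup = 500, seed = 2)
  # flat-ish prior, n = 120: posterior mean of the intercept ~ sample mean
  expect_lt(abs(coef(fit)[[1]] - mean(y)), 3 * sd(y) / sqrt(120))
  # closed-form conjugate check with sigma treated as known at the truth:
  # prior N(mean(y), (10 sd(y))^2) => posterior mean shrinks negligibly
  v0 <- (10 * sd(y))^2
  post_mean <- (mean(y) / v0 + sum(y) / 1) / (1 / v0 + 120 / 1)
  expect_lt(abs(coef(fit)[[1]] - post_mean), 0.05)
})

test_that("sampling is deterministic given the seed", {
  set.seed(1)
  d <- data.frame(x = rnorm(30))
  d$y <- d$x + rnorm(30)
  f1 <- bayes_lm(y ~ x, d, chains = 2, draws = 200, warmup = 200, seed = 99)
  f2 <- bayes_lm(y ~ x, d, chains = 2, draws = 200, warmup = 200, seed = 99)
  expect_identical(f1$draws, f2$draws)
  f3 <- bayes_lm(y ~ x, d, chains = 2, draws = 200, warmup = 200, seed = 100)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("with no data the sampler reproduces the prior", {
  d0 <- data.frame(y = numeric(0), x = numeric(0))
  prior <- list(b0 = c(0, 0), v0 = c(4, 1), scale_sigma = 1, scale_tau = 1,
                nu = 3)
  fit <- bayes_lm(y ~ x, d0, chains = 2, draws = 2000, warmup = 200,
                  seed = 12, priors = prior)
  ks1 <- suppressWarnings(
    ks.test(fit$draws[, "(Intercept)"], pnorm, 0, 2)$statistic)
  ks2 <- suppressWarnings(ks.test(fit$draws[, "x"], pnorm, 0, 1)$statistic)
  expect_lt(ks1, 0.1)
  expect_lt(ks2, 0.1)
  # sigma draws follow a half-t(3, 0, 1): compare against its cdf
  pht <- function(q) 2 * pt(q, df = 3) - 1
  ks3 <- suppressWarnings(ks.test(fit$draws[, "sigma"], pht)$statistic)
  expect_lt(ks3, 0.1)
})

test_that("design problems raise explicit errors", {
  d <- data.frame(y = rnorm(10), x = 1:10)
  d$x2 <- 2 * d$x
  expect_error(bayes_lm(y ~ x + x2, d, chains = 1, draws = 10, warmup = 10),
               "rank-deficient")
  expect_error(bayes_mv_lm(cbind(y, x) ~ x2 + I(2 * x2), d, random = ~x,
                           chains = 1, draws = 10, warmup = 10),
               "rank-deficient")
})

test_that("random intercepts shrink towards zero and are recovered", {
  set.seed(14)
  J <- 30
  u <- rnorm(J, 0, 0.8)
  d <- data.frame(g = rep(1:J, each = 4))
  d$y <- 2 + u[d$g] + rnorm(nrow(d), 0, 0.3)
  fit <- suppressWarnings(
    bayes_lm(y ~ 1, d, random = ~ g, chains = 2, draws = 500,
             warmup = 500, seed = 6))
  s <- summary(fit)
  tau <- s[s$parameter == "tau", "mean"]
  expect_gt(tau, 0.5); expect_lt(tau, 1.2)
  u_hat <- colMeans(fit$draws[, paste0("u[", 1:J, "]")])
  expect_gt(cor(u_hat, u), 0.9)
})

test_that("bivariate model recovers a fertile-only negative time effect", {
  set.seed(20)
  np <- 100
  fert <- rep(sample(rep(c("fertile", "infertile"), np / 2)), each = 2)
  dat <- data.frame(plot = rep(seq_len(np), each = 2),
                    period = factor(rep(c("old", "new"), np), c("old", "new")),
                    fertility = factor(fert, c("fertile", "infertile")))
  u1 <- rnorm(np, 0, 0.3); u2 <- rnorm(np, 0, 0.3)
  is_new_f <- dat$period == "new" & dat$fertility == "fertile"
  dat$logitC <- 0.3 - 0.5 * is_new_f + u1[dat$plot] + rnorm(2 * np, 0, 0.25)
  dat$logitS <- -0.5 + 0.4 * is_new_f + u2[dat$plot] + rnorm(2 * np, 0, 0.25)
  fit <- suppressWarnings(
    bayes_mv_lm(cbind(logitC, logitS) ~ period * fertility, dat,
                random = ~ plot, chains = 2, draws = 400, warmup = 400,
                seed = 8))
  b <- coef(fit)
  expect_lt(b["periodnew", "logitC"], 0)
  expect_gt(b["periodnew", "logitS"], 0)
  # interaction cancels the effect for infertile plots
  expect_lt(abs(b["periodnew", "logitC"] + b["periodnew:fertilityinfertile", "logitC"]),
            0.2)
})

test_that("bivariate residual correlation is recovered", {
  set.seed(33)
  np <- 100
  dat <- data.frame(plot = rep(seq_len(np), each = 2),
                    period = factor(rep(c("old", "new"), np), c("old", "new")))
  Sig <- matrix(c(0.09, 0.6 * 0.09, 0.6 * 0.09, 0.09), 2)
  E <- matrix(rnorm(2 * np * 2), ncol = 2) %*% chol(Sig)
  u <- matrix(rnorm(np * 2, 0, 0.2), ncol = 2)
  dat$logitC <- 0.1 + u[dat$plot, 1] + E[, 1]
  dat$logitS <- -0.2 + u[dat$plot, 2] + E[, 2]
  fit <- suppressWarnings(
    bayes_mv_lm(cbind(logitC, logitS) ~ period, dat, random = ~ plot,
                chains = 2, draws = 500, warmup = 500, seed = 3))
  rho <- mean(fit$draws[, "cor_e"])
  expect_gt(rho, 0.4); expect_lt(rho, 0.8)
})

test_that("diversity models transform, subset, and detect known shifts", {
  set.seed(40)
  np <- 40
  base <- data.frame(
    plot_id = rep(sprintf("p%02d", 1:np), 2),
    period = rep(c("old", "new"), each = np),
    fertility = rep(rep(c("fertile", "infertile"), np / 2), 2))
  div <- do.call(rbind, lapply(c("total", "vascular", "bryophyte"), function(g) {
    d <- base
    d$group <- g
    mult <- ifelse(g == "vascular" & d$period == "new" &
                     d$fertility == "fertile", 2, 1)
    d$effective_species <- exp(rnorm(nrow(d), log(6), 0.15)) * mult + 1
    d
  }))
  lich <- base[base$fertility == "infertile", ]
  lich$group <- "lichen"
  lich$effective_species <- exp(rnorm(nrow(lich), log(3), 0.1)) + 1
  div <- rbind(div, lich)
  fits <- suppressWarnings(
    fit_diversity_models(div, chains = 2, draws = 300, warmup = 300,
                         seed = 5))
  expect_setequal(names(fits), c("total", "vascular", "bryophyte", "lichen"))
  # lichen model has no fertility term
  expect_false(any(grepl("fertility", fits$lichen$coef_names)))
  # doubled fertile vascular diversity: positive time effect for fertile
  sv <- summary(fits$vascular)
  tn <- sv[sv$parameter == "periodnew", ]
  expect_gt(tn$mean, 0)
  expect_gt(tn[[4]], 0)       # whole credible interval above zero
  # stable groups: time effect interval covers zero
  st <- summary(fits$total)
  t0 <- st[st$parameter == "periodnew", ]
  expect_true(t0[[4]] < 0 && t0[[5]] > 0)
})

test_that("Bayesian R2 behaves at its limits", {
  set.seed(3)
  d <- data.frame(x = rnorm(50))
  d$y <- 2 * d$x + rnorm(50, 0, 0.005)
  fit <- bayes_lm(y ~ x, d, chains = 1, draws = 300, warmup = 300, seed = 1)
  expect_gt(median(bayes_r2(fit)), 0.999)
  d$y <- rnorm(50)
  fit0 <- suppressWarnings(
    bayes_lm(y ~ 1, d, chains = 1, draws = 300, warmup = 300, seed = 1))
  expect_true(all(bayes_r2(fit0) == 0))
})

test_that("posterior predictive simulation matches data scale", {
  set.seed(8)
  d <- data.frame(x = rnorm(60))
  d$y <- 1 + d$x + rnorm(60, 0, 0.4)
  fit <- bayes_lm(y ~ x, d, chains = 1, draws = 400, warmup = 300, seed = 2)
  sims <- simulate(fit, nsim = 50, seed = 7)
  expect_equal(dim(sims), c(60L, 50L))
  expect_lt(abs(mean(as.matrix(sims)) - mean(d$y)), 0.3)
  pr <- predict(fit, newdata = data.frame(x = c(0, 1)))
  expect_equal(unname(diff(pr)), unname(coef(fit)["x"]), tolerance = 1e-9)
})
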