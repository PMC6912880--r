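# Bayesian linear regression layer.
#
# Models are fitted by conditionally-conjugate Gibbs sampling:
#   y_i = x_i' b + u_{g(i)} + e_i,  e_i ~ N(0, sigma^2),  u_j ~ N(0, tau^2)
# with weakly informative, scale-adapted priors:
#   intercept  ~ N(mean(y), (10 sd(y))^2)
#   slope_j    ~ N(0, (10 sd(y)/sd(x_j))^2)
#   sigma, tau ~ half-Student-t(3, 0, 2.5 sd(y))
# The half-t scales are represented through the standard inverse-gamma
# auxiliary mixture, which keeps every full conditional conjugate.

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)

default_priors <- function(y, X) {
  sdy <- if (length(y) > 1) stats::sd(y) else 1
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  my <- if (length(y)) mean(y) else 0
  p <- ncol(X)
  b0 <- numeric(p)
  v0 <- numeric(p)
  for (j in seq_len(p)) {
    sdx <- if (nrow(X) > 1) stats::sd(X[, j]) else 0
    if (!is.finite(sdx)) sdx <- 0
    if (sdx == 0) {          # intercept (or constant column)
      b0[j] <- my
      v0[j] <- (10 * sdy)^2
    } else {
      v0[j] <- (10 * sdy / sdx)^2
    }
  }
  list(b0 = b0, v0 = v0, scale_sigma = 2.5 * sdy, scale_tau = 2.5 * sdy,
       nu = 3)
}

# one Gibbs chain for the univariate model; returns draws matrix
gibbs_chain_lm <- function(y, X, group, prior, warmup, draws, seed) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  has_re <- !is.null(group)
  J <- if (has_re) nlevels(group) else 0L
  gi <- if (has_re) as.integer(group) else integer(0)
  nu <- prior$nu
  XtX <- crossprod(X)
  P0 <- diag(1 / prior$v0, p)
  P0b0 <- P0 %*% prior$b0
  # initial state
  b <- prior$b0
  sigma2 <- if (n > 1) stats::var(y) else 1
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  tau2 <- sigma2
  u <- rep(0, J)
  a_sig <- a_tau <- 1
  keep <- matrix(NA_real_, draws,
                 p + 1L + if (has_re) 1L + J else 0L)
  nm <- c(colnames(X), "sigma",
          if (has_re) c("tau", paste0("u[", levels(group), "]")))
  colnames(keep) <- nm
  for (it in seq_len(warmup + draws)) {
    resid_re <- if (has_re) u[gi] else 0
    # coefficients
    if (n > 0) {
      Prec <- XtX / sigma2 + P0
      ch <- chol(Prec)
      mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y - resid_re) / sigma2 + P0b0))
      b <- drop(mu + backsolve(ch, stats::rnorm(p)))
    } else {
      b <- prior$b0 + sqrt(prior$v0) * stats::rnorm(p)
    }
    eta <- if (n > 0) drop(X %*% b) else numeric(0)
    # random intercepts
    if (has_re) {
      r <- y - eta
      sum_r <- numeric(J)
      rs <- rowsum(r, gi)
      sum_r[as.integer(rownames(rs))] <- rs[, 1]
      n_j <- tabulate(gi, J)
      prec_u <- n_j / sigma2 + 1 / tau2
      mean_u <- (sum_r / sigma2) / prec_u
      u <- stats::rnorm(J, mean_u, sqrt(1 / prec_u))
      ssu <- sum(u^2)
      tau2 <- rinvgamma1((J + nu) / 2, nu / a_tau + ssu / 2)
      a_tau <- rinvgamma1((nu + 1) / 2, nu / tau2 + 1 / prior$scale_tau^2)
      resid_re <- u[gi]
    }
    # residual scale
    ssr <- if (n > 0) sum((y - eta - resid_re)^2) else 0
    sigma2 <- rinvgamma1((n + nu) / 2, nu / a_sig + ssr / 2)
    a_sig <- rinvgamma1((nu + 1) / 2, nu / sigma2 + 1 / prior$scale_sigma^2)
    if (it > warmup) {
      keep[it - warmup, seq_len(p)] <- b
      keep[it - warmup, p + 1L] <- sqrt(sigma2)
      if (has_re) {
        keep[it - warmup, p + 2L] <- sqrt(tau2)
        keep[it - warmup, (p + 3L):(p + 2L + J)] <- u
      }
    }
  }
  keep
}

#' Bayesian linear regression with an optional plot random intercept
#'
#' Fits a normal-error linear model by Gibbs sampling, optionally with a
#' Gaussian random intercept per grouping level (e.g. plot identity in a
#' repeated-measures resurvey design). Priors are weakly informative and
#' scale-adapted (see Details in the package vignette). The fitted object
#' carries the pointwise log-likelihood needed for PSIS-LOO comparison.
#'
#' @param formula model formula for the fixed effects.
#' @param data data frame.
#' @param random optional one-sided formula naming the grouping factor for a
#'   random intercept, e.g. `~ plot_id`.
#' @param chains number of Markov chains (default 4).
#' @param draws post-warmup draws per chain (default 1000).
#' @param warmup warmup iterations per chain (default 1000).
#' @param seed integer RNG seed; chain c uses `seed + c - 1`.
#' @param priors optional list overriding the default priors (`b0`, `v0`,
#'   `scale_sigma`, `scale_tau`, `nu`).
#' @param rhat_threshold warn when any split R-hat exceeds this (default
#'   1.01).
#' @return An object of class `bayes_lm` with components `draws`
#'   (total-draws x parameters matrix), `chain_id`, `pointwise_loglik`,
#'   `rhat`, `ess`, plus the model frame pieces needed by the methods.
#' @seealso [psis_loo()], [bayes_r2()], [bayes_mv_lm()]
#' @export
bayes_lm <- function(formula, data, random = NULL, chains = 4, draws = 1000,
                     warmup = 1000, seed = 1, priors = NULL,
                     rhat_threshold = 1.01) {
  stopifnot(chains >= 1, draws >= 1)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(X) > 0 && qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix", call. = FALSE)
  group <- NULL
  if (!is.null(random)) {
    gv <- all.vars(random)
    if (length(gv) != 1) stop("`random` must name one grouping factor", call. = FALSE)
    group <- factor(data[[gv]])
    if (length(group) != length(y))
      stop("grouping factor length mismatch", call. = FALSE)
  }
  prior <- default_priors(y, X)
  if (!is.null(priors)) prior[names(priors)] <- priors
  chain_draws <- lapply(seq_len(chains), function(ch)
    gibbs_chain_lm(y, X, group, prior, warmup, draws,
                   seed = as.integer(seed) + ch - 1L))
  all_draws <- do.call(rbind, chain_draws)
  chain_id <- rep(seq_len(chains), each = draws)
  p <- ncol(X)
  b_idx <- seq_len(p)
  eta <- all_draws[, b_idx, drop = FALSE] %*% t(X)
  if (!is.null(group)) {
    u_cols <- paste0("u[", levels(group), "]")
    eta <- eta + all_draws[, u_cols, drop = FALSE][, as.integer(group), drop = FALSE]
  }
  sig <- all_draws[, "sigma"]
  pll <- matrix(stats::dnorm(rep(y, each = nrow(all_draws)),
                             mean = eta, sd = sig, log = TRUE),
                nrow = nrow(all_draws))
  diag_cols <- c(colnames(X), "sigma", if (!is.null(group)) "tau")
  rhat <- vapply(colnames(all_draws), function(cn)
    split_rhat(matrix(all_draws[, cn], ncol = chains)), numeric(1))
  ess <- vapply(colnames(all_draws), function(cn)
    ess_basic(matrix(all_draws[, cn], ncol = chains)), numeric(1))
  if (any(rhat[diag_cols] > rhat_threshold, na.rm = TRUE))
    warning("convergence: split R-hat above ", rhat_threshold, " for ",
            paste(diag_cols[which(rhat[diag_cols] > rhat_threshold)],
                  collapse = ", "), call. = FALSE)
  structure(list(call = match.call(), formula = formula, random = random,
                 y = y, X = X, group = group,
                 draws = all_draws, chain_id = chain_id,
                 n_chains = chains, n_draws = draws,
                 coef_names = colnames(X),
                 pointwise_loglik = pll,
                 rhat = rhat, ess = ess, prior = prior, seed = seed),
            class = "bayes_lm")
}

#' @export
print.bayes_lm <- function(x, ...) {
  cat("Bayesian linear model (Gibbs)\n")
  cat("  formula:", deparse(x$formula), "\n")
  if (!is.null(x$random)) cat("  random intercept:", deparse(x$random), "\n")
  cat(sprintf("  %d obs, %d chains x %d draws\n",
              length(x$y), x$n_chains, x$n_draws))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.bayes_lm <- function(object, ...) {
  colMeans(object$draws[, object$coef_names, drop = FALSE])
}

#' @export
summary.bayes_lm <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  cols <- colnames(object$draws)
  out <- data.frame(
    parameter = cols,
    mean = colMeans(object$draws),
    sd = apply(object$draws, 2, stats::sd),
    q_low = apply(object$draws, 2, stats::quantile, a),
    q_high = apply(object$draws, 2, stats::quantile, 1 - a),
    rhat = object$rhat[cols],
    ess = object$ess[cols],
    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[4:5] <- c(sprintf("q%g", 100 * a), sprintf("q%g", 100 * (1 - a)))
  class(out) <- c("summary.bayes_lm", "data.frame")
  out
}

#' @export
fitted.bayes_lm <- function(object, ...) {
  eta <- object$X %*% colMeans(object$draws[, object$coef_names, drop = FALSE])
  if (!is.null(object$group)) {
    u <- colMeans(object$draws[, paste0("u[", levels(object$group), "]"),
                               drop = FALSE])
    eta <- eta + u[as.integer(object$group)]
  }
  drop(eta)
}

#' @export
residuals.bayes_lm <- function(object, ...) object$y - fitted(object)

#' @export
predict.bayes_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  drop(X %*% colMeans(object$draws[, object$coef_names, drop = FALSE]))
}

#' @export
simulate.bayes_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$draws)
  idx <- sample.int(S, nsim, replace = nsim > S)
  out <- vapply(idx, function(s) {
    eta <- drop(object$X %*% object$draws[s, object$coef_names])
    if (!is.null(object$group)) {
      u <- object$draws[s, paste0("u[", levels(object$group), "]")]
      eta <- eta + u[as.integer(object$group)]
    }
    stats::rnorm(length(eta), eta, object$draws[s, "sigma"])
  }, numeric(length(object$y)))
  as.data.frame(out)
}

#' @export
plot.bayes_lm <- function(x, pars = x$coef_names, ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::plot(x$draws[, p], type = "l", ylab = p, xlab = "",
                   col = "grey30", ...)
  }
  invisible(x)
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the linear predictor divided by that
#' variance plus the draw's residual variance.
#'
#' @param object a [bayes_lm()] fit.
#' @param fixed_only use only the fixed-effect part of the linear predictor
#'   (default `FALSE`: random intercepts, when present, are included).
#' @return Numeric vector of per-draw R-squared values in \[0, 1\].
#' @export
bayes_r2 <- function(object, fixed_only = FALSE) {
  stopifnot(inherits(object, "bayes_lm"))
  eta <- object$draws[, object$coef_names, drop = FALSE] %*% t(object$X)
  if (!is.null(object$group) && !fixed_only) {
    u_cols <- paste0("u[", levels(object$group), "]")
    eta <- eta + object$draws[, u_cols, drop = FALSE][, as.integer(object$group),
                                                      drop = FALSE]
  }
  if (ncol(eta) < 2) stop("R-squared undefined for fewer than 2 observations",
                          call. = FALSE)
  var_fit <- apply(eta, 1, stats::var)
  sig2 <- object$draws[, "sigma"]^2
  var_fit / (var_fit + sig2)
}

# ---- convergence diagnostics ---------------------------------------------

# split R-hat on a (iterations x chains) matrix
split_rhat <- function(sims) {
  niter <- nrow(sims)
  if (niter < 4) return(NA_real_)
  half <- floor(niter / 2)
  split <- cbind(sims[seq_len(half), , drop = FALSE],
                 sims[(niter - half + 1):niter, , drop = FALSE])
  m <- ncol(split); n <- nrow(split)
  mu <- colMeans(split)
  s2 <- apply(split, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size: Geyer initial-positive-sequence truncation on the
# chain-averaged autocorrelation
ess_basic <- function(sims, max_lag = 200L) {
  niter <- nrow(sims); m <- ncol(sims)
  S <- niter * m
  if (niter < 4) return(NA_real_)
  max_lag <- min(max_lag, niter - 2L)
  var_tot <- mean(apply(sims, 2, stats::var))
  if (var_tot == 0) return(S)
  acov <- rowMeans(vapply(seq_len(m), function(ch)
    drop(stats::acf(sims[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)[-1],
    numeric(max_lag)))
  rho <- acov / var_tot
  # sum consecutive pairs while positive
  tau <- 1
  k <- 1
  while (k + 1 <= max_lag) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  min(S, S / tau)
}
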