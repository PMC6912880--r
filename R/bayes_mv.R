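# Bivariate hierarchical regression for logit CSR proportions.
#
# Row i of Y holds (logitC, logitS) for one plot x period record:
#   y_i = B' x_i + u_{g(i)} + e_i,   e_i ~ N2(0, Sigma_e),  u_j ~ N2(0, Sigma_u)
# Both 2x2 covariance matrices are free, so plot random effects and
# residuals may covary between the two strategy responses. Covariances get
# the Huang-Wand (2013) prior with nu = 2, i.e. marginal half-t(2) standard
# deviations and a marginally uniform correlation (the d = 2 LKJ(1) prior);
# auxiliary inverse-gamma scales keep the conditionals inverse-Wishart.

riwish <- function(df, S) {
  # Sigma ~ InvWishart(df, S)  <=>  Sigma^-1 ~ Wishart(df, S^-1)
  solve(stats::rWishart(1, df, solve(S))[, , 1])
}

gibbs_chain_mv <- function(Y, X, group, prior, warmup, draws, seed) {
  set.seed(seed)
  n <- nrow(Y); p <- ncol(X); d <- ncol(Y)
  J <- nlevels(group)
  gi <- as.integer(group)
  nu <- 2          # Huang-Wand: uniform marginal correlation for d = 2
  XtX <- crossprod(X)
  P0 <- diag(rep(1 / prior$v0, d), p * d)
  P0b0 <- P0 %*% as.vector(prior$b0)
  B <- prior$b0
  Sigma_e <- diag(prior$scale_e^2 / 4, d)
  Sigma_u <- diag(prior$scale_u^2 / 4, d)
  U <- matrix(0, J, d)
  a_e <- rep(1, d); a_u <- rep(1, d)
  n_j <- tabulate(gi, J)
  nm <- c(paste0(rep(colnames(X), d), "_", rep(colnames(Y), each = p)),
          "sd_e1", "sd_e2", "cor_e", "sd_u1", "sd_u2", "cor_u")
  keep <- matrix(NA_real_, draws, length(nm), dimnames = list(NULL, nm))
  keep_u <- array(NA_real_, c(draws, J, d))
  for (it in seq_len(warmup + draws)) {
    We <- solve(Sigma_e)
    # fixed effects: vec(B) (columns stacked) is multivariate normal
    Ytil <- Y - U[gi, , drop = FALSE]
    Prec <- kronecker(We, XtX) + P0
    rhs <- as.vector(crossprod(X, Ytil) %*% We) + P0b0
    ch <- chol(Prec)
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    B <- matrix(drop(mu + backsolve(ch, stats::rnorm(p * d))), p, d)
    # random intercepts
    R <- Y - X %*% B
    Wu <- solve(Sigma_u)
    sums <- matrix(0, J, d)
    rs <- rowsum(R, gi)
    sums[as.integer(rownames(rs)), ] <- rs
    # groups sharing a replicate count share the conditional precision
    for (nv in unique(n_j)) {
      jj <- which(n_j == nv)
      chj <- chol(nv * We + Wu)
      mj <- backsolve(chj, forwardsolve(t(chj), We %*% t(sums[jj, , drop = FALSE])))
      z <- backsolve(chj, matrix(stats::rnorm(d * length(jj)), d))
      U[jj, ] <- t(mj + z)
    }
    # residual covariance (Huang-Wand conditionals)
    E <- R - U[gi, , drop = FALSE]
    Sigma_e <- riwish(nu + d - 1 + n, 2 * nu * diag(1 / a_e, d) + crossprod(E))
    Wei <- solve(Sigma_e)
    for (k in seq_len(d))
      a_e[k] <- rinvgamma1((nu + d) / 2, nu * Wei[k, k] + 1 / prior$scale_e^2)
    # random-effect covariance
    Sigma_u <- riwish(nu + d - 1 + J, 2 * nu * diag(1 / a_u, d) + crossprod(U))
    Wui <- solve(Sigma_u)
    for (k in seq_len(d))
      a_u[k] <- rinvgamma1((nu + d) / 2, nu * Wui[k, k] + 1 / prior$scale_u^2)
    if (it > warmup) {
      s <- it - warmup
      keep[s, seq_len(p * d)] <- as.vector(B)
      keep[s, p * d + 1:6] <- c(sqrt(Sigma_e[1, 1]), sqrt(Sigma_e[2, 2]),
                                Sigma_e[1, 2] / sqrt(Sigma_e[1, 1] * Sigma_e[2, 2]),
                                sqrt(Sigma_u[1, 1]), sqrt(Sigma_u[2, 2]),
                                Sigma_u[1, 2] / sqrt(Sigma_u[1, 1] * Sigma_u[2, 2]))
      keep_u[s, , ] <- U
    }
  }
  list(keep = keep, keep_u = keep_u)
}

#' Bivariate hierarchical Bayesian regression for logit strategy proportions
#'
#' Fits the two logit-transformed main-strategy proportions (C and S; R is
#' omitted because it is determined as 100 - C - S) jointly with shared
#' fixed effects structure, a bivariate plot random intercept and freely
#' covarying bivariate residuals.
#'
#' @param formula two-response formula such as
#'   `cbind(logitC, logitS) ~ period * fertility`.
#' @param data data frame with one row per plot x period record.
#' @param random one-sided formula naming the plot grouping factor.
#' @param chains,draws,warmup,seed MCMC settings as in [bayes_lm()].
#' @param rhat_threshold warn when any split R-hat exceeds this.
#' @return An object of class `bayes_mv_lm` with `draws`,
#'   `pointwise_loglik` (one column per plot x period row; bivariate normal
#'   log density), `rhat`, `ess`.
#' @export
bayes_mv_lm <- function(formula, data, random, chains = 4, draws = 1000,
                        warmup = 1000, seed = 1, rhat_threshold = 1.01) {
  mf <- stats::model.frame(formula, data)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2)
    stop("formula must have exactly two responses, e.g. cbind(logitC, logitS) ~ ...",
         call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix (single-period data cannot identify a time effect)",
         call. = FALSE)
  gv <- all.vars(random)
  group <- factor(data[[gv]])
  if (is.null(colnames(Y))) colnames(Y) <- c("y1", "y2")
  sdy <- apply(Y, 2, stats::sd)
  prior <- list(
    b0 = matrix(rep(colMeans(Y), each = ncol(X)) *
                  rep(as.integer(apply(X, 2, stats::sd) == 0), 2),
                ncol(X), 2),
    v0 = {
      v <- numeric(ncol(X))
      for (j in seq_len(ncol(X))) {
        sdx <- stats::sd(X[, j])
        v[j] <- if (sdx == 0) (10 * max(sdy))^2 else (10 * max(sdy) / sdx)^2
      }
      v
    },
    scale_e = 2.5 * max(sdy), scale_u = 2.5 * max(sdy))
  res <- lapply(seq_len(chains), function(ch)
    gibbs_chain_mv(Y, X, group, prior, warmup, draws,
                   seed = as.integer(seed) + ch - 1L))
  all_draws <- do.call(rbind, lapply(res, `[[`, "keep"))
  chain_id <- rep(seq_len(chains), each = draws)
  p <- ncol(X)
  # pointwise bivariate normal log likelihood
  n <- nrow(Y)
  S <- nrow(all_draws)
  pll <- matrix(NA_real_, S, n)
  gi <- as.integer(group)
  for (ch in seq_len(chains)) {
    rows <- which(chain_id == ch)
    ku <- res[[ch]]$keep_u
    for (s_local in seq_along(rows)) {
      s <- rows[s_local]
      B <- matrix(all_draws[s, seq_len(2 * p)], p, 2)
      se1 <- all_draws[s, "sd_e1"]; se2 <- all_draws[s, "sd_e2"]
      re <- all_draws[s, "cor_e"]
      Sig <- matrix(c(se1^2, re * se1 * se2, re * se1 * se2, se2^2), 2, 2)
      Wi <- solve(Sig)
      ldet <- determinant(Sig, logarithm = TRUE)$modulus
      M <- X %*% B + ku[s_local, , ][gi, , drop = FALSE]
      E <- Y - M
      q <- rowSums((E %*% Wi) * E)
      pll[s, ] <- -0.5 * (2 * log(2 * pi) + as.numeric(ldet) + q)
    }
  }
  rhat <- vapply(colnames(all_draws), function(cn)
    split_rhat(matrix(all_draws[, cn], ncol = chains)), numeric(1))
  ess <- vapply(colnames(all_draws), function(cn)
    ess_basic(matrix(all_draws[, cn], ncol = chains)), numeric(1))
  if (any(rhat > rhat_threshold, na.rm = TRUE))
    warning("convergence: split R-hat above ", rhat_threshold, " for ",
            paste(names(rhat)[which(rhat > rhat_threshold)], collapse = ", "),
            call. = FALSE)
  structure(list(call = match.call(), formula = formula, random = random,
                 Y = Y, X = X, group = group,
                 draws = all_draws, chain_id = chain_id,
                 n_chains = chains, n_draws = draws,
                 responses = colnames(Y), coef_names = colnames(X),
                 pointwise_loglik = pll, rhat = rhat, ess = ess,
                 seed = seed),
            class = "bayes_mv_lm")
}

#' @export
print.bayes_mv_lm <- function(x, ...) {
  cat("Bivariate hierarchical Bayesian linear model (Gibbs)\n")
  cat("  responses:", paste(x$responses, collapse = ", "), "\n")
  cat(sprintf("  %d rows, %d groups, %d chains x %d draws\n",
              nrow(x$Y), nlevels(x$group), x$n_chains, x$n_draws))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.bayes_mv_lm <- function(object, ...) {
  p <- length(object$coef_names)
  m <- matrix(colMeans(object$draws[, seq_len(2 * p), drop = FALSE]), p, 2,
              dimnames = list(object$coef_names, object$responses))
  m
}

#' @export
summary.bayes_mv_lm <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  out <- data.frame(
    parameter = colnames(object$draws),
    mean = colMeans(object$draws),
    sd = apply(object$draws, 2, stats::sd),
    q_low = apply(object$draws, 2, stats::quantile, a),
    q_high = apply(object$draws, 2, stats::quantile, 1 - a),
    rhat = object$rhat, ess = object$ess,
    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[4:5] <- c(sprintf("q%g", 100 * a), sprintf("q%g", 100 * (1 - a)))
  out
}

#' @export
fitted.bayes_mv_lm <- function(object, ...) {
  object$X %*% coef(object)
}

#' @export
residuals.bayes_mv_lm <- function(object, ...) object$Y - fitted(object)
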