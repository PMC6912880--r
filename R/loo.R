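# Pareto-smoothed importance-sampling leave-one-out cross-validation.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Zhang & Stephens (2009) generalized Pareto fit (profile-likelihood grid,
# weakly-informative shrinkage of the shape as in Vehtari et al.)
gpd_fit <- function(x) {
  x <- sort(x)
  N <- length(x)
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(floor(N / 4 + 0.5), 1)]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(th) {
    xi <- mean(log1p(-th * x))
    N * (log(-th / xi) - xi - 1)
  }, numeric(1))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- mean(log1p(-th_hat * x))
  sigma <- -k / th_hat
  k <- -k                          # heavy-tail-positive convention
  k <- (k * N + 0.5 * 10) / (N + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * (exp(-k * log1p(-p)) - 1) / k
}

# smooth the right tail of importance ratios r (linear scale, any positive
# scaling); returns list(r = smoothed ratios, k = Pareto shape)
psis_smooth <- function(r) {
  S <- length(r)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || length(unique(r)) < 5)
    return(list(r = r, k = -Inf))
  ord <- order(r)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- r[ord[S - M]]
  exceed <- r[tail_ids] - cutoff
  if (all(exceed <= 0)) return(list(r = r, k = -Inf))
  fit <- gpd_fit(exceed[exceed > 0])
  if (!is.finite(fit$k)) return(list(r = r, k = -Inf))
  smoothed <- cutoff + vapply((seq_len(M) - 0.5) / M, qgpd, numeric(1),
                              k = fit$k, sigma = fit$sigma)
  smoothed <- pmin(smoothed, max(r))     # truncate at max raw weight
  r[tail_ids] <- smoothed                # tail_ids already in ascending order
  list(r = r, k = fit$k)
}

#' PSIS-LOO: approximate leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density under
#' leave-one-out cross-validation by Pareto-smoothed importance sampling.
#' For each observation the importance ratios are the reciprocals of its
#' pointwise likelihood across posterior draws; the largest
#' `min(0.2 S, 3 sqrt(S))` ratios are replaced by expected order statistics
#' of a generalized Pareto distribution fitted to the tail, truncated at
#' the largest raw ratio. The fitted Pareto shape k is the reliability
#' diagnostic (values above 0.7 flag unstable estimates).
#'
#' @param x a `bayes_lm`/`bayes_mv_lm` fit, or a draws x observations
#'   matrix of pointwise log-likelihood values.
#' @param ... unused.
#' @return An object of class `loo_result`: list with `elpd_loo`, `se_elpd`,
#'   `p_loo`, `pointwise` (per-observation elpd), `pareto_k`, `n_high_k`
#'   (count of k > 0.7).
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @export
psis_loo.bayes_lm <- function(x, ...) psis_loo(x$pointwise_loglik, ...)

#' @export
psis_loo.bayes_mv_lm <- function(x, ...) psis_loo(x$pointwise_loglik, ...)

#' @rdname psis_loo
#' @export
psis_loo.matrix <- function(x, ...) {
  ll <- x
  if (!all(is.finite(ll))) {
    bad <- unique(which(!is.finite(ll), arr.ind = TRUE)[, 2])
    stop("non-finite log-likelihood for observation(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  S <- nrow(ll); n <- ncol(ll)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  lpd_i <- numeric(n)
  for (i in seq_len(n)) {
    lr <- -ll[, i]
    r <- exp(lr - max(lr))          # scale-free: weights are normalised
    sm <- psis_smooth(r)
    logw <- log(sm$r)
    elpd_i[i] <- logsumexp(logw + ll[, i]) - logsumexp(logw)
    lpd_i[i] <- logsumexp(ll[, i]) - log(S)
    khat[i] <- sm$k
  }
  structure(list(elpd_loo = sum(elpd_i),
                 se_elpd = sqrt(n * stats::var(elpd_i)),
                 p_loo = sum(lpd_i - elpd_i),
                 pointwise = elpd_i,
                 pareto_k = khat,
                 n_high_k = sum(khat > 0.7),
                 n_obs = n, n_draws = S),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.2f (se %.2f), p_loo = %.2f, %d/%d k > 0.7\n",
              x$elpd_loo, x$se_elpd, x$p_loo, x$n_high_k, x$n_obs))
  invisible(x)
}

#' Rank models by PSIS-LOO
#'
#' @param loos named list of [psis_loo()] results computed on the same
#'   observations.
#' @return Data frame sorted by decreasing `elpd_loo` with the difference to
#'   the best model and the standard error of that difference (from the
#'   pointwise elpd differences).
#' @export
compare_models <- function(loos) {
  stopifnot(is.list(loos), length(loos) >= 1)
  if (is.null(names(loos)) || any(names(loos) == ""))
    names(loos) <- paste0("model", seq_along(loos))
  n <- vapply(loos, function(l) l$n_obs, integer(1))
  if (length(unique(n)) != 1)
    stop("models were fitted to different observation sets", call. = FALSE)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  ord <- order(elpd, decreasing = TRUE)
  best <- loos[[ord[1]]]
  rows <- lapply(ord, function(i) {
    diff_pw <- loos[[i]]$pointwise - best$pointwise
    data.frame(model = names(loos)[i],
               elpd_loo = loos[[i]]$elpd_loo,
               se_elpd = loos[[i]]$se_elpd,
               elpd_diff = sum(diff_pw),
               se_diff = sqrt(n[1] * stats::var(diff_pw)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
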