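# independent brute-force oracles, written from the index definitions
oracle_mh <- function(x, y) {
  p <- x / sum(x); q <- y / sum(y)
  num <- 0; dp <- 0; dq <- 0
  for (i in seq_along(p)) {
    num <- num + 2 * p[i] * q[i]
    dp <- dp + p[i]^2
    dq <- dq + q[i]^2
  }
  num / (dp + dq)
}
oracle_hill2 <- function(x) {
  p <- x / sum(x)
  s <- 0
  for (i in seq_along(p)) s <- s + p[i]^2
  1 / s
}
oracle_multi <- function(m) {
  n <- nrow(m)
  p <- sweep(m, 1, rowSums(m), "/")
  pooled <- colSums(p) / n
  d_gamma <- oracle_hill2(pooled)
  d_alpha <- 1 / mean(apply(p, 1, function(r) sum(r^2)))
  d_beta <- d_gamma / d_alpha
  1 - (1 / d_beta - 1 / n) / (1 - 1 / n)
}

test_that("relative abundances normalise and reject empty communities", {
  expect_equal(relative_abundance(c(50, 50)), c(0.5, 0.5))
  expect_equal(relative_abundance(c(30, 10, 0)), c(0.75, 0.25, 0))
  expect_error(relative_abundance(c(0, 0)), "empty community")
})

test_that("Morisita-Horn matches hand-computed values and extremes", {
  expect_equal(morisita_horn(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_equal(morisita_horn(c(1, 0), c(0, 1)), 0)
  expect_equal(morisita_horn(c(0.5, 0.5), c(1, 0)), 2 / 3)
  expect_error(morisita_horn(c(1, 0), c(1, 0, 0)), "axes")
})

test_that("Morisita-Horn is symmetric, zero-species invariant and scale-free", {
  set.seed(101)
  for (r in 1:30) {
    x <- random_community(12)
    y <- random_community(12)
    if (sum(x * y) == 0) next
    expect_equal(morisita_horn(x, y), morisita_horn(y, x), tolerance = 1e-12)
    expect_equal(morisita_horn(c(x, 0, 0), c(y, 0, 0)), morisita_horn(x, y),
                 tolerance = 1e-12)
    k <- runif(1, 0.1, 40)
    expect_equal(morisita_horn(k * x, y), morisita_horn(x, y),
                 tolerance = 1e-12)
  }
})

test_that("pairwise turnover spans the identical/replacement extremes", {
  m <- matrix(c(10, 5, 3, 50), 2, 2,
              dimnames = list(c("p1", "p2"), c("A", "B")))
  ps_same <- make_ps(m, m)
  expect_equal(pairwise_turnover(ps_same)$d, c(0, 0))
  old <- make_cm(matrix(c(10, 5), 2, 1, dimnames = list(c("p1", "p2"), "A")))
  new <- make_cm(matrix(c(4, 9), 2, 1, dimnames = list(c("p1", "p2"), "B")),
                 survey_year = 2014, label = "new")
  tt <- pairwise_turnover(pair_surveys(old, new))
  expect_equal(tt$d, c(1, 1))
  expect_equal(tt$sampling_time, c(44, 44))
})

test_that("turnover of a known mixture matches brute-force recomputation", {
  set.seed(7)
  p <- relative_abundance(random_community(20, 0))
  q <- relative_abundance(random_community(20, 0))
  for (w in c(0.1, 0.4, 0.9)) {
    mix <- (1 - w) * p + w * q
    old <- make_cm(matrix(p * 80, 1, 20,
                          dimnames = list("p1", sprintf("s%02d", 1:20))))
    new <- make_cm(matrix(mix * 120, 1, 20,
                          dimnames = list("p1", sprintf("s%02d", 1:20))),
                   survey_year = 2014, label = "new")
    expect_equal(pairwise_turnover(pair_surveys(old, new))$d,
                 1 - oracle_mh(p, mix), tolerance = 1e-12)
  }
})

test_that("Hill-Simpson effective numbers behave as effective numbers", {
  expect_equal(hill_simpson(rep(1, 10)), 10)
  expect_equal(hill_simpson(c(0.5, 0.5)), 2)
  expect_equal(hill_simpson(c(0.8, 0.2)), 1 / 0.68)
  set.seed(5)
  x <- random_community(15, 0)
  expect_equal(hill_simpson(sample(x)), hill_simpson(x), tolerance = 1e-12)
  # concentrating abundance strictly lowers the effective number
  even <- rep(10, 5)
  for (shift in c(2, 5, 8)) {
    conc <- even + c(shift, -shift / 4 * rep(1, 4))
    expect_lt(hill_simpson(conc), hill_simpson(even))
  }
})

test_that("per-group diversity subsets match whole-vector computation", {
  covers <- matrix(c(30, 30, 10, 0, 5), 1, 5,
                   dimnames = list("p1", c("b1", "b2", "v1", "v2", "v3")))
  traits <- make_traits(c("b1", "b2", "v1", "v2", "v3"),
                        morph = c("bryophytes", "bryophytes", "forbs",
                                  "forbs", "graminoids"),
                        vascular = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  cm <- make_cm(covers)
  d <- diversity_by_group(cm, traits)
  expect_equal(d$effective_species[d$group == "bryophyte"], 2)
  expect_true(is.na(d$effective_species[d$group == "lichen"]))
  expect_equal(d$effective_species[d$group == "vascular"],
               hill_simpson(c(10, 5)))
  expect_equal(d$effective_species[d$group == "total"],
               hill_simpson(covers[1, ]))
  # unknown species: warned, excluded from groups, kept in the total
  covers2 <- cbind(covers, mystery = 20)
  expect_warning(diversity_by_group(make_cm(covers2), traits), "mystery")
  d2 <- suppressWarnings(diversity_by_group(make_cm(covers2), traits))
  expect_equal(d2$effective_species[d2$group == "total"],
               hill_simpson(covers2[1, ]))
  expect_equal(d2$effective_species[d2$group == "vascular"],
               hill_simpson(c(10, 5)))
})

test_that("multiple-assemblage turnover matches the worked decomposition", {
  m3 <- matrix(rep(c(3, 1, 6), each = 3), 3, 3,
               dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  expect_equal(multi_assemblage_turnover(m3), 0, tolerance = 1e-12)
  disj <- rbind(c(1, 0), c(0, 1))
  expect_equal(multi_assemblage_turnover(disj), 1)
  ex <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(multi_assemblage_turnover(ex), 1 / 3, tolerance = 1e-12)
  expect_error(multi_assemblage_turnover(matrix(1, 1, 2)), "undefined")
  # N identical plots give zero for N = 2..10
  for (n in 2:10) {
    m <- matrix(rep(c(5, 2, 1, 9), each = n), n, 4)
    expect_equal(multi_assemblage_turnover(m), 0, tolerance = 1e-12)
  }
})

test_that("bootstrap SE is zero for identical plots and reproducible", {
  m <- matrix(rep(c(4, 6), each = 3), 3, 2)
  expect_equal(bootstrap_se_beta(m, reps = 50, seed = 1), 0)
  set.seed(31)
  het <- matrix(rexp(24), 4, 6)
  se1 <- bootstrap_se_beta(het, reps = 200, seed = 42)
  se2 <- bootstrap_se_beta(het, reps = 200, seed = 42)
  expect_identical(se1, se2)
  expect_gt(se1, 0)
})

test_that("bootstrap SE shrinks along a heterogeneity gradient", {
  # mix each plot towards the common mean: less between-plot heterogeneity
  set.seed(77)
  base <- matrix(rexp(60), 6, 10)
  ses <- vapply(c(0, 0.6, 0.95), function(a) {
    m <- (1 - a) * base + a * matrix(colMeans(base), 6, 10, byrow = TRUE)
    bootstrap_se_beta(m, reps = 400, seed = 5)
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("beta change carries sign information and splits by site", {
  m_old <- matrix(c(10, 0, 0, 10, 5, 5), 3, 2, byrow = TRUE,
                  dimnames = list(paste0("p", 1:3), c("A", "B")))
  m_new <- matrix(rep(c(5, 5), 3), 3, 2, byrow = TRUE,
                  dimnames = list(paste0("p", 1:3), c("A", "B")))
  ps <- make_ps(m_old, m_new)
  bc <- beta_change(ps, reps = NULL)
  expect_lt(bc$delta_beta, 0)       # plots became identical: homogenisation
  expect_equal(bc$beta_new, 0)
  bc0 <- beta_change(make_ps(m_old, m_old), reps = NULL)
  expect_equal(bc0$delta_beta, 0)
})

test_that("split_sites partitions plots by subregion x fertility", {
  covers <- matrix(rexp(12) + 0.1, 6, 2,
                   dimnames = list(paste0("p", 1:6), c("A", "B")))
  old <- make_cm(covers, fertility = rep(c("fertile", "infertile"), each = 3),
                 subregion = rep(c("MB", "NBs"), 3))
  new <- make_cm(covers, fertility = rep(c("fertile", "infertile"), each = 3),
                 subregion = rep(c("MB", "NBs"), 3),
                 survey_year = 2014, label = "new")
  sites <- split_sites(pair_surveys(old, new))
  expect_setequal(names(sites), c("MB.fertile", "NBs.fertile",
                                  "MB.infertile", "NBs.infertile"))
  expect_equal(sum(vapply(sites, function(s) nrow(s$plot_pairs), numeric(1))), 6)
})

test_that("agreement with an independent community-ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  for (r in 1:20) {
    x <- random_community(10) + 0.01
    y <- random_community(10) + 0.01
    d_pkg <- 1 - morisita_horn(x, y)
    d_vegan <- as.numeric(vegan::vegdist(rbind(x / sum(x), y / sum(y)),
                                         method = "horn"))
    expect_equal(d_pkg, d_vegan, tolerance = 1e-10)
  }
})
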