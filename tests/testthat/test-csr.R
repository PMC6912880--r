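test_that("cover-weighted CSR matches hand-weighted averages", {
  tr1 <- make_traits("a", list(c(20, 70, 10)))
  expect_equal(cwm_csr(c(a = 37), tr1),
               c(propC = 20, propS = 70, propR = 10))
  tr2 <- make_traits(c("a", "b"), list(c(100, 0, 0), c(0, 100, 0)))
  expect_equal(cwm_csr(c(a = 50, b = 50), tr2),
               c(propC = 50, propS = 50, propR = 0))
  tr3 <- make_traits(c("a", "b"), list(c(60, 30, 10), c(20, 60, 20)))
  expect_equal(cwm_csr(c(a = 30, b = 10), tr3),
               c(propC = 50, propS = 37.5, propR = 12.5))
})

test_that("CSR proportions sum to 100 and are scale invariant", {
  set.seed(13)
  tr <- make_traits(paste0("s", 1:6),
                    lapply(1:6, function(i) {
                      x <- rexp(3); round(100 * x / sum(x), 6) -> v
                      v[3] <- 100 - v[1] - v[2]; v
                    }))
  covers <- setNames(rexp(6) * 20, paste0("s", 1:6))
  p <- cwm_csr(covers, tr)
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(cwm_csr(covers * 7.3, tr), p, tolerance = 1e-12)
})

test_that("vascular-only vs whole-plot denominators are both well defined", {
  tr <- make_traits(c("v", "m"), list(c(80, 10, 10), c(0, 100, 0)),
                    morph = c("forbs", "bryophytes"),
                    vascular = c(TRUE, FALSE))
  covers <- c(v = 20, m = 60)
  expect_equal(cwm_csr(covers, tr), c(propC = 80, propS = 10, propR = 10))
  # whole-plot denominator still renormalises onto the three classes
  expect_equal(sum(cwm_csr(covers, tr, denominator = "total")), 100)
  expect_error(cwm_csr(c(m = 60), tr[2, ]), "undefined CSR profile")
})

test_that("logit transform: closed forms, round trip, domain", {
  expect_equal(logit_fraction(0.5), 0)
  expect_equal(logit_fraction(0, epsilon = 0.001), log(0.001 / 0.999))
  expect_equal(logit_fraction(0, epsilon = 0.001), -6.906755, tolerance = 1e-6)
  x <- c(0.02, 0.3, 0.97)
  expect_equal(inv_logit(logit_fraction(x, 0.001)), x, tolerance = 1e-12)
  expect_error(logit_fraction(1.2), "0, 1")
  expect_error(logit_fraction(0.5, epsilon = 0.6), "epsilon")
})

test_that("strategy profiles track both periods and rescaling", {
  tr <- make_traits(c("a", "b"), list(c(0, 100, 0), c(0, 100, 0)))
  m <- matrix(c(10, 30, 5, 20), 2, 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  ps <- make_ps(m, 3 * m)   # uniform rescaling of every plot
  prof <- strategy_profiles(ps, tr)
  expect_equal(nrow(prof), 4)
  expect_true(all(prof$propS == 100))
  wide_old <- prof[prof$period == "old", c("propC", "propS", "propR")]
  wide_new <- prof[prof$period == "new", c("propC", "propS", "propR")]
  expect_equal(unname(as.matrix(wide_old)), unname(as.matrix(wide_new)),
               tolerance = 1e-12)
})

test_that("a generated C-to-S shift shows up with a negative C change", {
  sim <- gen_paired_survey(simulation_truth(
    seed = 21, csr_time_effects = list(fertile = c(C = -2, S = 2),
                                       infertile = c(C = 0, S = 0))))
  prof <- strategy_profiles(sim$paired_survey, sim$traits)
  f <- prof[prof$fertility == "fertile", ]
  dC <- mean(f$propC[f$period == "new"]) - mean(f$propC[f$period == "old"])
  expect_lt(dC, 0)
})

test_that("group cover changes: zero-change and degenerate CIs", {
  tr <- make_traits(c("a", "b"), list(c(50, 25, 25), c(10, 80, 10)),
                    morph = c("forbs", "graminoids"), csr_class = c("C", "S"))
  m <- matrix(c(10, 30, 5, 20), 2, 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  gc <- group_cover_change(make_ps(m, m), tr, "morphological",
                           reps = 100, seed = 1)
  expect_true(all(gc$mean_change == 0))
  expect_true(all(gc$ci_low == 0 & gc$ci_high == 0))
  expect_false(gc$present[gc$group == "lichens"])
  # one plot: the interval collapses onto the point estimate
  m1 <- m[1, , drop = FALSE]
  m1b <- m1; m1b[1, 1] <- m1b[1, 1] + 4
  gc1 <- group_cover_change(make_ps(m1, m1b), tr, "csr", reps = 100, seed = 1)
  expect_equal(gc1$ci_low[gc1$group == "C"], 4)
  expect_equal(gc1$ci_high[gc1$group == "C"], 4)
  expect_equal(gc1$mean_change[gc1$group == "C"], 4)
})

test_that("a +10 cover shift is recovered inside the bootstrap CI", {
  set.seed(99)
  n <- 20
  species <- c(paste0("d", 1:3), paste0("f", 1:3))
  tr <- make_traits(species, morph = rep(c("dwarf shrubs", "forbs"), each = 3))
  m_old <- matrix(rexp(n * 6, 1 / 10), n, 6,
                  dimnames = list(sprintf("p%02d", 1:n), species))
  m_new <- m_old
  m_new[, 1:3] <- m_new[, 1:3] + 10 / 3   # +10 total dwarf-shrub cover
  gc <- group_cover_change(make_ps(m_old, m_new), tr, "morphological",
                           reps = 500, seed = 3)
  row <- gc[gc$group == "dwarf shrubs", ]
  expect_equal(row$mean_change, 10, tolerance = 1e-9)
  expect_true(row$ci_low <= 10 && 10 <= row$ci_high)
})
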