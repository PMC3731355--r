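test_that("burden scores sum minor-allele dosages with missing as zero", {
  # minor allele == alt here (low alt frequencies); per-sample row sums
  ge <- toyGE(rbind(c(0, 2, 1), c(1, 0, 1)))
  expect_equal(burdenScore(ge, 1, 2), c(1L, 2L, 2L))
  expect_equal(burdenScore(toyGE(rbind(c(0, 0), c(0, 0), c(0, 1))), 1, 2),
               c(0L, 0L))
  # missing contributes zero (alt stays minor at these frequencies)
  expect_equal(burdenScore(toyGE(rbind(c(NA, 0, 0, 0), c(2, 0, 1, 0))), 1, 2),
               c(2L, 0L, 1L, 0L))
})

test_that("burden orientation flips columns whose minor allele is REF", {
  d <- rbind(c(2, 2, 1, 2), c(0, 1, 0, 0))   # first variant: alt is major
  ge <- toyGE(d)
  expect_equal(burdenScore(ge, 1, 2, orientation = "minor"),
               as.integer((2 - d[1, ]) + d[2, ]))
  expect_equal(burdenScore(ge, 1, 2, orientation = "alt"),
               as.integer(colSums(d)))
})

test_that("constant covariates and monotone likelihoods are flagged", {
  f <- coxFit(rep(2, 5), time = 1:5, event = c(1, 0, 1, 1, 0))
  expect_equal(f@lrt, 0)
  expect_true(f@converged)
  # 2 samples, earlier death has higher x: l(beta) = beta - log(e^beta + 1)
  f2 <- coxFit(c(1, 0), time = c(1, 2), event = c(1, 1))
  expect_true(f2@divergent)
  expect_equal(f2@beta, 15)
  expect_error(coxFit(c(1, 0), c(1, 2), c(0, 0)), "no events")
})

test_that("coxFit agrees with an independent 1-D maximizer and coxph", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(6:30, 1)
    x <- rbinom(n, 4, 0.4)
    tt <- round(rexp(n, 0.1), 1) + 0.5   # induces ties
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    if (sd(x) == 0) next
    f <- coxFit(x, tt, ev)
    if (f@divergent) next
    o <- oracleCoxFit(x, tt, ev)
    expect_lt(abs(f@beta - o$beta), 1e-6)
    expect_lt(abs(f@lrt - o$lrt), 1e-6)
    cf <- suppressWarnings(survival::coxph(
      survival::Surv(tt, ev) ~ x, ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50)))
    expect_lt(abs(f@beta - unname(coef(cf))), 1e-6)
    expect_lt(abs(f@lrt - 2 * diff(cf$loglik)), 1e-6)
    # maximized likelihood dominates the null likelihood
    expect_gte(f@loglik_at_beta, f@loglik_at_zero)
  }
})

test_that("exhaustive survival permutation p equals direct enumeration", {
  skip_if_not_installed("survival")
  cfg <- simulationConfig(n_samples = 6, n_variants = 5, seed = 21,
                          censoring_rate = 0.2)
  sim <- simulateCohort(cfg)
  tt <- sim$survival$time; ev <- sim$survival$event
  res <- survivalScan(sim$ge, tt, ev,
                      plan = scanPlan(3, includeWholeRegion = FALSE), B = 7)
  expect_true(all(res$exhaustive))
  expect_equal(res$n_permutations[1], factorial(6))
  # oracle: enumerate all phenotype permutations, coxph LRT per window
  perms <- oraclePermutations(6)
  w <- 2L  # check one window in depth
  x <- burdenScore(sim$ge, res$start_index[w], 3)
  lrtOf <- function(ti, ei) {
    if (sd(x) == 0) return(0)
    f <- suppressWarnings(survival::coxph(survival::Surv(ti, ei) ~ x,
                                          ties = "breslow"))
    max(0, 2 * diff(f$loglik))
  }
  obs <- lrtOf(tt, ev)
  null <- apply(perms, 1, function(p) lrtOf(tt[p], ev[p]))
  expect_equal(res$p_unadjusted[w], mean(null >= obs - 1e-8),
               tolerance = 1e-10)
})

test_that("survival scan output is seed-reproducible and unit-invariant", {
  cfg <- simulationConfig(n_samples = 30, n_variants = 25, seed = 4,
                          causal_window = c(5, 10), survival_log_hr = 0.3)
  sim <- simulateCohort(cfg)
  plan <- scanPlan(10, includeWholeRegion = TRUE)
  a <- survivalScan(sim$ge, sim$survival$time, sim$survival$event, plan,
                    B = 150, seed = 8, exhaustiveCap = 1)
  b <- survivalScan(sim$ge, sim$survival$time, sim$survival$event, plan,
                    B = 150, seed = 8, exhaustiveCap = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # rescaling time units changes nothing (rank-based partial likelihood)
  c <- survivalScan(sim$ge, sim$survival$time * 12, sim$survival$event,
                    plan, B = 150, seed = 8, exhaustiveCap = 1)
  expect_equal(c$statistic, a$statistic)
  expect_equal(c$p_unadjusted, a$p_unadjusted)
  # estimator lower bound and adjusted-dominates-unadjusted
  expect_true(all(a$p_unadjusted >= 1 / 151))
  expect_true(all(a$p_adjusted >= a$p_unadjusted))
  # exactly one whole-region row spanning all variants
  expect_equal(sum(a$whole_region), 1L)
  expect_equal(a$n_markers[a$whole_region], nVariants(sim$ge))
})

test_that("samples with missing survival fields are dropped with a message", {
  cfg <- simulationConfig(n_samples = 12, n_variants = 10, seed = 2)
  sim <- simulateCohort(cfg)
  tt <- sim$survival$time; ev <- sim$survival$event
  tt[3] <- NA
  expect_message(
    res <- survivalScan(sim$ge, tt, ev,
                        plan = scanPlan(5, includeWholeRegion = FALSE),
                        B = 20, exhaustiveCap = 1),
    "dropping 1")
  expect_s4_class(res, "DFrame")
})
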