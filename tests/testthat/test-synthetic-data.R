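test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- simulationConfig(n_samples = 20, n_variants = 30, seed = 5,
                          causal_window = c(10, 5), expression_effect = 0.5,
                          survival_log_hr = 0.2)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosages(a$ge), dosages(b$ge))
  expect_identical(a$probes, b$probes)
  expect_identical(a$survival, b$survival)
  expect_false(identical(
    dosages(a$ge),
    dosages(simulateGenotypes(simulationConfig(n_samples = 20,
                                               n_variants = 30,
                                               seed = 6)))))
})

test_that("default MAF spectrum reproduces the common/rare mixture shape", {
  # frozen oracle baseline over 40 seeds: mean fraction with realized
  # MAF > 1% was 0.825 (sd 0.024), bracketing the 326/404 = 0.807 design
  fr <- vapply(1:8, function(s)
    mean(computeMAF(simulateGenotypes(simulationConfig(seed = 100 + s)))$maf
         > 0.01), 0)
  expect_gt(mean(fr), 0.825 - 4 * 0.024 / sqrt(8))
  expect_lt(mean(fr), 0.825 + 4 * 0.024 / sqrt(8))
  expect_lt(abs(mean(fr) - 326 / 404), 0.06)
})

test_that("block structure creates LD; unit blocks give independence", {
  withinBlockR2 <- function(cfg) {
    ge <- simulateGenotypes(cfg)
    d <- dosages(ge)[1:20, ]
    d <- d[apply(d, 1, sd) > 0, , drop = FALSE]
    cc <- cor(t(d))^2
    mean(cc[upper.tri(cc)])
  }
  ld <- vapply(1:5, function(s)
    withinBlockR2(simulationConfig(seed = 40 + s)), 0)
  indep <- vapply(1:5, function(s)
    withinBlockR2(simulationConfig(seed = 40 + s, ld_block_size = 1)), 0)
  # independence null for r2 at n = 60 is ~ 1/(n-1) = 0.017
  expect_gt(mean(ld), 0.06)
  expect_lt(mean(indep), 0.035)
})

test_that("expression links to the causal burden only through the effect", {
  cfgNull <- simulationConfig(n_samples = 60, n_variants = 40, seed = 1,
                              causal_window = c(10, 10),
                              expression_effect = 0)
  cors <- vapply(1:15, function(s) {
    cfg <- cfgNull; cfg$seed <- 200L + s
    ge <- simulateGenotypes(cfg)
    pr <- simulateExpression(ge, cfg)
    b <- burdenScore(ge, 10, 10, orientation = "alt")
    if (sd(b) == 0) return(0)
    cor(b, rowMeans(pr))
  }, 0)
  expect_lt(abs(mean(cors)), 0.12)
  # zero noise, one probe: probe is exactly affine in the burden
  cfg <- simulationConfig(n_samples = 30, n_variants = 40, seed = 77,
                          causal_window = c(10, 10),
                          expression_effect = 0.7, noise_sd = 0,
                          probe_noise_sd = 0, n_probes = 1)
  ge <- simulateGenotypes(cfg)
  pr <- simulateExpression(ge, cfg)
  b <- burdenScore(ge, 10, 10, orientation = "alt")
  expect_equal(unname(pr[, 1]), cfg$baseline_expression + 0.7 * b)
})

test_that("survival generator honors censoring and the baseline hazard", {
  cfg0 <- simulationConfig(n_samples = 400, n_variants = 5,
                           censoring_rate = 0, seed = 55)
  ge <- simulateGenotypes(cfg0)
  sv <- simulateSurvival(ge, cfg0)
  expect_true(all(sv$event == 1L))
  expect_true(all(sv$time > 0))
  # exponential null: median survival = log(2) / baseline_hazard = 20
  expect_lt(abs(median(sv$time) - 20) / 20, 0.2)
  cfg3 <- simulationConfig(n_samples = 400, n_variants = 5,
                           censoring_rate = 0.3, seed = 56)
  sv3 <- simulateSurvival(ge, cfg3)
  expect_lt(abs(mean(sv3$event == 0L) - 0.3), 0.08)
})

test_that("fixtures round-trip through the package readers", {
  cfg <- simulationConfig(n_samples = 15, n_variants = 25, seed = 8,
                          causal_window = c(5, 10), missing_rate = 0.05)
  dir <- withr::local_tempdir()
  paths <- writeFixture(dir, cfg)
  sim <- simulateCohort(cfg)
  back <- readVCF(paths$vcf)
  expect_identical(dosages(back), dosages(sim$ge))
  expect_equal(variantInfo(back), variantInfo(sim$ge)[names(variantInfo(back))])
  ph <- readPhenotypeTSV(paths$phenotype)
  expect_equal(ph$sample_id, colnames(sim$ge))
  expect_equal(ph$time, sim$survival$time, tolerance = 1e-9)
  expect_equal(ph$event, sim$survival$event)
  cfg2 <- readSimulationConfig(paths$config)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$causal_window, cfg$causal_window)
  # planted BED intervals recover exactly the chosen causal variants
  ann <- readAnnotationBed(paths$bed)
  hit <- annotateTF(sim$ge, ann)
  expect_true(all(hit$id %in% windowVariants(sim$ge, 5, 10)))
  expect_equal(nrow(hit), 5L)
})
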