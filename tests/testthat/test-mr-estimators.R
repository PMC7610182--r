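# Causal estimators and sensitivity diagnostics.

test_that("Wald ratio arithmetic and delta-method options", {
  w <- waldRatio(0.1, 0.01, 0.05, 0.05)
  expect_equal(estimate(w), 0.5)
  expect_equal(stdError(w), 0.5)
  expect_equal(estimate(waldRatio(0.2, 0.01, 0, 0.05)), 0)
  expect_error(waldRatio(0, 0.01, 0.05, 0.05), "zero")
  # second-order inflation term, closed form
  w1 <- waldRatio(0.1, 0.05, 0.05, 0.05)
  w2 <- waldRatio(0.1, 0.05, 0.05, 0.05, second_order = TRUE)
  expect_equal(stdError(w2)^2 - stdError(w1)^2,
               0.05^2 * 0.05^2 / 0.1^4, tolerance = 1e-12)
})

test_that("IVW closed form, degenerate cases, and single-variant delegation", {
  d <- harmonisedDataset(c(0.1, 0.2), 0.01, c(0.05, 0.10), 0.02)
  fit <- mrIVW(d)
  expect_equal(estimate(fit), 0.5, tolerance = 1e-14)
  expect_equal(fit@details$Q, 0, tolerance = 1e-24)

  # identical per-variant ratios reproduce that ratio exactly
  set.seed(1)
  g <- runif(5, 0.05, 0.2)
  d2 <- harmonisedDataset(g, 0.01, 1.7 * g, runif(5, 0.01, 0.05))
  expect_equal(estimate(mrIVW(d2)), 1.7, tolerance = 1e-12)
  expect_equal(cochranQ(d2)$Q, 0, tolerance = 1e-20)

  # one variant: IVW is the Wald ratio
  d1 <- harmonisedDataset(0.1, 0.01, 0.07, 0.03)
  expect_equal(estimate(mrIVW(d1)), estimate(waldRatio(0.1, 0.01, 0.07,
                                                       0.03)))
  expect_equal(mrMethod(mrIVW(d1)), "Wald")
})

test_that("IVW and Egger equal generic weighted least squares on random data", {
  for (s in 1:10) {
    d <- rand_dataset(J = 12, seed = 1000 + s)
    u <- smokemr:::.unpack(d)
    w <- 1 / u$sG^2
    expect_equal(estimate(mrIVW(d)), wls_origin_oracle(u$g, u$G, w),
                 tolerance = 1e-12)
    # Egger canonically orients gamma > 0 first
    flip <- sign(u$g)
    co <- wls_intercept_oracle(u$g * flip, u$G * flip, w)
    e <- mrEgger(d)
    expect_equal(e@details$intercept, co[1], tolerance = 1e-12)
    expect_equal(estimate(e), co[2], tolerance = 1e-12)
  }
})

test_that("Egger recovers exact linear data and refuses tiny sets", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  d <- harmonisedDataset(g, 0.01, 0.02 + 0.5 * g, 0.02)
  e <- mrEgger(d)
  expect_equal(estimate(e), 0.5, tolerance = 1e-12)
  expect_equal(e@details$intercept, 0.02, tolerance = 1e-12)
  expect_error(mrEgger(harmonisedDataset(g[1:2], 0.01, g[1:2], 0.02)),
               "at least 3")
})

test_that("I2_GX spans its limits and matches the direct formula", {
  # no spread at all: clamped to zero
  expect_equal(i2GX(rep(0.1, 5), rep(0.01, 5)), 0)
  # vanishing measurement error with distinct effects: approaches one
  expect_gt(i2GX(c(0.1, 0.2, 0.3), rep(1e-6, 3)), 0.999999)
  # random instance against an inline recomputation
  set.seed(42)
  g <- rnorm(20, 0.1, 0.05); sg <- runif(20, 0.005, 0.02)
  w <- 1 / sg^2
  Qgx <- sum(w * (abs(g) - weighted.mean(abs(g), w))^2)
  expect_equal(i2GX(g, sg), max(0, (Qgx - 19) / Qgx), tolerance = 1e-12)
  expect_true(i2GX(g, sg) >= 0 && i2GX(g, sg) <= 1)
})

test_that("mean F and Cochran's Q match their formulas", {
  expect_equal(meanF(0.1, 0.01), 100)
  expect_equal(meanF(c(0.1, 0.1 * sqrt(3)), c(0.01, 0.01)), 200)
  set.seed(43)
  d <- rand_dataset(15, seed = 43)
  u <- smokemr:::.unpack(d)
  expect_equal(meanF(d), mean((u$g / u$sg)^2), tolerance = 1e-12)
  q <- cochranQ(d, beta = 0.4)
  expect_equal(q$Q, sum((u$G - 0.4 * u$g)^2 / u$sG^2), tolerance = 1e-12)
  expect_equal(q$df, 14)
  expect_equal(q$pval, pchisq(q$Q, 14, lower.tail = FALSE))
})

test_that("Cochran's Q is calibrated under the correct model", {
  set.seed(44)
  qs <- replicate(500, {
    J <- 10
    g <- rnorm(J, 0.1, 0.03); sG <- runif(J, 0.02, 0.05)
    G <- 0.5 * g + rnorm(J, 0, sG)
    cochranQ(harmonisedDataset(g, 1e-8, G, sG))$Q
  })
  # Q ~ chi-square(J-1) up to the one estimated parameter
  expect_equal(mean(qs), 9, tolerance = 0.1)
})

test_that("weighted median follows cumulative-weight crossing and its oracle", {
  d <- harmonisedDataset(c(1, 1, 1), 0.01, c(1, 2, 3), 1)
  expect_equal(estimate(mrWeightedMedian(d, n_boot = 0)), 2)
  # weight concentrated on one variant pulls the median onto its ratio
  d2 <- harmonisedDataset(c(1, 1, 1), 0.01, c(1, 2, 3),
                          c(1e3, 1e3, 1e-3))
  expect_equal(estimate(mrWeightedMedian(d2, n_boot = 0)), 3,
               tolerance = 1e-3)
  for (s in 1:25) {
    set.seed(2000 + s)
    J <- sample(3:15, 1)
    r <- rnorm(J); w <- runif(J, 0.1, 5)
    expect_equal(smokemr:::.weighted_median(r, w),
                 weighted_median_oracle(r, w), tolerance = 1e-12)
  }
  # bootstrap SE is reproducible under a fixed seed
  d3 <- rand_dataset(10, seed = 3)
  m1 <- mrWeightedMedian(d3, n_boot = 50, seed = 9)
  m2 <- mrWeightedMedian(d3, n_boot = 50, seed = 9)
  expect_equal(stdError(m1), stdError(m2))
  expect_error(mrWeightedMedian(d3, n_boot = 10), "seed")
})

test_that("weighted mode picks the plurality ratio and resists outliers", {
  # six variants agreeing on 0.5, one wild outlier
  g <- rep(0.1, 7)
  G <- c(rep(0.05, 6), 0.5)
  d <- harmonisedDataset(g, 0.01, G, 0.02)
  expect_equal(estimate(mrWeightedMode(d, n_boot = 0)), 0.5,
               tolerance = 0.05)
  # bandwidth shrunk towards zero: the highest-weight ratio wins
  d2 <- harmonisedDataset(c(0.1, 0.1, 0.1), 0.01, c(0.03, 0.05, 0.08),
                          c(0.03, 0.01, 0.03))
  expect_equal(estimate(mrWeightedMode(d2, bandwidth_factor = 1e-6,
                                       n_boot = 0)), 0.5,
               tolerance = 1e-6)
  # a dispersed cluster plus an outlier: estimate stays within the cluster
  set.seed(45)
  g3 <- runif(12, 0.08, 0.2)
  G3 <- 0.5 * g3 + rnorm(12, 0, 0.002)
  G3[1] <- 2 * g3[1]
  d3 <- harmonisedDataset(g3, 0.01, G3, 0.02)
  expect_lt(abs(estimate(mrWeightedMode(d3, n_boot = 0)) - 0.5), 0.1)
})

test_that("RAPS reduces to fixed-effect IVW without exposure noise and handles degenerate data", {
  d <- rand_dataset(20, seed = 46)
  u <- smokemr:::.unpack(d)
  no_x_noise <- harmonisedDataset(u$g, 1e-12, u$G, u$sG)
  raps <- mrRAPS(no_x_noise)
  ivw_fe <- mrIVW(no_x_noise, robust = "fixed")
  expect_equal(estimate(raps), estimate(ivw_fe), tolerance = 1e-8)

  # all outcome effects zero: estimate collapses to zero
  d0 <- harmonisedDataset(c(0.1, 0.15, 0.2), 0.01, c(0, 0, 0), 0.02)
  expect_equal(estimate(mrRAPS(d0)), 0, tolerance = 1e-8)

  # huber loss and overdispersion converge on well-behaved data
  rob <- mrRAPS(d, overdispersion = TRUE, loss = "huber")
  expect_true(is.finite(estimate(rob)))
  expect_gte(rob@details$tau2, 0)
  expect_error(mrRAPS(harmonisedDataset(c(0.1, 0.2), 0.01, c(0, 0),
                                        0.02)),
               ">= 3")
})

test_that("SIMEX collapses correctly when there is nothing to correct", {
  d <- rand_dataset(15, seed = 47)
  u <- smokemr:::.unpack(d)
  # no exposure measurement error: corrected slope equals the plain
  # unweighted Egger slope
  clean <- harmonisedDataset(u$g, 0, u$G, u$sG)
  sx <- mrSIMEXEgger(clean, n_boot = 50, seed = 5)
  flip <- sign(u$g)
  naive <- unname(coef(lm(I(u$G * flip) ~ I(u$g * flip)))[2])
  expect_equal(estimate(sx), naive, tolerance = 1e-8)
  # single-lambda grid: the observed-noise estimate is returned as is
  one <- mrSIMEXEgger(d, lambda_grid = 0, n_boot = 10, seed = 5)
  u2 <- smokemr:::.unpack(d)
  flip2 <- sign(u2$g)
  expect_equal(estimate(one),
               unname(coef(lm(I(u2$G * flip2) ~ I(u2$g * flip2)))[2]),
               tolerance = 1e-10)
  expect_error(mrSIMEXEgger(d, n_boot = 10), "seed")
})

test_that("Steiger filtering orients variants and removes reverse-direction ones", {
  d <- harmonisedDataset(
    gamma_hat = c(0.2, 0.01, 0.1), gamma_se = 0.01,
    Gamma_hat = c(0.001, 0.3, 0.1), Gamma_se = 0.01,
    eaf_exposure = 0.3, eaf_outcome = 0.3)
  st <- steigerFilter(d, exposure_n = 1e5, outcome_n = 1e5)
  # strong exposure effect, null outcome effect: correct direction
  expect_true(st$flags$correct_direction[1])
  # the opposite pattern: wrong direction, filtered out
  expect_false(st$flags$correct_direction[2])
  expect_true("snp_2" %in% droppedSnps(st$filtered)$snp)
  # equal variance explained: indeterminate but retained
  expect_true(st$flags$indeterminate[3])
  expect_true("snp_3" %in% snpIds(st$filtered))
  expect_equal(nSnp(st$filtered), 2)

  # missing allele frequency: excluded from filtering but retained
  d2 <- harmonisedDataset(0.2, 0.01, 0.001, 0.01)
  expect_message(st2 <- steigerFilter(d2, 1e5, 1e5), "missing allele")
  expect_true(is.na(st2$flags$correct_direction))
  expect_equal(nSnp(st2$filtered), 1)
})

test_that("Steiger correctly orients a simulated exposure-to-outcome system", {
  share_at <- function(scale_n, s) {
    cfg <- simulationConfig(theta = log(2), n_snp = 50,
                            n_exposure = 462690 * scale_n,
                            n_outcome = 150064 * scale_n,
                            palindromic_frac = 0, swap_frac = 0,
                            strand_flip_frac = 0, seed = 500 + s)
    sim <- simulateSummaryStats(cfg)
    steigerFilter(truthDataset(sim), cfg$n_exposure,
                  cfg$n_outcome)$overall$share_correct
  }
  base <- vapply(1:5, function(s) share_at(1, s), numeric(1))
  mid <- vapply(1:5, function(s) share_at(25, s), numeric(1))
  large <- vapply(1:5, function(s) share_at(625, s), numeric(1))
  # a majority points the right way at realistic sample sizes, and the
  # correctly-flagged fraction approaches one as sampling noise shrinks
  expect_true(all(base > 0.6))
  expect_true(all(mid > 0.85))
  expect_true(all(large > 0.95))
  expect_gt(mean(mid), mean(base))
  expect_gte(mean(large), mean(mid))
})

test_that("estimators are equivariant to outcome rescaling and orientation flips", {
  d <- rand_dataset(12, seed = 48)
  u <- smokemr:::.unpack(d)
  k <- 3.7
  dk <- harmonisedDataset(u$g, u$sg, k * u$G, k * u$sG)
  for (fit in list(mrIVW, mrEgger,
                   function(x) mrWeightedMedian(x, n_boot = 0),
                   function(x) mrWeightedMode(x, n_boot = 0),
                   mrRAPS)) {
    a <- fit(d); b <- fit(dk)
    expect_equal(estimate(b), k * estimate(a), tolerance = 1e-6)
    if (!is.na(stdError(a)))
      expect_equal(stdError(b), k * stdError(a), tolerance = 1e-5)
  }

  # jointly sign-flipping (gamma, Gamma) pairs changes nothing
  set.seed(49)
  flip <- sample(c(-1, 1), 12, replace = TRUE)
  df <- harmonisedDataset(flip * u$g, u$sg, flip * u$G, u$sG)
  expect_equal(estimate(mrIVW(df)), estimate(mrIVW(d)), tolerance = 1e-12)
  expect_equal(estimate(mrEgger(df)), estimate(mrEgger(d)),
               tolerance = 1e-12)
  expect_equal(estimate(mrWeightedMedian(df, n_boot = 0)),
               estimate(mrWeightedMedian(d, n_boot = 0)),
               tolerance = 1e-12)
  expect_equal(estimate(mrRAPS(df)), estimate(mrRAPS(d)),
               tolerance = 1e-8)
})

test_that("runMR assembles the battery, annotates failures, and honours exclusions", {
  sim <- simulateSummaryStats(simulationConfig(
    theta = log(2), n_snp = 30, palindromic_frac = 0, swap_frac = 0,
    strand_flip_frac = 0, seed = 60))
  d <- truthDataset(sim)
  res <- runMR(d, outcome_type = "binary",
               config = mrConfig(seed = 1, n_boot = 30))
  est <- res$estimates
  expect_true(all(c("IVW", "Egger", "Weighted median", "Weighted mode",
                    "RAPS") %in% est$method))
  expect_true(all(c("or", "or_ci_low", "or_ci_high") %in% names(est)))
  expect_equal(est$or, exp(est$beta))
  expect_true(all(est$ci_low < est$beta & est$beta < est$ci_high))
  expect_equal(unique(est$n_snp), 30L)
  expect_false(is.null(res$diagnostics$mean_f))

  # single variant: only the Wald row
  d1 <- harmonisedDataset(0.1, 0.01, 0.07, 0.03)
  r1 <- runMR(d1, "continuous", mrConfig(seed = 1))
  expect_equal(r1$estimates$method, "Wald")

  # two variants: IVW works, the others are annotated, nothing aborts
  d2 <- harmonisedDataset(c(0.1, 0.2), 0.01, c(0.05, 0.1), 0.02)
  r2 <- runMR(d2, "continuous", mrConfig(seed = 1))
  expect_true("IVW" %in% r2$estimates$method)
  notes <- r2$estimates$note[r2$estimates$method == "RAPS"]
  expect_match(notes, ">= 3")

  # named exclusions shrink the instrument count and are logged as drops
  res_ex <- runMR(d, "binary",
                  mrConfig(seed = 1, n_boot = 30,
                           exclude_snps = snpIds(d)[1:5]))
  expect_equal(unique(res_ex$estimates$n_snp), 25L)
})
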