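test_that("noiseless exponential traces are recovered to 6 digits", {
  t <- seq(0, 600, by = 25)
  y_assoc <- 50 + (150 - 50) * (1 - exp(-0.01 * t))
  fa <- fit_exponential(fp_trace(t, y_assoc), "association")
  expect_equal(fa$K, 0.01, tolerance = 1e-8)
  expect_equal(fa$Y0, 50, tolerance = 1e-8)
  expect_equal(fa$plateau, 150, tolerance = 1e-8)
  # dissociation with the same parameters reversed gives the same K
  y_diss <- (150 - 50) * exp(-0.01 * t) + 50
  fd <- fit_exponential(fp_trace(t, y_diss), "dissociation")
  expect_equal(fd$K, 0.01, tolerance = 1e-8)
  expect_equal(fd$Y0, 150, tolerance = 1e-6)
  expect_equal(fd$plateau, 50, tolerance = 1e-6)
})

test_that("exponential rate estimates are unbiased under noise", {
  K <- 0.004
  est <- vapply(1:50, function(s) {
    tr <- simulate_fp_timecourses(fp_truth(100, noise_sd = 2), 500,
                                  fp_design_times(0.005), "association",
                                  seed = s)[[1]]
    fit_exponential(tr, "association")$K
  }, numeric(1))
  k_true <- 1e4 * 500e-9 + 100e-9 * 1e4
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - k_true), 2 * se + 1e-12)
})

test_that("generator k_obs is recovered exactly from noiseless traces", {
  truth <- fp_truth(38, k_a = 1e4, noise_sd = 0)
  concs <- c(0.25, 1, 4) * 38
  for (P in concs) {
    k_exp <- 1e4 * P * 1e-9 + truth$k_d
    tr <- simulate_fp_timecourses(truth, P, fp_design_times(k_exp),
                                  "association", seed = 1)[[1]]
    expect_equal(fit_exponential(tr, "association")$K, k_exp,
                 tolerance = 1e-7)
  }
})

test_that("association traces start at mP_free; [P]=0 traces are flat", {
  truth <- fp_truth(38, noise_sd = 0)
  tr0 <- simulate_fp_timecourses(truth, 0, seq(0, 1000, length.out = 11),
                                 "association", seed = 1)[[1]]
  expect_true(all(tr0$mP == truth$mP_free))
  expect_error(simulate_fp_timecourses(truth, -5, c(0, 1, 2, 3),
                                       "association"), "negative")
})

test_that("k_obs line gives exact OLS coefficients and delta-method K_D", {
  # exact line: k_a = 1e4 M^-1 s^-1, k_d = 9e-5 s^-1 -> K_D = 9 nM
  concs <- c(5, 10, 20, 40, 80)
  kobs <- 1e4 * concs * 1e-9 + 9e-5
  kf <- kinetic_kd(data.frame(protein_nM = concs, kobs = kobs))
  expect_equal(kf$k_a, 1e4, tolerance = 1e-9)
  expect_equal(kf$k_d, 9e-5, tolerance = 1e-9)
  expect_equal(kf$K_D, 9, tolerance = 1e-9)
  # two points define the line exactly
  k2 <- kinetic_kd(data.frame(protein_nM = c(10, 100),
                              kobs = 1e4 * c(10, 100) * 1e-9 + 2e-4))
  expect_equal(k2$K_D, 20, tolerance = 1e-9)
  # noisy line against the closed-form normal equations
  set.seed(5)
  for (i in 1:10) {
    x <- sort(runif(8, 1, 300))
    y <- 3e-6 * x + 1e-4 + rnorm(8, 0, 2e-5)
    got <- kinetic_kd(data.frame(protein_nM = x, kobs = abs(y)))
    yy <- abs(y)
    slope <- (mean(x * yy) - mean(x) * mean(yy)) / (mean(x^2) - mean(x)^2)
    icpt <- mean(yy) - slope * mean(x)
    expect_equal(got$k_d, icpt, tolerance = 1e-10)
    expect_equal(got$k_a, slope * 1e9, tolerance = 1e-10)
  }
})

test_that("negative intercepts are flagged, not silently returned", {
  df <- data.frame(protein_nM = c(10, 20, 40), kobs = c(1e-4, 3e-4, 7e-4))
  expect_warning(kf <- kinetic_kd(df), "negative intercept")
  expect_true(is.na(kf$K_D))
})

test_that("noiseless saturation isotherms are recovered exactly", {
  x <- 38 * 2^seq(-4, 5)
  crv <- dose_response_curve(x, 100 * x / (38 + x))
  f <- fit_saturation(crv, probe_conc = 1, model = "simple")
  expect_equal(f$Kd, 38, tolerance = 1e-8)
  expect_equal(f$Bmax, 100, tolerance = 1e-8)
  expect_error(fit_saturation(dose_response_curve(x, rep(5, length(x)))),
               "no binding signal")
})

test_that("probe depletion biases the naive fit; the quadratic fixes it", {
  # truth 9 nM at 25 nM probe: the free-ligand hyperbola overestimates K_D
  truth <- fp_truth(9, probe_conc = 25, noise_sd = 0)
  iso <- simulate_binding_isotherm(truth, 9 * 2^seq(-4, 6), depletion = "on")
  expect_warning(naive <- fit_saturation(iso, probe_conc = 25, "simple"),
                 "depletion")
  expect_gt(naive$Kd, 9 * 1.5)
  aware <- fit_saturation(iso, probe_conc = 25, "depletion")
  expect_equal(aware$Kd, 9, tolerance = 1e-6)
  # at probe 1 nM << K_D the two isotherm models agree above 3 K_D
  t1 <- fp_truth(9, probe_conc = 1, noise_sd = 0)
  x <- 9 * c(3, 4, 8, 16, 32)
  on  <- simulate_binding_isotherm(t1, x, "on")
  off <- simulate_binding_isotherm(t1, x, "off")
  expect_true(all(abs(on$responses - off$responses) / off$responses < 0.05))
})

test_that("isotherm generator: half-saturation at X = Kd without depletion", {
  truth <- fp_truth(40, noise_sd = 0)
  iso <- simulate_binding_isotherm(truth, c(0, 10, 40, 160, 1e4), "off")
  expect_equal(iso$responses[3], (truth$mP_bound - truth$mP_free) / 2)
  expect_true(all(diff(iso$responses) > 0))
  expect_true(all(iso$responses <= truth$mP_bound - truth$mP_free))
})

test_that("double-reciprocal diagnostic recovers the hyperbola parameters", {
  x <- c(5, 10, 20, 40, 80, 160)
  crv <- dose_response_curve(x, 100 * x / (38 + x))
  f <- fit_saturation(crv, model = "double_reciprocal")
  expect_equal(f$Kd, 38, tolerance = 1e-6)
  expect_equal(f$Bmax, 100, tolerance = 1e-6)
})

test_that("concordance report flags discordant K_D sets", {
  good <- kd_concordance(c(9, 9, 9))
  expect_equal(good$max_fold_difference, 1)
  expect_true(good$pass)
  bad <- kd_concordance(c(9, 20))
  expect_false(bad$pass)
  expect_equal(bad$geometric_mean_nM, sqrt(180))
})

test_that("minute-based traces yield the same K_D as second-based input", {
  truth <- fp_truth(38, noise_sd = 0)
  concs <- 38 * c(0.5, 1, 2, 4)
  kobs_s <- vapply(seq_along(concs), function(i) {
    k <- 1e4 * concs[i] * 1e-9 + truth$k_d
    tr <- simulate_fp_timecourses(truth, concs[i], fp_design_times(k),
                                  "association", seed = i)[[1]]
    fit_exponential(tr, "association")$K
  }, numeric(1))
  kobs_min <- vapply(seq_along(concs), function(i) {
    k <- 1e4 * concs[i] * 1e-9 + truth$k_d
    tt <- fp_design_times(k)
    tr <- simulate_fp_timecourses(truth, concs[i], tt, "association",
                                  seed = i)[[1]]
    tr_min <- fp_trace(tr$times / 60, tr$mP, tr$protein_conc,
                       time_unit = "min")
    per_min_to_per_s(per_s_to_per_min(fit_exponential(tr_min,
                                                      "association")$K))
  }, numeric(1))
  kd_s <- kinetic_kd(data.frame(protein_nM = concs, kobs = kobs_s))$K_D
  kd_m <- kinetic_kd(data.frame(protein_nM = concs, kobs = kobs_min))$K_D
  expect_equal(kd_m, kd_s, tolerance = 1e-9)
})

test_that("k_obs is linear in concentration with slope k_a (noiseless)", {
  kin <- fp_kinetic_pipeline(fp_truth(38, noise_sd = 0), seed = 1)
  expect_gt(kin$r_squared, 0.999999)
  expect_equal(kin$k_a, 1e4, tolerance = 1e-5)
  expect_equal(kin$K_D, 38, tolerance = 1e-5)
})
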