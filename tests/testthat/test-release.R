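# Cumulative release, kinetic fits, transport classification, AUC,
# centering and Spearman correlation.

test_that("cumulative release follows both summation modes", {
  expect_equal(cumulative_release(rep(0, 5), 1:5, V = 10, M = 1)$release, rep(0, 5))
  # single point: C = 0.05 mg/mL, V = 10 mL, M = 1 mg -> 50%
  one <- cumulative_release(0.05, times = 1, V = 10, M = 1, replace = FALSE)
  expect_equal(one$release, 50)
  # corrected >= uncorrected, equal when nothing is withdrawn
  conc <- c(0.02, 0.03)
  corr <- cumulative_release(conc, 1:2, V = 10, M = 2, withdrawn = 1)
  raw <- cumulative_release(conc, 1:2, V = 10, M = 2, replace = FALSE)
  none <- cumulative_release(conc, 1:2, V = 10, M = 2, withdrawn = 0)
  expect_true(all(corr$release >= none$release - 1e-12))
  expect_equal(corr$release[1], none$release[1])
  expect_gt(corr$release[2], none$release[2])
  expect_true(raw$meta$withdrawal_corrected == FALSE &&
                corr$meta$withdrawal_corrected == TRUE)
  expect_warning(cumulative_release(c(0.3, 0.3), 1:2, V = 10, M = 1),
                 "mass balance")
})

test_that("noiseless model curves are recovered exactly", {
  # zero order on an exact line
  zp <- gen_release_curve("zero_order", list(k0 = 0.06), times = 1:6, seed = 1)
  zf <- fit_kinetics(zp, "zero_order")
  expect_equal(unname(coef(zf)), 0.06, tolerance = 1e-12)
  expect_equal(zf$r2, 1)
  # first order
  fp <- gen_release_curve("first_order", list(k1 = 0.18), times = c(1, 2, 4, 8, 12, 24), seed = 1)
  expect_equal(unname(coef(fit_kinetics(fp, "first_order"))), 0.18, tolerance = 1e-7)
  # Higuchi
  hp <- gen_release_curve("higuchi", list(kH = 0.24), times = c(1, 2, 4, 8, 12), seed = 1)
  expect_equal(unname(coef(fit_kinetics(hp, "higuchi"))), 0.24, tolerance = 1e-12)
  # Korsmeyer-Peppas round trip at a bundled parameter pair
  kp <- gen_release_curve("korsmeyer_peppas", list(kKP = 0.370, n = 0.256),
                          times = c(1, 2, 4, 8, 12, 24), seed = 1)
  kf <- fit_kinetics(kp, "korsmeyer_peppas")
  expect_equal(coef(kf)[["n"]], 0.256, tolerance = 1e-7)
  expect_equal(coef(kf)[["kKP"]], 0.370, tolerance = 1e-7)
  expect_equal(kf$mechanism, "Fickian")
})

test_that("power law at n = 0.5 coincides with Higuchi", {
  tt <- c(1, 2, 4, 8, 12)
  kp <- gen_release_curve("korsmeyer_peppas", list(kKP = 0.2, n = 0.5), times = tt, seed = 1)
  hg <- gen_release_curve("higuchi", list(kH = 0.2), times = tt, seed = 1)
  expect_equal(kp$release, hg$release, tolerance = 1e-12)
  f1 <- fit_kinetics(kp, "korsmeyer_peppas")
  f2 <- fit_kinetics(kp, "higuchi")
  expect_equal(residuals(f1), residuals(f2), tolerance = 1e-6)
})

test_that("first order approaches zero order for small k t", {
  tt <- seq(0.5, 3, by = 0.5)
  fp <- gen_release_curve("first_order", list(k1 = 0.01), times = tt, seed = 1)
  zf <- fit_kinetics(fp, "zero_order")
  # series expansion: 1 - exp(-kt) = kt (1 - kt/2 + ...)
  expect_equal(unname(coef(zf)), 0.01, tolerance = 0.02)
})

test_that("noisy parameter recovery stays within its sampling error", {
  tt <- c(1, 2, 4, 8, 12, 24)
  sigma_frac <- 0.02
  # analytic SD of the through-origin OLS slope under iid noise; the
  # grid keeps the noisy curve clear of both truncation ends
  tz <- c(2, 4, 8, 12, 16)
  sd_k0 <- sigma_frac / sqrt(sum(tz^2))
  k0 <- sapply(1:20, function(s) {
    p <- gen_release_curve("zero_order", list(k0 = 0.04), times = tz,
                           noise_sd = 100 * sigma_frac, seed = s)
    coef(fit_kinetics(p, "zero_order"))[["k0"]]
  })
  expect_true(all(abs(k0 - 0.04) < 4 * sd_k0))
  sd_kH <- sigma_frac * sqrt(sum(tt)) / sum(tt) # slope on sqrt(t) regressor
  kH <- sapply(1:20, function(s) {
    p <- gen_release_curve("higuchi", list(kH = 0.1), times = tt,
                           noise_sd = 100 * sigma_frac, seed = s)
    coef(fit_kinetics(p, "higuchi"))[["kH"]]
  })
  expect_true(all(abs(kH - 0.1) < 4 * sd_kH))
  # nonlinear models: the 20-seed mean must sit within 3 standard errors
  ns <- sapply(1:20, function(s) {
    p <- gen_release_curve("korsmeyer_peppas", list(kKP = 0.3, n = 0.35),
                           times = tt, noise_sd = 2, seed = s)
    coef(fit_kinetics(p, "korsmeyer_peppas"))[["n"]]
  })
  expect_lt(abs(mean(ns) - 0.35), 3 * sd(ns) / sqrt(20))
})

test_that("transport classification brackets the Fickian bound", {
  expect_equal(classify_transport(0.27), "Fickian")
  expect_equal(classify_transport(0.5), "case-II-boundary/Higuchi")
  expect_equal(classify_transport(0.75), "anomalous")
  expect_equal(classify_transport(1.2), "super-case-II")
  expect_error(classify_transport(0), "must be > 0")
})

test_that("release AUC is exact on piecewise-linear profiles", {
  # constant release R over [1, 24] -> 23 R
  const <- release_profile(c(0.5, 1, 6, 24), rep(40, 4))
  expect_equal(auc_release(const), 23 * 40)
  # linear ramp R(t) = t -> (24^2 - 1)/2
  ramp <- release_profile(c(1, 4, 24), c(1, 4, 24))
  expect_equal(auc_release(ramp), (24^2 - 1^2) / 2)
  # endpoint interpolation: grid not containing t = 1 or 24
  ramp2 <- release_profile(c(0.5, 2, 10, 30), c(0.5, 2, 10, 30))
  expect_equal(auc_release(ramp2), 287.5)
  # refinement does not change a piecewise-linear integral
  t_coarse <- c(1, 5, 24); y <- c(10, 35, 80)
  fine_t <- sort(unique(c(seq(1, 24, by = 0.25), t_coarse)))
  fine_y <- approx(t_coarse, y, xout = fine_t)$y
  expect_equal(auc_release(release_profile(t_coarse, y)),
               auc_release(release_profile(fine_t, fine_y)), tolerance = 1e-9)
  expect_error(auc_release(release_profile(c(2, 5), c(1, 2))),
               "outside the sampled range")
})

test_that("within-material centering leaves zero group means and is idempotent", {
  rec <- data.frame(polymer = rep(c("A", "B"), each = 3),
                    v1 = c(9, 10, 11, 19, 20, 21),
                    v2 = c(5, 5, 5, 7, 7, 7))
  cen <- center_within_material(rec)
  for (g in c("A", "B")) {
    expect_equal(mean(cen$v1[cen$polymer == g]), 0)
    expect_equal(mean(cen$v2[cen$polymer == g]), 0)
  }
  expect_equal(cen$v2, rep(0, 6)) # constant variable centers to zero
  expect_equal(center_within_material(cen), cen)
  # single material behaves like global centering
  single <- center_within_material(rec[1:3, ])
  expect_equal(single$v1, rec$v1[1:3] - mean(rec$v1[1:3]))
  # missing values are dropped with a message
  rec$v1[2] <- NA
  expect_message(out <- center_within_material(rec), "dropping 1")
  expect_equal(nrow(out), 5)
})

test_that("Spearman correlation endpoints, ties and invariances", {
  x <- 1:8
  expect_equal(spearman_correlation(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_correlation(x, rev(x))$rho, -1)
  # tied example against independent mid-rank computation
  xt <- c(1, 2, 2, 3, 5)
  yt <- c(2, 1, 4, 4, 6)
  res <- spearman_correlation(xt, yt)
  expect_equal(res$rho, cor(brute_force_midranks(xt), brute_force_midranks(yt)))
  # invariance under strictly monotone transforms
  set.seed(8)
  a <- rnorm(12); b <- rnorm(12)
  base <- spearman_correlation(a, b)$rho
  expect_equal(spearman_correlation(exp(a), b)$rho, base)
  expect_equal(spearman_correlation(a, b^3 + 10 * b)$rho, base)
  # t-approximation p-value agrees with the closed form
  r <- base; n <- 12
  p_manual <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_equal(spearman_correlation(a, b)$p_value, p_manual)
  # exact permutation p for small n is a valid probability and
  # detects perfect association
  ex <- spearman_correlation(1:5, c(2, 3, 5, 7, 11), exact = TRUE)
  expect_equal(ex$rho, 1)
  expect_equal(ex$p_value, 2 / factorial(5)) # only the two perfect orders
  expect_error(spearman_correlation(rep(1, 5), 1:5), "zero rank variance")
})

test_that("descriptor-release correlation plumbing joins and centers", {
  desc <- nanogel_descriptors()
  set.seed(21)
  desc$auc_1_24h <- 10 * desc$mpd_A + rnorm(16, sd = 5)
  res <- correlate_descriptor(desc, "mpd_A")
  expect_equal(res$n, 16)
  expect_gt(res$rho, 0.5)
  expect_lt(res$p_value, 0.05)
})
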