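# Minimum-distance series, dissociated fraction, MSD/diffusion,
# radial density, hydrogen bonds.

test_that("minimum-distance series matches hand values and brute force", {
  # constant scenario: every molecule at its constructed radius
  tr <- gen_dissociation_scenario(n_total = 6, n_free = 2, cutoff = 5,
                                  margin = 1, n_frames = 3, seed = 2)
  s <- min_distance_series(tr)
  expect_equal(dim(s), c(6, 3))
  expect_equal(unname(s[, 1]), c(6, 6, 4, 4, 4, 4), tolerance = 1e-9)
  expect_equal(s[, 1], s[, 3])

  # two-frame toy with distances 3 and 7
  coords <- array(0, c(2, 3, 2))
  coords[1, , ] <- 5
  coords[2, , 1] <- c(8, 5, 5); coords[2, , 2] <- c(12, 5, 5)
  toy <- trajectory(coords, c(0, 10), rep(50, 3),
                    groups = list(polymer = 1L, drug = list(2L)))
  s2 <- min_distance_series(toy)
  expect_equal(unname(s2[1, ]), c(3, 7))
  expect_equal(mean(s2), 5)

  # periodic straddling vs 27-image brute force
  set.seed(3)
  box <- rep(10, 3)
  coords <- array(runif(12 * 3 * 2, 0, 10), c(12, 3, 2))
  tr2 <- trajectory(coords, c(0, 1), box,
                    groups = list(polymer = 1:9, drug = list(10L, 11L, 12L)))
  s3 <- min_distance_series(tr2)
  for (f in 1:2) for (m in 1:3) {
    expect_equal(unname(s3[m, f]),
                 brute_min_image_dist(coords[9 + m, , f], coords[1:9, , f], box),
                 tolerance = 1e-9)
  }
  expect_error(min_distance_series(toy, drug = list()), "empty selection")
})

test_that("dissociated fraction classifies by the strict average-distance rule", {
  tr <- gen_dissociation_scenario(50, 11, seed = 1)
  fd <- dissociated_fraction(tr)
  expect_equal(fd$fraction, 22)
  expect_equal(unname(fd$dissociated), attr(tr, "truth")$dissociated)

  expect_equal(dissociated_fraction(gen_dissociation_scenario(50, 0, seed = 2))$fraction, 0)
  expect_equal(dissociated_fraction(gen_dissociation_scenario(50, 6, seed = 3))$fraction, 12)

  # boundary: exactly at the cutoff is retained
  tr0 <- gen_dissociation_scenario(10, 4, margin = 0, seed = 4)
  expect_equal(dissociated_fraction(tr0)$fraction, 0)

  # attainable values are multiples of 100/N
  for (nf in c(0, 1, 7, 23, 50)) {
    f <- dissociated_fraction(gen_dissociation_scenario(50, nf, seed = nf + 1))$fraction
    expect_equal(f, 2 * nf)
    expect_equal(f %% 2, 0)
  }
})

test_that("MSD closed forms: stationary, ballistic, Brownian", {
  # stationary
  tr0 <- gen_brownian(0, n_mol = 5, n_steps = 50, seed = 1)
  expect_lt(max(msd(tr0)$msd), 1e-8)

  # ballistic r = v t: MSD(t) = v^2 t^2, poorly described by a line
  n <- 100; v <- c(0.3, -0.2, 0.1)
  coords <- array(0, c(2, 3, n))
  for (f in 1:n) { coords[1, , f] <- 50; coords[2, , f] <- 50 + v * (f - 1) }
  trb <- trajectory(coords, 0:(n - 1), rep(1000, 3),
                    groups = list(polymer = 1L, drug = list(2L)), unwrapped = TRUE)
  mb <- msd(trb, max_lag = n - 2)
  expect_equal(mb$msd, sum(v^2) * mb$lags^2, tolerance = 1e-9)
  full_fit <- fit_diffusion(mb, window = c(0, n - 2))
  expect_lt(full_fit$r2, 0.99)

  # Brownian with known D: slope/6 recovers D (tolerance ~2x the
  # per-seed sampling SD of this estimator at these sizes)
  trd <- gen_brownian(2.5, n_mol = 50, n_steps = 5000, seed = 7)
  est <- fit_diffusion(msd(trd))
  expect_equal(est$D, 2.5, tolerance = 0.12)
  expect_gt(est$r2, 0.95)

  expect_error(msd(trajectory(array(0, c(1, 3, 3)), 0:2, rep(10, 3),
                              groups = list(drug = list(1L)))),
               "wrap ambiguity")
})

test_that("MSD is invariant under global rotation and translation", {
  tr <- gen_brownian(1.5, n_mol = 8, n_steps = 400, seed = 9)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  tr2 <- tr
  for (f in seq_along(tr$times)) {
    tr2$coords[, , f] <- tr$coords[, , f] %*% rot + 3
  }
  expect_equal(msd(tr)$msd, msd(tr2)$msd, tolerance = 1e-9)
})

test_that("diffusion fit converts units correctly", {
  # exact line msd = 6 * 0.92e-3 * t (A^2 with t in ps) -> 0.92e-7 cm^2/s
  lags <- 0:100
  curve <- structure(list(lags = lags, msd = 6 * 0.92e-3 * lags,
                          n_origins = rep(100, 101)), class = "msd_curve")
  est <- fit_diffusion(curve, window = c(0, 100))
  expect_equal(est$D, 0.92, tolerance = 1e-9)
  expect_equal(est$r2, 1)

  # flat curve -> D = 0
  flat <- structure(list(lags = lags, msd = rep(2, 101),
                         n_origins = rep(100, 101)), class = "msd_curve")
  expect_equal(fit_diffusion(flat, window = c(0, 100))$D, 0)

  # hand slope: points (1, 6), (2, 12) in A^2/ps give slope 6 and
  # D = 1 A^2/ps-native = 1000 in 1e-7 cm^2/s
  two <- structure(list(lags = c(0, 1, 2), msd = c(0, 6, 12),
                        n_origins = rep(10, 3)), class = "msd_curve")
  est2 <- fit_diffusion(two, window = c(0, 2))
  expect_equal(est2$slope, 6, tolerance = 1e-12)
  expect_equal(est2$D, msd_slope_to_D(6))
  expect_equal(msd_slope_to_D(D_to_msd_slope(3.7)), 3.7)
})

test_that("radial density conserves molecules and localizes correctly", {
  tr <- gen_dissociation_scenario(20, 5, cutoff = 5, margin = 1, seed = 6)
  rd <- radial_density(tr, bin_width = 0.5)
  expect_equal(sum(rd$counts), 20)
  expect_true(all(rd$counts >= 0))
  # molecules sit at radii 4 and 6 from the single polymer atom
  occupied <- rd$mid[rd$counts > 0]
  expect_true(all(abs(occupied - 4) < 0.5 | abs(occupied - 6) < 0.5))
  # single shell -> a single occupied bin
  rd2 <- radial_density(gen_dissociation_scenario(10, 0, cutoff = 5, margin = 1,
                                                  seed = 2), bin_width = 1)
  expect_equal(sum(rd2$counts > 0), 1)
  expect_equal(sum(rd2$counts), 10)
  # normalization by shell volume
  rd3 <- radial_density(tr, bin_width = 0.5, normalize = TRUE)
  shell <- 4 / 3 * pi * (rd3$edges[-1]^3 - rd3$edges[-length(rd3$edges)]^3)
  expect_equal(rd3$density, rd3$counts / shell)
})

test_that("hydrogen-bond criteria are sharp at both cutoffs", {
  count_hb <- function(dDA, angle) {
    tp <- gen_hbond_triplet(dDA, angle)
    hydrogen_bonds(tp$xyz, tp$box, tp$donors, tp$hydrogens, tp$acceptors)$total
  }
  expect_equal(count_hb(2.9, 10), 1)
  expect_equal(count_hb(2.9, 40), 0)  # just beyond the angle cutoff
  expect_equal(count_hb(3.6, 10), 0)  # beyond the distance cutoff
  expect_equal(count_hb(3.5, 35), 1)  # boundary counted (<= convention)
  expect_equal(count_hb(2.9, 90), 0)
  expect_error(hydrogen_bonds(gen_hbond_triplet(2.9, 10)$xyz, rep(30, 3),
                              1L, list(), 3L), "topology error")
})

test_that("hydrogen bonds are categorized and geometry-invariant", {
  # two donors in different groups aimed at one acceptor
  xyz <- rbind(c(10, 10, 10), c(11, 10, 10),   # donor 1 (polymer) + H
               c(13, 10, 10),                  # acceptor (polymer)
               c(13, 13, 10), c(13, 12, 10))   # donor 2 (drug) + H
  box <- rep(30, 3)
  groups <- c("polymer", "polymer", "polymer", "drug", "drug")
  hb <- hydrogen_bonds(xyz, box, donors = c(1L, 4L), hydrogens = list(2L, 5L),
                       acceptors = 3L, group_of = groups)
  expect_equal(hb$total, 2)
  expect_equal(unname(as.vector(hb$by_category[c("polymer-polymer", "drug-polymer")])),
               c(1, 1))
  # global rotation + translation leaves counts unchanged
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  xyz2 <- sweep(xyz, 2, c(15, 15, 15), "-") %*% rot + 15
  hb2 <- hydrogen_bonds(xyz2, box, donors = c(1L, 4L), hydrogens = list(2L, 5L),
                        acceptors = 3L, group_of = groups)
  expect_equal(hb2$total, hb$total)
})
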