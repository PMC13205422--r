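# Distance grid, percolation descriptors, steric classification and
# molecular sizing.

test_that("distance grid values are exact within discretization", {
  # single atom: node 5 A away on-axis sees 5 - 1.7 = 3.3 A
  frame <- list(xyz = matrix(c(0, 0, 0), 1), box = rep(20, 3), radii = 1.7)
  g <- distance_grid(frame, spacing = 0.5)
  # node exactly at (5,0,0): grid origin is at 0 with spacing 0.5
  expect_equal(g$values[11, 1, 1], 3.3, tolerance = 1e-9)
  # empty frame: all values equal the half-box-diagonal cap
  ge <- distance_grid(list(xyz = NULL, box = rep(10, 3), radii = numeric()),
                      spacing = 0.5)
  expect_true(all(ge$values == sqrt(sum((rep(5, 3))^2))))
  # an atom near a face is seen across the boundary via minimum image
  frame2 <- list(xyz = matrix(c(19.8, 10, 10), 1), box = rep(20, 3), radii = 1.5)
  g2 <- distance_grid(frame2, spacing = 0.5)
  node <- c(0.5, 10, 10) # one node inside the opposite face
  brute <- brute_min_image_dist(node, frame2$xyz, frame2$box) - 1.5
  expect_equal(g2$values[2, 21, 21], brute, tolerance = 1e-9)
  # coarse grids are refused
  expect_error(distance_grid(frame, spacing = 6), "too coarse")
})

test_that("grid neighbour values satisfy the Lipschitz bound", {
  ph <- gen_pore_phantom("lattice", a = 4, atom_r = 1.2, n_cells = 3)
  g <- distance_grid(ph, spacing = 0.5)
  v <- g$values
  bound <- sqrt(sum(g$spacing^2)) + 1e-9
  for (d in 1:3) {
    shifted <- switch(d,
                      v[c(2:dim(v)[1], 1), , ],
                      v[, c(2:dim(v)[2], 1), ],
                      v[, , c(2:dim(v)[3], 1)])
    expect_lte(max(abs(v - shifted)), bound)
  }
})

test_that("MPD is twice the deepest pore value", {
  ph <- gen_pore_phantom("cavity", r = 3, box = 12)
  g <- distance_grid(ph, spacing = 0.4)
  expect_equal(max_pore_diameter(g), 2 * max(g$values))
  # fully occupied box
  full <- list(xyz = as.matrix(expand.grid(seq(0.75, 9.75, 1.5),
                                           seq(0.75, 9.75, 1.5),
                                           seq(0.75, 9.75, 1.5))),
               box = rep(10.5, 3), radii = NULL)
  full$radii <- rep(1.5, nrow(full$xyz))
  gf <- distance_grid(full, spacing = 0.5)
  expect_equal(max_pore_diameter(gf), 0)
  expect_equal(pore_limiting_diameter(gf), 0)
})

test_that("phantoms recover their analytic PLD/MPD within one grid spacing", {
  h <- 0.4
  ch <- gen_pore_phantom("channel", r = 3, box = 12)
  g <- distance_grid(ch, spacing = h)
  truth <- attr(ch, "truth")
  expect_lt(abs(pore_limiting_diameter(g) - truth$pld), h)
  expect_lt(abs(max_pore_diameter(g) - truth$mpd), h)

  cv <- gen_pore_phantom("cavity", r = 3, box = 12)
  g2 <- distance_grid(cv, spacing = h)
  truth2 <- attr(cv, "truth")
  expect_equal(pore_limiting_diameter(g2), 0)
  expect_lt(abs(max_pore_diameter(g2) - truth2$mpd), h)
  expect_gt(max_pore_diameter(g2), 0) # exercises pld <= mpd with pld = 0

  lt <- gen_pore_phantom("lattice", a = 4, atom_r = 1.2, n_cells = 3)
  g3 <- distance_grid(lt, spacing = 0.3)
  truth3 <- attr(lt, "truth")
  expect_lt(abs(pore_limiting_diameter(g3) - truth3$pld), 0.3)
  expect_lt(abs(max_pore_diameter(g3) - truth3$mpd), 0.3)
})

test_that("an empty box returns the capped degenerate answer", {
  g <- distance_grid(list(xyz = NULL, box = rep(10, 3), radii = numeric()),
                     spacing = 0.5)
  expect_equal(pore_limiting_diameter(g), 10)
  expect_equal(max_pore_diameter(g), 10)
})

test_that("adding atoms never increases PLD or MPD", {
  base <- gen_pore_phantom("lattice", a = 4, atom_r = 1.0, n_cells = 3)
  g <- distance_grid(base, spacing = 0.4)
  pld0 <- pore_limiting_diameter(g); mpd0 <- max_pore_diameter(g)
  set.seed(31)
  for (k in 1:3) {
    extra <- matrix(runif(9, 0, 12), 3)
    denser <- list(xyz = rbind(base$xyz, extra), box = base$box,
                   radii = c(base$radii, rep(1.0, 3)))
    g2 <- distance_grid(denser, spacing = 0.4)
    pld1 <- pore_limiting_diameter(g2); mpd1 <- max_pore_diameter(g2)
    expect_lte(pld1, pld0 + 1e-9)
    expect_lte(mpd1, mpd0 + 1e-9)
    base <- denser; pld0 <- pld1; mpd0 <- mpd1
  }
})

test_that("halving the spacing changes phantom descriptors by less than the coarse spacing", {
  ch <- gen_pore_phantom("channel", r = 3, box = 12)
  g_coarse <- distance_grid(ch, spacing = 0.6)
  g_fine <- distance_grid(ch, spacing = 0.3)
  expect_lt(abs(pore_limiting_diameter(g_coarse) - pore_limiting_diameter(g_fine)), 0.6)
  expect_lt(abs(max_pore_diameter(g_coarse) - max_pore_diameter(g_fine)), 0.6)
})

test_that("threshold search agrees with the exhaustive sweep and is a sharp boundary", {
  lt <- gen_pore_phantom("lattice", a = 4, atom_r = 1.3, n_cells = 2)
  g <- distance_grid(lt, spacing = 0.45) # <= 20^3 grid
  expect_lte(max(g$dims), 20)
  pld <- pore_limiting_diameter(g)
  expect_equal(pld, brute_force_pld(g))
  eps <- 0.05
  expect_true(probe_percolates(g, pld - eps))
  expect_false(probe_percolates(g, pld + eps))
})

test_that("pld <= mpd on phantom and network frames alike", {
  frames <- list(
    gen_pore_phantom("channel", r = 2.5, box = 11),
    gen_pore_phantom("cavity", r = 2.5, box = 11),
    gen_pore_phantom("lattice", a = 4, atom_r = 1.1, n_cells = 3)
  )
  for (fr in frames) {
    g <- distance_grid(fr, spacing = 0.45)
    expect_lte(pore_limiting_diameter(g), max_pore_diameter(g) + 1e-9)
  }
  net <- run_crosslinking(small_packed_system(), relax_steps = 5, seed = 1)$system
  gn <- distance_grid(net, spacing = 0.5)
  expect_lte(pore_limiting_diameter(gn), max_pore_diameter(gn) + 1e-9)
})

test_that("steric classification follows the size-match rules", {
  # reference values from the bundled descriptor table
  expect_equal(classify_steric_state(5.88, 12.46), "bottleneck_with_free_pockets")
  expect_equal(classify_steric_state(8.70, 10.87), "transition")
  expect_equal(classify_steric_state(0, 0), "bottleneck_limited")
  expect_equal(classify_steric_state(8.0, 13.0), "free")
  expect_equal(classify_steric_state(5.0, 10.0), "bottleneck_limited")
  expect_error(classify_steric_state(8, 6), "invariant")
  # every bundled system gets a label and satisfies pld <= mpd
  d <- nanogel_descriptors()
  expect_true(all(d$pld_A <= d$mpd_A))
  labels <- mapply(classify_steric_state, d$pld_A, d$mpd_A)
  expect_true(all(labels %in% c("bottleneck_limited", "bottleneck_with_free_pockets",
                                "transition", "free")))
})

test_that("molecular dimensions are exact on constructions and rotation-invariant", {
  md <- molecule_dimensions(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 1))
  expect_equal(md$Z, 6)
  expect_equal(md$X, 2)
  one <- molecule_dimensions(matrix(c(1, 2, 3), 1), 1.7)
  expect_equal(c(one$X, one$Y, one$Z), rep(3.4, 3))
  set.seed(12)
  pts <- matrix(rnorm(36), 12, 3)
  rad <- runif(12, 1, 1.8)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  a <- unlist(molecule_dimensions(pts, rad))
  b <- unlist(molecule_dimensions(pts %*% rot + 5, rad))
  expect_equal(a, b, tolerance = 1e-9)
  expect_warning(molecule_dimensions(matrix(0, 3, 3), rep(1, 3)), "degenerate")
  # the packaged drug yardstick is the ascending reference triple
  ibu <- ibu_dimensions()
  expect_equal(c(ibu$X, ibu$Y, ibu$Z), c(6.78, 7.47, 12.03))
})
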