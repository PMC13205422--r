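# Seeded synthetic-data generators. Each generator emulates one input
# class the pipeline consumes and attaches machine-readable ground
# truth, so every analysis stage can be validated without any
# molecular-dynamics output. Statistical generators expose the
# analytic mean/variance their tests rely on.

#' Generate a Brownian drug ensemble around a static polymer decoy
#'
#' Independent Gaussian displacement increments with per-step variance
#' `2 D dt` per dimension (the exact discretization of isotropic
#' diffusion), so the ensemble MSD slope is `6 D` by construction.
#' Coordinates are kept unwrapped. A single static decoy atom plays
#' the polymer group.
#'
#' @param D diffusion coefficient in 1e-7 cm^2 s^-1.
#' @param n_mol number of drug molecules (single-site), default 50.
#' @param dt frame spacing (ps), default 1.
#' @param n_steps number of frames, >= 2; default 10000 (10 ns at
#'   1 ps).
#' @param box cubic box edge (A), default 100.
#' @param seed integer seed.
#' @return a [trajectory()]; attribute `truth` holds the generating
#'   parameters (including the per-step displacement variance).
#' @export
gen_brownian <- function(D, n_mol = 50, dt = 1, n_steps = 10000, box = 100,
                         seed = 1L) {
  if (D < 0) stop("D must be >= 0")
  if (n_steps < 2) stop("n_steps must be >= 2")
  d_a2ps <- D / A2_PER_PS_TO_1E7_CM2_S
  step_sd <- sqrt(2 * d_a2ps * dt)
  n_atoms <- n_mol + 1L
  coords <- with_seed(seed, {
    arr <- array(0, dim = c(n_atoms, 3, n_steps))
    arr[1, , ] <- box / 2 # static polymer decoy
    start <- matrix(stats::runif(n_mol * 3, 0, box), n_mol, 3)
    for (k in 1:3) {
      inc <- matrix(stats::rnorm(n_mol * (n_steps - 1), sd = step_sd),
                    n_mol, n_steps - 1)
      arr[-1, k, ] <- cbind(start[, k], start[, k] + t(apply(inc, 1, cumsum)))
    }
    arr
  })
  tr <- trajectory(coords, times = (seq_len(n_steps) - 1) * dt, box = rep(box, 3),
                   groups = list(polymer = 1L, drug = as.list(seq_len(n_mol) + 1L)),
                   elements = rep("C", n_atoms), unwrapped = TRUE)
  attr(tr, "truth") <- list(D = D, step_sd = step_sd, dt = dt, seed = seed)
  tr
}

#' Generate a dissociation scenario with known labels
#'
#' Places `n_free` single-site molecules at exactly `cutoff + margin`
#' from a central polymer atom and the remaining `n_total - n_free` at
#' `cutoff - margin` (directions seeded at random), static over the
#' window, so the time-averaged minimum distance of every molecule is
#' exact. With `margin = 0` every molecule sits exactly at the cutoff
#' and, under the strict `> cutoff` rule, is retained.
#'
#' @param n_total total drug molecules, default 50.
#' @param n_free molecules beyond the cutoff, `0 <= n_free <= n_total`.
#' @param cutoff contact criterion (A), default 5.
#' @param margin offset from the cutoff (A), default 1.
#' @param window analysis span (ps), default 10000 (10 ns).
#' @param n_frames frames across the window, default 11.
#' @param seed integer seed (placement directions).
#' @return a [trajectory()]; attribute `truth` holds the
#'   per-molecule dissociation labels and expected fraction.
#' @export
gen_dissociation_scenario <- function(n_total = 50, n_free = 11, cutoff = 5,
                                      margin = 1, window = 10000, n_frames = 11,
                                      seed = 1L) {
  if (n_free < 0 || n_free > n_total) stop("need 0 <= n_free <= n_total")
  if (margin < 0) stop("margin must be >= 0")
  box <- 4 * (cutoff + margin + 1)
  center <- rep(box / 2, 3)
  radii <- c(rep(cutoff + margin, n_free), rep(cutoff - margin, n_total - n_free))
  pos <- if (margin == 0) {
    # tie case: exact axis placement so every distance is exactly the
    # cutoff in floating point (the strict > rule then retains all)
    matrix(rep(center, each = n_total), n_total) +
      cbind(radii, 0, 0)
  } else {
    dirs <- with_seed(seed, {
      v <- matrix(stats::rnorm(n_total * 3), n_total, 3)
      v / sqrt(rowSums(v * v))
    })
    sweep(dirs * radii, 2, center, "+")
  }
  coords <- array(0, dim = c(n_total + 1L, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- center
    coords[-1, , f] <- pos
  }
  tr <- trajectory(coords, times = seq(0, window, length.out = n_frames),
                   box = rep(box, 3),
                   groups = list(polymer = 1L, drug = as.list(seq_len(n_total) + 1L)),
                   elements = rep("C", n_total + 1L), unwrapped = TRUE)
  attr(tr, "truth") <- list(
    dissociated = c(rep(TRUE, n_free), rep(FALSE, n_total - n_free)),
    fraction = 100 * n_free / n_total, cutoff = cutoff, margin = margin)
  tr
}

#' Generate a noisy release curve from a kinetic model
#'
#' Evaluates the chosen model on the time grid, adds independent
#' Gaussian noise to each of `n_rep` replicates (in percent), truncates
#' to [0, 100]% with a warning when clipping occurs, and returns the
#' replicate mean and SD as a release profile.
#'
#' @param model one of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @param params named list/vector of model parameters (`k0`, `k1`,
#'   `kH`, or `kKP` and `n`).
#' @param times sampling grid (h), default `c(0.5, 1, 2, 4, 8, 12, 24)`.
#' @param noise_sd replicate noise SD in percent, default 0.
#' @param n_rep replicate count, default 3.
#' @param seed integer seed.
#' @param system_id carried into the profile.
#' @return a [release_profile()]; attribute `truth` holds the
#'   generating model and parameters.
#' @export
gen_release_curve <- function(model, params, times = c(0.5, 1, 2, 4, 8, 12, 24),
                              noise_sd = 0, n_rep = 3, seed = 1L,
                              system_id = NA_character_) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  ideal <- 100 * model_fun(model)(times, as.list(params))
  reps <- with_seed(seed, {
    matrix(rep(ideal, n_rep) + stats::rnorm(length(times) * n_rep, sd = noise_sd),
           nrow = n_rep, byrow = TRUE)
  })
  if (any(reps < 0 | reps > 100)) {
    warning("release values clipped to [0, 100]%")
    reps <- pmin(pmax(reps, 0), 100)
  }
  prof <- release_profile(times = times, release = colMeans(reps),
                          sd = if (n_rep > 1) apply(reps, 2, stats::sd) else NULL,
                          system_id = system_id, n_replicates = n_rep)
  attr(prof, "truth") <- list(model = model, params = as.list(params),
                              noise_sd = noise_sd, seed = seed)
  prof
}

# ---- pore phantoms ----------------------------------------------------------

# simple-cubic filler lattice covering the box (coverage is complete:
# spacing * sqrt(3)/2 <= radius), minus a carved predicate region
.fill_lattice <- function(box, spacing, keep) {
  g <- lapply(box, function(L) {
    n <- max(1L, round(L / spacing))
    (seq_len(n) - 0.5) * (L / n)
  })
  xyz <- as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
  xyz[keep(xyz), , drop = FALSE]
}

#' Generate a pore phantom with analytically known PLD/MPD
#'
#' Three geometries: `channel`, a straight cylindrical empty channel
#' of radius `r` along z through an otherwise blocked box
#' (PLD = MPD = 2r); `cavity`, a sealed spherical cavity of radius `r`
#' (PLD = 0, MPD = 2r); `lattice`, spheres of radius `atom_r` on a
#' simple cubic lattice of spacing `a` (PLD = a*sqrt(2) - 2*atom_r
#' through the face windows, MPD = a*sqrt(3) - 2*atom_r at the cell
#' centers).
#'
#' @param kind `"channel"`, `"cavity"`, or `"lattice"`.
#' @param r channel/cavity radius (A), default 3.
#' @param box cubic box edge (A), default 12 (lattice: `n_cells * a`).
#' @param a lattice spacing (A), default 4.
#' @param atom_r lattice sphere radius (A), default 1.2.
#' @param n_cells lattice cells per edge, default 3.
#' @param fill_spacing filler lattice spacing (A), default 1.2.
#' @param fill_r filler atom radius (A), default 1.1.
#' @param wall_step surface discretization step of the carved wall
#'   (A), default 0.35.
#' @return list of class `pore_frame` with `xyz`, `box`, `radii` and
#'   attribute `truth` (`pld`, `mpd`).
#' @export
gen_pore_phantom <- function(kind = c("channel", "cavity", "lattice"), r = 3,
                             box = 12, a = 4, atom_r = 1.2, n_cells = 3,
                             fill_spacing = 1.2, fill_r = 1.1, wall_step = 0.35) {
  kind <- match.arg(kind)
  if (kind == "lattice") {
    L <- n_cells * a
    g <- (seq_len(n_cells) - 0.5) * a
    xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
    frame <- structure(list(xyz = xyz, box = rep(L, 3),
                            radii = rep(atom_r, nrow(xyz))), class = "pore_frame")
    attr(frame, "truth") <- list(pld = a * sqrt(2) - 2 * atom_r,
                                 mpd = a * sqrt(3) - 2 * atom_r)
    return(frame)
  }
  b <- rep(box, 3)
  cen <- b / 2
  wall_r <- 1.0
  if (kind == "channel") {
    if (2 * (r + 2 * wall_r) > box) stop("channel does not fit the box")
    fill <- .fill_lattice(b, fill_spacing, keep = function(p) {
      sqrt((p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2) >= r + fill_r
    })
    nz <- max(1L, round(box / wall_step))
    zs <- (seq_len(nz) - 0.5) * (box / nz)
    nth <- max(8L, ceiling(2 * pi * (r + wall_r) / wall_step))
    th <- (seq_len(nth) - 1) * 2 * pi / nth
    ring <- cbind(cen[1] + (r + wall_r) * cos(th), cen[2] + (r + wall_r) * sin(th))
    wall <- cbind(ring[rep(seq_len(nth), times = nz), ],
                  rep(zs, each = nth))
    xyz <- rbind(fill, wall)
    radii <- c(rep(fill_r, nrow(fill)), rep(wall_r, nrow(wall)))
    truth <- list(pld = 2 * r, mpd = 2 * r)
  } else { # cavity
    if (2 * (r + 2 * wall_r) > box) stop("cavity does not fit the box")
    fill <- .fill_lattice(b, fill_spacing, keep = function(p) {
      sqrt(rowSums(sweep(p, 2, cen, "-")^2)) >= r + fill_r
    })
    npts <- max(32L, ceiling(4 * pi * (r + wall_r)^2 / wall_step^2))
    k <- seq_len(npts)
    phi <- acos(1 - 2 * (k - 0.5) / npts)
    theta <- pi * (1 + sqrt(5)) * k
    shell <- cbind(cen[1] + (r + wall_r) * sin(phi) * cos(theta),
                   cen[2] + (r + wall_r) * sin(phi) * sin(theta),
                   cen[3] + (r + wall_r) * cos(phi))
    xyz <- rbind(fill, shell)
    radii <- c(rep(fill_r, nrow(fill)), rep(wall_r, nrow(shell)))
    truth <- list(pld = 0, mpd = 2 * r)
  }
  frame <- structure(list(xyz = xyz, box = b, radii = radii), class = "pore_frame")
  attr(frame, "truth") <- truth
  frame
}

#' Generate a donor-hydrogen-acceptor triplet with exact geometry
#'
#' Places the donor at the box center, the acceptor at the requested
#' donor-acceptor distance along x, and the hydrogen at unit bond
#' length from the donor forming exactly the requested H-D...A angle.
#'
#' @param dDA donor-acceptor distance (A), > 0.
#' @param angle H-D...A angle (degrees), in [0, 180].
#' @param box cubic box edge (A), default 30.
#' @return list with `xyz` (rows: donor, hydrogen, acceptor), `box`,
#'   `donors`, `hydrogens`, `acceptors` ready for [hydrogen_bonds()].
#' @export
gen_hbond_triplet <- function(dDA, angle, box = 30) {
  if (dDA <= 0) stop("dDA must be > 0")
  if (angle < 0 || angle > 180) stop("angle must be in [0, 180]")
  cen <- rep(box / 2, 3)
  th <- angle * pi / 180
  xyz <- rbind(
    cen,
    cen + c(cos(th), sin(th), 0),
    cen + c(dDA, 0, 0)
  )
  list(xyz = xyz, box = rep(box, 3), donors = 1L, hydrogens = list(2L),
       acceptors = 3L)
}
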