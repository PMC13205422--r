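# Trajectory container and the metrics computed from it: per-molecule
# minimum-distance series, the dissociated-fraction statistic, the
# mean-squared displacement / Einstein-relation diffusion estimate,
# radial number density profiles, and geometric hydrogen-bond counts.

#' Construct a trajectory
#'
#' @param coords n_atoms x 3 x n_frames array of coordinates (A).
#' @param times frame times (ps), strictly increasing.
#' @param box 3 edge lengths (A), or an n_frames x 3 matrix.
#' @param groups named list of index sets. `polymer` and `water` are
#'   plain atom-index vectors; `drug` is a list of per-molecule atom
#'   index vectors (a plain vector is treated as one molecule per
#'   atom, the united-atom case).
#' @param elements optional per-atom element symbols.
#' @param masses optional per-atom masses (amu); derived from
#'   `elements` when needed and absent.
#' @param radii optional per-atom vdW radii (A).
#' @param unwrapped logical: are coordinates free of periodic wrapping
#'   (required for MSD)?
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, times, box, groups = list(), elements = NULL,
                       masses = NULL, radii = NULL, unwrapped = FALSE) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (length(times) != dim(coords)[3]) stop("times must match frame count")
  if (is.unsorted(times, strictly = TRUE)) stop("frame times must be strictly increasing")
  if (is.matrix(box)) {
    if (nrow(box) != length(times)) stop("per-frame box must have one row per frame")
  } else if (length(box) != 3) stop("box must be 3 edge lengths")
  if (!is.null(groups$drug) && !is.list(groups$drug)) {
    groups$drug <- as.list(groups$drug)
  }
  structure(list(coords = coords, times = times, box = box, groups = groups,
                 elements = elements, masses = masses, radii = radii,
                 unwrapped = unwrapped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, %.1f-%.1f ps%s\n",
              dim(x$coords)[1], dim(x$coords)[3], min(x$times), max(x$times),
              if (x$unwrapped) " (unwrapped)" else ""))
  if (length(x$groups)) {
    sizes <- vapply(x$groups, function(g) length(unlist(g)), 0L)
    cat("groups:", paste(names(sizes), sizes, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

frame_box <- function(traj, f) {
  if (is.matrix(traj$box)) traj$box[f, ] else traj$box
}

# coordinates of selected atoms in one frame, always an n x 3 matrix
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f, drop = FALSE], ncol = 3)
}

frame_window_idx <- function(traj, window) {
  if (is.null(window)) return(seq_along(traj$times))
  idx <- which(traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9)
  if (!length(idx)) stop("window contains no frames")
  idx
}

traj_masses <- function(traj) {
  traj$masses %||% (if (!is.null(traj$elements)) atomic_mass(traj$elements)
                    else rep(1, dim(traj$coords)[1]))
}

# ---- minimum-distance series and dissociation -------------------------------

#' Per-molecule minimum-distance time series
#'
#' For each drug molecule and frame, the minimum over all
#' (drug-atom, polymer-atom) minimum-image distances.
#'
#' @param traj a [trajectory()].
#' @param drug list of per-molecule atom index vectors (default: the
#'   trajectory's `drug` group).
#' @param polymer polymer atom indices (default: `polymer` group).
#' @param window optional `c(t0, t1)` ps restriction.
#' @return matrix (n_molecules x n_frames) of distances (A), with
#'   frame times as column names.
#' @export
min_distance_series <- function(traj, drug = NULL, polymer = NULL, window = NULL) {
  drug <- drug %||% traj$groups$drug
  polymer <- polymer %||% traj$groups$polymer
  if (is.null(drug) || !length(drug)) stop("empty selection: drug group required")
  if (is.null(polymer) || !length(polymer)) stop("empty selection: polymer group required")
  if (!is.list(drug)) drug <- as.list(drug)
  fidx <- frame_window_idx(traj, window)
  out <- matrix(NA_real_, length(drug), length(fidx))
  for (fi in seq_along(fidx)) {
    f <- fidx[fi]
    box <- frame_box(traj, f)
    poly <- frame_coords(traj, polymer, f)
    for (m in seq_along(drug)) {
      datoms <- frame_coords(traj, drug[[m]], f)
      out[m, fi] <- min(vapply(seq_len(nrow(datoms)), function(i) {
        min(min_image_dist(datoms[i, ], poly, box))
      }, numeric(1)))
    }
  }
  colnames(out) <- traj$times[fidx]
  out
}

#' Dissociated fraction of drug molecules
#'
#' A molecule is classified dissociated when its time-averaged minimum
#' distance to the polymer over the analysis window strictly exceeds
#' `cutoff` (a molecule sitting exactly at the cutoff is retained).
#' The fraction is `100 * N_dissociated / N_molecules`, so with N
#' molecules every attainable value is a multiple of `100/N`.
#'
#' @inheritParams min_distance_series
#' @param cutoff contact criterion (A), default 5.
#' @return list with `fraction` (percent), `dissociated` (logical per
#'   molecule), `avg_min_dist` (A per molecule), `n` (molecule count).
#' @export
dissociated_fraction <- function(traj, drug = NULL, polymer = NULL,
                                 cutoff = 5, window = NULL) {
  series <- min_distance_series(traj, drug, polymer, window)
  n <- nrow(series)
  if (n == 0) stop("undefined fraction: zero drug molecules")
  avg <- rowMeans(series)
  det <- avg > cutoff
  list(fraction = 100 * sum(det) / n, dissociated = det,
       avg_min_dist = avg, n = n)
}

# ---- mean-squared displacement and diffusion --------------------------------

# time-averaged MSD of one coordinate series via the FFT
# autocorrelation identity; returns msd for lags 0..max_lag
.msd_fft <- function(x, max_lag) {
  n <- length(x)
  # S2(t) = sum_k x_k x_{k+t} via FFT-based autocorrelation
  fx <- stats::fft(c(x, numeric(n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1)] / (2 * n)
  css <- cumsum(x^2)
  tot <- css[n]
  lags <- 0:max_lag
  # MSD(t) = (sum_{k<=n-t} x_k^2 + sum_{k>t} x_k^2 - 2 S2(t)) / (n - t)
  head_sum <- c(tot, css[n - seq_len(max_lag)])
  tail_sum <- c(tot, tot - css[seq_len(max_lag)])
  (head_sum + tail_sum - 2 * s2) / (n - lags)
}

#' Mean-squared displacement of a molecular group
#'
#' Center-of-mass MSD per molecule, averaged over molecules and over
#' all sliding time origins (origin stride 1 via an FFT-based
#' correlation identity; coarser strides fall back to direct
#' averaging). Requires unwrapped coordinates.
#'
#' @param traj a [trajectory()] with `unwrapped = TRUE`.
#' @param group list of per-molecule atom index vectors (default: the
#'   `drug` group).
#' @param max_lag largest lag (ps); default one tenth of the
#'   trajectory span, the customary cap that keeps every reported lag
#'   backed by many sliding origins.
#' @param origin_stride origin spacing in frames (default 1).
#' @return object of class `msd_curve`: `lags` (ps), `msd` (A^2),
#'   `n_origins`.
#' @export
msd <- function(traj, group = NULL, max_lag = NULL, origin_stride = 1L) {
  if (!traj$unwrapped) {
    stop("wrap ambiguity: MSD needs unwrapped coordinates (set unwrapped = TRUE ",
         "only if coordinates are continuous across the periodic boundary)")
  }
  group <- group %||% traj$groups$drug
  if (is.null(group) || !length(group)) stop("empty selection")
  if (!is.list(group)) group <- as.list(group)
  times <- traj$times
  nf <- length(times)
  dt <- times[2] - times[1]
  if (max(abs(diff(times) - dt)) > 1e-6 * dt) {
    stop("MSD requires uniformly spaced frames")
  }
  span <- times[nf] - times[1]
  if (is.null(max_lag)) max_lag <- span / 10
  if (max_lag >= span + 1e-9) stop("max_lag must be smaller than the trajectory span")
  nlag <- min(nf - 1L, as.integer(floor(max_lag / dt)))
  masses <- traj_masses(traj)

  # per-molecule COM series: n_frames x 3
  com_series <- function(idx) {
    m <- masses[idx]
    w <- m / sum(m)
    sapply(1:3, function(k) {
      if (length(idx) == 1) traj$coords[idx, k, ]
      else colSums(traj$coords[idx, k, , drop = FALSE][, 1, ] * w)
    })
  }

  acc <- numeric(nlag + 1)
  for (mol in group) {
    com <- com_series(mol)
    if (origin_stride == 1L) {
      acc <- acc + .msd_fft(com[, 1], nlag) + .msd_fft(com[, 2], nlag) +
        .msd_fft(com[, 3], nlag)
    } else {
      origins <- seq(1L, nf, by = origin_stride)
      for (lag in 0:nlag) {
        o <- origins[origins + lag <= nf]
        d <- com[o + lag, , drop = FALSE] - com[o, , drop = FALSE]
        acc[lag + 1] <- acc[lag + 1] + mean(rowSums(d * d))
      }
    }
  }
  msd_vals <- acc / length(group)
  n_origins <- if (origin_stride == 1L) nf - (0:nlag) else {
    vapply(0:nlag, function(l) sum(seq(1L, nf, by = origin_stride) + l <= nf), 0L)
  }
  structure(list(lags = (0:nlag) * dt, msd = pmax(msd_vals, 0),
                 n_origins = n_origins),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags up to %.1f ps, MSD(max) = %.3g A^2\n",
              length(x$lags), max(x$lags), x$msd[length(x$msd)]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lags, x$msd, type = "l", xlab = "lag (ps)",
                 ylab = expression(MSD ~ (ring(A)^2)), ...)
  invisible(x)
}

#' Einstein-relation diffusion coefficient from an MSD curve
#'
#' Ordinary least squares on MSD vs lag over the fit window; the
#' three-dimensional Einstein relation gives `D = slope / 6`, reported
#' in 1e-7 cm^2 s^-1 (1 A^2/ps = 1e3 x 1e-7 cm^2/s).
#'
#' @param curve an [msd()] result.
#' @param window lag range `c(lo, hi)` in ps; default the final 10% of
#'   lags (the late, linear regime).
#' @return object of class `diffusion_estimate`: `D` (1e-7 cm^2 s^-1),
#'   `slope` (A^2/ps), `window` (ps), `r2`.
#' @export
fit_diffusion <- function(curve, window = NULL) {
  lags <- curve$lags
  if (is.null(window)) window <- c(0.9 * max(lags), max(lags))
  sel <- which(lags >= window[1] - 1e-9 & lags <= window[2] + 1e-9)
  if (length(sel) < 3) stop("need at least 3 MSD points in the fit window")
  fit <- stats::lm(curve$msd[sel] ~ lags[sel])
  slope <- unname(stats::coef(fit)[2])
  if (slope < -1e-12) warning("negative MSD slope; D reported as fitted")
  ss_tot <- sum((curve$msd[sel] - mean(curve$msd[sel]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(D = msd_slope_to_D(slope), slope = slope,
                 window = range(lags[sel]), r2 = r2),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.3g x 1e-7 cm^2/s (slope %.4g A^2/ps over %.0f-%.0f ps, r^2 = %.4f)\n",
              x$D, x$slope, x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' @export
coef.diffusion_estimate <- function(object, ...) {
  c(D = object$D, slope = object$slope)
}

# ---- radial density ---------------------------------------------------------

#' Radial number density of drug molecules around the polymer
#'
#' Histogram of drug-molecule center-of-mass distances to the polymer
#' center of mass, averaged over the frames in the window. Counts per
#' bin conserve the number of drug molecules each frame; with
#' `normalize = TRUE` counts are divided by the spherical shell volume
#' `4 pi r^2 dr`.
#'
#' @inheritParams min_distance_series
#' @param bin_width radial bin width (A).
#' @param r_max histogram range (A); default half the shortest box
#'   edge, molecules beyond it are pooled into the last bin.
#' @param normalize divide by shell volumes (number density per A^3).
#' @return object of class `radial_density`: `edges`, `mid`, `counts`
#'   (mean molecules per bin per frame), `density` (if normalized).
#' @export
radial_density <- function(traj, drug = NULL, polymer = NULL, bin_width = 1,
                           window = NULL, r_max = NULL, normalize = FALSE) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  drug <- drug %||% traj$groups$drug
  polymer <- polymer %||% traj$groups$polymer
  if (!is.list(drug)) drug <- as.list(drug)
  fidx <- frame_window_idx(traj, window)
  masses <- traj_masses(traj)
  box0 <- frame_box(traj, fidx[1])
  if (is.null(r_max)) r_max <- max(box0) # generous; COM distances are unwrapped
  edges <- seq(0, r_max + bin_width, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (f in fidx) {
    pw <- masses[polymer] / sum(masses[polymer])
    pcom <- colSums(frame_coords(traj, polymer, f) * pw)
    r <- vapply(drug, function(idx) {
      w <- masses[idx] / sum(masses[idx])
      com <- colSums(frame_coords(traj, idx, f) * w)
      sqrt(sum((com - pcom)^2))
    }, numeric(1))
    r <- pmin(r, max(edges) - 1e-9)
    counts <- counts + graphics::hist(r, breaks = edges, plot = FALSE)$counts
  }
  counts <- counts / length(fidx)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  out <- list(edges = edges, mid = mid, counts = counts)
  if (normalize) {
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
    out$density <- counts / shell
  }
  structure(out, class = "radial_density")
}

#' @export
plot.radial_density <- function(x, ...) {
  y <- x$density %||% x$counts
  graphics::plot(x$mid, y, type = "h", xlab = "r (A)",
                 ylab = if (is.null(x$density)) "molecules / bin" else
                   expression(rho(r) ~ (ring(A)^-3)), ...)
  invisible(x)
}

# ---- hydrogen bonds ---------------------------------------------------------

#' Count hydrogen bonds by geometric criteria
#'
#' A donor-hydrogen-acceptor triplet is counted when the
#' donor-acceptor minimum-image distance is at most `d_cut` and the
#' H-D...A angle (at the donor, between the D->H and D->A vectors) is
#' at most `angle_cut`. Both cutoffs are inclusive. When both partners
#' of a pair can donate, each donor direction is counted once. Counts
#' are assigned to categories by the (donor group, acceptor group)
#' pair; the unordered pair label is used, so donor and acceptor
#' swaps of the same two groups accumulate together.
#'
#' @param xyz n x 3 coordinates (A) of one frame.
#' @param box 3 periodic edge lengths (A).
#' @param donors atom indices of donor heavy atoms.
#' @param hydrogens list parallel to `donors`: for each donor, the
#'   indices of its covalently bound hydrogens.
#' @param acceptors atom indices of acceptor heavy atoms.
#' @param d_cut donor-acceptor distance cutoff (A), default 3.5.
#' @param angle_cut H-D...A angle cutoff (degrees), default 35.
#' @param group_of optional named assignment: integer vector over
#'   atoms giving a group label (e.g. `"polymer"`, `"drug"`,
#'   `"water"`) used to categorize counts.
#' @return object of class `hbond_counts`: `total` and, when groups
#'   are given, `by_category` (named vector keyed
#'   `"groupA-groupB"`).
#' @export
hydrogen_bonds <- function(xyz, box, donors, hydrogens, acceptors,
                           d_cut = 3.5, angle_cut = 35, group_of = NULL) {
  if (length(hydrogens) != length(donors)) {
    stop("topology error: `hydrogens` must list the bound hydrogens of each donor")
  }
  total <- 0L
  cats <- character()
  for (di in seq_along(donors)) {
    d <- donors[di]
    hs <- hydrogens[[di]]
    if (!length(hs)) next
    dpos <- xyz[d, ]
    da <- min_image_dist(dpos, xyz[acceptors, , drop = FALSE], box)
    # inclusive cutoffs, with a hair of slack so constructed boundary
    # geometries are not lost to acos/sqrt rounding
    cand <- which(da <= d_cut + 1e-9 & acceptors != d)
    for (ci in cand) {
      a <- acceptors[ci]
      va <- min_image(xyz[a, ] - dpos, box)
      ok <- FALSE
      for (h in hs) {
        vh <- min_image(xyz[h, ] - dpos, box)
        cosang <- sum(vh * va) / (sqrt(sum(vh^2)) * sqrt(sum(va^2)))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= angle_cut + 1e-9) { ok <- TRUE; break }
      }
      if (ok) {
        total <- total + 1L
        if (!is.null(group_of)) {
          pair <- sort(c(group_of[d], group_of[a]))
          cats <- c(cats, paste(pair, collapse = "-"))
        }
      }
    }
  }
  out <- list(total = total, criteria = c(d_cut = d_cut, angle_cut = angle_cut))
  if (!is.null(group_of)) out$by_category <- table(cats)
  structure(out, class = "hbond_counts")
}

#' @export
print.hbond_counts <- function(x, ...) {
  cat(sprintf("hydrogen bonds: %d (d <= %.1f A, angle <= %.0f deg)\n",
              x$total, x$criteria["d_cut"], x$criteria["angle_cut"]))
  if (!is.null(x$by_category)) print(x$by_category)
  invisible(x)
}
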