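# Periodic pore descriptors. The box is discretized into a cubic
# lattice; each node stores the distance to the nearest atom van der
# Waals surface (negative inside an atom). The maximum pore diameter
# (MPD) is twice the largest node value; the pore limiting diameter
# (PLD) is the diameter of the largest probe whose accessible nodes
# still contain a cluster that winds around at least one periodic
# dimension. Cluster labeling uses union-find connected components
# (the Hoshen-Kopelman construction) with face (6-neighbour)
# connectivity.

#' Periodic distance grid from an atomic frame
#'
#' @param frame a `mol_system`, or a list with fields `xyz` (n x 3
#'   matrix, A), `box` (3 edge lengths, A) and optionally `radii`.
#' @param spacing requested grid spacing (A); the actual per-axis
#'   spacing is adjusted so the grid tiles the box periodically.
#' @param radii per-atom van der Waals radii (A); defaults to the
#'   frame's own radii or the Bondi table by element.
#' @return object of class `distance_grid` with fields `values`
#'   (nx x ny x nz array), `spacing` (3), `dims` (3), `box` (3).
#' @export
distance_grid <- function(frame, spacing = 0.4, radii = NULL) {
  if (inherits(frame, "mol_system")) {
    xyz <- coords_matrix(frame); box <- frame$box
    if (is.null(radii)) radii <- frame$atoms$vdw
  } else {
    xyz <- frame$xyz; box <- frame$box
    if (is.null(radii)) radii <- frame$radii
  }
  if (is.null(box)) stop("frame must carry a periodic box")
  if (spacing <= 0) stop("spacing must be > 0")
  if (spacing > min(box) / 4) {
    stop("grid too coarse: spacing must be <= min box edge / 4")
  }
  dims <- pmax(4L, as.integer(round(box / spacing)))
  h <- box / dims
  cap <- sqrt(sum((box / 2)^2))
  n_atoms <- if (is.null(xyz)) 0L else nrow(xyz)
  vals <- array(cap, dim = dims)
  if (n_atoms > 0) {
    gx <- (seq_len(dims[1]) - 1) * h[1]
    gy <- (seq_len(dims[2]) - 1) * h[2]
    gz <- (seq_len(dims[3]) - 1) * h[3]
    for (i in seq_len(n_atoms)) {
      dx <- min_image(gx - xyz[i, 1], box[1])
      dy <- min_image(gy - xyz[i, 2], box[2])
      dz <- min_image(gz - xyz[i, 3], box[3])
      d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
      vals <- pmin(vals, sqrt(d2) - radii[i])
    }
  }
  structure(list(values = vals, spacing = h, dims = dims, box = box),
            class = "distance_grid")
}

#' @export
print.distance_grid <- function(x, ...) {
  cat(sprintf("distance_grid: %d x %d x %d nodes, spacing %.3f/%.3f/%.3f A, range [%.2f, %.2f] A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Maximum pore diameter
#'
#' Twice the largest positive node distance: the diameter of the
#' largest spherical probe that fits anywhere in the pore space.
#' Capped at the shortest box edge (a probe cannot exceed the cell).
#'
#' @param grid a [distance_grid()].
#' @return diameter in A (0 if the box is fully occupied).
#' @export
max_pore_diameter <- function(grid) {
  m <- max(grid$values)
  if (m <= 0) return(0)
  min(2 * m, min(grid$box))
}

# linear indices of an array position grid
.lin_index <- function(i, j, k, dims) {
  (k - 1L) * dims[1] * dims[2] + (j - 1L) * dims[1] + i
}

# edges between open nodes under face connectivity; wrap edges for
# dimension `d` are included only when wrap[d] is TRUE
.open_edges <- function(open, wrap) {
  dims <- dim(open)
  idx <- array(seq_len(prod(dims)), dim = dims)
  edges <- vector("list", 6)
  n <- 0L
  for (d in 1:3) {
    perm_from <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    perm_to <- perm_from
    # interior neighbours
    perm_from[[d]] <- seq_len(dims[d] - 1L)
    perm_to[[d]] <- 2:dims[d]
    a <- idx[perm_from[[1]], perm_from[[2]], perm_from[[3]], drop = FALSE]
    b <- idx[perm_to[[1]], perm_to[[2]], perm_to[[3]], drop = FALSE]
    ok <- open[a] & open[b]
    n <- n + 1L
    edges[[n]] <- cbind(a[ok], b[ok])
    if (wrap[d]) {
      perm_from[[d]] <- dims[d]
      perm_to[[d]] <- 1L
      a <- idx[perm_from[[1]], perm_from[[2]], perm_from[[3]], drop = FALSE]
      b <- idx[perm_to[[1]], perm_to[[2]], perm_to[[3]], drop = FALSE]
      ok <- open[a] & open[b]
      n <- n + 1L
      edges[[n]] <- cbind(a[ok], b[ok])
    }
  }
  do.call(rbind, edges[seq_len(n)])
}

# does the open set percolate (wind) around periodic dimension `d`?
# clusters are built with wrap bonds in the other dimensions only; a
# wrap-adjacent pair across d falling in one cluster closes a loop
# that crosses the boundary exactly once, i.e. an infinite pathway.
.percolates_dim <- function(open, d) {
  dims <- dim(open)
  if (!any(open)) return(FALSE)
  wrap <- rep(TRUE, 3); wrap[d] <- FALSE
  edges <- .open_edges(open, wrap)
  idx <- array(seq_len(prod(dims)), dim = dims)
  sel_hi <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  sel_lo <- sel_hi
  sel_hi[[d]] <- dims[d]; sel_lo[[d]] <- 1L
  a <- as.vector(idx[sel_hi[[1]], sel_hi[[2]], sel_hi[[3]]])
  b <- as.vector(idx[sel_lo[[1]], sel_lo[[2]], sel_lo[[3]]])
  ok <- open[a] & open[b]
  if (!any(ok)) return(FALSE)
  a <- a[ok]; b <- b[ok]
  if (is.null(edges) || nrow(edges) == 0) return(FALSE)
  verts <- sort(unique(c(as.vector(edges), a, b)))
  g <- igraph::graph_from_edgelist(
    matrix(match(edges, verts), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(verts) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  any(comp[match(a, verts)] == comp[match(b, verts)])
}

#' Does a probe of the given diameter percolate the grid?
#'
#' @param grid a [distance_grid()].
#' @param diameter probe diameter (A).
#' @param dims_required `"any"` (default): winding around one periodic
#'   dimension suffices; `"all"`: all three are required.
#' @return logical.
#' @export
probe_percolates <- function(grid, diameter, dims_required = c("any", "all")) {
  dims_required <- match.arg(dims_required)
  open <- grid$values >= diameter / 2
  res <- vapply(1:3, function(d) .percolates_dim(open, d), logical(1))
  if (dims_required == "any") any(res) else all(res)
}

#' Pore limiting diameter by percolation threshold search
#'
#' The largest probe diameter whose accessible node set still contains
#' a periodically percolating cluster. The threshold is located by
#' binary search over the sorted node distance values (the bottleneck
#' is always attained at a node value), refined until exact at grid
#' resolution; `tol` bounds the search when the value set is
#' continuous.
#'
#' @param grid a [distance_grid()].
#' @param tol threshold tolerance in A (default 0.05).
#' @param dims_required as in [probe_percolates()].
#' @return PLD in A (0 if no percolation at any positive diameter);
#'   capped at the shortest box edge.
#' @export
pore_limiting_diameter <- function(grid, tol = 0.05, dims_required = "any") {
  vals <- sort(unique(grid$values[grid$values > 0]))
  if (!length(vals)) return(0)
  # does the open set at probe radius r percolate?
  perc <- function(r) probe_percolates(grid, 2 * r, dims_required)
  if (!perc(vals[1])) return(0)
  lo <- 1L; hi <- length(vals)
  if (perc(vals[hi])) {
    return(min(2 * vals[hi], min(grid$box)))
  }
  # vals[lo] percolates, vals[hi] does not; the search is discrete over
  # node values so it terminates exactly (log cost), `tol` only guards
  # pathological near-continuous value sets
  while (hi - lo > 1L && (vals[hi] - vals[lo]) > min(tol, 1e-9)) {
    mid <- (lo + hi) %/% 2L
    if (perc(vals[mid])) lo <- mid else hi <- mid
  }
  min(2 * vals[lo], min(grid$box))
}

#' Classify the steric accessibility of a pore network for a molecule
#'
#' Compares the transport bottleneck (PLD) and largest cavity (MPD)
#' against the molecule's principal extents (X <= Y <= Z):
#' if MPD > Z the largest cavities admit the molecule in any
#' orientation -- `free` when the bottleneck also passes it
#' (PLD >= Y), otherwise `bottleneck_with_free_pockets` (confined at
#' bottlenecks yet releasable from local pockets); if MPD > Y but
#' MPD <= Z the passage is orientation-sensitive -- `transition` when
#' PLD >= Y, else `bottleneck_limited`; if MPD <= Y everything is
#' `bottleneck_limited`.
#'
#' @param pld pore limiting diameter (A).
#' @param mpd maximum pore diameter (A); must be >= `pld`.
#' @param dims a [molecule_dims()]; defaults to ibuprofen.
#' @return one of `"bottleneck_limited"`,
#'   `"bottleneck_with_free_pockets"`, `"transition"`, `"free"`.
#' @export
#' @examples
#' classify_steric_state(5.88, 12.46)  # bottleneck_with_free_pockets
#' classify_steric_state(8.70, 10.87)  # transition
classify_steric_state <- function(pld, mpd, dims = ibu_dimensions()) {
  if (pld > mpd) stop("invariant violation: PLD must not exceed MPD")
  if (mpd > dims$Z) {
    if (pld < dims$Y) "bottleneck_with_free_pockets" else "free"
  } else if (mpd > dims$Y) {
    if (pld >= dims$Y) "transition" else "bottleneck_limited"
  } else {
    "bottleneck_limited"
  }
}

#' Aggregate pore metrics over trajectory frames
#'
#' Uniformly samples `n_frames` frames (first and last inclusive) from
#' the analysis window, computes PLD and MPD on each, and reports the
#' per-frame values with mean and unbiased SD.
#'
#' @param traj a [trajectory()].
#' @param n_frames number of frames to sample (default 20).
#' @param window time span `c(t0, t1)` in ps; default the final 10 ns.
#' @param spacing grid spacing (A).
#' @param radii per-atom radii; defaults to the trajectory's, else
#'   Bondi by element.
#' @param atoms indices of the atoms forming the network (default: the
#'   `polymer` group if present, else all atoms).
#' @param ... passed to [pore_limiting_diameter()].
#' @return object of class `pore_metrics`: `per_frame` data.frame
#'   (`time`, `pld`, `mpd`) plus `mean_pld`, `sd_pld`, `mean_mpd`,
#'   `sd_mpd`.
#' @export
aggregate_pore_metrics <- function(traj, n_frames = 20, window = NULL,
                                   spacing = 0.4, radii = NULL, atoms = NULL, ...) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  times <- traj$times
  if (is.null(window)) window <- c(max(times) - 1e4, max(times))
  in_win <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(in_win) < n_frames) {
    stop("insufficient frames: window holds ", length(in_win),
         " frames, need ", n_frames)
  }
  pick <- in_win[unique(round(seq(1, length(in_win), length.out = n_frames)))]
  if (is.null(atoms)) atoms <- traj$groups$polymer %||% seq_len(dim(traj$coords)[1])
  atoms <- unlist(atoms, use.names = FALSE)
  if (is.null(radii)) radii <- (traj$radii %||% vdw_radius(traj$elements))[atoms]
  per <- lapply(pick, function(f) {
    frame <- list(xyz = traj$coords[atoms, , f, drop = FALSE][, , 1],
                  box = frame_box(traj, f), radii = radii)
    g <- distance_grid(frame, spacing = spacing)
    data.frame(time = times[f],
               pld = pore_limiting_diameter(g, ...),
               mpd = max_pore_diameter(g))
  })
  per <- do.call(rbind, per)
  structure(list(
    per_frame = per,
    mean_pld = mean(per$pld), sd_pld = stats::sd(per$pld),
    mean_mpd = mean(per$mpd), sd_mpd = stats::sd(per$mpd)
  ), class = "pore_metrics")
}

#' @export
print.pore_metrics <- function(x, ...) {
  cat(sprintf("pore metrics over %d frames: PLD %.2f +/- %.2f A, MPD %.2f +/- %.2f A\n",
              nrow(x$per_frame), x$mean_pld, x$sd_pld, x$mean_mpd, x$sd_mpd))
  invisible(x)
}

#' Principal-axis molecular dimensions
#'
#' Extents of the van der Waals surface along the three principal axes
#' of the atomic position covariance: for each axis, the span of
#' (projection +/- radius), sorted ascending.
#'
#' @param xyz n x 3 coordinate matrix (A), n >= 2.
#' @param radii per-atom radii (A).
#' @return a [molecule_dims()].
#' @export
molecule_dimensions <- function(xyz, radii) {
  if (nrow(xyz) < 1) stop("need at least 1 atom")
  if (nrow(xyz) == 1) return(molecule_dims(2 * radii, 2 * radii, 2 * radii))
  centered <- sweep(xyz, 2, colMeans(xyz), "-")
  if (max(abs(centered)) < 1e-9) {
    warning("degenerate geometry: all atoms coincide; extents are 2*radius")
    axes <- diag(3)
  } else {
    axes <- eigen(crossprod(centered) / nrow(centered), symmetric = TRUE)$vectors
  }
  ext <- vapply(1:3, function(k) {
    p <- centered %*% axes[, k]
    max(p + radii) - min(p - radii)
  }, numeric(1))
  molecule_dims(ext[1], ext[2], ext[3])
}
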