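# Shared fixtures, all built in code.

# minimal system with two reactive carbons at a controlled separation,
# each carbon dressed as a BIS vinyl site (one carbonyl-carbon
# neighbour) so the default templates accept it
two_site_system <- function(separation, box = rep(20, 3), same_molecule = FALSE) {
  atoms <- data.frame(
    id = 1:4,
    element = "C",
    x = c(5, 6.5, 5 + separation, 5 + separation + 1.5),
    y = c(5, 5, 5, 5),
    z = c(5, 5, 5, 5),
    vdw = 1.7,
    residue = "BIS",
    mol_id = if (same_molecule) c(1L, 1L, 1L, 1L) else c(1L, 1L, 2L, 2L),
    resid = 1L,
    reactive = c(TRUE, FALSE, TRUE, FALSE),
    reacted = FALSE,
    protonated = FALSE,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(a = c(1L, 3L), b = c(2L, 4L))
  molecular_system(atoms, bonds, box = box)
}

# small packed chain/BIS system used by several cross-linking tests
small_packed_system <- function(seed = 3) {
  chains <- lapply(1:2, function(k) {
    build_chain(10, 2, protonation_model("acidic"), seed = k)
  })
  pack_system(chains, n_bis = 8, density = 0.8, seed = seed)
}

# brute-force minimum-image distance over all 27 periodic images
brute_min_image_dist <- function(p, pts, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    shift <- c(ix, iy, iz) * box
    d <- sweep(pts, 2, p - shift, "-")
    best <- min(best, sqrt(min(rowSums(d * d))))
  }
  best
}

# exhaustive PLD: sweep every candidate threshold value downward and
# return twice the largest node value whose open set percolates
brute_force_pld <- function(grid) {
  vals <- sort(unique(grid$values[grid$values > 0]), decreasing = TRUE)
  for (v in vals) {
    if (probe_percolates(grid, 2 * v)) return(min(2 * v, min(grid$box)))
  }
  0
}

# independent mid-rank computation by pairwise counting
brute_force_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}
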