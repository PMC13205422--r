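# Iterative template-matching cross-linking: candidate reactive pairs
# are selected by an intermolecular distance criterion on a widening
# cutoff ladder, screened against pre-reaction connectivity templates,
# bonded greedily by ascending distance, and the structure is relaxed
# between reaction searches until a target reactive-site conversion is
# reached or the ladder is exhausted.

# covalent radii (A) used for harmonic rest lengths in the relaxer
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, Cl = 1.02, Na = 1.66, K = 2.03)

#' Henderson-Hasselbalch degree of deprotonation
#'
#' Percent of a weak acid deprotonated at a given pH:
#' `100 / (1 + 10^(pKa - pH))`.
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant (default 4.75, the
#'   representative acrylic-acid value).
#' @return percent deprotonated, in `[0, 100]`.
#' @export
#' @examples
#' henderson_hasselbalch(2.75)  # ~0.99: the acidic limit is nearly fully -COOH
#' henderson_hasselbalch(7.4)   # ~99.8: the basic limit is nearly fully -COO-
henderson_hasselbalch <- function(pH, pKa = 4.75) {
  100 / (1 + 10^(pKa - pH))
}

#' Default pre-reaction connectivity templates
#'
#' A reactive site passes template screening when all of its bonded
#' neighbours are unreacted and the multiset of neighbour elements
#' matches one of the allowed signatures for its residue type. Chain
#' pendant sites (backbone CH of NIPAM/AAC) accept 2 or 3 carbon
#' neighbours (terminal or interior monomer); BIS vinyl carbons accept
#' a single carbon neighbour. BIS-BIS and chain-chain pairings are
#' forbidden by default (both configurable).
#'
#' @param allow_bis_bis permit reactions between two BIS sites.
#' @param allow_chain_chain permit reactions between two chain sites.
#' @return template configuration list.
#' @export
crosslink_templates <- function(allow_bis_bis = FALSE, allow_chain_chain = FALSE) {
  list(
    neighbours = list(
      NIPAM = list(c("C", "C"), c("C", "C", "C")),
      AAC   = list(c("C", "C"), c("C", "C", "C")),
      BIS   = list("C")
    ),
    allow_bis_bis = allow_bis_bis,
    allow_chain_chain = allow_chain_chain
  )
}

#' Find candidate reactive pairs within a distance cutoff
#'
#' Returns all pairs of reactive, unreacted atoms on different
#' molecules whose minimum-image distance does not exceed `cutoff`,
#' sorted by ascending distance.
#'
#' @param system a `mol_system` with a periodic box.
#' @param cutoff distance criterion (A), > 0.
#' @return data.frame with columns `a`, `b` (atom ids) and `dist` (A).
#' @export
find_reactive_pairs <- function(system, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- system$atoms
  idx <- which(a$reactive & !a$reacted)
  if (length(idx) < 2) {
    return(data.frame(a = integer(), b = integer(), dist = numeric()))
  }
  box <- system$box
  xyz <- coords_matrix(system)[idx, , drop = FALSE]
  pr <- t(utils::combn(seq_along(idx), 2))
  d <- xyz[pr[, 1], , drop = FALSE] - xyz[pr[, 2], , drop = FALSE]
  if (!is.null(box)) d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  dist <- sqrt(rowSums(d * d))
  keep <- dist <= cutoff & a$mol_id[idx[pr[, 1]]] != a$mol_id[idx[pr[, 2]]]
  out <- data.frame(a = a$id[idx[pr[keep, 1]]], b = a$id[idx[pr[keep, 2]]],
                    dist = dist[keep])
  out[order(out$dist, pmin(out$a, out$b), pmax(out$a, out$b)), , drop = FALSE]
}

site_matches_template <- function(system, id, templates) {
  a <- system$atoms
  row <- match(id, a$id)
  res <- a$residue[row]
  allowed <- templates$neighbours[[res]]
  if (is.null(allowed)) stop("template missing for residue ", res)
  nb <- c(system$bonds$b[system$bonds$a == id], system$bonds$a[system$bonds$b == id])
  nbrow <- match(nb, a$id)
  if (any(a$reacted[nbrow])) return(FALSE)
  sig <- sort(a$element[nbrow])
  any(vapply(allowed, function(s) identical(sort(s), sig), logical(1)))
}

#' Template-match a candidate reactive pair
#'
#' Checks that each endpoint's bonded neighbourhood (element multiset
#' to depth 1, all neighbours unreacted) matches the pre-reaction
#' template for its residue type, and that the pairing itself is
#' permitted (BIS-BIS and chain-chain are rejected under the default
#' templates).
#'
#' @param system a `mol_system`.
#' @param pair one row from [find_reactive_pairs()] (fields `a`, `b`).
#' @param templates template configuration from [crosslink_templates()].
#' @return logical.
#' @export
match_reaction_template <- function(system, pair, templates = crosslink_templates()) {
  a <- system$atoms
  res_a <- a$residue[match(pair$a, a$id)]
  res_b <- a$residue[match(pair$b, a$id)]
  both_bis <- res_a == "BIS" && res_b == "BIS"
  both_chain <- res_a %in% c("NIPAM", "AAC") && res_b %in% c("NIPAM", "AAC")
  if (both_bis && !templates$allow_bis_bis) return(FALSE)
  if (both_chain && !templates$allow_chain_chain) return(FALSE)
  site_matches_template(system, pair$a, templates) &&
    site_matches_template(system, pair$b, templates)
}

# ---- surrogate-energy relaxation -------------------------------------------

relax_energy_grad <- function(xyz, bonds, r0, box, k_bond, k_rep, sigma) {
  n <- nrow(xyz)
  grad <- matrix(0, n, 3)
  e <- 0
  if (nrow(bonds)) {
    d <- xyz[bonds$ai, , drop = FALSE] - xyz[bonds$bi, , drop = FALSE]
    if (!is.null(box)) d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    r <- sqrt(rowSums(d * d))
    e <- e + sum(k_bond * (r - r0)^2)
    coef <- 2 * k_bond * (r - r0) / pmax(r, 1e-9)
    f <- d * coef
    for (k in 1:3) {
      gk <- numeric(n)
      gk_add <- tapply(f[, k], bonds$ai, sum)
      gk[as.integer(names(gk_add))] <- gk[as.integer(names(gk_add))] + gk_add
      gk_sub <- tapply(f[, k], bonds$bi, sum)
      gk[as.integer(names(gk_sub))] <- gk[as.integer(names(gk_sub))] - gk_sub
      grad[, k] <- gk
    }
  }
  # soft-sphere repulsion between non-bonded pairs
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  r2 <- dx * dx + dy * dy + dz * dz
  ut <- upper.tri(r2)
  ov <- which(ut & r2 < sigma^2)
  if (nrow(bonds)) {
    bonded_lin <- (pmax(bonds$ai, bonds$bi) - 1L) * n + pmin(bonds$ai, bonds$bi)
    ov <- setdiff(ov, bonded_lin)
  }
  if (length(ov)) {
    i <- ((ov - 1L) %% n) + 1L
    j <- ((ov - 1L) %/% n) + 1L
    r <- sqrt(r2[ov])
    e <- e + sum(k_rep * (sigma - r)^2)
    coef <- -2 * k_rep * (sigma - r) / pmax(r, 1e-9)
    f <- cbind(dx[ov], dy[ov], dz[ov]) * coef
    for (k in 1:3) {
      gk <- numeric(n)
      gk_add <- tapply(f[, k], i, sum)
      gk[as.integer(names(gk_add))] <- gk[as.integer(names(gk_add))] + gk_add
      gk_sub <- tapply(f[, k], j, sum)
      gk[as.integer(names(gk_sub))] <- gk[as.integer(names(gk_sub))] - gk_sub
      grad[, k] <- grad[, k] + gk
    }
  }
  if (!is.finite(e)) stop("relaxation diverged: non-finite surrogate energy")
  list(e = e, grad = grad)
}

#' Relax a structure on a surrogate energy surface
#'
#' Steepest-descent displacement minimization of harmonic bonds (rest
#' lengths from covalent radii) plus a purely repulsive soft-sphere
#' term between non-bonded pairs. The per-step displacement is bounded
#' and a backtracking step ensures the energy never increases; the
#' topology is left untouched.
#'
#' @param system a `mol_system`.
#' @param steps number of descent steps (0 returns the input).
#' @param k_bond harmonic bond constant (energy/A^2).
#' @param k_rep soft-sphere constant (energy/A^2).
#' @param sigma_scale overlap diameter as a fraction of summed vdW
#'   radii (single scalar applied via the mean vdW radius).
#' @param max_disp per-atom displacement bound per step (A).
#' @return relaxed `mol_system`; attribute `energy_trace` holds the
#'   energy after each accepted step.
#' @export
relax_structure <- function(system, steps, k_bond = 10, k_rep = 5,
                            sigma_scale = 0.8, max_disp = 0.2) {
  if (steps < 0) stop("steps must be >= 0")
  if (steps == 0) return(system)
  a <- system$atoms
  xyz <- coords_matrix(system)
  n <- nrow(xyz)
  bonds <- system$bonds
  bonds$ai <- match(bonds$a, a$id)
  bonds$bi <- match(bonds$b, a$id)
  r0 <- if (nrow(bonds)) {
    COVALENT_RADII[a$element[bonds$ai]] + COVALENT_RADII[a$element[bonds$bi]]
  } else numeric()
  sigma <- sigma_scale * 2 * mean(a$vdw)
  box <- system$box

  eg <- relax_energy_grad(xyz, bonds, r0, box, k_bond, k_rep, sigma)
  trace <- numeric(0)
  gamma <- 0.05
  for (s in seq_len(steps)) {
    g <- eg$grad
    gnorm <- sqrt(rowSums(g * g))
    if (max(gnorm) < 1e-10) break
    step_ok <- FALSE
    gam <- gamma
    for (try in 1:25) {
      disp <- -gam * g
      dn <- sqrt(rowSums(disp * disp))
      over <- dn > max_disp
      if (any(over)) disp[over, ] <- disp[over, ] * (max_disp / dn[over])
      trial <- xyz + disp
      eg_new <- relax_energy_grad(trial, bonds, r0, box, k_bond, k_rep, sigma)
      if (eg_new$e <= eg$e) { step_ok <- TRUE; break }
      gam <- gam / 2
    }
    if (!step_ok) break
    xyz <- trial; eg <- eg_new
    trace <- c(trace, eg$e)
  }
  system$atoms$x <- xyz[, 1]; system$atoms$y <- xyz[, 2]; system$atoms$z <- xyz[, 3]
  attr(system, "energy_trace") <- trace
  system
}

# ---- the cross-linking loop -------------------------------------------------

reactive_conversion <- function(system) {
  nr <- sum(system$atoms$reactive)
  if (nr == 0) return(0)
  sum(system$atoms$reacted) / nr
}

#' Run iterative cross-linking to a target conversion
#'
#' Loops over the cutoff ladder with several reaction searches per
#' cutoff. Each search forms bonds for all template-matched candidate
#' pairs, greedy by ascending distance with each site used at most once
#' per cycle (ties broken by lowest atom id), marks the endpoints
#' reacted, then relaxes the structure. The loop stops when the
#' reactive-site conversion (reacted sites / all flagged sites,
#' chain pendant and BIS vinyl alike) reaches `target_conversion` or
#' the ladder is exhausted.
#'
#' @param system packed `mol_system`.
#' @param cutoffs ascending cutoff ladder (A); default 3.5 to 5.0 in
#'   0.5 steps.
#' @param searches_per_cutoff reaction searches per cutoff (default 3).
#' @param target_conversion target fraction in (0, 1] (default 0.8).
#' @param relax_steps descent steps after each search (default 10).
#' @param seed integer recorded with the report (the reaction loop
#'   itself is deterministic).
#' @param templates from [crosslink_templates()].
#' @return list with `system` (cross-linked) and `report`
#'   (class `crosslink_report`: per-cycle table, final conversion,
#'   ladder-exhausted flag).
#' @export
run_crosslinking <- function(system, cutoffs = seq(3.5, 5.0, by = 0.5),
                             searches_per_cutoff = 3, target_conversion = 0.8,
                             relax_steps = 10, seed = 1L,
                             templates = crosslink_templates()) {
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoff ladder must be ascending")
  if (target_conversion <= 0 || target_conversion > 1) {
    stop("target_conversion must be in (0, 1]")
  }
  cycles <- NULL
  done <- FALSE
  for (cutoff in cutoffs) {
    for (srch in seq_len(searches_per_cutoff)) {
      cand <- find_reactive_pairs(system, cutoff)
      used <- integer(0)
      formed <- 0L
      if (nrow(cand)) {
        for (r in seq_len(nrow(cand))) {
          p <- cand[r, ]
          if (p$a %in% used || p$b %in% used) next
          if (!match_reaction_template(system, p, templates)) next
          system$bonds <- rbind(system$bonds[, c("a", "b")],
                                data.frame(a = min(p$a, p$b), b = max(p$a, p$b)))
          system$atoms$reacted[match(c(p$a, p$b), system$atoms$id)] <- TRUE
          used <- c(used, p$a, p$b)
          formed <- formed + 1L
        }
      }
      if (relax_steps > 0) {
        system <- relax_structure(system, relax_steps)
      }
      conv <- reactive_conversion(system)
      cycles <- rbind(cycles, data.frame(cutoff = cutoff, search_index = srch,
                                         bonds_formed = formed, conversion = conv))
      if (conv >= target_conversion) { done <- TRUE; break }
    }
    if (done) break
  }
  report <- structure(list(
    cycles = cycles %||% data.frame(cutoff = numeric(), search_index = integer(),
                                    bonds_formed = integer(), conversion = numeric()),
    final_conversion = reactive_conversion(system),
    target_conversion = target_conversion,
    ladder_exhausted = !done,
    pruned_bis = NA_integer_,
    seed = seed
  ), class = "crosslink_report")
  list(system = system, report = report)
}

#' @export
print.crosslink_report <- function(x, ...) {
  cat(sprintf("cross-linking: %d cycles, final conversion %.1f%% (target %.0f%%)%s\n",
              nrow(x$cycles), 100 * x$final_conversion, 100 * x$target_conversion,
              if (x$ladder_exhausted) " [ladder exhausted]" else ""))
  print(x$cycles)
  invisible(x)
}

#' Remove unreacted BIS molecules
#'
#' Deletes every BIS molecule none of whose reactive sites has reacted,
#' re-indexing atom ids and bonds consistently.
#'
#' @param system cross-linked `mol_system`.
#' @return pruned `mol_system`; attribute `pruned_bis` counts removals.
#' @export
prune_unreacted_bis <- function(system) {
  a <- system$atoms
  bis_mols <- unique(a$mol_id[a$residue == "BIS"])
  drop_mols <- bis_mols[vapply(bis_mols, function(m) {
    !any(a$reacted[a$mol_id == m])
  }, logical(1))]
  if (!length(drop_mols)) {
    attr(system, "pruned_bis") <- 0L
    return(system)
  }
  keep <- !(a$mol_id %in% drop_mols)
  old_ids <- a$id[keep]
  new_ids <- seq_along(old_ids)
  amap <- stats::setNames(new_ids, old_ids)
  atoms <- a[keep, , drop = FALSE]
  atoms$id <- new_ids
  b <- system$bonds
  bk <- b$a %in% old_ids & b$b %in% old_ids
  bonds <- data.frame(a = unname(amap[as.character(b$a[bk])]),
                      b = unname(amap[as.character(b$b[bk])]))
  out <- molecular_system(atoms, bonds, box = system$box)
  attr(out, "pruned_bis") <- length(drop_mols)
  out
}
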