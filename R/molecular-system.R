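# Molecular systems: atoms + bonds + periodic box, and the monomer
# templates from which chains, cross-linkers and the drug are built.
# The representation is united-atom-level (backbone carbons + labeled
# pendant heavy atoms): the analyses downstream need topology and
# geometry, not force-field energetics.

RESIDUE_LABELS <- c("NIPAM", "AAC", "BIS", "IBU", "WAT", "ION", "OTHER")

#' Construct a molecular system
#'
#' @param atoms data.frame with columns `id`, `element`, `x`, `y`, `z`,
#'   `vdw`, `residue`, `mol_id`, `resid`, `reactive`, `reacted`,
#'   `protonated`.
#' @param bonds data.frame with columns `a`, `b` (atom ids, `a < b`).
#' @param box numeric length-3 orthorhombic box edge lengths (A), or
#'   `NULL` for an unboxed molecule.
#' @return object of class `mol_system`.
#' @export
molecular_system <- function(atoms, bonds = data.frame(a = integer(), b = integer()),
                             box = NULL) {
  atoms$id <- as.integer(atoms$id)
  bonds$a <- as.integer(bonds$a)
  bonds$b <- as.integer(bonds$b)
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  sys <- structure(list(atoms = atoms, bonds = bonds, box = box),
                   class = "mol_system")
  validate_system(sys)
}

#' @export
print.mol_system <- function(x, ...) {
  cat(sprintf("mol_system: %d atoms, %d bonds", nrow(x$atoms), nrow(x$bonds)))
  if (!is.null(x$box)) cat(sprintf(", box %.2f x %.2f x %.2f A", x$box[1], x$box[2], x$box[3]))
  cat("\n")
  cens <- table(x$atoms$residue[!duplicated(paste(x$atoms$mol_id, x$atoms$resid))])
  cat("residue census:", paste(names(cens), cens, sep = ":", collapse = " "), "\n")
  invisible(x)
}

validate_system <- function(sys) {
  a <- sys$atoms
  needed <- c("id", "element", "x", "y", "z", "vdw", "residue", "mol_id",
              "resid", "reactive", "reacted", "protonated")
  if (!all(needed %in% names(a))) {
    stop("atoms table missing columns: ", paste(setdiff(needed, names(a)), collapse = ", "))
  }
  if (anyDuplicated(a$id)) stop("duplicate atom ids")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) stop("non-finite atom positions")
  if (!all(a$residue %in% RESIDUE_LABELS)) {
    stop("unknown residue label(s): ",
         paste(setdiff(unique(a$residue), RESIDUE_LABELS), collapse = ", "))
  }
  b <- sys$bonds
  if (nrow(b)) {
    if (!all(c(b$a, b$b) %in% a$id)) stop("bond endpoint references missing atom")
    if (any(b$a == b$b)) stop("self-bond")
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key)) stop("duplicate bonds")
  }
  if (any(a$reacted & !a$reactive)) stop("reacted flag set on non-reactive atom")
  if (!is.null(sys$box)) {
    if (length(sys$box) != 3 || any(!is.finite(sys$box)) || any(sys$box <= 0)) {
      stop("box must be 3 positive finite edge lengths")
    }
  }
  sys
}

coords_matrix <- function(sys) as.matrix(sys$atoms[, c("x", "y", "z")])

new_atoms <- function(element, pos, residue, mol_id, resid, reactive = FALSE,
                      protonated = FALSE) {
  data.frame(
    id = seq_len(length(element)),
    element = element,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vdw = vdw_radius(element),
    residue = residue, mol_id = mol_id, resid = resid,
    reactive = reactive, reacted = FALSE, protonated = protonated,
    stringsAsFactors = FALSE
  )
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# ---- protonation ------------------------------------------------------------

#' Two-state protonation model
#'
#' The acidic limit protonates every AAc/IBU carboxyl (-COOH, pH 2.75
#' regime); the basic limit deprotonates them (-COO-, pH 7.4 regime).
#'
#' @param mode `"acidic"` or `"basic"`.
#' @param pKa acid dissociation constant of the carboxyl (default 4.75,
#'   the representative acrylic-acid value).
#' @param pH nominal pH of the modelled medium; defaults to 2.75
#'   (acidic) or 7.4 (basic).
#' @return object of class `protonation_model`.
#' @export
protonation_model <- function(mode = c("acidic", "basic"), pKa = 4.75, pH = NULL) {
  mode <- match.arg(mode)
  if (is.null(pH)) pH <- if (mode == "acidic") 2.75 else 7.4
  structure(list(mode = mode, pKa = pKa, pH = pH), class = "protonation_model")
}

#' @export
print.protonation_model <- function(x, ...) {
  cat(sprintf("protonation model: %s (pH %.2f, pKa %.2f; HH deprotonation %.2f%%)\n",
              x$mode, x$pH, x$pKa, henderson_hasselbalch(x$pH, x$pKa)))
  invisible(x)
}

# ---- monomer / molecule templates ------------------------------------------

# local-frame heavy-atom geometry of one chain monomer; the backbone CH
# carbon carries the pendant reactive flag used by the cross-linker
monomer_template <- function(residue, protonated) {
  if (residue == "NIPAM") {
    list(
      element = c("C", "C", "C", "O", "N", "C"),
      pos = rbind(c(0, 0, 0), c(1.25, 0.85, 0), c(1.25, 2.35, 0),
                  c(0.15, 3.00, 0), c(2.40, 3.05, 0), c(2.40, 4.55, 0)),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5), c(5, 6)),
      reactive = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      protonated = rep(FALSE, 6),
      backbone_in = 1L, backbone_out = 2L
    )
  } else if (residue == "AAC") {
    list(
      element = c("C", "C", "C", "O", "O"),
      pos = rbind(c(0, 0, 0), c(1.25, 0.85, 0), c(1.25, 2.35, 0),
                  c(0.15, 3.00, 0), c(2.40, 3.05, 0)),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)),
      reactive = c(FALSE, TRUE, FALSE, FALSE, FALSE),
      # the hydroxyl oxygen is the titratable site
      protonated = c(FALSE, FALSE, FALSE, FALSE, protonated),
      backbone_in = 1L, backbone_out = 2L
    )
  } else {
    stop("no monomer template for residue ", residue)
  }
}

#' Build one BIS cross-linker molecule
#'
#' N,N'-methylenebisacrylamide at united-atom level: two vinyl carbons
#' (the reactive sites) flanking an amide-methylene-amide bridge.
#'
#' @return `mol_system` with 9 heavy atoms and 2 reactive sites.
#' @export
build_bis <- function() {
  el <- c("C", "C", "O", "N", "C", "N", "C", "O", "C")
  pos <- rbind(
    c(0.0, 0.0, 0), c(1.50, 0.0, 0), c(2.05, 1.15, 0), c(2.25, -1.20, 0),
    c(3.75, -1.20, 0), c(4.50, 0.0, 0), c(6.00, 0.0, 0), c(6.55, 1.15, 0),
    c(6.75, -1.20, 0)
  )
  bonds <- data.frame(a = c(1, 2, 2, 4, 5, 6, 7, 7), b = c(2, 3, 4, 5, 6, 7, 8, 9))
  atoms <- new_atoms(el, pos, residue = "BIS", mol_id = 1L, resid = 1L,
                     reactive = c(TRUE, rep(FALSE, 7), TRUE))
  molecular_system(atoms, bonds)
}

#' Build one coarse ibuprofen molecule
#'
#' Heavy-atom skeleton (phenyl ring, propanoic-acid head, isobutyl
#' tail); used for packing demonstrations and distance-based analyses.
#'
#' @param protonated logical; carboxyl protonation state.
#' @return `mol_system` with residue label `IBU`.
#' @export
build_ibu <- function(protonated = TRUE) {
  ring <- t(vapply(0:5, function(k) {
    th <- pi / 3 * k
    c(1.4 * cos(th), 1.4 * sin(th), 0)
  }, numeric(3)))
  pos <- rbind(
    ring,                                  # 1-6 phenyl
    c(2.9, 0.0, 0.2),                      # 7  CH(CH3)
    c(4.3, 0.3, 0.0),                      # 8  carboxyl C
    c(4.9, 1.4, 0.2),                      # 9  =O
    c(5.0, -0.8, -0.3),                    # 10 -OH / -O-
    c(-2.9, 0.0, 0.2),                     # 11 CH2
    c(-4.3, 0.3, 0.0),                     # 12 CH(CH3)2
    c(2.9, -1.5, 0.4),                     # 13 methyl on C7
    c(-4.9, 1.6, 0.3), c(-5.1, -0.9, -0.4) # 14,15 isobutyl methyls
  )
  el <- c(rep("C", 6), "C", "C", "O", "O", "C", "C", "C", "C", "C")
  bonds <- data.frame(
    a = c(1, 2, 3, 4, 5, 1, 1, 7, 8, 8, 4, 11, 7, 12, 12),
    b = c(2, 3, 4, 5, 6, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15)
  )
  prot <- rep(FALSE, 15); prot[10] <- protonated
  atoms <- new_atoms(el, pos, residue = "IBU", mol_id = 1L, resid = 1L,
                     protonated = prot)
  molecular_system(atoms, bonds)
}

# ---- chain construction -----------------------------------------------------

#' Build a linear P(NIPAM-co-AAc) chain
#'
#' Constructs one pre-polymerized chain of `dp` monomers with exactly
#' `aac_count` acrylic-acid units placed at seeded uniformly-chosen
#' positions; all other monomers are NIPAM. Each monomer's backbone CH
#' carbon is flagged as a pendant reactive site for the cross-linker.
#'
#' @param dp degree of polymerization (monomer count), >= 1.
#' @param aac_count number of AAc units, `0 <= aac_count <= dp`.
#' @param protonation a [protonation_model()]; acidic protonates AAc
#'   carboxyls, basic deprotonates them.
#' @param seed integer seed controlling AAc placement.
#' @return `mol_system`; attribute `aac_mol_pct` gives the AAc mol%.
#' @export
#' @examples
#' ch <- build_chain(20, 3, protonation_model("acidic"), seed = 1)
#' table(ch$atoms$residue[!duplicated(ch$atoms$resid)])
build_chain <- function(dp, aac_count, protonation = protonation_model("acidic"),
                        seed = 1L) {
  if (dp < 1) stop("dp must be >= 1")
  if (aac_count < 0 || aac_count > dp) {
    stop("invalid composition: aac_count must be between 0 and dp")
  }
  aac_pos <- if (aac_count > 0) {
    with_seed(seed, sort(sample.int(dp, aac_count)))
  } else integer()
  labels <- rep("NIPAM", dp)
  labels[aac_pos] <- "AAC"
  prot <- protonation$mode == "acidic"

  atoms <- NULL; bonds <- NULL; offset <- 0L
  backbone_spacing <- 2.2
  prev_out <- NA_integer_
  for (i in seq_len(dp)) {
    tpl <- monomer_template(labels[i], protonated = prot)
    shift <- c((i - 1) * backbone_spacing, ifelse(i %% 2 == 0, 0.4, 0), 0)
    pos <- sweep(tpl$pos, 2, shift, "+")
    at <- new_atoms(tpl$element, pos, residue = labels[i], mol_id = 1L,
                    resid = i, reactive = tpl$reactive, protonated = tpl$protonated)
    at$id <- at$id + offset
    bd <- data.frame(a = tpl$bonds[, 1] + offset, b = tpl$bonds[, 2] + offset)
    if (!is.na(prev_out)) bd <- rbind(bd, data.frame(a = prev_out, b = tpl$backbone_in + offset))
    prev_out <- tpl$backbone_out + offset
    atoms <- rbind(atoms, at); bonds <- rbind(bonds, bd)
    offset <- offset + length(tpl$element)
  }
  sys <- molecular_system(atoms, bonds)
  attr(sys, "aac_mol_pct") <- 100 * aac_count / dp
  sys
}

# concatenate systems into one, re-indexing atom ids and mol_ids
merge_systems <- function(systems, box = NULL) {
  offset <- 0L; molo <- 0L
  atoms <- vector("list", length(systems)); bonds <- vector("list", length(systems))
  for (k in seq_along(systems)) {
    s <- systems[[k]]
    a <- s$atoms
    a$id <- a$id + offset
    a$mol_id <- a$mol_id + molo
    b <- s$bonds
    if (nrow(b)) { b$a <- b$a + offset; b$b <- b$b + offset }
    atoms[[k]] <- a; bonds[[k]] <- b
    offset <- offset + nrow(a); molo <- molo + max(s$atoms$mol_id)
  }
  molecular_system(do.call(rbind, atoms), do.call(rbind, bonds), box = box)
}

# ---- packing ----------------------------------------------------------------

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

#' Pack molecules into a periodic cubic box at a target density
#'
#' Emulates random rigid-body insertion with rejection: the cubic box
#' edge is fixed by total mass / density, then each molecule is placed
#' with a seeded random rotation and translation, rejecting placements
#' that bring any intermolecular atom pair closer than `tolerance`
#' under the minimum-image convention.
#'
#' @param chains list of `mol_system` molecules (chains and/or others).
#' @param n_bis number of BIS cross-linker molecules to add.
#' @param density target packing density in g cm^-3 (default 0.8).
#' @param tolerance minimum intermolecular atom-atom distance (A),
#'   default 2.0.
#' @param seed integer seed for placement.
#' @param max_attempts placement attempts per molecule before a
#'   packing-infeasible error (default 1e5).
#' @return packed `mol_system` with a periodic cubic box.
#' @export
pack_system <- function(chains, n_bis = 0L, density = 0.8, tolerance = 2.0,
                        seed = 1L, max_attempts = 1e5) {
  if (density <= 0) stop("density must be > 0")
  if (tolerance < 0) stop("tolerance must be >= 0")
  mols <- c(chains, replicate(n_bis, build_bis(), simplify = FALSE))
  total_mass <- sum(vapply(mols, function(s) sum(atomic_mass(s$atoms$element)), 0))
  vol_cm3 <- total_mass * AMU_TO_G / density
  L <- vol_cm3^(1 / 3) * CM_TO_ANGSTROM
  box <- rep(L, 3)

  placed <- NULL
  out <- with_seed(seed, {
    systems <- vector("list", length(mols))
    for (k in seq_along(mols)) {
      s <- mols[[k]]
      xyz <- coords_matrix(s)
      xyz <- sweep(xyz, 2, colMeans(xyz), "-")
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        rot <- random_rotation()
        trial <- xyz %*% t(rot)
        trial <- sweep(trial, 2, stats::runif(3, 0, L), "+")
        if (is.null(placed) || nrow(trial) == 0) { ok <- TRUE } else {
          ok <- TRUE
          for (i in seq_len(nrow(trial))) {
            if (any(min_image_dist(trial[i, ], placed, box) < tolerance)) { ok <- FALSE; break }
          }
        }
        if (ok) break
      }
      if (!ok) {
        stop("packing infeasible after ", max_attempts,
             " attempts; lower the density or tolerance")
      }
      s$atoms$x <- trial[, 1]; s$atoms$y <- trial[, 2]; s$atoms$z <- trial[, 3]
      systems[[k]] <- s
      placed <- rbind(placed, trial)
    }
    merge_systems(systems, box = box)
  })
  attr(out, "seed") <- seed
  attr(out, "density") <- density
  out
}
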