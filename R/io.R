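# File formats and bundled reference tables. Coordinates are always
# Angstrom internally; GRO files (nm) are converted on the way in and
# out. Connectivity and flags travel in a JSON sidecar because none of
# the coordinate formats carry them.

PDB_RESNAME <- c(NIPAM = "NIP", AAC = "AAC", BIS = "BIS", IBU = "IBU",
                 WAT = "HOH", ION = "ION", OTHER = "UNK")

label_from_resname <- function(res) {
  rev_map <- stats::setNames(names(PDB_RESNAME), PDB_RESNAME)
  out <- rev_map[toupper(trimws(res))]
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown residue name(s) mapped to OTHER: ",
            paste(unique(res[unknown]), collapse = ", "))
    out[unknown] <- "OTHER"
  }
  unname(out)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a molecular system to PDB, GRO or XYZ
#'
#' The topology (bonds, reactive/reacted/protonation flags, box) is
#' written alongside as a JSON sidecar (`<file>.json`, 0-based atom
#' ids) since the coordinate formats cannot carry it.
#'
#' @param system a `mol_system`.
#' @param path output path; the extension picks the format unless
#'   `format` is given.
#' @param format `"pdb"`, `"gro"` or `"xyz"`.
#' @param sidecar write the JSON topology sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = NULL, sidecar = TRUE) {
  format <- tolower(format %||% tools::file_ext(path))
  a <- system$atoms
  if (format == "pdb") {
    lines <- character()
    if (!is.null(system$box)) {
      lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       system$box[1], system$box[2], system$box[3], 90, 90, 90)
    }
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$id %% 100000, substr(paste0(a$element, a$id %% 100), 1, 4),
      PDB_RESNAME[a$residue], a$resid %% 10000, a$x, a$y, a$z, 1, 0, a$element))
    lines <- c(lines, "END")
    writeLines(lines, path)
  } else if (format == "gro") {
    lines <- c("generated by gelmesh", sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000, PDB_RESNAME[a$residue],
                       substr(paste0(a$element, a$id %% 100), 1, 5),
                       a$id %% 100000, a$x / 10, a$y / 10, a$z / 10),
               if (!is.null(system$box)) {
                 sprintf("%10.5f%10.5f%10.5f", system$box[1] / 10,
                         system$box[2] / 10, system$box[3] / 10)
               } else "   0.00000   0.00000   0.00000")
    writeLines(lines, path)
  } else if (format == "xyz") {
    lines <- c(sprintf("%d", nrow(a)), "generated by gelmesh",
               sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
    writeLines(lines, path)
  } else stop("unknown format: ", format)
  if (sidecar) write_topology_json(system, sidecar_path(path))
  invisible(path)
}

write_topology_json <- function(system, path) {
  a <- system$atoms
  obj <- list(
    atoms = data.frame(id = a$id - 1L, element = a$element, residue = a$residue,
                       mol_id = a$mol_id, resid = a$resid, reactive = a$reactive,
                       reacted = a$reacted, protonated = a$protonated),
    bonds = if (nrow(system$bonds)) {
      unname(lapply(seq_len(nrow(system$bonds)), function(i) {
        c(system$bonds$a[i] - 1L, system$bonds$b[i] - 1L)
      }))
    } else list(),
    box = system$box
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a molecular system from PDB, GRO or XYZ
#'
#' Coordinates are converted to Angstrom regardless of the source
#' convention (GRO stores nm). If a JSON topology sidecar
#' (`<file>.json`) exists it supplies bonds, flags and the box;
#' otherwise the system has no bonds and default flags. Unknown
#' residue names map to `OTHER` with a warning.
#'
#' @param path input file.
#' @param format `"pdb"`, `"gro"` or `"xyz"`; default from extension.
#' @return a `mol_system`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  box <- NULL
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    element <- ifelse(is.na(at$elesy) | at$elesy == "",
                      substr(trimws(at$elety), 1, 1), trimws(at$elesy))
    residue <- label_from_resname(at$resid)
    xyz <- cbind(at$x, at$y, at$z)
    resid <- at$resno
    cry <- grep("^CRYST1", readLines(path), value = TRUE)
    if (length(cry)) {
      box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                          substr(cry[1], 25, 33)))
    }
  } else if (format == "gro") {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[2]))
    if (is.na(n) || length(lines) < n + 3) stop("parse error in GRO at line 2")
    body <- lines[3:(2 + n)]
    resid <- as.integer(substr(body, 1, 5))
    residue <- label_from_resname(substr(body, 6, 10))
    name <- trimws(substr(body, 11, 15))
    element <- substr(name, 1, 1)
    xyz <- 10 * cbind(as.numeric(substr(body, 21, 28)),
                      as.numeric(substr(body, 29, 36)),
                      as.numeric(substr(body, 37, 44)))
    bv <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
    if (all(is.finite(bv)) && all(bv > 0)) box <- 10 * bv
  } else if (format == "xyz") {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    if (is.na(n)) stop("parse error in XYZ at line 1")
    parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4)
    if (length(bad)) stop("parse error in XYZ at line ", bad[1] + 2)
    element <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    residue <- rep("OTHER", n)
    resid <- seq_len(n)
  } else stop("unknown format: ", format)

  n <- nrow(xyz)
  atoms <- data.frame(
    id = seq_len(n), element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw = vdw_radius(ifelse(element %in% names(BONDI_RADII), element, "C")),
    residue = residue, mol_id = 1L, resid = resid,
    reactive = FALSE, reacted = FALSE, protonated = FALSE,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(a = integer(), b = integer())
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    top <- jsonlite::read_json(sc, simplifyVector = TRUE)
    ta <- top$atoms
    if (nrow(ta) == n) {
      atoms$residue <- ta$residue
      atoms$mol_id <- ta$mol_id
      atoms$resid <- ta$resid
      atoms$reactive <- ta$reactive
      atoms$reacted <- ta$reacted
      atoms$protonated <- ta$protonated
    }
    if (length(top$bonds)) {
      bm <- if (is.matrix(top$bonds)) top$bonds else do.call(rbind, top$bonds)
      bonds <- data.frame(a = bm[, 1] + 1L, b = bm[, 2] + 1L)
    }
    if (!is.null(top$box)) box <- unlist(top$box)
  }
  molecular_system(atoms, bonds, box = box)
}

#' Read a multi-frame trajectory
#'
#' Supports multi-model PDB and concatenated XYZ frames (each with its
#' own atom-count header). Box and frame times come from a JSON
#' sidecar (`<file>.json`) with fields `box` (A), `times` (ps) and
#' optionally `groups`; a fallback box/time grid may be supplied
#' directly.
#'
#' @param path trajectory file.
#' @param format `"pdb"` or `"xyz"`; default from extension.
#' @param box,times,groups used when no sidecar exists.
#' @param unwrapped passed through to [trajectory()].
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = NULL, box = NULL, times = NULL,
                            groups = list(), unwrapped = FALSE) {
  format <- tolower(format %||% tools::file_ext(path))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    box <- box %||% side$box
    times <- times %||% side$times
    if (length(side$groups)) {
      groups <- lapply(side$groups, function(g) if (is.list(g)) g else unlist(g))
    }
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    na <- ncol(xyz) / 3
    coords <- array(0, dim = c(na, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    element <- ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                      substr(trimws(pdb$atom$elety), 1, 1), trimws(pdb$atom$elesy))
  } else if (format == "xyz") {
    lines <- readLines(path)
    coords_list <- list(); element <- NULL
    i <- 1L
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      n <- as.integer(trimws(lines[i]))
      parts <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
      if (is.null(element)) element <- vapply(parts, `[`, "", 1)
      coords_list[[length(coords_list) + 1L]] <-
        t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      i <- i + 2L + n
    }
    nf <- length(coords_list)
    na <- nrow(coords_list[[1]])
    coords <- array(unlist(coords_list), dim = c(na, 3, nf))
  } else stop("unknown trajectory format: ", format)
  if (is.null(times)) times <- seq_len(dim(coords)[3]) - 1
  if (is.null(box)) stop("trajectory needs a box (sidecar or argument)")
  trajectory(coords, times = times, box = box, groups = groups,
             elements = element, unwrapped = unwrapped)
}

#' Write a trajectory as concatenated XYZ with a JSON sidecar
#'
#' @param traj a [trajectory()].
#' @param path output `.xyz` path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  na <- dim(traj$coords)[1]
  el <- traj$elements %||% rep("C", na)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$coords)[3])) {
    writeLines(c(sprintf("%d", na), sprintf("frame t=%g ps", traj$times[f]),
                 sprintf("%-2s %12.6f %12.6f %12.6f", el,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f])), con)
  }
  jsonlite::write_json(
    list(box = if (is.matrix(traj$box)) traj$box[1, ] else traj$box,
         times = traj$times,
         groups = traj$groups),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a group index file
#'
#' Plain-text group definitions, one group per line:
#' `name: id id id ...` (1-based atom ids).
#'
#' @param path file path.
#' @return named list of integer vectors.
#' @export
read_index_file <- function(path) {
  lines <- grep(":", readLines(path), value = TRUE)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    out[[trimws(kv[1])]] <- as.integer(strsplit(trimws(kv[2]), "\\s+")[[1]])
  }
  out
}

# ---- tabular inputs ---------------------------------------------------------

#' Read release profiles from CSV
#'
#' Expected columns: `system_id`, `polymer`, `aac_mol_pct`, `ph`,
#' `temp_K`, `urea`, `time_h`, `release_pct` and optionally `sd_pct`.
#'
#' @param path CSV path.
#' @return named list of [release_profile()] objects, one per
#'   `system_id`.
#' @export
read_release_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("system_id", "time_h", "release_pct")
  if (!all(needed %in% names(df))) {
    stop("release CSV missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  out <- lapply(split(df, df$system_id), function(d) {
    d <- d[order(d$time_h), ]
    release_profile(d$time_h, d$release_pct,
                    sd = if ("sd_pct" %in% names(d)) d$sd_pct else NULL,
                    system_id = d$system_id[1],
                    meta = as.list(d[1, intersect(c("polymer", "aac_mol_pct",
                                                    "ph", "temp_K", "urea"),
                                                  names(d))]))
  })
  out
}

#' Bundled trajectory-descriptor table for the sixteen nanogel systems
#'
#' Reference descriptors for the 4 compositions x 2 pH x 2 temperature
#' P(NIPAM-co-AAc) systems: diffusion coefficient (1e-7 cm^2/s),
#' dissociated fraction (%), polymer-polymer and polymer-drug
#' hydrogen-bond counts, and PLD/MPD (mean and SD, A).
#'
#' @return data.frame with one row per system.
#' @export
nanogel_descriptors <- function() {
  utils::read.csv(system.file("extdata", "nanogel_descriptors.csv",
                              package = "gelmesh"), stringsAsFactors = FALSE)
}

#' Bundled release-kinetics parameter table
#'
#' Fitted parameters and goodness of fit of the four kinetic models
#' (zero order, first order, Higuchi, Korsmeyer-Peppas) for the
#' sixteen release systems; `kKP` and `n` use time in hours.
#'
#' @return data.frame with one row per system.
#' @export
release_kinetics_reference <- function() {
  utils::read.csv(system.file("extdata", "release_kinetics_params.csv",
                              package = "gelmesh"), stringsAsFactors = FALSE)
}

# ---- system-ID grammar ------------------------------------------------------

#' Parse / format system identifiers
#'
#' The grammar is `Polymer-AAcPct-{L,H}-{298,310}`: e.g. `PN-0-L-298`
#' is the PNIPAM homopolymer at low pH and 298 K, `CA-15-H-310` the
#' 15 mol% AAc copolymer at high pH and 310 K.
#'
#' @param id character vector of system ids.
#' @return `parse_system_id`: data.frame with `polymer` (e.g.
#'   `"CA-15"`), `polymer_type`, `aac_mol_pct`, `ph_label`, `temp_K`.
#' @export
parse_system_id <- function(id) {
  parts <- strsplit(id, "-", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad)) stop("malformed system id: ", paste(id[bad], collapse = ", "))
  df <- data.frame(
    polymer_type = vapply(parts, `[`, "", 1),
    aac_mol_pct = as.numeric(vapply(parts, `[`, "", 2)),
    ph_label = vapply(parts, `[`, "", 3),
    temp_K = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  if (!all(df$ph_label %in% c("L", "H"))) stop("ph label must be L or H")
  df$polymer <- paste(df$polymer_type, df$aac_mol_pct, sep = "-")
  df[, c("polymer", "polymer_type", "aac_mol_pct", "ph_label", "temp_K")]
}

#' @rdname parse_system_id
#' @param polymer_type,aac_mol_pct,ph_label,temp_K id components.
#' @export
format_system_id <- function(polymer_type, aac_mol_pct, ph_label, temp_K) {
  sprintf("%s-%g-%s-%d", polymer_type, aac_mol_pct, ph_label, as.integer(temp_K))
}
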