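# End-to-end orchestration: build -> pores -> metrics -> kinetics ->
# correlate on synthetic inputs, with every stage's output written to
# CSV/JSON and a manifest recording the configuration, seed and a
# config hash so any number in any report is reproducible.

# FNV-1a 32-bit hash of a string (config fingerprinting)
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply in two 16-bit halves (stays exact in doubles)
    h0 <- h %% 65536; h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  h0 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - h0) / 65536), as.integer(h0))
}

#' Build a pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stage derives from it.
#' @param aac_mol_pct AAc content of the demonstration build (mol%).
#' @param ph `"acidic"` or `"basic"`.
#' @param dp chain degree of polymerization.
#' @param n_chains chains in the build.
#' @param n_bis BIS cross-linkers in the build.
#' @param density packing density (g/cm^3).
#' @param spacing pore-grid spacing (A).
#' @param d_truth generating diffusion coefficient for the Brownian
#'   stage (1e-7 cm^2/s).
#' @param n_free,n_total dissociation-scenario composition.
#' @param stages character vector of stages to run, in order.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, aac_mol_pct = 15, ph = "acidic",
                       dp = 10, n_chains = 2, n_bis = 10, density = 0.8,
                       spacing = 0.5, d_truth = 4.0, n_free = 11, n_total = 50,
                       stages = c("build", "pores", "metrics", "kinetics",
                                  "correlate")) {
  cfg <- structure(list(out_dir = out_dir, seed = as.integer(seed),
                        aac_mol_pct = aac_mol_pct, ph = ph, dp = dp,
                        n_chains = n_chains, n_bis = n_bis, density = density,
                        spacing = spacing, d_truth = d_truth, n_free = n_free,
                        n_total = n_total, stages = stages),
                   class = "run_config")
  cfg$hash <- fnv1a32(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  cfg
}

pipeline_log <- function(manifest, stage, event, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s: %s", stage, event, msg))
  manifest$log <- c(manifest$log, sprintf("%s %s %s", stage, event, msg))
  manifest
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order on synthetic inputs with
#' known ground truth: `build` constructs and cross-links a small
#' network and writes it as PDB + topology sidecar; `pores` computes
#' PLD/MPD and the steric state of the built network; `metrics` runs
#' the diffusion and dissociation estimators on generated ensembles;
#' `kinetics` fits the four release models to curves generated from
#' the bundled parameter table; `correlate` reproduces the
#' within-material centered Spearman analysis of MPD and polymer-drug
#' hydrogen bonds against release AUC. Outputs are CSV/JSON per stage
#' plus `manifest.json`; rerunning with an identical config reproduces
#' the numbers.
#'
#' @param config a [run_config()].
#' @return named list of stage results, invisibly; side effect: files
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), hash = config$hash,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("gelmesh")),
                   log = character())
  results <- list()
  for (stage in config$stages) {
    manifest <- pipeline_log(manifest, stage, "start", "seed %d", config$seed)
    res <- tryCatch(
      switch(stage,
        build = stage_build(config),
        pores = stage_pores(config, results),
        metrics = stage_metrics(config),
        kinetics = stage_kinetics(config),
        correlate = stage_correlate(config),
        stop("unknown stage: ", stage)
      ),
      error = function(e) {
        stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
             call. = FALSE)
      })
    results[[stage]] <- res
    for (w in res$warnings %||% character()) {
      manifest <- pipeline_log(manifest, stage, "warning", "%s", w)
    }
    manifest <- pipeline_log(manifest, stage, "done", "%s", res$summary)
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

stage_build <- function(config) {
  prot <- protonation_model(if (config$ph == "acidic") "acidic" else "basic")
  aac_count <- round(config$aac_mol_pct / 100 * config$dp)
  chains <- lapply(seq_len(config$n_chains), function(k) {
    build_chain(config$dp, aac_count, prot, seed = config$seed + k)
  })
  packed <- pack_system(chains, n_bis = config$n_bis, density = config$density,
                        seed = config$seed)
  xl <- run_crosslinking(packed, seed = config$seed)
  pruned <- prune_unreacted_bis(xl$system)
  xl$report$pruned_bis <- attr(pruned, "pruned_bis")
  out <- file.path(config$out_dir, "network.pdb")
  write_structure(pruned, out)
  utils::write.csv(xl$report$cycles, file.path(config$out_dir, "crosslink_cycles.csv"),
                   row.names = FALSE)
  list(system = pruned, report = xl$report,
       summary = sprintf("conversion %.1f%%, %d BIS pruned, wrote %s",
                         100 * xl$report$final_conversion,
                         xl$report$pruned_bis, out))
}

stage_pores <- function(config, results) {
  sys <- results$build$system
  if (is.null(sys)) {
    sys <- read_structure(file.path(config$out_dir, "network.pdb"))
  }
  g <- distance_grid(sys, spacing = config$spacing)
  pld <- pore_limiting_diameter(g)
  mpd <- max_pore_diameter(g)
  state <- classify_steric_state(pld, mpd)
  df <- data.frame(pld_A = pld, mpd_A = mpd, steric_state = state)
  utils::write.csv(df, file.path(config$out_dir, "pores.csv"), row.names = FALSE)
  list(pld = pld, mpd = mpd, state = state,
       summary = sprintf("PLD %.2f A, MPD %.2f A, %s", pld, mpd, state))
}

stage_metrics <- function(config) {
  tr <- gen_brownian(config$d_truth, n_mol = 20, n_steps = 2000,
                     seed = config$seed)
  est <- fit_diffusion(msd(tr))
  ds <- gen_dissociation_scenario(n_total = config$n_total,
                                  n_free = config$n_free, seed = config$seed)
  fd <- dissociated_fraction(ds)
  df <- data.frame(D_1e7_cm2_s = est$D, D_truth = config$d_truth,
                   msd_r2 = est$r2, f_det_pct = fd$fraction,
                   f_det_truth = 100 * config$n_free / config$n_total)
  utils::write.csv(df, file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  list(diffusion = est, f_det = fd,
       summary = sprintf("D %.3g (truth %.3g), f_det %.1f%%",
                         est$D, config$d_truth, fd$fraction))
}

stage_kinetics <- function(config) {
  ref <- release_kinetics_reference()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    prof <- gen_release_curve("korsmeyer_peppas",
                              list(kKP = ref$kKP[i], n = ref$n[i]),
                              times = c(0.5, 1, 2, 4, 8, 12),
                              noise_sd = 0, seed = config$seed + i,
                              system_id = ref$system_id[i])
    fits <- lapply(c("zero_order", "first_order", "higuchi", "korsmeyer_peppas"),
                   function(m) fit_kinetics(prof, m))
    kp <- fits[[4]]
    data.frame(system_id = ref$system_id[i],
               kKP = coef(kp)[["kKP"]], n = coef(kp)[["n"]],
               r2_kp = kp$r2, mechanism = kp$mechanism,
               n_truth = ref$n[i])
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(config$out_dir, "kinetics.csv"), row.names = FALSE)
  list(fits = tab,
       summary = sprintf("%d systems refit; n range %.3f-%.3f, all %s",
                         nrow(tab), min(tab$n), max(tab$n),
                         paste(unique(tab$mechanism), collapse = "/")))
}

stage_correlate <- function(config) {
  desc <- nanogel_descriptors()
  ref <- release_kinetics_reference()
  aucs <- vapply(seq_len(nrow(ref)), function(i) {
    prof <- gen_release_curve("korsmeyer_peppas",
                              list(kKP = ref$kKP[i], n = ref$n[i]),
                              times = c(1, 2, 4, 6, 8, 12, 16, 20, 24),
                              noise_sd = 0, seed = config$seed + i,
                              system_id = ref$system_id[i])
    suppressWarnings(auc_release(prof))
  }, numeric(1))
  rec <- merge(desc, data.frame(system_id = ref$system_id, auc_1_24h = aucs),
               by = "system_id")
  res <- list(
    mpd = correlate_descriptor(rec, "mpd_A"),
    hb_pd = correlate_descriptor(rec, "hb_pd")
  )
  out <- data.frame(descriptor = c("mpd_A", "hb_pd"),
                    rho = c(res$mpd$rho, res$hb_pd$rho),
                    p_value = c(res$mpd$p_value, res$hb_pd$p_value),
                    n = c(res$mpd$n, res$hb_pd$n))
  jsonlite::write_json(out, file.path(config$out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(correlations = res,
       summary = sprintf("MPD rho %.3f (p %.3f), HB(p-d) rho %.3f (p %.3f), n %d",
                         res$mpd$rho, res$mpd$p_value, res$hb_pd$rho,
                         res$hb_pd$p_value, res$mpd$n))
}
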