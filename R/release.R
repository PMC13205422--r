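# Release analysis: cumulative-release computation with optional
# sampling-withdrawal correction, four kinetic models fitted to
# fractional release, transport-mechanism classification from the
# power-law exponent, release AUC, within-material centering and
# Spearman rank correlation of descriptors with release.

#' Construct a release profile
#'
#' @param times sampling times (h), strictly increasing.
#' @param release cumulative release (%), same length.
#' @param sd replicate standard deviations (%), optional.
#' @param system_id system identifier (e.g. `"CA-15-H-310"`).
#' @param n_replicates replicate count behind the means.
#' @param meta named list of extra metadata.
#' @return object of class `release_profile`.
#' @export
release_profile <- function(times, release, sd = NULL, system_id = NA_character_,
                            n_replicates = NA_integer_, meta = list()) {
  if (length(times) != length(release)) stop("times and release lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(release < 0 | release > 100 + 1e-9)) {
    warning("cumulative release outside [0, 100]%: mass balance violated; values retained")
  }
  if (!is.null(sd) && any(sd < 0)) stop("sd must be >= 0")
  structure(list(times = times, release = release, sd = sd,
                 system_id = system_id, n_replicates = n_replicates, meta = meta),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat(sprintf("release profile %s: %d points, %.2f-%.1f h, final %.1f%%\n",
              x$system_id, length(x$times), min(x$times), max(x$times),
              x$release[length(x$release)]))
  invisible(x)
}

#' Cumulative release from sampled concentrations
#'
#' With `replace = FALSE` the literal summation `sum(C_t) * V / M *
#' 100` is used. With `replace = TRUE` (the default, matching a
#' sample-and-replenish protocol where `withdrawn` mL are taken at
#' each time point and replaced with fresh medium) the standard
#' correction adds back the drug removed in earlier samples:
#' `release_t = (C_t * V + withdrawn * sum_{s<t} C_s) / M * 100`.
#'
#' @param concentrations measured concentrations (mg/mL) at `times`.
#' @param times sampling times (h).
#' @param V release-medium volume (mL).
#' @param M loaded drug mass (mg).
#' @param withdrawn sample volume withdrawn per time point (mL),
#'   default 1.
#' @param replace logical; apply the withdrawal correction.
#' @param ... passed to [release_profile()].
#' @return a [release_profile()]; the mode used is recorded in `meta`.
#' @export
cumulative_release <- function(concentrations, times, V, M, withdrawn = 1,
                               replace = TRUE, ...) {
  if (M <= 0 || V <= 0) stop("V and M must be > 0")
  rel <- if (replace) {
    (concentrations * V + withdrawn * c(0, cumsum(concentrations)[-length(concentrations)])) / M * 100
  } else {
    cumsum(concentrations) * V / M * 100
  }
  prof <- release_profile(times, rel, ...)
  prof$meta$withdrawal_corrected <- replace
  prof$meta$withdrawn_mL <- if (replace) withdrawn else 0
  prof
}

# ---- kinetic models ---------------------------------------------------------

KINETIC_MODELS <- c("zero_order", "first_order", "higuchi", "korsmeyer_peppas")

model_fun <- function(model) {
  switch(model,
    zero_order = function(t, p) p[["k0"]] * t,
    first_order = function(t, p) 1 - exp(-p[["k1"]] * t),
    higuchi = function(t, p) p[["kH"]] * sqrt(t),
    korsmeyer_peppas = function(t, p) p[["kKP"]] * t^p[["n"]],
    stop("unknown kinetic model: ", model)
  )
}

#' Fit a release-kinetics model
#'
#' Fits one of the four classical models to fractional release
#' `Mt/Minf` (cumulative percent / 100, with the loaded mass as
#' `Minf`): zero order `k0*t` (linear through the origin), first
#' order `1 - exp(-k1*t)`, Higuchi `kH*sqrt(t)`, or Korsmeyer-Peppas
#' `kKP * t^n`. Nonlinear models use Levenberg-Marquardt least squares
#' on the untransformed form; `log_log = TRUE` instead fits the
#' power law by log-log regression. `r2 = 1 - SSres/SStot` and can be
#' negative for the through-origin zero-order form. The
#' Korsmeyer-Peppas fit attaches a transport-mechanism label from
#' [classify_transport()].
#'
#' @param profile a [release_profile()], or a list with `times` (h)
#'   and `release` (%).
#' @param model one of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @param log_log fit the power law on log-log axes instead.
#' @param max_release_frac optional cap: drop points with fractional
#'   release above it (e.g. 0.6, the classical power-law validity
#'   bound); default `NULL` uses all points.
#' @return object of class `kinetic_fit` with fields `model`,
#'   `parameters`, `r2`, `mechanism` (KP only), `data`.
#' @export
fit_kinetics <- function(profile, model = c("korsmeyer_peppas", "zero_order",
                                            "first_order", "higuchi"),
                         log_log = FALSE, max_release_frac = NULL) {
  model <- match.arg(model)
  t <- profile$times
  y <- profile$release / 100
  if (any(y < 0)) stop("negative release")
  if (max(y) > 1 + 1e-9) {
    warning("fractional release exceeds 1; check units")
  }
  if (!is.null(max_release_frac)) {
    keep <- y <= max_release_frac
    t <- t[keep]; y <- y[keep]
  }
  min_pts <- if (model == "korsmeyer_peppas") 4 else 3
  if (length(t) < min_pts) stop("need at least ", min_pts, " points for ", model)

  fitted_pars <- switch(model,
    zero_order = c(k0 = sum(t * y) / sum(t * t)),
    higuchi = c(kH = sum(sqrt(t) * y) / sum(t)),
    first_order = {
      k_start <- -log(pmax(1 - min(max(y), 0.99), 1e-6)) / max(t)
      f <- minpack.lm::nlsLM(y ~ 1 - exp(-k1 * t), start = list(k1 = k_start),
                             lower = 0, control = minpack.lm::nls.lm.control(maxiter = 200))
      c(k1 = unname(stats::coef(f)["k1"]))
    },
    korsmeyer_peppas = {
      pos <- t > 0 & y > 0
      if (sum(pos) < 2) stop("fit failure: need positive points for the power law")
      lf <- stats::lm(log(y[pos]) ~ log(t[pos]))
      start <- list(kKP = exp(unname(stats::coef(lf)[1])),
                    n = max(0.05, unname(stats::coef(lf)[2])))
      if (log_log) {
        c(kKP = start$kKP, n = start$n)
      } else {
        f <- minpack.lm::nlsLM(y ~ kKP * t^n, start = start,
                               lower = c(1e-9, 1e-3),
                               control = minpack.lm::nls.lm.control(maxiter = 500))
        stats::coef(f)[c("kKP", "n")]
      }
    }
  )
  if (any(fitted_pars < 0)) warning("parameter at or below zero at the optimum")
  pred <- model_fun(model)(t, as.list(fitted_pars))
  ssres <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / sstot
  out <- structure(list(
    model = model,
    parameters = fitted_pars,
    r2 = r2,
    mechanism = if (model == "korsmeyer_peppas") classify_transport(fitted_pars[["n"]]) else NA_character_,
    data = list(times = t, frac = y, fitted = pred),
    system_id = profile$system_id %||% NA_character_
  ), class = "kinetic_fit")
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit%s: %s; r2 = %.3f%s\n",
              x$model,
              if (!is.na(x$system_id)) paste0(" [", x$system_id, "]") else "",
              paste(names(x$parameters), signif(x$parameters, 4),
                    sep = " = ", collapse = ", "),
              x$r2,
              if (!is.na(x$mechanism)) paste0("; mechanism: ", x$mechanism) else ""))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  res <- object$data$frac - object$data$fitted
  cat(sprintf("Kinetic model: %s (%d points)\n", object$model,
              length(object$data$times)))
  print(object)
  cat(sprintf("residuals: min %.4f, median %.4f, max %.4f, RMSE %.4f\n",
              min(res), stats::median(res), max(res), sqrt(mean(res^2))))
  invisible(object)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$parameters

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$data$frac - object$data$fitted
}

#' @export
predict.kinetic_fit <- function(object, times = NULL, percent = FALSE, ...) {
  times <- times %||% object$data$times
  p <- model_fun(object$model)(times, as.list(object$parameters))
  if (percent) 100 * p else p
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  graphics::plot(x$data$times, 100 * x$data$frac, xlab = "time (h)",
                 ylab = "cumulative release (%)", ...)
  tt <- seq(min(x$data$times), max(x$data$times), length.out = 200)
  graphics::lines(tt, 100 * predict(x, tt))
  invisible(x)
}

#' Transport-mechanism label from the power-law release exponent
#'
#' For the thin-film convention: `n < 0.5` Fickian diffusion,
#' `n = 0.5` the Higuchi boundary (labelled
#' `"case-II-boundary/Higuchi"`), `0.5 < n <= 1` anomalous transport,
#' `n > 1` super case II.
#'
#' @param n Korsmeyer-Peppas release exponent, > 0.
#' @return character label.
#' @export
classify_transport <- function(n) {
  if (n <= 0) stop("release exponent must be > 0")
  if (n < 0.5) "Fickian"
  else if (n == 0.5) "case-II-boundary/Higuchi"
  else if (n <= 1) "anomalous"
  else "super-case-II"
}

# ---- AUC, centering, correlation -------------------------------------------

#' Area under the cumulative-release curve
#'
#' Trapezoidal integral of release (%) over `[t_start, t_end]` hours,
#' with the endpoints linearly interpolated when not sampled.
#'
#' @param profile a [release_profile()] (or list with `times`,
#'   `release`).
#' @param t_start,t_end integration limits (h); default 1 and 24.
#' @return AUC in %.h.
#' @export
auc_release <- function(profile, t_start = 1, t_end = 24) {
  t <- profile$times; y <- profile$release
  if (t_start < min(t) || t_end > max(t)) {
    stop("integration limits outside the sampled range")
  }
  inside <- t > t_start & t < t_end
  tt <- c(t_start, t[inside], t_end)
  yy <- stats::approx(t, y, xout = tt)$y
  if (length(tt) < 2) stop("insufficient points for AUC")
  pracma::trapz(tt, yy)
}

#' Within-material centering of descriptor records
#'
#' Subtracts each material's own mean from every numeric variable, so
#' baseline differences between materials do not drive subsequent
#' correlations. Records with missing values in the centered columns
#' are dropped with a message.
#'
#' @param records data.frame of matched descriptor/release records.
#' @param material name of the grouping column (default `"polymer"`).
#' @param cols columns to center; default all numeric columns except
#'   the grouping key.
#' @return data.frame with the named columns centered per material.
#' @export
center_within_material <- function(records, material = "polymer", cols = NULL) {
  if (!material %in% names(records)) stop("missing grouping column: ", material)
  if (is.null(cols)) {
    cols <- names(records)[vapply(records, is.numeric, logical(1))]
    cols <- setdiff(cols, material)
  }
  cc <- stats::complete.cases(records[, cols, drop = FALSE])
  if (any(!cc)) {
    message("dropping ", sum(!cc), " record(s) with missing values")
    records <- records[cc, , drop = FALSE]
  }
  g <- records[[material]]
  for (cn in cols) {
    records[[cn]] <- records[[cn]] - stats::ave(records[[cn]], g)
  }
  records
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p-value uses the t approximation with n - 2 degrees of
#' freedom, or the exact permutation distribution for `n <= 10` when
#' `exact = TRUE`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use the exact permutation p-value (only for n <= 10).
#' @param descriptor optional descriptor name carried in the result.
#' @return object of class `correlation_result`: `rho`, `p_value`,
#'   `n`, `method`, `descriptor`.
#' @export
spearman_correlation <- function(x, y, exact = FALSE, descriptor = NA_character_) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero rank variance")
  }
  rho <- stats::cor(rx, ry)
  if (exact && n <= 10) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation (n - 2 df)"
  }
  structure(list(rho = rho, p_value = min(p_value, 1), n = n,
                 method = method, descriptor = descriptor),
            class = "correlation_result")
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3f (n = %d, %s)%s\n",
              x$rho, x$p_value, x$n, x$method,
              if (!is.na(x$descriptor)) paste0(" [", x$descriptor, "]") else ""))
  invisible(x)
}

#' Correlate centered descriptors with centered release AUC
#'
#' Convenience wrapper: within-material centering of the chosen
#' descriptor and the AUC column, then Spearman correlation.
#'
#' @param records data.frame with one row per matched system.
#' @param descriptor descriptor column name (e.g. `"mpd"`, `"hb_pd"`).
#' @param auc AUC column name (default `"auc_1_24h"`).
#' @param material grouping column (default `"polymer"`).
#' @param ... passed to [spearman_correlation()].
#' @return a `correlation_result`.
#' @export
correlate_descriptor <- function(records, descriptor, auc = "auc_1_24h",
                                 material = "polymer", ...) {
  cen <- center_within_material(records, material, cols = c(descriptor, auc))
  spearman_correlation(cen[[descriptor]], cen[[auc]],
                       descriptor = descriptor, ...)
}
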