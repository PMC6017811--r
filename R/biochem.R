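#' NADH molar extinction coefficient at 340 nm
#'
#' 6.22 mM^-1 cm^-1, the standard value used to convert A340 slopes of the
#' pyruvate-kinase / lactate-dehydrogenase coupled assay into NADH
#' consumption rates.
#' @export
NADH_EXTINCTION_MM_CM <- 6.22

#' Mass of an oligomeric assembly
#'
#' @param protomer_kda Protomer mass in kDa (the Cpa protomer is 75 kDa).
#' @param n_subunits Number of subunits (6 for the hexamer, 12 for the
#'   dodecamer).
#' @return Assembly mass in kDa.
#' @export
oligomer_mass <- function(protomer_kda, n_subunits = 6L) {
  stopifnot(protomer_kda > 0, n_subunits >= 1)
  protomer_kda * n_subunits
}

#' Construct a binding curve
#'
#' @param S Titrant concentrations (µM), strictly increasing, all >= 0.
#' @param y Signal values, same length as `S`.
#' @param replicate_id Optional replicate label.
#' @return Object of class `fs_binding_curve`.
#' @export
binding_curve <- function(S, y, replicate_id = NULL) {
  S <- as.numeric(S); y <- as.numeric(y)
  if (length(S) != length(y)) {
    stop("precondition error: S and y lengths differ", call. = FALSE)
  }
  if (any(S < 0) || any(diff(S) <= 0)) {
    stop("precondition error: S must be strictly increasing and >= 0",
         call. = FALSE)
  }
  structure(list(S = S, y = y, replicate_id = replicate_id),
            class = "fs_binding_curve")
}

#' Hill binding equation
#'
#' `y = U + (B - U) * S^h / (Kd^h + S^h)`: `U` is the unbound-state signal,
#' `B` the bound-state signal, `Kd` the dissociation constant and `h` the
#' Hill coefficient. `y(0) = U` exactly and `y(Kd) = (U + B) / 2` for any h.
#'
#' @param S Concentration(s) of the titrated species (>= 0).
#' @param U,B Unbound/bound-state signals.
#' @param Kd Dissociation constant (> 0), same units as `S`.
#' @param h Hill coefficient (> 0).
#' @return Predicted signal(s).
#' @export
hill_predict <- function(S, U, B, Kd, h) {
  if (Kd <= 0 || h <= 0) {
    stop("parameter error: Kd and h must be positive", call. = FALSE)
  }
  if (any(S < 0)) {
    stop("parameter error: S must be >= 0", call. = FALSE)
  }
  frac <- ifelse(S == 0, 0, S^h / (Kd^h + S^h))
  U + (B - U) * frac
}

#' Least-squares Hill fit of a binding curve
#'
#' Unweighted nonlinear least squares of `(U, B, Kd, h)` via bounded
#' Levenberg-Marquardt. Auto-initialisation takes `U` from the signal at the
#' lowest concentration, `B` from the highest, `Kd` from the concentration
#' nearest the half-signal and `h = 1`. Bounds stabilise the fit:
#' `Kd` in (0, 100 * max(S)], `h` in (0, 10].
#'
#' @param curve An [fs_binding_curve][binding_curve] (>= 4 points,
#'   non-constant signal).
#' @param init `"auto"` or a named list/vector with `U`, `B`, `Kd`, `h`.
#' @param kd_max,h_max Upper bounds on `Kd` and `h`.
#' @return Object of class `fs_hill_fit`: `U`, `B`, `Kd`, `h`,
#'   `residual_sum_squares`, `converged`, `stderr` (named vector), plus the
#'   underlying data.
#' @export
fit_hill <- function(curve, init = "auto", kd_max = 100 * max(curve$S),
                     h_max = 10) {
  stopifnot(inherits(curve, "fs_binding_curve"))
  S <- curve$S; y <- curve$y
  if (length(S) < 4L) {
    stop("precondition error: need >= 4 points to fit the Hill equation",
         call. = FALSE)
  }
  if (diff(range(y)) == 0) {
    stop("degenerate-data error: constant signal", call. = FALSE)
  }
  if (identical(init, "auto")) {
    U0 <- y[which.min(S)]
    B0 <- y[which.max(S)]
    half <- (U0 + B0) / 2
    Kd0 <- S[which.min(abs(y - half))]
    if (Kd0 <= 0) Kd0 <- min(S[S > 0], max(S) / 2)
    start <- list(U = U0, B = B0, Kd = Kd0, h = 1)
  } else {
    start <- as.list(init)[c("U", "B", "Kd", "h")]
  }
  eps <- 1e-9
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ U + (B - U) * S^h / (Kd^h + S^h),
      data = data.frame(S = S, y = y),
      start = start,
      lower = c(U = -Inf, B = -Inf, Kd = eps, h = eps),
      upper = c(U = Inf, B = Inf, Kd = kd_max, h = h_max),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(U = NA_real_, B = NA_real_, Kd = NA_real_, h = NA_real_,
           residual_sum_squares = NA_real_, converged = FALSE,
           stderr = c(U = NA, B = NA, Kd = NA, h = NA),
           message = conditionMessage(fit), S = S, y = y),
      class = "fs_hill_fit"
    ))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4L))
  structure(
    list(U = unname(co["U"]), B = unname(co["B"]), Kd = unname(co["Kd"]),
         h = unname(co["h"]),
         residual_sum_squares = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv,
         stderr = stats::setNames(as.numeric(se), c("U", "B", "Kd", "h")),
         S = S, y = y),
    class = "fs_hill_fit"
  )
}

#' @export
print.fs_hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: Kd = %.4g, h = %.3g, U = %.4g, B = %.4g (RSS %.3g, %s)\n",
    x$Kd, x$h, x$U, x$B, x$residual_sum_squares,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' ATPase turnover from a coupled-assay A340 slope
#'
#' In the pyruvate-kinase / lactate-dehydrogenase coupled assay one NADH is
#' oxidised per ATP hydrolysed, so the NADH consumption rate equals the ATP
#' hydrolysis rate: `rate (µM/min) = |slope| / (eps * path)` with
#' `eps = 6.22e-3 µM^-1 cm^-1`, and turnover = rate / [enzyme].
#'
#' @param slope A340 change per minute (negative for NADH consumption).
#' @param path_cm Optical path length in cm (must be supplied; plate-reader
#'   path depends on fill volume).
#' @param enzyme_conc Enzyme (hexamer) concentration in µM.
#' @return Turnover in ATP min^-1 per hexamer.
#' @export
atpase_rate <- function(slope, path_cm, enzyme_conc) {
  if (path_cm <= 0 || enzyme_conc <= 0) {
    stop("parameter error: path_cm and enzyme_conc must be positive",
         call. = FALSE)
  }
  eps_uM <- NADH_EXTINCTION_MM_CM / 1000  # per µM per cm
  rate_uM_min <- abs(slope) / (eps_uM * path_cm)
  rate_uM_min / enzyme_conc
}

#' Fraction of assembled protein from SEC peak areas
#'
#' `(hexamer + dodecamer) / (monomer + hexamer + dodecamer)` — the fraction
#' of protein in ring assemblies in a size-exclusion trace.
#'
#' @param areas Named numeric vector/list with (a subset of) `monomer`,
#'   `hexamer`, `dodecamer`; missing species count as area 0.
#' @return Fraction in `[0, 1]`.
#' @export
assembly_fraction <- function(areas) {
  areas <- unlist(areas)
  known <- c("monomer", "hexamer", "dodecamer")
  bad <- setdiff(names(areas), known)
  if (length(bad) > 0L) {
    stop("parameter error: unknown species '", bad[1L], "'", call. = FALSE)
  }
  if (any(areas < 0)) {
    stop("parameter error: negative peak area", call. = FALSE)
  }
  a <- stats::setNames(rep(0, 3L), known)
  a[names(areas)] <- areas
  total <- sum(a)
  if (total == 0) {
    stop("degenerate-input error: all peak areas zero", call. = FALSE)
  }
  unname((a["hexamer"] + a["dodecamer"]) / total)
}

#' Construct a chromatogram
#'
#' @param volume Elution volumes (ml), strictly increasing.
#' @param absorbance A280 signal, same length.
#' @param peak_windows Named list species -> `c(v_start, v_end)`;
#'   windows must lie within the volume range and not overlap.
#' @return Object of class `fs_chromatogram`.
#' @export
chromatogram <- function(volume, absorbance, peak_windows = list()) {
  volume <- as.numeric(volume); absorbance <- as.numeric(absorbance)
  if (length(volume) != length(absorbance) || length(volume) < 2L) {
    stop("precondition error: volume/absorbance must be equal length >= 2",
         call. = FALSE)
  }
  if (any(diff(volume) <= 0)) {
    stop("precondition error: volume must be strictly increasing",
         call. = FALSE)
  }
  if (length(peak_windows) > 0L) {
    w <- do.call(rbind, peak_windows)
    if (any(w[, 1L] >= w[, 2L])) {
      stop("precondition error: window start must precede end", call. = FALSE)
    }
    if (any(w[, 1L] < volume[1L]) || any(w[, 2L] > volume[length(volume)])) {
      stop("range error: peak window outside volume range", call. = FALSE)
    }
    ord <- order(w[, 1L])
    if (any(w[ord, 2L][-nrow(w)] > w[ord, 1L][-1L])) {
      stop("precondition error: peak windows overlap", call. = FALSE)
    }
  }
  structure(list(volume = volume, absorbance = absorbance,
                 peak_windows = peak_windows),
            class = "fs_chromatogram")
}

# trapezoidal rule on an irregular grid
trapz_fs <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Integrate chromatogram peaks
#'
#' Trapezoidal integral of the baseline-subtracted absorbance over each
#' named window; the baseline is the straight line between the window
#' endpoints.
#'
#' @param chrom An [fs_chromatogram][chromatogram] with `peak_windows`.
#' @return Named numeric vector of peak areas (ml x absorbance units).
#' @export
integrate_peaks <- function(chrom) {
  stopifnot(inherits(chrom, "fs_chromatogram"))
  if (length(chrom$peak_windows) == 0L) {
    stop("precondition error: no peak windows defined", call. = FALSE)
  }
  vapply(chrom$peak_windows, function(w) {
    sel <- chrom$volume >= w[1L] & chrom$volume <= w[2L]
    if (sum(sel) < 2L) {
      stop("range error: window [", w[1L], ", ", w[2L],
           "] covers fewer than 2 data points", call. = FALSE)
    }
    v <- chrom$volume[sel]
    a <- chrom$absorbance[sel]
    # linear baseline between window endpoints
    base <- a[1L] + (a[length(a)] - a[1L]) *
      (v - v[1L]) / (v[length(v)] - v[1L])
    trapz_fs(v, a - base)
  }, numeric(1L))
}
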