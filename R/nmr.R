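# 15N/1H gyromagnetic ratio magnitude: nu_N = 0.10136767 * nu_1H
GAMMA_RATIO_15N <- 0.10136767

#' Amide-shift temperature coefficients by ordinary least squares
#'
#' Fits `shift_ppm ~ temperature_K` per residue and reports the slope in
#' ppb/K (ppm/K x 1000), the intercept, r-squared and the point count.
#' Residues with fewer than 3 usable points are skipped with a warning;
#' an error is raised when no residue survives.
#'
#' @param table An `"observable_table"` of kind `"tempseries"`.
#' @param threshold Classification threshold in ppb/K: slopes strictly above
#'   it are flagged as intramolecularly hydrogen bonded (see
#'   [classify_hbond_from_tempco()]).
#' @return data.frame with columns `residue`, `slope` (ppb/K), `intercept`
#'   (ppm), `r_squared`, `n_points`, `hb_classified`.
#' @export
temp_coefficient <- function(table, threshold = -5.0) {
  stopifnot(inherits(table, "observable_table"),
            attr(table, "kind") == "tempseries")
  out <- list()
  skipped <- character(0)
  for (res in unique(table$residue)) {
    sub <- table[table$residue == res &
                   !is.na(table$shift_ppm) & !is.na(table$temperature_K), ]
    if (nrow(sub) < 3) {
      skipped <- c(skipped, res)
      next
    }
    fit <- stats::lm(shift_ppm ~ temperature_K, data = sub)
    slope_ppb <- unname(stats::coef(fit)[2]) * 1000
    ss_tot <- sum((sub$shift_ppm - mean(sub$shift_ppm))^2)
    r2 <- if (ss_tot < 1e-300) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
    out[[length(out) + 1]] <- data.frame(
      residue = res, slope = slope_ppb,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = min(max(r2, 0), 1), n_points = nrow(sub),
      hb_classified = classify_hbond_from_tempco(slope_ppb, threshold))
  }
  if (length(skipped) > 0) {
    warning("skipped residue(s) with < 3 points: ",
            paste(skipped, collapse = ", "))
  }
  if (length(out) == 0) stop("no residue has >= 3 usable points")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify an amide as hydrogen bonded from its temperature coefficient
#'
#' The empirical rule: a temperature coefficient strictly greater than the
#' threshold (default -5.0 ppb/K; -2.72 ppb/K is the common alternative
#' calibration) indicates an intramolecular hydrogen bond.
#'
#' @param slope Temperature coefficient(s), ppb/K.
#' @param threshold Threshold, ppb/K.
#' @return Logical vector: `TRUE` where `slope > threshold`.
#' @export
classify_hbond_from_tempco <- function(slope, threshold = -5.0) {
  slope > threshold
}

#' Correlate two per-residue temperature-coefficient profiles
#'
#' Computed over the intersection of residue keys; no imputation.
#'
#' @param profileA,profileB Named numeric vectors, residue -> slope (ppb/K).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `n_matched`, `method`.
#' @export
tempco_correlation <- function(profileA, profileB,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(profileA), names(profileB))
  if (length(common) < 3) {
    stop("need at least 3 matched residues, got ", length(common))
  }
  list(r = stats::cor(profileA[common], profileB[common], method = method),
       n_matched = length(common), method = method)
}

#' Hydrogen-deuterium exchange protection ratios and counts
#'
#' The protection ratio of a residue is `I(t) / I(0)`. A residue is
#' protected at threshold `theta` when `ratio >= theta` (inclusive, the
#' default convention for the 0.2 threshold) or `ratio > theta` when the
#' threshold is declared strict (the convention for thresholds quoted as
#' "> 60 %" or "> 10 %"). Residues with `I(0) <= 0` are excluded with a
#' warning.
#'
#' @param table An `"observable_table"` of kind `"hdx"`.
#' @param t Exchange time (h) whose intensities form the numerator.
#' @param thresholds Numeric vector of ratio thresholds.
#' @param strict Logical, recycled over `thresholds`: use strict inequality.
#' @return List with `results` (data.frame `residue`, `ratio`, plus one
#'   logical `protected_at_<theta>` column per threshold) and `counts`
#'   (named integer vector of protected residues per threshold).
#' @export
hdx_protection <- function(table, t = 48, thresholds = 0.2, strict = FALSE) {
  stopifnot(inherits(table, "observable_table"),
            attr(table, "kind") == "hdx")
  strict <- rep_len(strict, length(thresholds))
  i0 <- table[table$time_h == 0, c("residue", "intensity")]
  it <- table[table$time_h == t, c("residue", "intensity")]
  if (nrow(it) == 0) stop("no intensities at t = ", t, " h")
  m <- merge(i0, it, by = "residue", suffixes = c("_0", "_t"))
  bad <- m$residue[is.na(m$intensity_0) | m$intensity_0 <= 0]
  if (length(bad) > 0) {
    warning("excluded residue(s) with I(0) <= 0: ",
            paste(bad, collapse = ", "))
    m <- m[!m$residue %in% bad, ]
  }
  if (nrow(m) == 0) stop("no residue has a positive reference intensity")
  res <- data.frame(residue = m$residue,
                    ratio = m$intensity_t / m$intensity_0,
                    stringsAsFactors = FALSE)
  counts <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    prot <- if (strict[k]) res$ratio > thresholds[k] else
      res$ratio >= thresholds[k]
    res[[sprintf("protected_at_%g", thresholds[k])]] <- prot
    counts[k] <- sum(prot, na.rm = TRUE)
  }
  names(counts) <- sprintf("%g", thresholds)
  list(results = res, counts = counts)
}

#' Rotational correlation time from the 15N R2/R1 ratio
#'
#' Single-field isotropic estimator:
#' `tau_c = sqrt(6 R2/R1 - 7) / (4 pi nu_N)` with
#' `nu_N = 0.10136767 x field_1H`. Valid only where `6 R2/R1 - 7 > 0`.
#' This closed form is an approximation to full spectral-density fitting;
#' it assumes isotropic tumbling and negligible fast internal motion.
#'
#' @param r1 Longitudinal relaxation rate(s), 1/s.
#' @param r2 Transverse relaxation rate(s), 1/s.
#' @param field_1H Proton Larmor frequency, MHz.
#' @return Rotational correlation time(s) in ns.
#' @export
tauc_from_relaxation <- function(r1, r2, field_1H) {
  stopifnot(all(r1 > 0), all(r2 > 0), field_1H > 0)
  radicand <- 6 * r2 / r1 - 7
  if (any(radicand <= 0)) {
    stop("6 R2/R1 - 7 must be positive; offending ratio(s): ",
         paste(signif((r2 / r1)[radicand <= 0], 4), collapse = ", "))
  }
  nu_n <- field_1H * 1e6 * GAMMA_RATIO_15N     # Hz
  tau_s <- sqrt(radicand) / (4 * pi * nu_n)
  tau_s * 1e9
}

#' Invert the tau_c estimator: the R2/R1 ratio implied by a tau_c
#'
#' @param tauc_ns Rotational correlation time, ns.
#' @param field_1H Proton Larmor frequency, MHz.
#' @return The implied R2/R1 ratio.
#' @export
r2r1_from_tauc <- function(tauc_ns, field_1H) {
  nu_n <- field_1H * 1e6 * GAMMA_RATIO_15N
  ((tauc_ns * 1e-9 * 4 * pi * nu_n)^2 + 7) / 6
}
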