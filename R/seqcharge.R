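#' Charge composition of a protein sequence
#'
#' Counts positively and negatively charged residues: K and R positive, D
#' and E negative under the default `"KR_DE"` scheme (histidine neutral,
#' termini excluded); `"KRH_DE"` adds histidine to the positives. The net
#' charge is `n_positive - n_negative` in units of e.
#'
#' @param sequence Amino-acid sequence (one-letter codes, `X` allowed and
#'   counted neutral).
#' @param scheme Charge scheme.
#' @param id Sequence identifier carried into the output.
#' @return One-row data.frame of class `"charge_profile"`: `sequence_id`,
#'   `length`, `n_positive`, `n_negative`, `pct_positive`, `pct_negative`,
#'   `net_charge`.
#' @export
#' @examples
#' charge_profile("KRDE")
charge_profile <- function(sequence, scheme = c("KR_DE", "KRH_DE"),
                           id = "") {
  scheme <- match.arg(scheme)
  check_sequence(sequence, if (nzchar(id)) id else "<sequence>")
  chars <- strsplit(sequence, "")[[1]]
  pos_set <- if (scheme == "KRH_DE") c("K", "R", "H") else c("K", "R")
  n_pos <- sum(chars %in% pos_set)
  n_neg <- sum(chars %in% c("D", "E"))
  len <- length(chars)
  structure(data.frame(sequence_id = id, length = len,
                       n_positive = n_pos, n_negative = n_neg,
                       pct_positive = n_pos / len * 100,
                       pct_negative = n_neg / len * 100,
                       net_charge = n_pos - n_neg,
                       stringsAsFactors = FALSE),
            class = c("charge_profile", "data.frame"))
}

#' Counterions required to neutralise a solute
#'
#' @param x A `"charge_profile"` (or any data.frame with a `net_charge`
#'   column), or a bare net charge in e.
#' @return Named integer vector `c(n_cations, n_anions)`; adding
#'   `n_cations - n_anions` to the net charge gives exactly zero.
#' @export
#' @examples
#' counterions_for_neutrality(-3)   # three cations
counterions_for_neutrality <- function(x) {
  net <- if (is.data.frame(x)) x$net_charge else as.numeric(x)
  stopifnot(length(net) == 1, is.finite(net))
  c(n_cations = max(0L, as.integer(-net)),
    n_anions = max(0L, as.integer(net)))
}

#' Positions at which a variant differs from its template
#'
#' @param template,variant Equal-length sequences (after applying `offset`
#'   leading residues trimmed from the longer one).
#' @param offset Declared alignment offset (variant starts `offset` residues
#'   into the template), default 0.
#' @return data.frame with columns `position` (1-based, template numbering),
#'   `from`, `to`; the substitution count is `nrow()` and is also stored in
#'   the `"count"` attribute.
#' @export
substitution_map <- function(template, variant, offset = 0) {
  check_sequence(template, "template")
  check_sequence(variant, "variant")
  tc <- strsplit(template, "")[[1]]
  vc <- strsplit(variant, "")[[1]]
  if (offset > 0) tc <- tc[-seq_len(offset)]
  if (length(tc) != length(vc)) {
    stop(sprintf("length mismatch: template %d vs variant %d (offset %d)",
                 length(tc), length(vc), offset))
  }
  diff_at <- which(tc != vc)
  out <- data.frame(position = diff_at + offset, from = tc[diff_at],
                    to = vc[diff_at], stringsAsFactors = FALSE)
  attr(out, "count") <- nrow(out)
  out
}

#' Charged-residue enrichment statistics over a design set
#'
#' For each variant, the change in percent positive and percent negative
#' composition relative to the template; means and standard deviations over
#' the set.
#'
#' @param designs A `"design_set"` (see [make_design_set()]) or a named
#'   character vector of variant sequences.
#' @param template Template sequence; defaults to the design set's own.
#' @param scheme Charge scheme, see [charge_profile()].
#' @return List of class `"enrichment_summary"`: `n_variants`,
#'   `mean_delta_pct_positive`, `mean_delta_pct_negative`,
#'   `sd_delta_pct_positive`, `sd_delta_pct_negative`, and `per_variant`
#'   (data.frame of the individual deltas).
#' @export
enrichment_stats <- function(designs, template = NULL,
                             scheme = c("KR_DE", "KRH_DE")) {
  scheme <- match.arg(scheme)
  if (inherits(designs, "design_set")) {
    if (is.null(template)) template <- designs$template
    variants <- designs$variants
  } else {
    variants <- designs
    if (is.null(template)) stop("template is required")
  }
  if (length(variants) == 0) stop("design set is empty")
  tp <- charge_profile(template, scheme, id = "template")
  per <- lapply(seq_along(variants), function(i) {
    vp <- charge_profile(variants[[i]], scheme, id = names(variants)[i])
    data.frame(variant_id = names(variants)[i],
               delta_pct_positive = vp$pct_positive - tp$pct_positive,
               delta_pct_negative = vp$pct_negative - tp$pct_negative,
               delta_n_positive = vp$n_positive - tp$n_positive,
               delta_n_negative = vp$n_negative - tp$n_negative,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(
    n_variants = length(variants),
    mean_delta_pct_positive = mean(per$delta_pct_positive),
    mean_delta_pct_negative = mean(per$delta_pct_negative),
    sd_delta_pct_positive = stats::sd(per$delta_pct_positive),
    sd_delta_pct_negative = stats::sd(per$delta_pct_negative),
    per_variant = per), class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(paste0("Enrichment over %d variants: mean d%%pos = %+.2f ",
                     "(sd %.2f), mean d%%neg = %+.2f (sd %.2f)\n"),
              x$n_variants, x$mean_delta_pct_positive,
              x$sd_delta_pct_positive, x$mean_delta_pct_negative,
              x$sd_delta_pct_negative))
  invisible(x)
}
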