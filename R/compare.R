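#' @include affinity.R
NULL

#' Compare ancestral and minor allele affinity estimates
#'
#' The standardized difference
#' `Z = (minor - ancestral) / sqrt(delta_a^2 + delta_m^2)` on the -ln KD
#' scale, referred to the standard normal (two-sided). The verdict maps
#' direction to predicted gene-product abundance: significantly higher TBP
#' affinity of the minor allele predicts overexpression (`"excess"`),
#' significantly lower predicts `"deficiency"`, otherwise
#' `"insignificant"`. Equality with the alpha quantile counts as
#' significant (closed boundary).
#'
#' @param ancestral,minor [AffinityEstimate-class] objects for the two alleles.
#' @param alpha two-sided significance level, default 0.05.
#' @return An [AlleleComparison-class].
#' @examples
#' # identical estimates give Z = 0 and an insignificant verdict
#' @export
compareAlleles <- function(ancestral, minor, alpha = 0.05) {
  stopifnot(is(ancestral, "AffinityEstimate"), is(minor, "AffinityEstimate"))
  if (uncertainty(ancestral) <= 0 || uncertainty(minor) <= 0)
    stop("both estimates must carry a positive delta")
  diff <- minusLnKd(minor) - minusLnKd(ancestral)
  z <- diff / sqrt(uncertainty(ancestral)^2 + uncertainty(minor)^2)
  p <- 2 * stats::pnorm(-abs(z))
  verdict <- if (p > alpha) "insignificant" else if (z > 0) "excess" else "deficiency"
  new("AlleleComparison", z = z, pValue = p, verdict = verdict,
      foldChange = exp(diff), alpha = alpha,
      ancestral = ancestral, minor = minor)
}

#' Scan a variant table against loaded promoters
#'
#' For each variant, scores the ancestral promoter and the promoter carrying
#' the alternate base over `region`, compares the two estimates, and emits
#' one report row. A failing row (unknown gene, reference mismatch) becomes
#' an error row; the run continues and the number of failures is attached.
#'
#' @param promoters list of [PromoterSequence-class] (e.g. from
#'   [readPromoterFasta()]).
#' @param variants data.frame with columns gene, position, ref, alt, label
#'   (e.g. from [readVariantTable()]).
#' @param model calibrated [TataAffinityModel-class].
#' @param region scanned promoter interval, default `c(-70, -20)`.
#' @param alpha significance level for the verdict.
#' @return data.frame with one row per variant, in input order: gene,
#'   variant_label, ancestral_estimate, ancestral_delta, minor_estimate,
#'   minor_delta, z, p_value, verdict, fold_change, error. Attribute
#'   `n_failed` carries the failure count (0 on full success).
#' @export
scanVariants <- function(promoters, variants, model = defaultAffinityModel(),
                         region = c(-70, -20), alpha = 0.05) {
  requireCalibrated(model)
  genes <- vapply(promoters, geneLabel, "")
  empty_row <- function(gene, label, err = NA_character_) {
    data.frame(gene = gene, variant_label = label,
               ancestral_estimate = NA_real_, ancestral_delta = NA_real_,
               minor_estimate = NA_real_, minor_delta = NA_real_,
               z = NA_real_, p_value = NA_real_, verdict = NA_character_,
               fold_change = NA_real_, error = err, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    tryCatch({
      hit <- which(genes == v$gene)
      if (!length(hit)) stop("unknown gene label '", v$gene, "'")
      prom <- promoters[[hit[1]]]
      minor_prom <- applyVariant(prom, v$position, v$ref, v$alt)
      anc <- promoterAffinity(prom, model, region)
      min_ <- promoterAffinity(minor_prom, model, region)
      cmpr <- compareAlleles(anc, min_, alpha)
      data.frame(gene = v$gene, variant_label = v$label,
                 ancestral_estimate = minusLnKd(anc),
                 ancestral_delta = uncertainty(anc),
                 minor_estimate = minusLnKd(min_),
                 minor_delta = uncertainty(min_),
                 z = zScore(cmpr), p_value = pValue(cmpr),
                 verdict = verdict(cmpr), fold_change = foldChange(cmpr),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) empty_row(v$gene, v$label, conditionMessage(e)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_row("", "")[0, ]
  n_failed <- sum(!is.na(out$error))
  if (n_failed)
    warning(n_failed, " of ", nrow(out), " variant rows failed; see the 'error' column")
  attr(out, "n_failed") <- n_failed
  out
}
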