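#' @include AllGenerics.R
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Promoter sequence with TSS-anchored coordinates
#'
#' Holds a promoter DNA sequence together with the position of the
#' transcription start site (TSS), so that biological promoter coordinates
#' (\ldots, -2, -1, +1, +2, \ldots; there is no position 0) can be mapped
#' onto the sequence. Coordinate -1 immediately precedes +1.
#'
#' @slot gene single gene label.
#' @slot seq a [Biostrings::DNAString] over the unambiguous alphabet
#'   \{A,C,G,T\}; lowercase input is uppercased on construction.
#' @slot tss 1-based position within `seq` of the base denoted +1. May be
#'   `length(seq) + 1`, meaning the whole record lies upstream of the TSS.
#'
#' @seealso [PromoterSequence()], [coordToIndex()], [applyVariant()]
#' @export
setClass("PromoterSequence",
  representation(gene = "character", seq = "DNAString", tss = "integer"))

setValidity("PromoterSequence", function(object) {
  msg <- character()
  if (length(object@gene) != 1L || !nzchar(object@gene))
    msg <- c(msg, "'gene' must be a single non-empty string")
  s <- as.character(object@seq)
  if (nchar(s) == 0L)
    msg <- c(msg, "empty sequence")
  bad <- which(!strsplit(s, "")[[1]] %in% DNA_BASES4)
  if (length(bad))
    msg <- c(msg, sprintf("non-ACGT character at position %d ('%s')",
                          bad[1], substr(s, bad[1], bad[1])))
  if (length(object@tss) != 1L || is.na(object@tss) ||
      object@tss < 1L || object@tss > nchar(s) + 1L)
    msg <- c(msg, "'tss' must lie in [1, length(seq) + 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterSequence
#'
#' @param gene gene label.
#' @param sequence DNA string (character or `DNAString`); lowercase accepted.
#' @param tss 1-based position of the +1 base within `sequence`. Defaults to
#'   `nchar(sequence) + 1`, i.e. the whole record is upstream sequence.
#' @return A [PromoterSequence-class] object.
#' @examples
#' p <- PromoterSequence("LEP", "acgtACGT", tss = 5)
#' tssIndex(p)
#' @export
PromoterSequence <- function(gene, sequence, tss = nchar(as.character(sequence)) + 1L) {
  s <- toupper(as.character(sequence))
  new("PromoterSequence", gene = as.character(gene),
      seq = Biostrings::DNAString(s), tss = as.integer(tss))
}

#' @rdname accessors
#' @export
setMethod("geneLabel", "PromoterSequence", function(x, ...) x@gene)

#' @rdname accessors
#' @export
setMethod("tssIndex", "PromoterSequence", function(x, ...) x@tss)

#' @rdname accessors
#' @export
setMethod("promoterSeq", "PromoterSequence", function(x, ...) x@seq)

setMethod("show", "PromoterSequence", function(object) {
  n <- length(object@seq)
  cat(sprintf("PromoterSequence '%s': %d nt, TSS (+1) at base %s\n",
              object@gene, n,
              if (object@tss > n) "beyond 3' end (all upstream)" else object@tss))
  cat("  ", as.character(if (n > 60)
      Biostrings::subseq(object@seq, 1, 60) else object@seq),
      if (n > 60) "..." else "", "\n", sep = "")
})

#' 26-bp probe sequence with provenance
#'
#' A fixed-length (26 nt) oligodeoxyribonucleotide probe cut from a promoter,
#' as used in the mobility-shift binding assays.
#'
#' @slot label probe label.
#' @slot seq a 26-nt `DNAString`.
#' @slot gene source gene label.
#' @slot start promoter coordinate of the first probe base.
#' @slot strand `"+"` or `"-"`.
#' @export
setClass("ProbeSequence",
  representation(label = "character", seq = "DNAString", gene = "character",
                 start = "integer", strand = "character"))

setValidity("ProbeSequence", function(object) {
  if (length(object@seq) != 26L) return("probe must be exactly 26 nt")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  TRUE
})

setMethod("show", "ProbeSequence", function(object) {
  cat(sprintf("ProbeSequence '%s' (%s, start %+d, strand %s)\n  %s\n",
              object@label, object@gene, object@start, object@strand,
              as.character(object@seq)))
})

#' Calibrated three-component TBP affinity model
#'
#' Bundles the TATA-box position weight matrix, the dinucleotide minor-groove
#' width scale, and the calibrated linear coefficients that map the three
#' mechanism components (specific recognition, minor-groove geometry,
#' nonspecific A/T sliding tract content) to -ln KD (KD in mol/L).
#'
#' @slot pwm 4 x width matrix of ln-odds weights, rows A,C,G,T.
#' @slot background background base frequencies (length 4, sums to 1).
#' @slot groove named numeric of 16 dinucleotide minor-groove widths (Angstrom).
#' @slot coefficients named numeric: `intercept`, `pwm`, `groove`, `slide`.
#' @slot singleCoefficients 3 x 2 matrix of per-component intercept/slope pairs
#'   used for the uncertainty (delta) ensemble.
#' @slot windowLength scan window length in bp.
#' @slot deltaFloor lower bound for delta (natural-log units).
#' @slot meta provenance list (training set, residual sd, notes).
#' @export
setClass("TataAffinityModel",
  representation(pwm = "matrix", background = "numeric", groove = "numeric",
                 coefficients = "numeric", singleCoefficients = "matrix",
                 windowLength = "integer", deltaFloor = "numeric",
                 meta = "list"))

setValidity("TataAffinityModel", function(object) {
  msg <- character()
  if (!identical(rownames(object@pwm), DNA_BASES4))
    msg <- c(msg, "pwm rows must be A,C,G,T")
  if (ncol(object@pwm) < 6L)
    msg <- c(msg, "pwm width must be >= 6")
  if (any(!is.finite(object@pwm)))
    msg <- c(msg, "pwm weights must be finite")
  if (length(object@background) != 4L || any(object@background <= 0) ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 strictly positive frequencies summing to 1")
  dn <- as.vector(outer(DNA_BASES4, DNA_BASES4, paste0))
  if (!all(dn %in% names(object@groove)))
    msg <- c(msg, "groove scale must cover all 16 dinucleotides")
  if (any(object@groove < 2 | object@groove > 8))
    msg <- c(msg, "groove widths outside the documented 2-8 Angstrom range")
  if (length(object@coefficients) &&
      !identical(names(object@coefficients), c("intercept", "pwm", "groove", "slide")))
    msg <- c(msg, "coefficients must be named intercept, pwm, groove, slide")
  if (any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  if (object@windowLength < ncol(object@pwm))
    msg <- c(msg, "windowLength must be >= pwm width")
  if (object@deltaFloor <= 0)
    msg <- c(msg, "deltaFloor must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("modelCoefficients", "TataAffinityModel", function(x, ...) x@coefficients)

#' @rdname accessors
#' @export
setMethod("windowLength", "TataAffinityModel", function(x, ...) x@windowLength)

setMethod("show", "TataAffinityModel", function(object) {
  cat(sprintf("TataAffinityModel: %d-bp windows, %d-position matrix\n",
              object@windowLength, ncol(object@pwm)))
  if (length(object@coefficients)) {
    cat("  calibrated coefficients (-ln KD scale):\n")
    print(round(object@coefficients, 4))
    if (!is.null(object@meta$residual_sd))
      cat(sprintf("  calibration: %s (n = %s, residual sd %.3f)\n",
                  object@meta$training %||% "unspecified",
                  object@meta$n %||% "?", object@meta$residual_sd))
  } else cat("  (uncalibrated: matrix and groove scale only)\n")
})

#' Windowed TBP affinity estimate
#'
#' Result of scanning a promoter region: the maximal window score on the
#' -ln KD scale, its uncertainty, the best window's location and component
#' values, and the full scan trace.
#'
#' @slot minusLnKd maximal window score, -ln KD with KD in mol/L.
#' @slot delta uncertainty (> 0), natural-log units.
#' @slot bestStart promoter coordinate of the best window start.
#' @slot strand strand of the best window.
#' @slot components named numeric of the three component values there.
#' @slot trace data.frame of every scored (start, strand, score).
#' @export
setClass("AffinityEstimate",
  representation(minusLnKd = "numeric", delta = "numeric", bestStart = "integer",
                 strand = "character", components = "numeric", trace = "data.frame"))

setValidity("AffinityEstimate", function(object) {
  msg <- character()
  if (object@delta <= 0) msg <- c(msg, "delta must be > 0")
  if (nrow(object@trace) &&
      abs(object@minusLnKd - max(object@trace$score)) > 1e-9)
    msg <- c(msg, "minusLnKd must equal the maximum of the scan trace")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("minusLnKd", "AffinityEstimate", function(x, ...) x@minusLnKd)

#' @rdname accessors
#' @export
setMethod("uncertainty", "AffinityEstimate", function(x, ...) x@delta)

#' @rdname accessors
#' @export
setMethod("bestWindow", "AffinityEstimate",
          function(x, ...) list(start = x@bestStart, strand = x@strand))

#' @rdname accessors
#' @export
setMethod("componentValues", "AffinityEstimate", function(x, ...) x@components)

#' @rdname accessors
#' @export
setMethod("scanTrace", "AffinityEstimate", function(x, ...) x@trace)

setMethod("show", "AffinityEstimate", function(object) {
  cat(sprintf("AffinityEstimate: -ln KD = %.3f +/- %.3f (KD ~ %.3g M)\n",
              object@minusLnKd, object@delta, exp(-object@minusLnKd)))
  cat(sprintf("  best window: start %+d, strand %s; %d windows scanned\n",
              object@bestStart, object@strand, nrow(object@trace)))
})

#' Ancestral-vs-minor allele comparison
#'
#' The standardized difference (Z) between two affinity estimates, its
#' two-sided normal p-value, and the resulting verdict on predicted gene
#' product abundance: `"excess"` (minor allele binds TBP more tightly),
#' `"deficiency"`, or `"insignificant"`.
#'
#' @slot z signed Z-score; positive means the minor allele increases affinity.
#' @slot pValue two-sided p-value.
#' @slot verdict one of `"excess"`, `"deficiency"`, `"insignificant"`.
#' @slot foldChange predicted KD ratio ancestral/minor.
#' @slot alpha significance level used.
#' @slot ancestral,minor the two [AffinityEstimate-class] inputs.
#' @export
setClass("AlleleComparison",
  representation(z = "numeric", pValue = "numeric", verdict = "character",
                 foldChange = "numeric", alpha = "numeric",
                 ancestral = "AffinityEstimate", minor = "AffinityEstimate"))

setValidity("AlleleComparison", function(object) {
  msg <- character()
  if (!object@verdict %in% c("excess", "deficiency", "insignificant"))
    msg <- c(msg, "invalid verdict")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must be in (0, 1]")
  if (object@foldChange <= 0)
    msg <- c(msg, "foldChange must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("zScore", "AlleleComparison", function(x, ...) x@z)

#' @rdname accessors
#' @export
setMethod("pValue", "AlleleComparison", function(x, ...) x@pValue)

#' @rdname accessors
#' @export
setMethod("verdict", "AlleleComparison", function(x, ...) x@verdict)

#' @rdname accessors
#' @export
setMethod("foldChange", "AlleleComparison", function(x, ...) x@foldChange)

setMethod("show", "AlleleComparison", function(object) {
  cat(sprintf("AlleleComparison: Z = %.2f, p = %.3g -> %s (alpha = %g)\n",
              object@z, object@pValue, object@verdict, object@alpha))
  cat(sprintf("  ancestral -ln KD %.3f +/- %.3f | minor %.3f +/- %.3f | KD fold-change %.2f\n",
              object@ancestral@minusLnKd, object@ancestral@delta,
              object@minor@minusLnKd, object@minor@delta, object@foldChange))
})

#' Global association-kinetics fit
#'
#' Shared association/dissociation rate constants fitted jointly across
#' time courses at several probe concentrations, with derived constants.
#'
#' @slot ka association rate constant, 1/(M s).
#' @slot kd dissociation rate constant, 1/s.
#' @slot amplitude signal per unit bound fraction.
#' @slot se named standard errors (`ka`, `kd`, `amplitude`).
#' @slot temperature kelvin.
#' @slot derived named numeric: `kStarD` (mol/L), `tHalf` (s),
#'   `minusDeltaG` (kcal/mol).
#' @slot diagnostics list: residual sd, iterations, points, curves.
#' @export
setClass("KineticsFit",
  representation(ka = "numeric", kd = "numeric", amplitude = "numeric",
                 se = "numeric", temperature = "numeric", derived = "numeric",
                 diagnostics = "list"))

setValidity("KineticsFit", function(object) {
  msg <- character()
  if (object@ka <= 0 || object@kd <= 0)
    msg <- c(msg, "rate constants must be positive")
  d <- object@derived
  if (!identical(names(d), c("kStarD", "tHalf", "minusDeltaG")))
    msg <- c(msg, "derived must be named kStarD, tHalf, minusDeltaG")
  else {
    if (d[["kStarD"]] != object@kd / object@ka)
      msg <- c(msg, "kStarD must equal kd/ka exactly")
    if (d[["tHalf"]] != log(2) / object@kd)
      msg <- c(msg, "tHalf must equal ln(2)/kd exactly")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("rateConstants", "KineticsFit",
          function(x, ...) c(ka = x@ka, kd = x@kd))

#' @rdname accessors
#' @export
setMethod("derivedConstants", "KineticsFit", function(x, ...) x@derived)

#' @rdname accessors
#' @export
setMethod("standardErrors", "KineticsFit", function(x, ...) x@se)

setMethod("show", "KineticsFit", function(object) {
  d <- object@derived
  cat("KineticsFit (global, shared ka/kd/amplitude)\n")
  cat(sprintf("  ka = %.3g +/- %.2g 1/(M s);  kd = %.3g +/- %.2g 1/s\n",
              object@ka, object@se[["ka"]], object@kd, object@se[["kd"]]))
  cat(sprintf("  K*D = %.3g M (%.1f nM);  t1/2 = %.1f min;  -dG = %.2f kcal/mol at %.2f K\n",
              d[["kStarD"]], d[["kStarD"]] * 1e9, d[["tHalf"]] / 60,
              d[["minusDeltaG"]], object@temperature))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
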