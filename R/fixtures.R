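#' @include sequence-io.R
NULL

#' Measured binding constants for the six packaged probes
#'
#' The six 26-bp double-stranded probes covering the ancestral and minor
#' alleles of the leptin (LEP) promoter variants -38a, -35g, -30t and the
#' glucagon (GCG) promoter variant -41g, with their measured association and
#' dissociation rate constants (gel-shift association kinetics at 25 C,
#' 0.3 nM TBP) and the reported apparent constant, half-life and free
#' energy. Rates are the primary data: `kstar_reported_nM` is the reported
#' value, which for the GCG rows differs slightly from `kd/ka` at the
#' reported precision; [deriveConstants()] always derives from the rates.
#'
#' @return data.frame with columns label, gene, allele, odn, odn_start
#'   (promoter coordinate of the probe's first base), variant_position,
#'   ref, alt, ka (1/(M s)), ka_se, kd (1/s), kd_se, kstar_reported_nM,
#'   thalf_reported_min, minus_dg_reported_kcal.
#' @examples
#' tab <- probeKinetics()
#' deriveConstants(tab$ka[1], tab$kd[1])
#' @export
probeKinetics <- function() {
  data.frame(
    label = c("LEP_WT", "LEP_-38a", "LEP_-30t", "LEP_-35g", "GCG_WT", "GCG_-41g"),
    gene = c(rep("LEP", 4), rep("GCG", 2)),
    allele = c("ancestral", "minor", "minor", "minor", "ancestral", "minor"),
    odn = c("ATCGGGCCGCTATAAGAGGGGCGGGC",
            "ATCGGGCCACTATAAGAGGGGCGGGC",
            "ATCGGGCCGCTATAAGTGGGGCGGGC",
            "ATCGGGCCGCTGTAAGAGGGGCGGGC",
            "AGCTGGAGAGTATATAAAAGCAGTGC",
            "AGCTGGAGAGTGTATAAAAGCAGTGC"),
    odn_start = c(rep(-46L, 4), rep(-52L, 2)),
    variant_position = c(NA, -38L, -30L, -35L, NA, -41L),
    ref = c(NA, "G", "A", "A", NA, "A"),
    alt = c(NA, "A", "T", "G", NA, "G"),
    ka = c(2.3e3, 3.5e3, 11.0e3, 5.6e3, 70e3, 30e3),
    ka_se = c(0.6e3, 0.5e3, 2.0e3, 0.8e3, 10e3, 10e3),
    kd = c(1.8e-4, 1.5e-4, 8.0e-4, 13.0e-4, 5e-4, 6e-4),
    kd_se = c(0.6e-4, 0.2e-4, 1.0e-4, 2e-4, 1.0e-4, 1.0e-4),
    kstar_reported_nM = c(78, 43, 73, 232, 8, 18),
    thalf_reported_min = c(64, 77, 14, 9, 23, 19),
    minus_dg_reported_kcal = c(9.7, 10.0, 9.7, 9.0, 11.1, 10.5),
    stringsAsFactors = FALSE)
}

# Synthetic flanks used to embed the assayed probes in a promoter-sized
# sequence: GC-rich, free of W|W dinucleotide steps, so the pads neither
# mimic a TATA box nor extend A/T sliding tracts. The true genomic flanks
# are not part of the packaged data.
PAD5 <- "CTCGCACCTGCCGCGCACCTCACGCGCACCGCTG"
PAD3 <- "CGCCTGCCACCGCGCCTCCGCTCGCACCACCGCCCGCGCTCCGCGC"

syntheticPromoter <- function(gene, odn, odn_start) {
  # promoter spans coordinates -80..-1, +1..+20 (100 nt), +1 at base 81
  up <- odn_start + 80L
  seqc <- paste0(substr(PAD5, 1L, up), odn,
                 substr(PAD3, 1L, 100L - up - nchar(odn)))
  PromoterSequence(gene, seqc, tss = 81L)
}

#' Synthetic example promoters carrying the assayed probes
#'
#' 100-nt promoter sequences (coordinates -80..+20) in which the packaged
#' ancestral 26-bp probe is embedded at its promoter position (LEP at
#' -46..-21, GCG at -52..-27) inside synthetic GC-rich flanks. The flanks
#' are constructed, not genomic; only the probe region is the assayed
#' sequence.
#'
#' @return A [PromoterSequence-class].
#' @examples
#' lep <- lepPromoterExample()
#' extractProbe(lep, -46)  # the assayed wild-type probe
#' @export
lepPromoterExample <- function() {
  tab <- probeKinetics()
  syntheticPromoter("LEP", tab$odn[tab$label == "LEP_WT"], -46L)
}

#' @rdname lepPromoterExample
#' @export
gcgPromoterExample <- function() {
  tab <- probeKinetics()
  syntheticPromoter("GCG", tab$odn[tab$label == "GCG_WT"], -52L)
}

#' The four assayed promoter variants
#'
#' The LEP -38a, -35g, -30t and GCG -41g single-nucleotide substitutions as
#' a variant table matching [lepPromoterExample()] / [gcgPromoterExample()].
#'
#' @return data.frame with columns gene, position, ref, alt, label.
#' @export
exampleVariants <- function() {
  tab <- probeKinetics()
  v <- tab[tab$allele == "minor", ]
  data.frame(gene = v$gene, position = v$variant_position,
             ref = v$ref, alt = v$alt, label = v$label,
             stringsAsFactors = FALSE)
}
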