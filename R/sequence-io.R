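#' @include AllClasses.R
NULL

#' Read promoter sequences from FASTA
#'
#' Headers follow the dialect `>GENE tss=<i>` where `i` is the 0-based index
#' of the +1 base within the record. A header without a `tss=` key means the
#' whole record lies upstream of the TSS (the TSS sits just past the 3' end).
#' Lowercase bases are uppercased; IUPAC ambiguity codes are rejected with a
#' message naming the offending record and offset.
#'
#' @param path FASTA file.
#' @return A list of [PromoterSequence-class] objects, in record order.
#' @seealso [writePromoterFasta()]
#' @export
readPromoterFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    raw <- toupper(as.character(set[[i]]))
    if (nchar(raw) == 0L)
      stop("empty record '", header, "' in ", path)
    bad <- regexpr("[^ACGT]", raw)
    if (bad > 0L)
      stop(sprintf("record '%s': non-ACGT character '%s' at offset %d",
                   header, substr(raw, bad, bad), as.integer(bad)))
    fields <- strsplit(header, "\\s+")[[1]]
    gene <- fields[1]
    tss_field <- grep("^tss=", fields[-1], value = TRUE)
    tss <- if (length(tss_field)) {
      as.integer(sub("^tss=", "", tss_field[1])) + 1L  # header key is 0-based
    } else nchar(raw) + 1L
    PromoterSequence(gene, raw, tss)
  })
}

#' Write promoter sequences to FASTA
#'
#' Inverse of [readPromoterFasta()]: emits `>GENE tss=<0-based index>`
#' headers so that a write/read round trip is the identity.
#'
#' @param promoters list of [PromoterSequence-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePromoterFasta <- function(promoters, path) {
  lines <- unlist(lapply(promoters, function(p) {
    c(sprintf(">%s tss=%d", geneLabel(p), tssIndex(p) - 1L),
      as.character(promoterSeq(p)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Map promoter coordinates to sequence indices
#'
#' Biological promoter coordinates have no position 0: -1 immediately
#' precedes +1 (the TSS). `coordToIndex` returns the 1-based index within
#' the sequence; `indexToCoord` is its inverse.
#'
#' @param promoter a [PromoterSequence-class].
#' @param coordinate signed promoter coordinate(s), nonzero.
#' @param index 1-based sequence index(es).
#' @return Integer vector of indices (or coordinates).
#' @examples
#' p <- PromoterSequence("X", strrep("A", 10), tss = 8)
#' coordToIndex(p, -1)  # 7
#' coordToIndex(p, +1)  # 8
#' @export
coordToIndex <- function(promoter, coordinate) {
  stopifnot(is(promoter, "PromoterSequence"))
  coordinate <- as.integer(coordinate)
  if (any(coordinate == 0L))
    stop("promoter coordinate 0 does not exist (convention: -1 precedes +1)")
  idx <- ifelse(coordinate < 0L, tssIndex(promoter) + coordinate,
                tssIndex(promoter) + coordinate - 1L)
  n <- length(promoterSeq(promoter))
  out <- which(idx < 1L | idx > n)
  if (length(out))
    stop(sprintf("coordinate %d falls outside the %d-nt sequence",
                 coordinate[out[1]], n))
  as.integer(idx)
}

#' @rdname coordToIndex
#' @export
indexToCoord <- function(promoter, index) {
  stopifnot(is(promoter, "PromoterSequence"))
  index <- as.integer(index)
  n <- length(promoterSeq(promoter))
  if (any(index < 1L | index > n)) stop("index outside the sequence")
  ifelse(index < tssIndex(promoter), index - tssIndex(promoter),
         index - tssIndex(promoter) + 1L)
}

#' Apply a single-nucleotide substitution
#'
#' Replaces the base at a promoter coordinate after checking that the
#' reference base matches the sequence; exactly one base differs between
#' input and output.
#'
#' @param promoter a [PromoterSequence-class].
#' @param position promoter coordinate of the variant (negative upstream).
#' @param ref,alt single reference and alternate bases, `ref != alt`.
#' @return A new [PromoterSequence-class] carrying the alternate base.
#' @export
applyVariant <- function(promoter, position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% DNA_BASES4 || !alt %in% DNA_BASES4)
    stop("ref and alt must be single A/C/G/T bases")
  if (ref == alt) stop("ref and alt must differ")
  i <- coordToIndex(promoter, position)
  s <- as.character(promoterSeq(promoter))
  found <- substr(s, i, i)
  if (found != ref)
    stop(sprintf("reference mismatch at %+d: expected '%s', sequence has '%s'",
                 as.integer(position), ref, found))
  substr(s, i, i) <- alt
  PromoterSequence(geneLabel(promoter), s, tssIndex(promoter))
}

#' Extract a probe window from a promoter
#'
#' Cuts the subsequence starting at a promoter coordinate, recording its
#' provenance. The default length (26 bp) matches the synthesized
#' double-stranded probes used in the binding assays.
#'
#' @param promoter a [PromoterSequence-class].
#' @param start promoter coordinate of the first probe base.
#' @param length probe length in bp (>= 1).
#' @param label probe label; defaults to `"<gene>:<start>"`.
#' @return A [ProbeSequence-class] (length must be 26 for the class; other
#'   lengths return a plain `DNAString` with provenance attributes).
#' @export
extractProbe <- function(promoter, start, length = 26L, label = NULL) {
  length <- as.integer(length)
  if (length < 1L) stop("probe length must be >= 1")
  i <- coordToIndex(promoter, start)
  n <- length(promoterSeq(promoter))  # note: base length() on DNAString
  if (i + length - 1L > n)
    stop(sprintf("probe window [%+d, +%d bases] extends past the sequence end",
                 as.integer(start), length))
  sub <- Biostrings::subseq(promoterSeq(promoter), i, i + length - 1L)
  if (is.null(label)) label <- sprintf("%s:%+d", geneLabel(promoter), as.integer(start))
  if (length == 26L)
    new("ProbeSequence", label = label, seq = sub, gene = geneLabel(promoter),
        start = as.integer(start), strand = "+")
  else
    structure(sub, label = label, gene = geneLabel(promoter),
              start = as.integer(start), strand = "+")
}

#' Read a variant table
#'
#' Tab-separated with header `gene position ref alt label`. Positions are
#' promoter coordinates (negative upstream of the TSS).
#'
#' @param path TSV file.
#' @return data.frame with columns gene, position, ref, alt, label.
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("gene", "position", "ref", "alt", "label")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$position <- as.integer(df$position)
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  validateVariants(df)
  df
}

#' Write a variant table
#' @param variants data.frame as returned by [readVariantTable()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  utils::write.table(variants[, c("gene", "position", "ref", "alt", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateVariants <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (any(df$position == 0L))
    stop("variant at coordinate 0: no such promoter position")
  if (any(df$position > 0L))
    stop("variants must lie upstream of the TSS (negative coordinates)")
  bad <- !(df$ref %in% DNA_BASES4) | !(df$alt %in% DNA_BASES4)
  if (any(bad)) stop("ref/alt must be single A/C/G/T bases (row ",
                     which(bad)[1], ")")
  same <- df$ref == df$alt
  if (any(same)) stop("ref and alt identical in row ", which(same)[1])
  invisible(df)
}

#' Read variants from a minimal TSS-relative VCF dialect
#'
#' Accepts the small VCF-like dialect in which CHROM carries the gene label
#' and POS carries the (negative) promoter coordinate. Only single-nucleotide
#' substitution records are accepted; anything else errors. Note this is not
#' genomic VCF: conforming VCF requires positive POS, which is why the
#' dialect is parsed directly.
#'
#' @param path file with `#CHROM POS ID REF ALT ...` columns after `##` meta
#'   lines.
#' @return data.frame with columns gene, position, ref, alt, label.
#' @export
readVariantVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM"))
    stop("missing #CHROM header line")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(gene = character(), position = integer(),
                      ref = character(), alt = character(),
                      label = character(), stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L)) stop("VCF record with fewer than 5 fields")
  df <- data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    position = as.integer(vapply(parts, `[[`, "", 2L)),
    ref = toupper(vapply(parts, `[[`, "", 4L)),
    alt = toupper(vapply(parts, `[[`, "", 5L)),
    label = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
    stop("only single-nucleotide substitutions are supported")
  df$label[df$label == "."] <- sprintf("%s%+d%s", df$gene, df$position,
                                       tolower(df$alt))[df$label == "."]
  validateVariants(df)
  df
}
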