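# shared helpers: seeded random sequences and independent brute-force oracles

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

randomPromoter <- function(n = 80, tss = n - 9L, gene = "RND")
  PromoterSequence(gene, randomSeq(n), tss = tss)

revcomp_chr <- function(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# an AffinityEstimate built directly from numbers, for comparator tests
makeEstimate <- function(mlkd, delta) {
  new("AffinityEstimate", minusLnKd = mlkd, delta = delta,
      bestStart = -46L, strand = "+",
      components = c(pwm = 0, groove = 0, slide = 0),
      trace = data.frame(start = integer(), strand = character(),
                         score = numeric(), stringsAsFactors = FALSE))
}

# exhaustive promoter-scan oracle: enumerates every (start, strand) placement
# with plain string operations, independent of the scan implementation
oracleScanMax <- function(promoter, model, region) {
  L <- windowLength(model)
  seqc <- as.character(promoterSeq(promoter))
  tss <- tssIndex(promoter)
  best <- -Inf
  for (st in setdiff(region[1]:region[2], 0)) {
    i <- if (st < 0) tss + st else tss + st - 1L
    if (i < 1 || i + L - 1L > nchar(seqc)) next
    w <- substr(seqc, i, i + L - 1L)
    for (ww in c(w, revcomp_chr(w)))
      best <- max(best, windowAffinity(ww, model)$score)
  }
  best
}

# brute-force placement oracle for the matrix score
oraclePwm <- function(window, model) {
  m <- model@pwm
  s <- strsplit(window, "")[[1]]
  width <- ncol(m)
  max(vapply(seq_len(length(s) - width + 1L), function(i)
    sum(vapply(seq_len(width), function(j) m[s[i + j - 1L], j], 0)), 0))
}

# concordant/discordant pair counting, written independently of the package
oraclePairs <- function(x, y) {
  C <- 0; D <- 0; n <- length(x)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx * dy > 0) C <- C + 1
    if (dx * dy < 0) D <- D + 1
  }
  list(C = C, D = D)
}

oracleTauA <- function(x, y) {
  cd <- oraclePairs(x, y)
  (cd$C - cd$D) / choose(length(x), 2)
}

# independent recursive full enumeration of permutations (for checking the
# package's exact permutation significance at small n)
allPermsRec <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in allPermsRec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
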