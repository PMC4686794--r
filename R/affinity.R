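#' @include model-config.R
NULL

# windows are plain uppercase ACGT character scalars throughout this file;
# DNAString inputs are converted once at the promoterAffinity boundary.

asWindowString <- function(window) {
  w <- toupper(as.character(window))
  if (length(w) != 1L) stop("a single window string is expected")
  if (grepl("[^ACGT]", w)) stop("window contains non-ACGT characters")
  w
}

#' TATA-matrix recognition score of a window
#'
#' Maximal sum of per-position ln-odds weights over every placement of the
#' weight matrix inside the window (forward orientation; strand handling
#' happens at the scan level).
#'
#' @param window DNA window (character or `DNAString`), length >= matrix width.
#' @param model a [TataAffinityModel-class] (its `pwm` slot is used).
#' @return Numeric score (ln-odds units).
#' @export
pwmScore <- function(window, model) {
  w <- asWindowString(window)
  m <- model@pwm
  width <- ncol(m)
  n <- nchar(w)
  if (n < width)
    stop(sprintf("window (%d nt) shorter than the matrix (%d positions)", n, width))
  s <- match(strsplit(w, "")[[1]], DNA_BASES4)
  best <- -Inf
  for (i in seq_len(n - width + 1L)) {
    sc <- sum(m[cbind(s[i:(i + width - 1L)], seq_len(width))])
    if (sc > best) best <- sc
  }
  best
}

#' Minor-groove geometry term of a window
#'
#' Mean minor-groove width over the central 8 dinucleotide steps of the
#' window (all steps if fewer), *negated* so that a narrower minor groove --
#' the deformable geometry TBP prefers -- raises the term. With a
#' strand-symmetrized scale the term equals that of the reverse complement
#' exactly whenever the central block is uniquely centred (odd-length
#' windows, or windows with at most 9 bases); for other lengths the
#' floor-centred block can differ from the mirrored one by one boundary
#' step.
#'
#' @param window DNA window, length >= 2.
#' @param model a [TataAffinityModel-class] (its `groove` scale is used).
#' @return Numeric, minus the mean width in Angstrom.
#' @export
grooveTerm <- function(window, model) {
  w <- asWindowString(window)
  n <- nchar(w)
  if (n < 2L) stop("window must have at least one dinucleotide step")
  s <- strsplit(w, "")[[1]]
  steps <- paste0(s[-n], s[-1L])
  ns <- length(steps)
  k <- min(8L, ns)
  # floor-centred block: when ns - k is odd there is no uniquely central
  # 8-step block; the lower placement is taken, so exact reverse-complement
  # symmetry holds whenever the block is uniquely centred (ns - k even,
  # e.g. every odd-length window) and is off by at most one boundary step
  # otherwise
  lo <- (ns - k) %/% 2L + 1L
  -mean(model@groove[steps[lo:(lo + k - 1L)]])
}

#' Nonspecific sliding term of a window
#'
#' Fraction of dinucleotide steps that are W|W steps (TA, AT, AA, TT),
#' a proxy for the A/T tract content along which TBP slides nonspecifically
#' before site recognition. Always in `[0, 1]`.
#'
#' @param window DNA window, length >= 2.
#' @return Numeric fraction.
#' @examples
#' slideTerm("TATATA")  # 1
#' slideTerm("GCGCGC")  # 0
#' @export
slideTerm <- function(window) {
  w <- asWindowString(window)
  n <- nchar(w)
  if (n < 2L) stop("window must have at least one dinucleotide step")
  s <- strsplit(w, "")[[1]]
  steps <- paste0(s[-n], s[-1L])
  mean(steps %in% c("TA", "AT", "AA", "TT"))
}

windowComponents <- function(window, model) {
  c(pwm = pwmScore(window, model),
    groove = grooveTerm(window, model),
    slide = slideTerm(window))
}

#' Score one window under a calibrated model
#'
#' The affinity score is the calibrated linear combination
#' `intercept + w_pwm * pwm + w_groove * groove + w_slide * slide`,
#' on the -ln KD scale (KD in mol/L).
#'
#' @param window DNA window of exactly `windowLength(model)` bases.
#' @param model a calibrated [TataAffinityModel-class].
#' @return List with `score` and the named `components` vector.
#' @export
windowAffinity <- function(window, model) {
  requireCalibrated(model)
  w <- asWindowString(window)
  if (nchar(w) != model@windowLength)
    stop(sprintf("window length %d != model window length %d",
                 nchar(w), model@windowLength))
  cm <- windowComponents(w, model)
  co <- model@coefficients
  list(score = unname(co[["intercept"]] + sum(co[c("pwm", "groove", "slide")] * cm)),
       components = cm)
}

requireCalibrated <- function(model) {
  if (!length(model@coefficients))
    stop("model is not calibrated; run calibrateAffinity() or use defaultAffinityModel()")
  invisible(model)
}

#' Scan a promoter region for the maximal TBP affinity
#'
#' Scores every window whose start coordinate lies in `region`, on both
#' strands, and returns the maximum as the promoter's affinity estimate,
#' with the uncertainty delta defined as the spread (sample sd) of the three
#' single-component predictions at the best window, floored at the model's
#' `deltaFloor`. Ties are broken toward the lower start coordinate, forward
#' strand first.
#'
#' @param promoter a [PromoterSequence-class].
#' @param model calibrated [TataAffinityModel-class].
#' @param region length-2 promoter coordinates, default `c(-70, -20)`: the
#'   interval where the proven TBP-binding sites of these promoters lie.
#' @return An [AffinityEstimate-class].
#' @export
promoterAffinity <- function(promoter, model = defaultAffinityModel(),
                             region = c(-70, -20)) {
  requireCalibrated(model)
  L <- model@windowLength
  seqc <- as.character(promoterSeq(promoter))
  n <- nchar(seqc)
  starts <- region[1]:region[2]
  starts <- starts[starts != 0L]
  if (!length(starts)) stop("empty scan region")
  keep <- vapply(starts, function(st) {
    i <- tryCatch(coordToIndex(promoter, st), error = function(e) NA_integer_)
    !is.na(i) && i + L - 1L <= n
  }, logical(1))
  starts <- starts[keep]
  if (!length(starts))
    stop(sprintf("region [%+d, %+d] leaves no room for a %d-bp window",
                 region[1], region[2], L))

  rows <- vector("list", 2L * length(starts))
  k <- 0L
  for (st in starts) {
    i <- coordToIndex(promoter, st)
    w <- substr(seqc, i, i + L - 1L)
    for (strand in c("+", "-")) {
      ww <- if (strand == "+") w else revcompChar(w)
      k <- k + 1L
      rows[[k]] <- list(start = st, strand = strand,
                        score = windowAffinity(ww, model)$score, window = ww)
    }
  }
  trace <- data.frame(start = vapply(rows, `[[`, 0L, "start"),
                      strand = vapply(rows, `[[`, "", "strand"),
                      score = vapply(rows, `[[`, 0, "score"),
                      stringsAsFactors = FALSE)
  best <- which.max(trace$score)  # first maximum: lower start, '+' first
  bw <- rows[[best]]$window
  cm <- windowComponents(bw, model)
  sp <- singleComponentPredictions(cm, model)
  new("AffinityEstimate",
      minusLnKd = trace$score[best],
      delta = max(stats::sd(sp), model@deltaFloor),
      bestStart = as.integer(trace$start[best]),
      strand = trace$strand[best],
      components = cm,
      trace = trace)
}

singleComponentPredictions <- function(components, model) {
  sc <- model@singleCoefficients
  vapply(rownames(sc), function(v) sc[v, 1L] + sc[v, 2L] * components[[v]], 0)
}

#' Calibrate the affinity model by ordinary least squares
#'
#' Fits intercept and the three component weights against measured -ln KD
#' over training windows of uniform length (the packaged default uses the
#' six 26-bp assay probes). Also fits the three one-component regressions
#' whose prediction spread defines the uncertainty delta. Deterministic.
#'
#' @param windows character vector of training windows (uniform length).
#' @param minusLnKd measured -ln KD values (KD in mol/L), same length.
#' @param model a [TataAffinityModel-class] skeleton (matrix + groove scale);
#'   its `windowLength` is set to the training window length.
#' @param meta extra provenance entries merged into the model meta.
#' @return A calibrated [TataAffinityModel-class].
#' @export
calibrateAffinity <- function(windows, minusLnKd, model = readModelConfig(),
                              meta = list()) {
  windows <- vapply(windows, asWindowString, "")
  if (length(windows) < 4L)
    stop("need at least 4 training pairs to identify 4 coefficients")
  if (length(unique(nchar(windows))) != 1L)
    stop("training windows must have uniform length")
  if (length(minusLnKd) != length(windows))
    stop("windows and minusLnKd lengths differ")
  X <- t(vapply(windows, windowComponents, numeric(3), model = model))
  for (v in colnames(X)) {
    if (stats::sd(X[, v]) == 0)
      stop("rank-deficient design: component '", v,
           "' is constant across the training windows")
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 4L)
    stop("rank-deficient design: components are collinear (rank ", qrX$rank, ")")
  df <- data.frame(X, y = minusLnKd)
  fit <- stats::lm(y ~ pwm + groove + slide, data = df)
  co <- stats::coef(fit)
  names(co) <- c("intercept", "pwm", "groove", "slide")
  sc <- t(vapply(c("pwm", "groove", "slide"), function(v)
    stats::coef(stats::lm(stats::reformulate(v, "y"), data = df)), numeric(2)))
  colnames(sc) <- c("intercept", "slope")
  res_sd <- sqrt(sum(stats::resid(fit)^2) / max(1L, length(windows) - 4L))
  newAffinityModel(
    pwm = model@pwm, background = model@background, groove = model@groove,
    windowLength = nchar(windows[1]), deltaFloor = model@deltaFloor,
    coefficients = co, singleCoefficients = sc,
    meta = utils::modifyList(model@meta, c(meta, list(
      n = length(windows), residual_sd = res_sd,
      calibrated = format(Sys.Date())))))
}
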