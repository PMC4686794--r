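#' @include AllClasses.R
NULL

checkPairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("at least 3 pairs are needed for significance")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in pairs")
  invisible(length(x))
}

#' Pearson product-moment correlation with significance
#'
#' Standard r; the significance level comes from the t transform
#' `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom, two-sided.
#'
#' @param x,y paired numeric vectors, n >= 3, each with nonzero variance.
#' @return list with `r` and `alpha`.
#' @export
pearsonR <- function(x, y) {
  checkPairs(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), alpha = ct$p.value)
}

countPairs <- function(x, y) {
  # concordant / discordant over all unordered pairs, ties excluded
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
  }
  c(C = C, D = D)
}

permutationAlpha <- function(x, y, stat, observed) {
  # exact enumeration over all orderings of y for n <= 8, two-sided on |stat|
  n <- length(y)
  perms <- permutationsOf(n)
  vals <- apply(perms, 1L, function(p) stat(x, y[p]))
  mean(abs(vals) >= abs(observed) - 1e-12)
}

permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Kendall rank correlation (tau-b) with significance
#'
#' Tie-corrected tau-b (equal to tau-a on tie-free data). Significance by
#' exact permutation enumeration for n <= 8, otherwise by the usual normal
#' approximation `z = 3 tau sqrt(n(n-1)) / sqrt(2(2n+5))`.
#'
#' @inheritParams pearsonR
#' @return list with `tau` and `alpha`.
#' @export
kendallTau <- function(x, y) {
  n <- checkPairs(x, y)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("all-tied variable: tau undefined")
  tau <- stats::cor(x, y, method = "kendall")
  alpha <- if (n <= 8L) {
    permutationAlpha(x, y, function(a, b) stats::cor(a, b, method = "kendall"), tau)
  } else {
    z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, alpha = alpha)
}

#' Goodman-Kruskal gamma with significance
#'
#' `gamma = (C - D) / (C + D)` over concordant and discordant pairs, tied
#' pairs excluded from both counts; equals tau-a on tie-free data.
#' Significance by the same permutation scheme as [kendallTau()].
#'
#' @inheritParams pearsonR
#' @return list with `gamma` and `alpha`.
#' @export
gkGamma <- function(x, y) {
  n <- checkPairs(x, y)
  cd <- countPairs(x, y)
  if (sum(cd) == 0L)
    stop("all pairs tied: gamma undefined")
  g <- unname((cd["C"] - cd["D"]) / (cd["C"] + cd["D"]))
  gstat <- function(a, b) {
    cd2 <- countPairs(a, b)
    if (sum(cd2) == 0L) return(0)
    (cd2[["C"]] - cd2[["D"]]) / (cd2[["C"]] + cd2[["D"]])
  }
  alpha <- if (n <= 8L) {
    permutationAlpha(x, y, gstat, g)
  } else {
    z <- 3 * g * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    2 * stats::pnorm(-abs(z))
  }
  list(gamma = g, alpha = alpha)
}

#' Full correlation report
#'
#' The three association measures used to confront predicted and measured
#' affinities (both on the -ln KD scale): Pearson r, Kendall tau-b and
#' Goodman-Kruskal gamma, each with its significance level.
#'
#' @inheritParams pearsonR
#' @param labels optional pair labels (recorded, not used in computation).
#' @return One-row data.frame: n, r, alpha_r, tau, alpha_tau, gamma,
#'   alpha_gamma.
#' @export
correlationReport <- function(x, y, labels = NULL) {
  pr <- pearsonR(x, y)
  kt <- kendallTau(x, y)
  gg <- gkGamma(x, y)
  out <- data.frame(n = length(x), r = pr$r, alpha_r = pr$alpha,
                    tau = kt$tau, alpha_tau = kt$alpha,
                    gamma = gg$gamma, alpha_gamma = gg$alpha)
  attr(out, "labels") <- labels
  out
}

#' Read a paired-measurement table
#'
#' TSV with header `label x y` (e.g. predicted and measured -ln KD).
#'
#' @param path TSV file.
#' @return data.frame with columns label, x, y.
#' @export
readPairedTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x", "y") %in% names(df)))
    stop("paired table must have columns: label, x, y")
  df[, c("label", "x", "y")]
}
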