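model <- defaultAffinityModel()

test_that("matrix score is the best placement and the consensus attains the bound", {
  consensus <- paste(rownames(model@pwm)[apply(model@pwm, 2, which.max)],
                     collapse = "")
  expect_equal(pwmScore(consensus, model), sum(apply(model@pwm, 2, max)))

  set.seed(21)
  for (rep in 1:25) {
    w <- randomSeq(sample(8:30, 1))
    expect_equal(pwmScore(w, model), oraclePwm(w, model))
  }
  expect_error(pwmScore("ACGTACG", model), "shorter than the matrix")
})

test_that("mutating the most conserved core A to G lowers the matrix score", {
  ctx <- "GGGCGTATAAAAGGGCG"
  mut <- sub("TATAAA", "TGTAAA", ctx)   # second core position, A -> G
  expect_lt(pwmScore(mut, model), pwmScore(ctx, model))
  mut4 <- sub("TATAAA", "TATGAA", ctx)  # fourth core position, A -> G
  expect_lt(pwmScore(mut4, model), pwmScore(ctx, model))
})

test_that("groove term averages the central steps, negated", {
  expect_equal(grooveTerm(strrep("A", 12), model), -model@groove[["AA"]])
  set.seed(22)
  for (rep in 1:25) {
    w <- randomSeq(sample(2:30, 1))
    s <- strsplit(w, "")[[1]]
    steps <- paste0(s[-length(s)], s[-1])
    k <- min(8, length(steps))
    from <- (length(steps) - k) %/% 2 + 1
    expect_equal(grooveTerm(w, model),
                 -mean(model@groove[steps[from:(from + k - 1)]]))
  }
})

test_that("groove term is reverse-complement symmetric where uniquely centred", {
  # the central 8-step block is uniquely centred for odd window lengths
  # (and any window of <= 9 bases), where symmetry under the symmetrized
  # scale is exact
  set.seed(28)
  for (n in c(3, 5, 7, 9, 11, 15, 21, 27)) {
    for (rep in 1:5) {
      w <- randomSeq(n)
      expect_equal(grooveTerm(revcomp_chr(w), model), grooveTerm(w, model))
    }
  }
})

test_that("slide term is the W|W step fraction", {
  expect_equal(slideTerm("TATATA"), 1)
  expect_equal(slideTerm("GCGCGC"), 0)
  set.seed(23)
  for (rep in 1:25) {
    w <- randomSeq(sample(2:30, 1))
    s <- strsplit(w, "")[[1]]
    steps <- paste0(s[-length(s)], s[-1])
    expect_equal(slideTerm(w),
                 sum(steps %in% c("TA", "AT", "AA", "TT")) / length(steps))
    expect_gte(slideTerm(w), 0); expect_lte(slideTerm(w), 1)
  }
})

test_that("window score is the calibrated linear combination", {
  skeleton <- readModelConfig()
  w <- "ATCGGGCCGCTATAAGAGGGGCGGGC"
  zero <- skeleton
  zero@coefficients <- c(intercept = 3.5, pwm = 0, groove = 0, slide = 0)
  zero@singleCoefficients <- matrix(0, 3, 2,
                                    dimnames = list(c("pwm", "groove", "slide"),
                                                    c("intercept", "slope")))
  expect_equal(windowAffinity(w, zero)$score, 3.5)

  base <- zero; base@coefficients["pwm"] <- 0.2
  dbl <- zero; dbl@coefficients["pwm"] <- 0.4
  contrib <- function(m) windowAffinity(w, m)$score - 3.5
  expect_equal(contrib(dbl), 2 * contrib(base))

  expect_error(windowAffinity("ACGT", model), "window length")
})

test_that("the calibrated model ranks the strong GCG probe above the LEP probe", {
  tab <- probeKinetics()
  gcg <- windowAffinity(tab$odn[tab$label == "GCG_WT"], model)$score
  lep <- windowAffinity(tab$odn[tab$label == "LEP_WT"], model)$score
  expect_gt(gcg, lep)  # measured K*D 8 nM vs 78 nM
})

test_that("promoter scan equals the exhaustive placement/strand oracle", {
  set.seed(24)
  for (rep in 1:40) {
    p <- randomPromoter(70, tss = 65)
    est <- promoterAffinity(p, model, region = c(-60, -30))
    expect_equal(minusLnKd(est), oracleScanMax(p, model, c(-60, -30)))
    expect_equal(minusLnKd(est), max(scanTrace(est)$score))
    expect_gt(uncertainty(est), 0)
  }
})

test_that("scan is local: bases outside every scanned window cannot change it", {
  lep <- lepPromoterExample()
  est <- promoterAffinity(lep, model)
  # region -70..-20 with 26-bp windows reaches at most +6; mutate +15
  i <- coordToIndex(lep, +15)
  s <- as.character(promoterSeq(lep))
  alt <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
  mut <- applyVariant(lep, +15, substr(s, i, i), alt)
  est2 <- promoterAffinity(mut, model)
  expect_identical(minusLnKd(est2), minusLnKd(est))
  expect_identical(uncertainty(est2), uncertainty(est))
})

test_that("scanning the reverse-complemented promoter mirrors the estimate", {
  set.seed(25)
  for (rep in 1:10) {
    p <- randomPromoter(70, tss = 65)
    region <- c(-60, -30)
    L <- windowLength(model)
    rcseq <- revcomp_chr(as.character(promoterSeq(p)))
    # window [st, st+L-1] maps onto the reverse complement as a window whose
    # start index is n - (i+L-1) + 1; express the mirrored region via a tss
    # placed so that the mirrored starts are scanned
    n <- nchar(rcseq)
    starts_fwd <- setdiff(region[1]:region[2], 0)
    idx_fwd <- ifelse(starts_fwd < 0, tssIndex(p) + starts_fwd,
                      tssIndex(p) + starts_fwd - 1)
    idx_rc <- sort(n - (idx_fwd + L - 1) + 1)
    prc <- PromoterSequence("RC", rcseq, tss = max(idx_rc) + L)
    region_rc <- range(idx_rc - (max(idx_rc) + L))
    est <- promoterAffinity(p, model, region)
    est_rc <- promoterAffinity(prc, model, region_rc)
    expect_equal(minusLnKd(est_rc), minusLnKd(est))
  }
})

test_that("disrupting the best window's strongest matrix position never helps", {
  set.seed(26)
  for (rep in 1:15) {
    p <- randomPromoter(70, tss = 65)
    region <- c(-60, -30)
    est <- promoterAffinity(p, model, region)
    bw <- bestWindow(est)
    i0 <- coordToIndex(p, bw$start)
    L <- windowLength(model)
    w <- substr(as.character(promoterSeq(p)), i0, i0 + L - 1)
    ww <- if (bw$strand == "+") w else revcomp_chr(w)
    # locate the matrix placement inside the oriented best window
    m <- model@pwm
    width <- ncol(m)
    scores <- vapply(seq_len(L - width + 1), function(i)
      sum(vapply(seq_len(width), function(j)
        m[substr(ww, i + j - 1, i + j - 1), j], 0)), 0)
    pl <- which.max(scores)
    col <- which.max(apply(m, 2, max))            # highest-weight position
    worst <- rownames(m)[which.min(m[, col])]     # its lowest-weight base
    pos_in_w <- pl + col - 1
    sub <- ww
    substr(sub, pos_in_w, pos_in_w) <- worst
    # write the disrupted window back into the promoter on the right strand
    neww <- if (bw$strand == "+") sub else revcomp_chr(sub)
    s <- as.character(promoterSeq(p))
    s2 <- paste0(substr(s, 1, i0 - 1), neww, substr(s, i0 + L, nchar(s)))
    est2 <- promoterAffinity(PromoterSequence("MUT", s2, tssIndex(p)), model, region)
    expect_lte(minusLnKd(est2), minusLnKd(est))
  }
})

test_that("calibration recovers known coefficients exactly on noiseless data", {
  skeleton <- readModelConfig()
  set.seed(27)
  windows <- replicate(8, randomSeq(26))
  X <- t(sapply(windows, function(w) c(pwmScore(w, skeleton),
                                       grooveTerm(w, skeleton), slideTerm(w))))
  truth <- c(intercept = 17, pwm = 0.3, groove = 1.5, slide = 4)
  y <- truth[1] + X %*% truth[-1]
  fit <- calibrateAffinity(windows, as.numeric(y), skeleton)
  expect_equal(modelCoefficients(fit), truth, tolerance = 1e-9)

  # duplicating a pair of an exactly-fitting training set changes nothing
  fit2 <- calibrateAffinity(c(windows, windows[1]), as.numeric(c(y, y[1])), skeleton)
  expect_equal(modelCoefficients(fit2), truth, tolerance = 1e-9)
})

test_that("the shipped calibration reproduces the measured probe ordering", {
  tab <- probeKinetics()
  pred <- vapply(tab$odn, function(w) windowAffinity(w, model)$score, 0)
  measured <- -log(tab$kstar_reported_nM * 1e-9)
  expect_equal(order(pred), order(measured))  # GCG WT strongest ... LEP -35g weakest
  expect_equal(unname(which.max(pred)), which(tab$label == "GCG_WT"))
  expect_equal(unname(which.min(pred)), which(tab$label == "LEP_-35g"))
})

test_that("degenerate training designs raise a component-naming error", {
  skeleton <- readModelConfig()
  gc_only <- c("GCGCGCGCGCGCGCGCGCGCGCGCGC", "CGCGCGCGCGCGCGCGCGCGCGCGCG",
               "GGCCGGCCGGCCGGCCGGCCGGCCGG", "CCGGCCGGCCGGCCGGCCGGCCGGCC")
  expect_error(calibrateAffinity(gc_only, c(10, 11, 12, 13), skeleton),
               "slide")
  expect_error(calibrateAffinity(gc_only[1:3], 1:3, skeleton), "at least 4")
})

test_that("estimates are bit-reproducible and carry positive delta", {
  lep <- lepPromoterExample()
  a <- promoterAffinity(lep, model)
  b <- promoterAffinity(lep, model)
  expect_identical(minusLnKd(a), minusLnKd(b))
  expect_identical(uncertainty(a), uncertainty(b))
  expect_gt(uncertainty(a), 0)
  expect_gte(uncertainty(a), model@deltaFloor)
})
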