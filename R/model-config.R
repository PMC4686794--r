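#' @include AllClasses.R
NULL

#' Read an affinity-model configuration file
#'
#' Parses the versioned key-value + matrix-block text format that ships the
#' TATA weight matrix and the dinucleotide minor-groove scale. The returned
#' model is *uncalibrated* (no coefficients); see [calibrateAffinity()] and
#' [defaultAffinityModel()].
#'
#' @param path configuration file; defaults to the packaged model.
#' @return A [TataAffinityModel-class] without calibrated coefficients.
#' @export
readModelConfig <- function(path = system.file("extdata", "tbp_affinity_model.cfg",
                                               package = "tatakit")) {
  if (!nzchar(path) || !file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  getval <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) stop("config key missing: ", key)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  block <- function(key, n) {
    at <- grep(paste0("^", key, ":"), lines)
    if (!length(at)) stop("config block missing: ", key)
    lines[(at + 1L):(at + n)]
  }

  freq_lines <- block("pwm_frequencies", 4L)
  freq <- do.call(rbind, lapply(freq_lines, function(l) {
    f <- strsplit(l, "\\s+")[[1]]
    as.numeric(f[-1])
  }))
  rownames(freq) <- vapply(strsplit(freq_lines, "\\s+"), `[[`, "", 1L)
  freq <- freq[DNA_BASES4, , drop = FALSE]
  background <- as.numeric(strsplit(getval("background"), "\\s+")[[1]])

  gw_lines <- grep("^[ACGT]{2} ", lines, value = TRUE)
  gw <- vapply(strsplit(gw_lines, "\\s+"), function(f) as.numeric(f[2]), 0)
  names(gw) <- vapply(strsplit(gw_lines, "\\s+"), `[[`, "", 1L)

  newAffinityModel(
    pwm = log(sweep(freq, 1, background, "/")),
    background = background,
    groove = symmetrizeGroove(gw),
    windowLength = as.integer(getval("window_length")),
    deltaFloor = as.numeric(getval("delta_floor")),
    meta = list(config = path, version = getval("version"),
                provenance = getval("provenance")))
}

#' Write an affinity-model configuration file
#'
#' Serializes the matrix and groove scale of a model back to the text
#' format accepted by [readModelConfig()] (coefficients are recomputed at
#' load time and are not written).
#'
#' @param model a [TataAffinityModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelConfig <- function(model, path) {
  freq <- exp(model@pwm) * model@background  # invert the ln-odds transform
  gw <- model@groove
  canonical <- unique(vapply(names(gw), function(d) {
    rc <- revcompChar(d)
    if (d <= rc) d else rc
  }, ""))
  lines <- c(
    "# tatakit TBP affinity model configuration",
    paste0("version: ", model@meta$version %||% "1"),
    paste0("window_length: ", model@windowLength),
    paste0("delta_floor: ", format(model@deltaFloor)),
    paste0("provenance: ", model@meta$provenance %||% "user model"),
    "pwm_frequencies:",
    vapply(DNA_BASES4, function(b)
      paste(b, paste(format(freq[b, ], digits = 8), collapse = " ")), ""),
    paste0("background: ", paste(format(model@background), collapse = " ")),
    "groove_widths:",
    vapply(canonical, function(d) paste(d, format(gw[[d]])), ""))
  writeLines(lines, path)
  invisible(path)
}

# expand a scale given on canonical steps to all 16, value(step) = value(revcomp)
symmetrizeGroove <- function(gw) {
  dn <- as.vector(outer(DNA_BASES4, DNA_BASES4, paste0))
  out <- stats::setNames(numeric(16), dn)
  for (d in dn) {
    out[d] <- if (d %in% names(gw)) gw[[d]] else {
      rc <- revcompChar(d)
      if (!rc %in% names(gw)) stop("groove scale misses step ", d)
      gw[[rc]]
    }
  }
  out
}

revcompChar <- function(x)
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), ""))

newAffinityModel <- function(pwm, background, groove, windowLength, deltaFloor,
                             meta, coefficients = numeric(),
                             singleCoefficients = matrix(numeric(), 0, 2)) {
  new("TataAffinityModel", pwm = pwm, background = background, groove = groove,
      coefficients = coefficients, singleCoefficients = singleCoefficients,
      windowLength = as.integer(windowLength), deltaFloor = deltaFloor,
      meta = meta)
}

model_cache <- new.env(parent = emptyenv())

#' The packaged, calibrated affinity model
#'
#' Loads the shipped matrix/groove configuration and calibrates the linear
#' coefficients on the six packaged probe/affinity pairs
#' ([probeKinetics()]). Deterministic; the result is cached per session.
#'
#' @return A calibrated [TataAffinityModel-class].
#' @examples
#' m <- defaultAffinityModel()
#' modelCoefficients(m)
#' @export
defaultAffinityModel <- function() {
  if (is.null(model_cache$default)) {
    skeleton <- readModelConfig()
    tab <- probeKinetics()
    model_cache$default <- calibrateAffinity(
      windows = tab$odn,
      minusLnKd = -log(tab$kstar_reported_nM * 1e-9),
      model = skeleton,
      meta = list(training = "six packaged 26-bp probes (LEP, GCG alleles)",
                  note = "smoke-level calibration, n = 6; not a genome-wide model"))
  }
  model_cache$default
}
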