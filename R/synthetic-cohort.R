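#' Cohort simulation configuration
#'
#' Defines a synthetic study: specimen ages, the metric-versus-age lines
#' the ground truths are drawn on (width, INAG, rho), per-metric Gaussian
#' residual standard deviations, the number of imaged regions per specimen,
#' and the imaging geometry and noise.
#'
#' The default lines are the aging relations the analysis targets:
#' peritubular width 0.03 um/year + 3.47 um, INAG -0.003/year - 0.25, and
#' rho -0.02/year - 1.03. The default residual sds are zero, so ground
#' truths lie exactly on the lines and the full pipeline can be checked by
#' parameter recovery; realistic specimen scatter is opt-in via
#' \code{residualSds}.
#'
#' @param agesYears specimen ages (default 9 ages evenly spanning 19-82).
#' @param sexes per-specimen sex labels, recycled (default 4 "M" then "F").
#' @param widthLine c(slope um/yr, intercept um) of the width-age line.
#' @param inagLine c(slope /yr, intercept) of the INAG-age line.
#' @param rhoLine c(slope /yr, intercept) of the rho-age line.
#' @param residualSds named numeric: Gaussian residual sd for
#'   \code{width} (um), \code{inag}, \code{rho}.
#' @param regionsPerSpecimen imaged regions per specimen (default 5).
#' @param nPx pixels per side (default 512 over a 180 um field).
#' @param fieldUm field width in microns (default 180).
#' @param orientationDeg stripe orientation of the synthetic fields.
#' @param jitterDeg orientation jitter sd in degrees.
#' @param ridgeContrast,duty stripe profile shape, see
#'   [tubuleFieldParams()].
#' @param tpefMean,background,photonGain,readNoiseSd,bitDepth channel
#'   rendering, see [channelRenderParams()] (defaults noiseless).
#' @param polAnglesDeg the three polarization angles for the stacks.
#' @param polScale intensity constant K for polarimetric renders.
#' @param seed RNG seed governing the whole cohort.
#' @return a validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(agesYears = round(seq(19, 82, length.out = 9)),
                         sexes = c(rep("M", 4), rep("F", 5)),
                         widthLine = c(0.03, 3.47),
                         inagLine = c(-0.003, -0.25),
                         rhoLine = c(-0.02, -1.03),
                         residualSds = c(width = 0, inag = 0, rho = 0),
                         regionsPerSpecimen = 5L,
                         nPx = 512L, fieldUm = 180,
                         orientationDeg = 0, jitterDeg = 0,
                         ridgeContrast = 0.9, duty = 0.5,
                         tpefMean = 1000, background = 0.05,
                         photonGain = 0, readNoiseSd = 0, bitDepth = 16L,
                         polAnglesDeg = c(0, 90, 60), polScale = 1000,
                         seed = 1L) {
  if (!length(agesYears) || any(!is.finite(agesYears)) ||
      any(agesYears <= 0))
    stop("'agesYears' must be positive and non-empty")
  sd <- c(width = 0, inag = 0, rho = 0)
  sd[names(residualSds)] <- residualSds
  if (any(sd < 0)) stop("'residualSds' must be >= 0")
  if (regionsPerSpecimen < 1L) stop("'regionsPerSpecimen' must be >= 1")
  structure(list(
    agesYears = agesYears,
    sexes = rep_len(as.character(sexes), length(agesYears)),
    widthLine = widthLine, inagLine = inagLine, rhoLine = rhoLine,
    residualSds = sd, regionsPerSpecimen = as.integer(regionsPerSpecimen),
    nPx = as.integer(nPx), fieldUm = fieldUm,
    orientationDeg = orientationDeg, jitterDeg = jitterDeg,
    ridgeContrast = ridgeContrast, duty = duty, tpefMean = tpefMean,
    background = background, photonGain = photonGain,
    readNoiseSd = readNoiseSd, bitDepth = as.integer(bitDepth),
    polAnglesDeg = polAnglesDeg, polScale = polScale,
    seed = as.integer(seed)), class = "CohortConfig")
}

#' Convert an INAG value to the SHG/TPEF ratio that produces it
#'
#' Inverts the INAG contrast: \code{r = (1 + INAG) / (1 - INAG)}. Used to
#' back-solve the per-region rendering ratio from a target INAG ground
#' truth.
#'
#' @param inag INAG value(s) strictly inside (-1, 1).
#' @return the SHG/TPEF mean-intensity ratio(s).
#' @examples
#' ratioFromInag(-0.322)  # 0.5129
#' @export
ratioFromInag <- function(inag) {
  if (any(!is.finite(inag)) || any(inag <= -1) || any(inag >= 1))
    stop("INAG must lie strictly inside (-1, 1); the ratio is undefined ",
         "at the boundaries")
  (1 + inag) / (1 - inag)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-specimen ground-truth width, INAG and rho as
#' \code{line(age) + N(0, residualSd)}, back-solves the per-region
#' SHG/TPEF rendering ratio from the target INAG, and renders
#' \code{regionsPerSpecimen} TPEF/SHG pairs (and optionally
#' three-polarization stacks) per specimen. Fully reproducible from the
#' config seed.
#'
#' @param config a [cohortConfig()] object.
#' @param what which image sets to render: any of \code{"pairs"} and
#'   \code{"stacks"} (both by default). Ground truths are always drawn
#'   identically regardless, so the truth table does not depend on
#'   \code{what}.
#' @return list with \code{specimens} (list of
#'   \linkS4class{SpecimenRecord}), \code{truth} (data.frame with
#'   specimen_id, age_years, sex, width_true_um, inag_true, rho_true,
#'   ratio_true) and the \code{config}.
#' @examples
#' co <- generateCohort(cohortConfig(agesYears = c(20, 50, 80),
#'                                   regionsPerSpecimen = 1, nPx = 64),
#'                      what = "pairs")
#' co$truth
#' @export
generateCohort <- function(config = cohortConfig(),
                           what = c("pairs", "stacks")) {
  stopifnot(inherits(config, "CohortConfig"))
  what <- match.arg(what, several.ok = TRUE)
  ages <- config$agesYears
  n <- length(ages)
  line <- function(l, a) l[1] * a + l[2]
  truthVals <- withSeed(config$seed, {
    data.frame(
      width = line(config$widthLine, ages) +
        stats::rnorm(n, sd = config$residualSds["width"]),
      inag = line(config$inagLine, ages) +
        stats::rnorm(n, sd = config$residualSds["inag"]),
      rho = line(config$rhoLine, ages) +
        stats::rnorm(n, sd = config$residualSds["rho"])
    )
  })
  if (any(truthVals$inag <= -1) || any(truthVals$inag >= 1))
    stop("drawn INAG ground truth outside (-1, 1); reduce the residual sd")
  px <- config$fieldUm / config$nPx
  if (any(truthVals$width <= 2 * px))
    stop("drawn width ground truth at or below the Nyquist limit ",
         sprintf("%.3g um", 2 * px))
  truth <- data.frame(
    specimen_id = sprintf("S%02d", seq_len(n)),
    age_years = ages,
    sex = config$sexes,
    width_true_um = truthVals$width,
    inag_true = truthVals$inag,
    rho_true = truthVals$rho,
    ratio_true = ratioFromInag(truthVals$inag),
    stringsAsFactors = FALSE
  )
  specimens <- vector("list", n)
  for (i in seq_len(n)) {
    regs <- vector("list", config$regionsPerSpecimen)
    for (j in seq_len(config$regionsPerSpecimen)) {
      rseed <- (config$seed + 7919L * i + 101L * j) %% .Machine$integer.max
      fp <- tubuleFieldParams(
        periodUm = truth$width_true_um[i],
        orientationDeg = config$orientationDeg,
        jitterDeg = config$jitterDeg,
        ridgeContrast = config$ridgeContrast,
        fieldUm = config$fieldUm, nPx = config$nPx, duty = config$duty)
      pattern <- generateTubuleField(fp, seed = rseed)
      meta <- list(specimen_id = truth$specimen_id[i],
                   age_years = ages[i], sex = config$sexes[i],
                   region_id = sprintf("R%02d", j), seed = rseed)
      reg <- list()
      if ("pairs" %in% what) {
        cp <- channelRenderParams(
          tpefMean = config$tpefMean,
          shgTpefRatio = truth$ratio_true[i],
          background = config$background,
          photonGain = config$photonGain,
          readNoiseSd = config$readNoiseSd, bitDepth = config$bitDepth)
        pair <- renderChannelPair(pattern, cp, seed = rseed + 1L,
                                  pixelSizeUm = px, meta = meta)
        reg$tpef <- pair$tpef
        reg$shg <- pair$shg
      }
      if ("stacks" %in% what) {
        pp <- polarimetricRenderParams(
          rho = truth$rho_true[i], anglesDeg = config$polAnglesDeg,
          scale = config$polScale, photonGain = config$photonGain,
          readNoiseSd = config$readNoiseSd, bitDepth = config$bitDepth)
        reg$stack <- renderPolarimetricStack(
          pattern, pp, fiberOrientationDeg = config$orientationDeg,
          seed = rseed + 2L, pixelSizeUm = px, meta = meta)
      }
      regs[[j]] <- reg
    }
    specimens[[i]] <- SpecimenRecord(
      specimenId = truth$specimen_id[i], ageYears = ages[i],
      sex = config$sexes[i], regions = regs,
      truth = as.list(truth[i, c("width_true_um", "inag_true", "rho_true",
                                 "ratio_true")]))
  }
  list(specimens = specimens, truth = truth, config = config)
}
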