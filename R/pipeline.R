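# End-to-end orchestration: simulate (or load) -> per-region analysis ->
# per-specimen aggregation -> age regressions -> report.

#' Pipeline run configuration
#'
#' Bundles the cohort (a [cohortConfig()] to simulate, or a pre-generated
#' [generateCohort()] result) with every analysis tunable, so a run is
#' fully described -- and reproducible -- from this object alone. The
#' resolved configuration is serialized into the output for provenance.
#'
#' @param cohort a \code{CohortConfig} or a [generateCohort()] result.
#' @param orientation \code{"hough"}: estimate the tubule orientation per
#'   region with [estimateOrientationHough()] (the standard path);
#'   \code{"known"}: use the cohort's configured stripe orientation
#'   (synthetic shortcut for noise-free geometry checks).
#' @param inagSmoothUm map smoothing for [inagMap()], microns.
#' @param nSections,prominence width estimation, see [peritubuleWidth()].
#' @param gradSigmaUm,tensorSigmaUm structure tensor, see
#'   [structureTensorSD()].
#' @param rhoFloor noise floor for [rhoMap()] (NULL = 1 percent of max).
#' @param withPolarimetry analyze polarimetric stacks when present.
#' @param outputDir write CSV/JSON outputs here (NULL = in-memory only).
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(cohort = cohortConfig(),
                      orientation = c("hough", "known"),
                      inagSmoothUm = 1, nSections = 10L, prominence = 0.1,
                      gradSigmaUm = 0.5, tensorSigmaUm = 2,
                      rhoFloor = NULL, withPolarimetry = TRUE,
                      outputDir = NULL) {
  orientation <- match.arg(orientation)
  structure(list(cohort = cohort, orientation = orientation,
                 inagSmoothUm = inagSmoothUm,
                 nSections = as.integer(nSections),
                 prominence = prominence, gradSigmaUm = gradSigmaUm,
                 tensorSigmaUm = tensorSigmaUm, rhoFloor = rhoFloor,
                 withPolarimetry = withPolarimetry,
                 outputDir = outputDir), class = "RunConfig")
}

# Analyze one region (tpef/shg pair + optional stack) into a one-row
# data.frame of metrics.
analyzeRegion <- function(reg, config, knownOrientationDeg = NA) {
  out <- data.frame(orientation_deg = NA_real_, width_um = NA_real_,
                    width_sd_um = NA_real_, sd_deg = NA_real_,
                    org_class = NA_character_, inag = NA_real_,
                    ratio = NA_real_, rho_mean = NA_real_,
                    rho_sd = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(reg$shg)) {
    theta <- if (config$orientation == "known" &&
                 is.finite(knownOrientationDeg)) knownOrientationDeg
             else estimateOrientationHough(reg$shg)
    out$orientation_deg <- theta
    tw <- peritubuleWidth(reg$shg, theta, nSections = config$nSections,
                          prominence = config$prominence)
    out$width_um <- tw$widthUm
    out$width_sd_um <- tw$widthSdUm
    om <- structureTensorSD(reg$shg, config$gradSigmaUm,
                            config$tensorSigmaUm)
    out$sd_deg <- om$sdDeg
    out$org_class <- om$orgClass
  }
  if (!is.null(reg$shg) && !is.null(reg$tpef)) {
    out$inag <- inagSummary(reg$shg, reg$tpef)
    out$ratio <- shgTpefRatio(reg$shg, reg$tpef)
  }
  if (config$withPolarimetry && !is.null(reg$stack)) {
    theta <- if (is.finite(out$orientation_deg)) out$orientation_deg
             else NULL
    rm <- rhoMap(reg$stack, thetaDeg = theta, floor = config$rhoFloor)
    out$rho_mean <- rm@summaryMean
    out$rho_sd <- rm@summarySd
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or takes) a cohort, measures every region (INAG and
#' SHG/TPEF ratio, Hough orientation, peritubular width, structural
#' dispersion, signed rho), aggregates regions into per-specimen means,
#' and regresses each metric on age. Rerunning with the same configuration
#' and seed reproduces the outputs bit for bit.
#'
#' @param config a [runConfig()] object (a bare \code{CohortConfig} is
#'   also accepted and wrapped with defaults).
#' @return list with \code{regionMetrics} (data.frame, one row per
#'   region), \code{specimenMetrics} (one row per specimen),
#'   \code{regressions} (named list of \linkS4class{AgeRegression}, or a
#'   character message when n < 3), and \code{config}. When
#'   \code{outputDir} is set, writes \code{region_metrics.csv},
#'   \code{specimen_metrics.csv}, \code{regressions.json} and
#'   \code{run_config.json} there.
#' @examples
#' cfg <- runConfig(cohortConfig(agesYears = c(20, 50, 80),
#'                               regionsPerSpecimen = 2, nPx = 128),
#'                  orientation = "known")
#' res <- runPipeline(cfg)
#' res$regressions$width_um
#' @export
runPipeline <- function(config) {
  if (inherits(config, "CohortConfig")) config <- runConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  cohort <- if (inherits(config$cohort, "CohortConfig")) {
    what <- if (config$withPolarimetry) c("pairs", "stacks") else "pairs"
    generateCohort(config$cohort, what = what)
  } else config$cohort
  if (!length(cohort$specimens)) stop("empty cohort")
  knownOri <- if (inherits(cohort$config, "CohortConfig"))
    cohort$config$orientationDeg else NA
  regionRows <- list()
  for (sp in cohort$specimens) {
    for (j in seq_along(sp@regions)) {
      row <- tryCatch(
        analyzeRegion(sp@regions[[j]], config, knownOri),
        error = function(e) {
          warning(sprintf("region %s/R%02d skipped: %s", sp@specimenId,
                          j, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(row)) next
      regionRows[[length(regionRows) + 1L]] <- cbind(
        data.frame(specimen_id = sp@specimenId,
                   region_id = sprintf("R%02d", j),
                   age_years = sp@ageYears, sex = sp@sex,
                   stringsAsFactors = FALSE), row)
    }
  }
  if (!length(regionRows)) stop("no analyzable regions in the cohort")
  regionMetrics <- do.call(rbind, regionRows)
  metricCols <- c("width_um", "sd_deg", "inag", "ratio", "rho_mean")
  specRows <- lapply(split(regionMetrics, regionMetrics$specimen_id),
                     function(df) {
    agg <- aggregateSpecimen(df[metricCols])
    cbind(data.frame(specimen_id = df$specimen_id[1],
                     age_years = df$age_years[1], sex = df$sex[1],
                     n_regions = agg$nRegions, stringsAsFactors = FALSE),
          as.data.frame(as.list(agg$mean)),
          stats::setNames(as.data.frame(as.list(agg$sd)),
                          paste0(metricCols, "_sd")))
  })
  specimenMetrics <- do.call(rbind, specRows)
  specimenMetrics <- specimenMetrics[order(specimenMetrics$specimen_id), ]
  rownames(specimenMetrics) <- NULL
  regressions <- list()
  for (mc in metricCols) {
    v <- specimenMetrics[[mc]]
    ok <- is.finite(v)
    regressions[[mc]] <- if (sum(ok) < 3L)
      sprintf("not fitted: %d specimen(s) with finite %s (need >= 3)",
              sum(ok), mc)
    else tryCatch(
      fitAgeRegression(specimenMetrics$age_years[ok], v[ok], mc),
      error = function(e) sprintf("not fitted: %s", conditionMessage(e)))
  }
  out <- list(regionMetrics = regionMetrics,
              specimenMetrics = specimenMetrics,
              regressions = regressions, config = config)
  if (!is.null(config$outputDir)) {
    d <- config$outputDir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    utils::write.csv(regionMetrics, file.path(d, "region_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(specimenMetrics,
                     file.path(d, "specimen_metrics.csv"),
                     row.names = FALSE)
    regJson <- lapply(regressions, function(r) {
      if (is.character(r)) list(status = r)
      else list(slope = r@slope, intercept = r@intercept, r = r@pearsonR,
                p = r@pValue, n = r@n, residual_sd = r@residualSd)
    })
    jsonlite::write_json(regJson, file.path(d, "regressions.json"),
                         auto_unbox = TRUE, digits = NA)
    cfgJson <- config
    cfgJson$cohort <- if (inherits(config$cohort, "CohortConfig"))
      unclass(config$cohort) else unclass(cohort$config)
    jsonlite::write_json(unclass(cfgJson),
                         file.path(d, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
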