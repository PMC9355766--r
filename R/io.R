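# TIFF + JSON sidecar IO. Each image is a single-channel grayscale TIFF
# (float32 for noiseless renders, 16-bit integer otherwise) with a JSON
# sidecar carrying specimen metadata and the intensity scale so counts
# round-trip.

sidecarPath <- function(tifPath) sub("\\.tiff?$", ".json", tifPath)

#' Write an MPImage as TIFF plus JSON sidecar
#'
#' Intensities are stored divided by \code{intensityScale} (so integer
#' counts fit the 16-bit range); the scale is recorded in the sidecar and
#' restored by [readMPImage()]. Integer-valued images are written as
#' 16-bit TIFF, continuous ones as 32-bit float.
#'
#' @param img an \linkS4class{MPImage}.
#' @param tifPath output path (`.tif`); the sidecar goes next to it with a
#'   `.json` extension.
#' @param intensityScale counts corresponding to 1.0 in the TIFF (default
#'   \code{2^16 - 1}).
#' @return `tifPath`, invisibly.
#' @export
writeMPImage <- function(img, tifPath, intensityScale = 2^16 - 1) {
  stopifnot(is(img, "MPImage"))
  x <- img@intensity / intensityScale
  if (max(x) > 1)
    stop("intensities exceed 'intensityScale'; increase it")
  integerCounts <- all(img@intensity == round(img@intensity))
  tiff::writeTIFF(x, tifPath,
                  bits.per.sample = if (integerCounts) 16L else 32L)
  side <- list(channel = img@channel,
               pixel_size_um = img@pixelSizeUm,
               intensity_scale = intensityScale)
  if (!is.na(img@polarizationDeg))
    side$polarization_deg <- img@polarizationDeg
  side <- c(side, img@meta)
  jsonlite::write_json(side, sidecarPath(tifPath), auto_unbox = TRUE,
                       digits = NA)
  invisible(tifPath)
}

#' Read an MPImage written by [writeMPImage()]
#'
#' @param tifPath path to the TIFF; the JSON sidecar must sit next to it.
#' @return an \linkS4class{MPImage}.
#' @export
readMPImage <- function(tifPath) {
  side <- jsonlite::read_json(sidecarPath(tifPath), simplifyVector = TRUE)
  x <- tiff::readTIFF(tifPath)
  scale <- scalarOr(side$intensity_scale, 2^16 - 1)
  meta <- side[setdiff(names(side),
                       c("channel", "polarization_deg", "pixel_size_um",
                         "intensity_scale"))]
  MPImage(x * scale, channel = side$channel,
          pixelSizeUm = side$pixel_size_um,
          polarizationDeg = scalarOr(side$polarization_deg, NA_real_),
          meta = meta)
}

# A single atomic value from a parsed JSON field, or the default.
scalarOr <- function(x, default) {
  if (is.atomic(x) && length(x) == 1L) x else default
}

#' Write a synthetic cohort to disk
#'
#' One TIFF + sidecar per image, named
#' `<specimen>_<region>_<channel>[_pol<angle>].tif`, plus
#' `ground_truth.csv` with the per-specimen ground-truth table.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in cohort$specimens) {
    for (j in seq_along(sp@regions)) {
      reg <- sp@regions[[j]]
      base <- file.path(dir, sprintf("%s_R%02d", sp@specimenId, j))
      if (!is.null(reg$tpef))
        writeMPImage(reg$tpef, paste0(base, "_TPEF.tif"))
      if (!is.null(reg$shg))
        writeMPImage(reg$shg, paste0(base, "_SHG.tif"))
      if (!is.null(reg$stack))
        for (img in reg$stack@images)
          writeMPImage(img, sprintf("%s_SHG_pol%03d.tif", base,
                                    round(img@polarizationDeg)))
    }
  }
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Validate an input directory of images and sidecars
#'
#' Non-destructively scans a directory written in the [writeCohort()]
#' convention: lists the specimens and regions found and reports missing
#' sidecars, missing metadata fields (age), channel mismatches and
#' TPEF/SHG shape mismatches.
#'
#' @param dir directory to scan.
#' @return list with \code{manifest} (data.frame: file, specimen_id,
#'   region_id, channel, polarization_deg, age_years) and
#'   \code{diagnostics} (character vector, empty when well-formed).
#' @export
validateInputs <- function(dir) {
  tifs <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  diags <- character(0)
  rows <- list()
  for (f in tifs) {
    sc <- sidecarPath(f)
    if (!file.exists(sc)) {
      diags <- c(diags, sprintf("missing sidecar for %s", basename(f)))
      next
    }
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(side$age_years))
      diags <- c(diags, sprintf("sidecar %s is missing 'age_years'",
                                basename(sc)))
    if (is.null(side$channel) || !side$channel %in% c("TPEF", "SHG"))
      diags <- c(diags, sprintf("sidecar %s has no valid 'channel'",
                                basename(sc)))
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(f),
      specimen_id = scalarOr(side$specimen_id, NA_character_),
      region_id = scalarOr(side$region_id, NA_character_),
      channel = scalarOr(side$channel, NA_character_),
      polarization_deg = scalarOr(side$polarization_deg, NA_real_),
      age_years = scalarOr(side$age_years, NA_real_),
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0))
  # shape check per specimen/region TPEF vs SHG pair
  if (nrow(manifest)) {
    key <- paste(manifest$specimen_id, manifest$region_id)
    for (k in unique(key)) {
      sub <- manifest[key == k & is.na(manifest$polarization_deg), ]
      tp <- sub$file[sub$channel == "TPEF"]
      sh <- sub$file[sub$channel == "SHG"]
      if (length(tp) == 1L && length(sh) == 1L) {
        d1 <- dim(tiff::readTIFF(file.path(dir, tp)))
        d2 <- dim(tiff::readTIFF(file.path(dir, sh)))
        if (!identical(d1, d2))
          diags <- c(diags, sprintf(
            "shape mismatch between %s (%s) and %s (%s)",
            tp, paste(d1, collapse = "x"), sh, paste(d2, collapse = "x")))
      }
    }
  }
  list(manifest = manifest, diagnostics = diags)
}
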