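# Inversion of three-polarization SHG stacks into signed rho maps under
# the cylindrical-symmetry response (see polarimetricRenderParams):
#   I(alpha) = K p g(D, rho),  g(D, rho) = sin^2 2D + (sin^2 D +
#   rho cos^2 D)^2,  D = alpha - theta.
#
# Two states give the candidate values, the third resolves the ambiguity.
# The orthogonal pair (alpha, alpha + 90) yields, for the measured ratio
# R = I1/I2 (the unknown K p cancels; sin^2 2D is shared),
#   rho^2 (b^2 - R a^2) + 2 rho a b (1 - R) + (a^2 - R b^2)
#     + sin^2(2D) (1 - R) = 0,   a = sin^2 D, b = cos^2 D,
# a quadratic whose two roots are the rho candidates; the oblique state
# votes for the root whose predicted intensity ratio is closer. In the
# fiber-aligned frame (D = 0) the roots are exactly +/- sqrt(I_par/I_perp),
# recovering the classical "two states for the magnitude, the third for
# the sign" scheme, which rhoMagnitude/rhoSign expose directly. All ratios
# are taken against the second state, so no inter-image calibration beyond
# co-registration is assumed.

# Fold a fiber-frame polarization offset to [0, 90] degrees.
foldDelta <- function(alphaDeg, thetaDeg) {
  d <- abs(alphaDeg - thetaDeg) %% 180
  pmin(d, 180 - d)
}

# Identify the states closest to parallel (D = 0) and perpendicular
# (D = 90) in the fiber frame, for the aligned-frame two-state magnitude.
stackGeometry <- function(stack, thetaDeg) {
  d <- foldDelta(stack@anglesDeg, thetaDeg)
  iPar <- which.min(d)
  iPerp <- which.max(d)
  if (iPar == iPerp || d[iPerp] - d[iPar] < 65)
    stop(sprintf(
      "geometry unresolvable: fiber-frame offsets %s deg contain no near-orthogonal pair",
      paste(sprintf("%.1f", d), collapse = "/")))
  iThird <- setdiff(1:3, c(iPar, iPerp))
  list(iPar = iPar, iPerp = iPerp, iThird = iThird, delta = d)
}

# The lab-frame orthogonal pair plus the remaining (oblique) state.
orthogonalPair <- function(stack) {
  d <- abs(outer(stack@anglesDeg, stack@anglesDeg, "-")) %% 180
  d <- pmin(d, 180 - d)
  hit <- which(abs(d - 90) < 1e-6, arr.ind = TRUE)
  i1 <- hit[1, 1]; i2 <- hit[1, 2]
  list(i1 = min(i1, i2), i2 = max(i1, i2),
       iThird = setdiff(1:3, c(i1, i2)))
}

#' Hyperpolarizability-ratio magnitude from the orthogonal pair
#'
#' In the fiber-aligned frame the states closest to parallel and
#' perpendicular give the magnitude pixelwise:
#' \code{|rho| = sqrt(I_par / I_perp)}. Pixels whose perpendicular
#' intensity is at or below the noise floor are masked (NA). When no state
#' is near-parallel and another near-perpendicular to the fibers the
#' two-state magnitude is not defined and an error is raised (use
#' [rhoMap()], whose full-model inversion handles oblique geometry).
#'
#' @param stack a \linkS4class{PolarimetricStack}.
#' @param thetaDeg fiber orientation in degrees.
#' @param floor noise floor on the perpendicular intensity; \code{NULL}
#'   (default) uses 1 percent of its maximum.
#' @return matrix of \code{|rho|}, NA where masked.
#' @export
rhoMagnitude <- function(stack, thetaDeg, floor = NULL) {
  stopifnot(is(stack, "PolarimetricStack"))
  geo <- stackGeometry(stack, thetaDeg)
  iPar <- stack@images[[geo$iPar]]@intensity
  iPerp <- stack@images[[geo$iPerp]]@intensity
  if (is.null(floor)) floor <- 0.01 * max(iPerp)
  out <- matrix(NA_real_, nrow(iPar), ncol(iPar))
  ok <- iPerp > floor
  out[ok] <- sqrt(pmax(iPar[ok], 0) / iPerp[ok])
  out
}

#' Sign of rho from the oblique polarization state
#'
#' For each pixel, predicts the oblique-to-perpendicular intensity ratio
#' under the forward model for \code{+|rho|} and \code{-|rho|} and assigns
#' the sign with the smaller absolute discrepancy. Pixels where the two
#' hypotheses tie (within \code{tol}) or where \code{|rho|} is close to
#' zero are masked.
#'
#' @param stack a \linkS4class{PolarimetricStack}.
#' @param absRho matrix of \code{|rho|} from [rhoMagnitude()].
#' @param thetaDeg fiber orientation in degrees.
#' @param floor noise floor on the perpendicular intensity (default as in
#'   [rhoMagnitude()]).
#' @param tol tie tolerance on the discrepancy difference.
#' @return matrix with values in \code{\{-1, +1\}}, NA where masked.
#' @export
rhoSign <- function(stack, absRho, thetaDeg, floor = NULL, tol = 1e-9) {
  stopifnot(is(stack, "PolarimetricStack"))
  geo <- stackGeometry(stack, thetaDeg)
  dThird <- geo$delta[geo$iThird]
  if (min(dThird, abs(90 - dThird)) < 5)
    stop(sprintf(
      "third polarization state is degenerate (fiber-frame offset %.1f deg, too close to 0 or 90)",
      dThird))
  iThird <- stack@images[[geo$iThird]]@intensity
  iPerp <- stack@images[[geo$iPerp]]@intensity
  if (is.null(floor)) floor <- 0.01 * max(iPerp)
  alpha3 <- stack@anglesDeg[geo$iThird]
  alphaPerp <- stack@anglesDeg[geo$iPerp]
  ok <- iPerp > floor & !is.na(absRho) & absRho > tol
  out <- matrix(NA_real_, nrow(iPerp), ncol(iPerp))
  ratio <- iThird[ok] / iPerp[ok]
  pred <- function(rho) shgPolResponse(alpha3, thetaDeg, rho) /
    shgPolResponse(alphaPerp, thetaDeg, rho)
  dPlus <- abs(ratio - pred(absRho[ok]))
  dMinus <- abs(ratio - pred(-absRho[ok]))
  out[ok] <- ifelse(dMinus < dPlus - tol, -1,
                    ifelse(dPlus < dMinus - tol, 1, NA_real_))
  out
}

# Exact pixelwise inversion: candidate roots from the orthogonal pair,
# root selection by the oblique state. Returns the signed rho field.
rhoInvert <- function(stack, thetaDeg, floor = NULL, tol = 1e-9) {
  op <- orthogonalPair(stack)
  I1 <- stack@images[[op$i1]]@intensity
  I2 <- stack@images[[op$i2]]@intensity
  I3 <- stack@images[[op$iThird]]@intensity
  a1 <- stack@anglesDeg[op$i1]
  a2 <- stack@anglesDeg[op$i2]
  a3 <- stack@anglesDeg[op$iThird]
  d3 <- foldDelta(a3, thetaDeg)
  if (min(d3, abs(90 - d3)) < 5)
    stop(sprintf(
      "third polarization state is degenerate (fiber-frame offset %.1f deg, too close to 0 or 90)",
      d3))
  # Mirror degeneracy: the response is even in (alpha - theta), so if the
  # oblique state sits at the same folded offset as one of the orthogonal
  # pair, it duplicates that measurement and the two quadratic roots fit
  # all three intensities identically -- rho is unidentifiable.
  d12 <- foldDelta(c(a1, a2), thetaDeg)
  if (any(abs(d3 - d12) < 1))
    stop(sprintf(
      "rho unidentifiable: the oblique state (fiber-frame offset %.1f deg) mirrors an orthogonal-pair state (offsets %s deg); its intensity duplicates that state for every rho",
      d3, paste(sprintf("%.1f", d12), collapse = "/")))
  if (is.null(floor)) floor <- 0.01 * max(I2)
  ok <- I2 > floor
  out <- matrix(NA_real_, nrow(I1), ncol(I1))
  D <- deg2rad(a1 - thetaDeg)
  a <- sin(D)^2; b <- cos(D)^2; s <- sin(2 * D)^2
  R <- I1[ok] / I2[ok]
  A <- b^2 - R * a^2
  B <- 2 * a * b * (1 - R)
  C <- a^2 - R * b^2 + s * (1 - R)
  disc <- B^2 - 4 * A * C
  lin <- abs(A) < 1e-12
  r1 <- r2 <- rep(NA_real_, length(R))
  qok <- !lin & disc >= 0
  sq <- sqrt(pmax(disc[qok], 0))
  r1[qok] <- (-B[qok] + sq) / (2 * A[qok])
  r2[qok] <- (-B[qok] - sq) / (2 * A[qok])
  if (any(lin)) {
    lok <- lin & abs(B) > 1e-12
    r1[lok] <- r2[lok] <- -C[lok] / B[lok]
  }
  ratio3 <- I3[ok] / I2[ok]
  g <- function(alphaDeg, rho) shgPolResponse(alphaDeg, thetaDeg, rho)
  d1 <- abs(ratio3 - g(a3, r1) / g(a2, r1))
  d2v <- abs(ratio3 - g(a3, r2) / g(a2, r2))
  pick <- ifelse(is.na(r1) | is.na(r2), NA_real_,
                 ifelse(d1 < d2v - tol, r1,
                        ifelse(d2v < d1 - tol, r2, NA_real_)))
  pick[!is.na(pick) & abs(pick) <= tol] <- NA_real_
  out[ok] <- pick
  out
}

#' Signed rho map from a three-polarization stack
#'
#' Inverts the forward model pixelwise: the orthogonal polarization pair
#' yields a quadratic whose two roots are the candidate rho values, and
#' the oblique state votes for the root whose predicted intensity ratio
#' matches. In the fiber-aligned frame this is exactly
#' magnitude-from-the-orthogonal-pair ([rhoMagnitude()]) plus
#' sign-from-the-third-state ([rhoSign()]); the full inversion also
#' recovers rho exactly when the fibers are oblique to the polarization
#' states. When \code{thetaDeg} is not supplied, the fiber orientation is
#' estimated from the stack with [estimateOrientationHough()].
#'
#' @param stack a \linkS4class{PolarimetricStack}.
#' @param thetaDeg fiber orientation in degrees, or \code{NULL} to
#'   estimate it from the stack.
#' @param floor noise floor on the reference (second orthogonal state)
#'   intensity; \code{NULL} uses 1 percent of its maximum, so masking is
#'   invariant to global intensity rescaling.
#' @param summary \code{"pixelwise"} (default): invert per pixel, then
#'   average the unmasked map. \code{"image_mean"}: invert the spatially
#'   averaged intensities into a single rho.
#' @return a \linkS4class{RhoMap}.
#' @examples
#' f <- generateTubuleField(tubuleFieldParams(5, nPx = 64), seed = 1)
#' st <- renderPolarimetricStack(f, polarimetricRenderParams(rho = -1.25))
#' rhoMap(st, thetaDeg = 0)
#' @export
rhoMap <- function(stack, thetaDeg = NULL, floor = NULL,
                   summary = c("pixelwise", "image_mean")) {
  stopifnot(is(stack, "PolarimetricStack"))
  summary <- match.arg(summary)
  if (is.null(thetaDeg)) {
    op <- orthogonalPair(stack)
    best <- which.max(vapply(stack@images, function(x) mean(x@intensity),
                             numeric(1)))
    thetaDeg <- estimateOrientationHough(stack@images[[best]])
  }
  vals <- rhoInvert(stack, thetaDeg, floor)
  mask <- !is.na(vals)
  v <- vals[mask]
  if (summary == "pixelwise") {
    m <- if (length(v)) mean(v) else NA_real_
    s <- if (length(v) > 1) stats::sd(v) else NA_real_
  } else {
    meanStack <- PolarimetricStack(lapply(stack@images, function(x) {
      MPImage(matrix(mean(x@intensity[mask]), 1, 1), channel = "SHG",
              pixelSizeUm = x@pixelSizeUm,
              polarizationDeg = x@polarizationDeg)
    }), anglesDeg = stack@anglesDeg)
    m <- as.numeric(rhoInvert(meanStack, thetaDeg, floor = 0))
    s <- 0
  }
  new("RhoMap", values = vals, mask = mask, summaryMean = m,
      summarySd = s, fiberOrientationDeg = thetaDeg %% 180)
}
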