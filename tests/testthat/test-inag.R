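# INAG contrast index: map, image-level summary, SHG/TPEF ratio.

test_that("INAG map hits the algebraic anchor points", {
  nPx <- 32
  tpef <- uniformImage(1000, "TPEF", nPx)
  # S = T everywhere -> 0
  shgEq <- uniformImage(1000, "SHG", nPx)
  expect_true(all(abs(inagMap(shgEq, tpef, smoothUm = 0)@values) < 1e-12))
  # S = 0, T > 0 -> -1
  shg0 <- uniformImage(0, "SHG", nPx)
  m <- inagMap(shg0, tpef, smoothUm = 0)
  expect_true(all(m@values[m@mask] == -1))
  # uniform S = 0.57, T = 1 -> (0.57 - 1) / (0.57 + 1)
  m57 <- inagMap(uniformImage(570, "SHG", nPx), tpef, smoothUm = 0)
  expect_equal(m57@summaryMean, -0.43 / 1.57, tolerance = 1e-12)
  expect_true(all(m57@values[m57@mask] >= -1 & m57@values[m57@mask] <= 1))
})

test_that("mismatched pairs are rejected with diagnostics", {
  expect_error(inagMap(uniformImage(1, "SHG", 16),
                       uniformImage(1, "TPEF", 32)), "co-registered")
  expect_error(inagSummary(uniformImage(1, "TPEF", 16),
                           uniformImage(1, "TPEF", 16)), "channel")
  expect_error(inagSummary(uniformImage(0, "SHG", 16),
                           uniformImage(0, "TPEF", 16)), "zero")
})

test_that("summary INAG equals the ratio algebra on rendered pairs", {
  for (r in c(0.62, 0.57, 0.39)) {
    pair <- smallPair(ratio = r)
    expect_equal(inagSummary(pair$shg, pair$tpef), (r - 1) / (r + 1),
                 tolerance = 1e-12)
    expect_equal(shgTpefRatio(pair$shg, pair$tpef), r, tolerance = 1e-12)
  }
  # endpoints of the reported specimen ratio range
  expect_equal((0.62 - 1) / (0.62 + 1), -0.2345679, tolerance = 1e-6)
  expect_equal((0.39 - 1) / (0.39 + 1), -0.4388489, tolerance = 1e-6)
})

test_that("ratio and INAG are a bijection on arbitrary valid pairs", {
  set.seed(42)
  for (i in 1:5) {
    s <- matrix(stats::runif(64 * 64, 10, 2000), 64)
    t <- matrix(stats::runif(64 * 64, 10, 2000), 64)
    shg <- MPImage(s, "SHG", pixelSizeUm = 1)
    tpef <- MPImage(t, "TPEF", pixelSizeUm = 1)
    r <- shgTpefRatio(shg, tpef)
    expect_equal((r - 1) / (r + 1), inagSummary(shg, tpef),
                 tolerance = 1e-12)
  }
})

test_that("INAG summary is gain-invariant, shuffle-invariant and
           monotone in SHG scaling", {
  pair <- smallPair(ratio = 0.57)
  base <- inagSummary(pair$shg, pair$tpef)
  scale2 <- function(img, c) MPImage(intensity(img) * c, channel(img),
                                     pixelSizeUm = pixelSize(img))
  # common gain cancels
  expect_equal(inagSummary(scale2(pair$shg, 3.7), scale2(pair$tpef, 3.7)),
               base, tolerance = 1e-12)
  # shrinking SHG strictly decreases INAG
  prev <- base
  for (c in c(0.8, 0.5, 0.2)) {
    cur <- inagSummary(scale2(pair$shg, c), pair$tpef)
    expect_lt(cur, prev)
    prev <- cur
  }
  # mean-preserving spatial shuffle of both channels
  set.seed(1)
  perm <- sample(length(intensity(pair$shg)))
  reshape <- function(img) MPImage(
    matrix(intensity(img)[perm], nrow(intensity(img))), channel(img),
    pixelSizeUm = pixelSize(img))
  expect_equal(inagSummary(reshape(pair$shg), reshape(pair$tpef)), base,
               tolerance = 1e-12)
})

test_that("both ratio conventions agree on proportional channels", {
  pair <- smallPair(ratio = 0.57)
  expect_equal(shgTpefRatio(pair$shg, pair$tpef, method = "mean_of_ratios"),
               0.57, tolerance = 1e-12)
})
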