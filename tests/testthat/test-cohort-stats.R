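# Aggregation, age regressions, relative change, sex comparison.

test_that("specimen aggregation is the unweighted region mean and sd", {
  agg <- aggregateSpecimen(data.frame(width_um = c(4, 5, 6)))
  expect_equal(unname(agg$mean["width_um"]), 5)
  expect_equal(unname(agg$sd["width_um"]), 1)
  one <- aggregateSpecimen(data.frame(width_um = 4.2))
  expect_equal(unname(one$mean["width_um"]), 4.2)
  expect_equal(unname(one$sd["width_um"]), 0)
  expect_false(one$sdDefined)
  same <- aggregateSpecimen(data.frame(inag = rep(-0.3, 5)))
  expect_equal(unname(same$sd["inag"]), 0)
  expect_error(aggregateSpecimen(data.frame()), "non-empty")
})

test_that("age regression recovers exact lines and textbook r", {
  ages <- c(20, 35, 50, 65, 80)
  reg <- fitAgeRegression(ages, 2 * ages + 1, "y")
  expect_equal(reg@slope, 2, tolerance = 1e-12)
  expect_equal(reg@intercept, 1, tolerance = 1e-12)
  expect_equal(reg@pearsonR, 1, tolerance = 1e-12)
  # r = 0.5 by the direct Pearson formula
  reg2 <- fitAgeRegression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(reg2@pearsonR, 0.5, tolerance = 1e-12)
  expect_equal(sign(reg2@slope), sign(reg2@pearsonR))
  # cohort ground-truth widths, zero residual: the configured line
  tr <- generateCohort(cohortConfig(regionsPerSpecimen = 1, nPx = 64,
                                    fieldUm = 64 * stdPx),
                       what = "pairs")$truth
  regW <- fitAgeRegression(tr$age_years, tr$width_true_um, "width")
  expect_equal(regW@slope, 0.03, tolerance = 1e-12)
  expect_equal(regW@intercept, 3.47, tolerance = 1e-12)
  expect_equal(regW@pearsonR, 1, tolerance = 1e-12)
})

test_that("regression degenerate inputs are refused", {
  expect_error(fitAgeRegression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitAgeRegression(c(5, 5, 5), c(1, 2, 3)), "constant")
  expect_error(fitAgeRegression(c(1, 2, 3), c(7, 7, 7)), "constant")
  expect_error(fitAgeRegression(1:3, 1:4), "length")
})

test_that("relative change reads 'larger' as growth in magnitude", {
  rc <- relativeChange(c(-0.003, -0.25), 20, 80)
  expect_equal(rc$valueFrom, -0.31)
  expect_equal(rc$valueTo, -0.49)
  expect_equal(rc$percentMagnitude, 100 * (0.49 - 0.31) / 0.31,
               tolerance = 1e-12)   # 58.06
  rcW <- relativeChange(c(0.03, 3.47), 20, 80)
  expect_equal(rcW$percentMagnitude, 100 * (5.87 - 4.07) / 4.07,
               tolerance = 1e-12)   # 44.23
  expect_equal(relativeChange(c(0, -0.4), 20, 80)$percentMagnitude, 0)
  # invariant under positive rescaling of the line
  expect_equal(relativeChange(c(-0.006, -0.5), 20, 80)$percentMagnitude,
               rc$percentMagnitude, tolerance = 1e-12)
  # zero crossing is flagged
  expect_true(relativeChange(c(0.01, -0.3), 20, 80)$crossesZero)
})

test_that("Mann-Whitney comparison matches enumeration and symmetry", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 2/6
  r <- sexComparison(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  # identical groups: p = 1 under mid-ranks
  rt <- sexComparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rt$p, 1, tolerance = 1e-12)
  # label swap leaves p unchanged
  a <- c(19, 27, 44, 60); b <- c(24, 35, 50, 71, 82)
  expect_equal(sexComparison(a, b)$p, sexComparison(b, a)$p)
  expect_error(sexComparison(numeric(0), 1:3), "non-empty")
})
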