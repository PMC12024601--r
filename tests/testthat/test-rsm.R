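test_that("Box-Behnken generator produces the canonical run set", {
  d <- bbd_design(factor_spec(), center_replicates = 4)
  expect_equal(nrow(d$coded), 28L)

  d0 <- bbd_design(factor_spec(), center_replicates = 0)
  expect_equal(nrow(d0$coded), 24L)
  expect_false(any(rowSums(d0$coded != 0) == 0))
  # every non-center run has exactly two nonzero codes, both +/-1
  expect_true(all(rowSums(d0$coded != 0) == 2L))
  expect_true(all(d0$coded %in% c(-1, 0, 1)))
  # all six factor pairs appear with all four sign combinations
  keys <- apply(d0$coded, 1, function(r) {
    nz <- which(r != 0)
    paste(nz[1], nz[2], r[nz[1]], r[nz[2]])
  })
  expect_equal(length(unique(keys)), 24L)

  # natural decoding: -1 -> low, 0 -> midpoint, +1 -> high
  fs <- factor_spec()
  expect_equal(unname(apply(d$natural, 2, min)), fs$low)
  expect_equal(unname(apply(d$natural, 2, max)), fs$high)
  expect_equal(unname(d$natural[25, ]), (fs$low + fs$high) / 2)

  expect_error(bbd_design(structure(list(low = 1:3, high = 2:4),
                                    class = "factor_spec")),
               "four factors")
})

test_that("design scoring agrees with direct chart scoring", {
  # integer-level runs score identically to reba_total
  d <- bbd_design(factor_spec(c(2, 3, 3, 1), c(3, 5, 5, 2)), 0)
  scored <- score_design(d)
  for (i in c(1, 7, 24)) {
    lv <- scored$natural[i, ]
    if (all(lv == round(lv))) {
      expect_equal(scored$response[i],
                   reba_total(reba_points(lv[1], lv[2], 1, lv[3], lv[4],
                                          2))$total)
    }
  }
  # the two verification profiles
  score_at <- function(lv) {
    d1 <- bbd_design(factor_spec(), 0)
    d1$natural[1, ] <- lv
    score_design(d1)$response[1]
  }
  expect_equal(score_at(c(2, 3, 3, 1)), 7)
  expect_equal(score_at(c(3, 5, 4, 1)), 11)

  # integer rounding conventions differ only at half-levels
  dh <- score_design(bbd_design(factor_spec(), 4),
                     level_rounding = "half_up")
  expect_true(all(dh$response == round(dh$response)))
})

test_that("linear fit recovers exact coefficients and permutes correctly", {
  d <- bbd_design(factor_spec(), 4)
  beta <- c(1.2, -0.7, 0.5, 2.0)
  d$response <- as.numeric(3 + d$natural %*% beta)
  fit <- fit_linear(d)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
  expect_equal(fit$intercept, 3, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # permuting factor columns permutes coefficients
  df <- as.data.frame(d$natural)[, c(2, 1, 4, 3)]
  df$response <- d$response
  fit2 <- fit_linear(df)
  expect_equal(unname(fit2$coefficients), beta[c(2, 1, 4, 3)],
               tolerance = 1e-9)

  # rank-deficient design is refused
  bad <- as.data.frame(d$natural)
  bad[, 2] <- 2 * bad[, 1]
  bad$response <- d$response
  expect_error(fit_linear(bad), "rank-deficient")
  expect_error(fit_linear(bbd_design(factor_spec(), 4)), "no responses")
})

test_that("chart-scored design yields a strong, all-positive linear fit", {
  d <- score_design(bbd_design(factor_spec(), 4))
  fit <- fit_linear(d)
  expect_true(all(fit$coefficients > 0))
  expect_gte(fit$adjusted_r2, 0.8)
  expect_lt(fit$anova$p[1], 0.05)
  expect_true(all(fit$anova$p < 0.05))
  # R-squared ordering: predicted <= adjusted <= plain
  expect_lte(fit$predicted_r2, fit$adjusted_r2)
  expect_lte(fit$adjusted_r2, fit$r2)

  # half-up integer scoring also gives strictly positive coefficients
  fit_hu <- fit_linear(score_design(bbd_design(factor_spec(), 4),
                                    level_rounding = "half_up"))
  expect_true(all(fit_hu$coefficients > 0))
})

test_that("pinned reference model evaluates profiles as published", {
  m <- reference_model()
  expect_equal(round(predict(m, c(2, 3, 3, 1)), 1), 7.2)
  expect_equal(predict(m, c(2, 3, 4, 1), rounded = TRUE), 8)
  expect_equal(predict(m, c(0, 0, 0, 0)), -1.53635)

  # seated survey profiles: rounded predictions are within 10% relative
  # error of the observed totals (and in fact within 2% unrounded)
  sv <- make_points_fixture("survey")
  seated <- sv[!sv$standing, ]
  lv <- as.matrix(seated[, c("neck", "trunk", "upper_arm", "lower_arm")])
  rel <- 100 * abs(predict(m, lv) - seated$reba) / seated$reba
  expect_lt(max(rel), 2)
  expect_true(all(predict(m, lv, rounded = TRUE) == seated$reba))
})

test_that("desirability optimization finds box optima deterministically", {
  m <- reference_model()
  fs <- factor_spec()

  omin <- optimize_desirability(m, fs, "minimize", starts = 40, seed = 3)
  best <- omin$solutions[1, ]
  expect_equal(as.numeric(best[c("N", "T", "U.A", "L.A")]), c(2, 3, 3, 1),
               tolerance = 1e-6)
  expect_equal(best$desirability, 1, tolerance = 1e-6)
  expect_equal(round(best$response, 1), 7.2)

  # all-positive coefficients maximize at the all-high corner
  omax <- optimize_desirability(m, fs, "maximize", starts = 40, seed = 3)
  expect_equal(as.numeric(omax$solutions[1, c("N", "T", "U.A", "L.A")]),
               c(3, 5, 6, 2), tolerance = 1e-6)

  # desirability is 1 at the upper anchor when maximizing (by definition)
  o2 <- optimize_desirability(m, fs, "maximize",
                              response_bounds = c(0, max(omax$solutions$response)),
                              starts = 10, seed = 1)
  expect_equal(o2$solutions$desirability[1], 1, tolerance = 1e-9)

  # reproducibility: identical seed, identical ranked solutions
  again <- optimize_desirability(m, fs, "minimize", starts = 40, seed = 3)
  expect_identical(omin$solutions, again$solutions)

  expect_error(optimize_desirability(m, fs, "minimize",
                                     response_bounds = c(5, 5)), "L < H")
})
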