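test_that("retention factor follows (tR - t0)/t0 and validates its inputs", {
  expect_equal(retention_factor(2, 1), 1)    # tR = 2 t0: equal distribution
  expect_equal(retention_factor(1, 1), 0)    # unretained
  expect_equal(retention_factor(4.0, 1.0), 3.0)
  expect_equal(retention_factor(c(2, 3), 1), c(1, 2))
  expect_error(retention_factor(2, 0), "dead_time")
  expect_error(retention_factor(2, -1), "dead_time")
  expect_error(retention_factor(0.5, 1), "mis-assigned")
})

test_that("isocratic CHI is the acetonitrile % where log k = 0", {
  s <- isocratic_chi(c(10, 30, 50), c(0.8, 0.4, 0.0))  # log k = 1 - 0.02 phi
  expect_equal(s$chi, 50)
  expect_equal(s$logk0, 1)
  expect_equal(isocratic_chi(c(10, 30), c(0.5, -0.5))$chi, 20)
  expect_error(isocratic_chi(c(10, 10), c(0.5, 0.4)), "distinct")
  expect_error(isocratic_chi(c(10, 30), c(0.1, 0.5)), "degenerate")
  expect_error(isocratic_chi(c(-5, 30), c(0.5, 0.1)), "\\[0, 100\\]")
})

test_that("noiseless isocratic series recover -intercept/slope to machine precision", {
  set.seed(11)
  for (rep in 1:20) {
    b <- -runif(1, 0.005, 0.05)
    logk0 <- runif(1, 0.2, 2)
    phi <- sort(sample(seq(5, 95, by = 5), 5))
    s <- isocratic_chi(phi, logk0 + b * phi)
    # closed-form two-point oracle on the line's endpoints
    phi2 <- range(phi); lk2 <- logk0 + b * phi2
    slope2 <- diff(lk2) / diff(phi2)
    oracle <- phi2[1] - lk2[1] / slope2
    expect_equal(s$chi, oracle, tolerance = 1e-12)
    # invariant to re-ordering and to adding an on-line point
    perm <- sample(seq_along(phi))
    expect_equal(isocratic_chi(phi[perm], (logk0 + b * phi)[perm])$chi, s$chi)
    phi3 <- c(phi, 50.5)
    expect_equal(isocratic_chi(phi3, logk0 + b * phi3)$chi, s$chi)
  }
})

test_that("the nine-standard calibration reproduces reference CHI within 3 units", {
  std <- load_fixture("table1")
  cal <- chi_calibration(std)
  expect_equal(cal$n_points, 9)
  expect_lt(max(abs(residuals(cal))), 3)
  expect_gt(cal$r_squared, 0.99)
  # reference CHI and log K(IAM) increase with retention time
  ord <- order(std$retention_time_min)
  expect_true(all(diff(std$chi_ref[ord]) > 0))
  expect_true(all(diff(std$logk_iam_ref[ord]) > 0))
  # paracetamol's own retention time maps back near its reference CHI
  expect_lt(abs(predict(cal, 1.58) - 2.90), 3)
})

test_that("leave-one-out prediction for valerophenone lands within 2 CHI units", {
  std <- load_fixture("table1")
  loo <- chi_calibration(std[std$name != "Valerophenone", ])
  expect_lt(abs(predict(loo, 3.66) - 37.3), 2)
})

test_that("two standards give the exact interpolating line with SEE 0", {
  cal <- chi_calibration(tiny_standards(tr = c(1, 3)))
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$see, 0)
  expect_equal(unname(coef(cal)), c(-20, 16))
  expect_error(chi_calibration(tiny_standards(tr = 2)), "at least 2")
  dup <- data.frame(name = c("a", "b"), retention_time_min = c(2, 2),
                    chi_ref = c(10, 30))
  expect_error(chi_calibration(dup), "singular")
})

test_that("noisy calibration recovers the generating line within 3 standard errors", {
  set.seed(21)
  std <- tiny_standards(tr = seq(1.4, 4.4, length.out = 9), sd = 0.5)
  cal <- chi_calibration(std)
  ne <- normal_equations(std$chi_ref, std$retention_time_min)
  expect_equal(unname(coef(cal)), unname(ne), tolerance = 1e-10)
  lm_se <- summary(lm(chi_ref ~ retention_time_min, std))$coefficients[, 2]
  expect_lt(abs(cal$intercept - (-20)), 3 * lm_se[1])
  expect_lt(abs(cal$slope - 16), 3 * lm_se[2])
})

test_that("the fitted line agrees with a brute-force SSE grid search", {
  set.seed(31)
  std <- tiny_standards(sd = 1)
  cal <- chi_calibration(std)
  g <- grid_search_line(std$retention_time_min, std$chi_ref,
                        center = c(cal$intercept, cal$slope),
                        half_width = 1, steps = 81)
  expect_equal(g[1], cal$intercept, tolerance = 0.03)
  expect_equal(g[2], cal$slope, tolerance = 0.03)
})

test_that("prediction is affine and round-trips a zero-noise generator", {
  cal <- chi_calibration(tiny_standards())
  a <- predict(cal, 2.5); b <- predict(cal, 4.0)
  expect_equal(a - b, cal$slope * (2.5 - 4.0))
  # identity mapping
  ident <- cal; ident$slope <- 1; ident$intercept <- 0
  expect_equal(predict(ident, 3.7), 3.7)
  # round trip: generated CHI reproduced exactly at sd = 0
  std <- tiny_standards(slope = 14.5, intercept = -18)
  cal2 <- chi_calibration(std)
  expect_equal(predict(cal2, std$retention_time_min), std$chi_ref)
  # negative CHI is a legal output, not truncated
  expect_lt(predict(cal2, 0.5), 0)
})

test_that("calibration JSON serialization round-trips exactly", {
  cal <- chi_calibration(load_fixture("table1"))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(coef(back), coef(cal))
  expect_equal(predict(back, c(1.58, 3.66)), predict(cal, c(1.58, 3.66)))
  # corrupting the stored standards trips the hash check
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  doc$standards$chi_ref[1] <- doc$standards$chi_ref[1] + 1
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_calibration(f), "hash mismatch")
})
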