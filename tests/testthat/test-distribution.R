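test_that("identity-link Vdss estimates are the linear score, exactly superposable", {
  mc <- model_coefficients("demo", c(logk_iam = 0.5, logk_hsa = -0.2), -0.6)
  expect_equal(estimate_log_vdss(
    data.frame(logk_iam = 0, logk_hsa = 0), mc), -0.6)
  d1 <- data.frame(logk_iam = 2, logk_hsa = 1)
  d2 <- data.frame(logk_iam = -1, logk_hsa = 3)
  dsum <- d1 + d2
  # superposition: f(a + b) - f(0) = (f(a) - f(0)) + (f(b) - f(0))
  f0 <- estimate_log_vdss(data.frame(logk_iam = 0, logk_hsa = 0), mc)
  expect_equal(estimate_log_vdss(dsum, mc) - f0,
               (estimate_log_vdss(d1, mc) - f0) +
                 (estimate_log_vdss(d2, mc) - f0))
  expect_error(estimate_log_vdss(data.frame(logk_iam = 1), mc), "logk_hsa")
  lp <- model_coefficients("p", c(logk_iam = 1), 0, link = "logistic_percent")
  expect_error(estimate_log_vdss(data.frame(logk_iam = 1), lp),
               "identity link")
})

test_that("recovered study coefficients reproduce aligned tabulated estimates", {
  mc <- recovered_vdss_coefficients()
  conv <- default_conversion()
  # acetazolamide: CHI 0.99, log K(HSA) 1.44 -> tabulated -0.47
  aceta <- data.frame(logk_iam = as.numeric(predict(conv, 0.99, quiet = TRUE)),
                      logk_hsa = 1.44)
  expect_equal(estimate_log_vdss(aceta, mc), -0.47, tolerance = 0.05 / 0.47)
  # tamoxifen: CHI 54.23 (extrapolated), realigned log K(HSA) 4.82 -> 0.94
  tamo <- data.frame(logk_iam = as.numeric(predict(conv, 54.23, quiet = TRUE)),
                     logk_hsa = 4.82)
  expect_lt(abs(estimate_log_vdss(tamo, mc) - 0.94), 0.05)
  # the recovered binding weights match the published model's magnitudes
  expect_equal(abs(unname(mc$terms["logk_hsa"])), 0.22, tolerance = 0.05 / 0.22)
  expect_equal(abs(unname(mc$terms["logk_iam"])), 0.44, tolerance = 0.05 / 0.44)
})

test_that("coefficient recovery is exact on clean synthetic tables and warns on noisy ones", {
  set.seed(5)
  logk_iam <- runif(30, 1, 6); logk_hsa <- runif(30, 0, 6)
  est <- -0.6 + 0.5 * logk_iam - 0.2 * logk_hsa
  rec <- recover_vdss_model(est, logk_iam, logk_hsa)
  expect_equal(unname(coef(rec)), c(-0.6, 0.5, -0.2), tolerance = 1e-10)
  expect_equal(rec$fit_stats$r_squared, 1, tolerance = 1e-12)
  # gaussian noise sigma = 0.02, n = 72: recovery within 3 standard errors
  set.seed(6)
  logk_iam <- runif(72, 1, 6); logk_hsa <- runif(72, 0, 6)
  est <- -0.6 + 0.5 * logk_iam - 0.2 * logk_hsa + rnorm(72, 0, 0.02)
  rec2 <- recover_vdss_model(est, logk_iam, logk_hsa)
  se <- rec2$std_errors
  expect_lt(abs(coef(rec2)[["logk_iam"]] - 0.5), 3 * se[["logk_iam"]])
  expect_lt(abs(coef(rec2)[["logk_hsa"]] - (-0.2)), 3 * se[["logk_hsa"]])
  expect_equal(unname(coef(rec2)),
               unname(normal_equations(est, logk_iam, logk_hsa)),
               tolerance = 1e-8)
  # heavy corruption trips the data-inconsistency warning
  bad <- est + rnorm(72, 0, 1)
  expect_warning(recover_vdss_model(bad, logk_iam, logk_hsa),
                 "data-inconsistency")
})

test_that("recovery from the printed (misaligned) HSA column fires the warning path", {
  d <- study_data(realign = FALSE)
  conv <- default_conversion()
  expect_warning(
    rec <- recover_vdss_model(
      d$log_vdss_est_r20511,
      predict(conv, d$chi_iam_r20511, quiet = TRUE),
      d$logk_hsa_new),
    "data-inconsistency")
  expect_lt(rec$fit_stats$r_squared, 0.98)
})

test_that("clinical refit matches the normal-equations oracle and its F statistic", {
  d <- study_data()
  conv <- default_conversion()
  li <- as.numeric(predict(conv, d$chi_iam_r20511, quiet = TRUE))
  fit <- suppressMessages(
    fit_vdss_model(d$log_vdss_clinical, li, d$logk_hsa_new))
  ok <- complete.cases(d$logk_hsa_new)
  ne <- normal_equations(d$log_vdss_clinical[ok], li[ok], d$logk_hsa_new[ok])
  expect_equal(unname(coef(fit)), unname(ne), tolerance = 1e-8)
  st <- fit$fit_stats
  expect_equal(st$f_value,
               (st$r_squared / 2) / ((1 - st$r_squared) / (st$n - 3)),
               tolerance = 1e-10)
  # noiseless synthetic refit: exact recovery with r^2 = 1
  set.seed(7)
  li2 <- runif(20, 1, 6); lh2 <- runif(20, 0, 6)
  y <- 0.3 + 0.7 * li2 - 0.1 * lh2
  f2 <- fit_vdss_model(y, li2, lh2)
  expect_equal(unname(coef(f2)), c(0.3, 0.7, -0.1), tolerance = 1e-10)
  expect_equal(f2$fit_stats$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_vdss_model(y[1:5], li2[1:5], lh2[1:5]), ">= 10")
  expect_error(fit_vdss_model(y, li2, li2 * 2), "singular|rank")
})

test_that("logistic-link estimators are bounded, anchored at 50 % and monotone", {
  mc <- model_coefficients("btb", c(logk_iam = 0.8, logk_hsa = 0.4), 0,
                           link = "logistic_percent")
  z <- data.frame(logk_iam = 0, logk_hsa = 0)
  expect_equal(estimate_percent_btb(z, mc), 50)
  expect_equal(estimate_fu_tissue(z, mc), 0.5)
  expect_equal(estimate_drug_efficiency(z, mc), 50)
  big <- data.frame(logk_iam = 1e4, logk_hsa = 0)
  expect_equal(estimate_percent_btb(big, mc), 100)
  expect_equal(estimate_percent_btb(-big, mc), 0)
  # strictly increasing in logk_iam at 5 probe points (positive weight)
  probes <- data.frame(logk_iam = c(-2, -1, 0, 1, 2), logk_hsa = 1)
  expect_true(all(diff(estimate_percent_btb(probes, mc)) > 0))
  # fu is the exact complement of %BTB under a shared score
  set.seed(8)
  rand <- data.frame(logk_iam = rnorm(10), logk_hsa = rnorm(10))
  expect_equal(estimate_fu_tissue(rand, mc) +
                 estimate_percent_btb(rand, mc) / 100,
               rep(1, 10))
  expect_true(all(diff(estimate_fu_tissue(probes, mc)) < 0))
  # identity-link set is a configuration error for percentage outputs
  idc <- model_coefficients("id", c(logk_iam = 1), 0)
  expect_error(estimate_percent_btb(z, idc), "logistic_percent")
})

test_that("equal binding sums give equal efficiency; ranks reverse the sums", {
  mc <- model_coefficients("de", c(logk_iam = -0.5, logk_hsa = -0.5), 1,
                           link = "logistic_percent")
  a <- data.frame(logk_iam = 3, logk_hsa = 1)
  b <- data.frame(logk_iam = 1, logk_hsa = 3)   # same sum, symmetric weights
  expect_equal(estimate_drug_efficiency(a, mc),
               estimate_drug_efficiency(b, mc))
  set.seed(9)
  prof <- data.frame(logk_iam = runif(10, 0, 5), logk_hsa = runif(10, 0, 5))
  de <- estimate_drug_efficiency(prof, mc)
  expect_equal(order(de), order(-(prof$logk_iam + prof$logk_hsa)))
})

test_that("unbound volume of distribution follows log Vdu = log Vdss - log10(fu)", {
  expect_equal(estimate_log_vdu(0.5, 1), 0.5)
  expect_equal(estimate_log_vdu(0.5, 0.1), 1.5)
  expect_error(estimate_log_vdu(0.5, 0), "\\(0, 1\\]")
  expect_error(estimate_log_vdu(0.5, -0.2), "\\(0, 1\\]")
  set.seed(10)
  fu <- runif(50, 1e-6, 1); v <- rnorm(50)
  expect_true(all(estimate_log_vdu(v, fu) >= v))
})

test_that("phospholipidosis flag is strict: basic AND CHI > 50", {
  expect_true(phospholipidosis_flag("basic", 61.9))    # chlorpromazine
  expect_false(phospholipidosis_flag("acidic", 21.9))  # ketoprofen
  expect_false(phospholipidosis_flag("basic", 50))     # boundary excluded
  expect_equal(phospholipidosis_flag(c("basic", "neutral", "weak base"),
                                     c(55, 55, 55)),
               c(TRUE, FALSE, FALSE))
  expect_error(phospholipidosis_flag("zwitterionic", 10), "unknown")
})

test_that("bridge model gains r^2 from an informative descriptor and ignores a flat one", {
  set.seed(12)
  chi_new <- runif(40, 0, 60)
  desc <- rnorm(40)
  chi_ref <- 2 + 1.02 * chi_new + 0.5 * desc + rnorm(40, 0, 0.3)
  fit <- fit_bridge_model(chi_new, chi_ref, data.frame(desc = desc))
  expect_gt(fit$r_squared_gain, 0)
  expect_gt(fit$fit_stats$r_squared, fit$baseline_r_squared)
  # zero-variance descriptor: baseline coefficients, weight 0
  flat <- fit_bridge_model(chi_new, chi_ref,
                           data.frame(desc = rep(2, 40)))
  base <- suppressMessages(fit_distribution_model(
    chi_ref, data.frame(chi_new = chi_new), "b"))
  expect_equal(flat$terms[["chi_new"]], base$terms[["chi_new"]])
  expect_equal(flat$terms[["desc"]], 0)
  # exact linear relation: r^2 = 1
  exact <- fit_bridge_model(chi_new, 1 + 0.9 * chi_new)
  expect_equal(exact$fit_stats$r_squared, 1, tolerance = 1e-12)
  # rows with missing descriptors are excluded with a message
  desc_na <- desc; desc_na[c(3, 7)] <- NA
  expect_message(fit_bridge_model(chi_new, chi_ref,
                                  data.frame(desc = desc_na)),
                 "2 row")
})

test_that("estimate_distribution assembles the full block with flags", {
  d <- data.frame(name = c("a", "b"),
                  chi_iam = c(55, 10),
                  logk_hsa = c(1.5, 0.5),
                  acid_base_class = c("basic", "neutral"))
  btb <- model_coefficients("btb", c(logk_iam = 0.6, logk_hsa = 0.4), -2,
                            link = "logistic_percent")
  out <- estimate_distribution(d, btb_coeffs = btb, de_coeffs = btb)
  expect_true(all(c("logk_iam", "log_vdss", "percent_btb", "fu_tissue",
                    "log_vdu", "drug_efficiency", "extrapolated_chi",
                    "phospholipidosis_risk") %in% names(out)))
  expect_equal(out$extrapolated_chi, c(TRUE, FALSE))
  expect_equal(out$phospholipidosis_risk, c(TRUE, FALSE))
  expect_true(all(out$percent_btb >= 0 & out$percent_btb <= 100))
  expect_true(all(out$fu_tissue >= 0 & out$fu_tissue <= 1))
  expect_true(all(out$log_vdu >= out$log_vdss))
})
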