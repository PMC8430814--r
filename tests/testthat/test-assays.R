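test_that("noiseless 4PL data round-trips the generating parameters", {
  cur <- simulate_dose_response(ic50 = 10, hill = 1, top = 100, bottom = 0,
                                noise_sd = 0)
  fit <- fit_ic50(cur)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["ic50"]), 10, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[c("top", "bottom", "hill")]), c(100, 0, 1),
               tolerance = 1e-5)
  # invariance to dose reordering and uniform viability rescaling
  shuffled <- dose_response(rev(cur$dose), rev(cur$viability))
  expect_equal(coef(fit_ic50(shuffled))["ic50"], coef(fit)["ic50"],
               tolerance = 1e-8)
  scaled <- dose_response(cur$dose, cur$viability * 0.6)
  expect_equal(unname(coef(fit_ic50(scaled))["ic50"]), 10, tolerance = 1e-6)
  # steeper curve, non-zero floor
  cur2 <- simulate_dose_response(ic50 = 6, hill = 2.5, top = 95, bottom = 15,
                                 noise_sd = 0)
  expect_equal(unname(coef(fit_ic50(cur2))["ic50"]), 6, tolerance = 1e-6)
})

test_that("noisy seeded curves recover the IC50 within 15 percent", {
  cur <- simulate_dose_response(ic50 = 10, hill = 1, top = 100, bottom = 0,
                                n_replicates = 3, noise_sd = 2, seed = 7)
  fit <- fit_ic50(cur)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)["ic50"] - 10) / 10, 0.15)
})

test_that("degenerate viability flags non-convergence honestly", {
  rising <- dose_response(c(1, 2, 5, 10, 20), c(20, 35, 55, 80, 95))
  fit <- fit_ic50(rising)
  expect_false(fit$converged)  # not a decreasing viability curve
  expect_error(fit_ic50(dose_response(c(1, 2, 5), c(90, 50, 10))),
               ">= 4 distinct doses")
})

test_that("replicate IC50 summaries reproduce published means and significance", {
  s <- summarize_ic50(c(5.7, 11.39, 6.7))
  expect_equal(round(s$mean, 2), 7.93)
  cmp <- summarize_ic50(c(17.32, 23.3, 20.4), reference = c(5.7, 11.39, 6.7))
  expect_equal(round(cmp$mean, 2), 20.34)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$stars, "**")
  # pooled t matches the textbook formula
  expect_equal(cmp$p_value,
               student_oracle(c(17.32, 23.3, 20.4), c(5.7, 11.39, 6.7)),
               tolerance = 1e-12)
  welch <- summarize_ic50(c(17.32, 23.3, 20.4),
                          reference = c(5.7, 11.39, 6.7), var_equal = FALSE)
  expect_equal(welch$p_value,
               welch_oracle(c(17.32, 23.3, 20.4), c(5.7, 11.39, 6.7)),
               tolerance = 1e-12)
  # group against itself: p = 1
  self <- summarize_ic50(c(5, 6, 7), reference = c(5, 6, 7))
  expect_equal(self$p_value, 1)
  expect_equal(self$stars, "")
  expect_warning(summarize_ic50(5, reference = c(5, 6)), "singleton")
})

test_that("delta-Ct quantification follows the reference-minus-target formula", {
  m <- delta_ct(target_ct = c(25, 25, 25), reference_ct = c(20, 20, 20))
  expect_equal(m$delta_ct, -5)
  expect_equal(m$relative_expression, 0.03125)
  eq <- delta_ct(c(22, 23), c(22.5, 22.5))
  expect_equal(eq$delta_ct, 0)
  expect_equal(eq$relative_expression, 1)
  # antisymmetry: swapping target and reference negates delta-Ct
  a <- delta_ct(c(24, 25), c(20, 21))
  b <- delta_ct(c(20, 21), c(24, 25))
  expect_equal(a$delta_ct, -b$delta_ct)
  # parental normalised to itself reads 1
  par <- delta_ct(c(25, 25), c(20, 20))
  par_norm <- delta_ct(c(25, 25), c(20, 20), parental = par)
  expect_equal(par_norm$relative_to_parental, 1)
  expect_error(delta_ct(c(25, 25), numeric()), "reference Ct")
  expect_error(delta_ct(c(-1, 25), c(20, 20)), "positive")
})

test_that("assay CSV readers reconstruct curves and measurements", {
  td <- withr::local_tempdir()
  dr <- file.path(td, "dr.csv")
  cur <- simulate_dose_response(8, noise_sd = 1, seed = 3, sample = "c1")
  write.csv(data.frame(sample = "c1", dose_uM = cur$dose,
                       replicate = rep(1:3, length.out = nrow(cur)),
                       viability_pct = cur$viability),
            dr, row.names = FALSE)
  curves <- read_dose_response(dr)
  expect_named(curves, "c1")
  expect_equal(curves$c1$viability, cur$viability)
  qp <- file.path(td, "qpcr.csv")
  write.csv(data.frame(
    sample = rep(c("parental", "c1"), each = 6),
    assay = rep(rep(c("CD274", "GAPDH"), each = 3), 2),
    role = rep(rep(c("target", "reference"), each = 3), 2),
    ct = c(26, 26.1, 25.9, 20, 20, 20,  24, 24.2, 23.8, 20, 20, 20)),
    qp, row.names = FALSE)
  ms <- read_qpcr(qp, parental_sample = "parental")
  expect_equal(ms$parental$relative_to_parental, 1)
  expect_equal(ms$c1$relative_to_parental, 2^(mean(c(26, 26.1, 25.9)) -
                                              mean(c(24, 24.2, 23.8))),
               tolerance = 1e-12)
  # Mann-Whitney comparison is the rank-sum test
  w <- qpcr_compare(c(4.1, 3.9, 4.0), c(1.0, 1.1, 0.9))
  expect_equal(w$p.value, wilcox.test(c(4.1, 3.9, 4.0),
                                      c(1.0, 1.1, 0.9))$p.value)
})
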