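random_table <- function(n, seed) {
  set.seed(seed)
  data.frame(class_code = sample(c(0, 0.5, 1), n, TRUE),
             separation_nm = runif(n, 0, 26),
             protrusion_flag = rbinom(n, 1, 0.4),
             n_densities = sample(2:34, n, TRUE))
}

# brute-force two-pass covariance oracle
cor_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

test_that("cc_matrix matches a brute-force covariance oracle to 1e-12", {
  for (seed in 1:50) {
    tb <- random_table(sample(20:100, 1), seed)
    got <- cc_matrix(tb)$pooled$r
    for (a in 1:3) for (b in (a + 1):4) {
      expect_equal(got[a, b],
                   cor_oracle(tb[[a]], tb[[b]]), tolerance = 1e-12)
    }
    expect_equal(got, t(got))
    expect_equal(unname(diag(got)), rep(1, 4))
  }
})

test_that("self- and perfectly linear correlations behave as expected", {
  tb <- data.frame(class_code = c(0, 0.5, 1),
                   separation_nm = c(0, 1, 2),
                   protrusion_flag = c(0, 1, 0),
                   n_densities = c(1, 2, 3))
  cc <- cc_matrix(tb)$pooled
  expect_equal(cc$r["class_code", "class_code"], 1)
  expect_equal(cc$p["class_code", "class_code"], 0)
  expect_equal(cc$r["class_code", "separation_nm"], 1)   # perfect line
  expect_equal(cc$r["class_code", "n_densities"], 1)
})

test_that("zero-variance columns give NA correlations, not zero", {
  tb <- data.frame(class_code = rep(0.5, 10),
                   separation_nm = runif(10),
                   protrusion_flag = rbinom(10, 1, 0.5),
                   n_densities = sample(2:10, 10, TRUE))
  r <- cc_matrix(tb)$pooled$r
  expect_true(all(is.na(r["class_code", ])))
})

test_that("the class-separation correlation matches its analytic value", {
  tb <- simulate_code_separation(10000, seed = 42)
  r <- cc_matrix(cbind(tb, protrusion_flag = 0, n_densities = 2),
                 vars = c("class_code", "separation_nm"))$pooled$r
  # law of total variance: Cov = -2, Var(code) = 1/6, Var(sep) = 41.861
  analytic <- -2 / sqrt((1 / 6) * (515 / 36 + 27.55556))
  expect_equal(analytic, -0.757, tolerance = 0.001)
  expect_equal(r["class_code", "separation_nm"], analytic,
               tolerance = 0.015)
})

test_that("strength labels follow the printed scheme with left-closed bins", {
  expect_identical(strength_label(c(0.05, 0.1, 0.3, 0.5, 0.9)),
                   c("negligible", "small", "moderate", "strong", "strong"))
  expect_identical(strength_label(-0.76), "strong")
  expect_identical(strength_label(0.22), "small")
  expect_true(is.na(strength_label(NaN)))
})

test_that("summaries report separation fractions and contact statistics", {
  tb <- data.frame(class_code = c(1, 1, 0, 0),
                   separation_nm = c(2, 5, 9, 12),
                   n_densities = c(4, 6, 8, 10),
                   contact_diameter_nm = c(16, 0, 0, 0))
  s <- summarize_junctions(tb)$all
  expect_equal(s$frac_sep_lt_10, 0.75)
  expect_identical(s$n_sep_gt_20, 0L)
  expect_equal(s$densities_mean, 7)
  expect_equal(s$contact_diameter_mean, 16)
  expect_equal(sum(s$histogram$counts), 4)
  # empty condition: no crash, NA summaries
  tb$condition <- factor(rep("WT", 4), levels = c("WT", "d84"))
  s2 <- summarize_junctions(tb)
  expect_true(is.na(s2$d84$frac_sep_lt_10))
  expect_equal(s2$WT$n, 4)
})
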