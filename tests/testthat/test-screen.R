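test_that("molecular subtype rules follow receptor status", {
  expect_identical(classify_subtype(70, 0, FALSE), "LuminalA")
  expect_identical(classify_subtype(0, 40, FALSE), "LuminalA")
  expect_identical(classify_subtype(70, 10, TRUE), "LuminalB")
  expect_identical(classify_subtype(0, 0, FALSE), "TripleNegative")
  expect_identical(classify_subtype(0, 0, TRUE), "HER2pos")
  expect_identical(classify_subtype(c(70, 0), c(0, 0), c(FALSE, TRUE)),
                   c("LuminalA", "HER2pos"))
  expect_error(classify_subtype(120, 0, FALSE), class = "lq_argument_error")
})

test_that("Spearman correlation handles monotone, exact and degenerate cases", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  expect_equal(spearman_corr(x, -2 * x + 1)$rho, -1)
  # invariance under strictly monotone transforms
  set.seed(41)
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(spearman_corr(exp(a), b)$rho, spearman_corr(a, b)$rho)
  expect_warning(res <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(res$undefined)
  expect_error(spearman_corr(1:2, 1:2), class = "lq_argument_error")
})

test_that("exact Spearman p-values match the reference implementation at n = 8", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    got <- spearman_corr(x, y)
    expect_identical(got$method, "exact permutation")
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney reproduces the symmetric and separated cases", {
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$U, 4.5)
  expect_equal(res$p, 1)
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 2 / choose(6, 3))  # minimal exact two-sided p
  expect_error(mann_whitney(numeric(0), 1:3), class = "lq_argument_error")
})

test_that("small-sample Mann-Whitney matches the exact reference distribution", {
  set.seed(43)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    got <- mann_whitney(a, b)
    expect_identical(got$method, "exact enumeration")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis reduces to the squared Mann-Whitney z for two groups", {
  set.seed(44)
  a <- rnorm(9); b <- rnorm(12)
  kw <- kruskal_wallis(list(a, b))
  U <- mann_whitney(a, b)$U
  n1 <- 9; n2 <- 12; N <- n1 + n2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-10)
  expect_equal(kw$df, 1)
  expect_warning(res <- kruskal_wallis(list(rep(1, 4), rep(1, 3))), "tied")
  expect_true(res$undefined)
  expect_error(kruskal_wallis(list(1:5)), class = "lq_argument_error")
})

test_that("linear regression recovers exact and closed-form fits", {
  x <- c(1, 2, 4, 7, 8)
  fit <- suppressWarnings(linear_fit(x, 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  set.seed(45)
  xx <- rnorm(40); yy <- 0.5 * xx + rnorm(40)
  f2 <- linear_fit(xx, yy)
  # closed-form normal equations
  slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  expect_equal(f2$slope, slope, tolerance = 1e-12)
  expect_equal(f2$intercept, mean(yy) - slope * mean(xx), tolerance = 1e-12)
  expect_equal(f2$r_squared, f2$correlation^2, tolerance = 1e-12)
  expect_error(linear_fit(rep(2, 5), rnorm(5)), class = "lq_degenerate_error")
})

make_fake_cohort <- function(n = 38, entropy_shift = 0) {
  set.seed(46)
  labels <- generate_clinical_labels(n)
  feats <- as.data.frame(matrix(rnorm(n * 44), n, 44))
  names(feats) <- c(paste0("pet_", feature_names("PET")),
                    paste0("mr_", feature_names("MR")))
  feats$mr_entropy <- feats$mr_entropy + entropy_shift * labels$pcr
  cbind(feats, labels)
}

test_that("the screen routes each comparison to the prescribed test", {
  co <- make_fake_cohort()
  res <- suppressWarnings(run_screen(co))
  expect_s3_class(res, "screen_result")
  expect_true(res$uncorrected)
  expect_equal(dim(res$p), c(44, 6))
  expect_true(all(res$test[, "pcr"] == "Mann-Whitney", na.rm = TRUE))
  expect_true(all(res$test[, "subtype"] == "Kruskal-Wallis", na.rm = TRUE))
  expect_true(all(res$test[, "mib1"] == "Spearman", na.rm = TRUE))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  expect_equal(nrow(res$pet_vs_mr), 22)
  expect_true(all(res$pet_vs_mr$test == "Spearman"))
})

test_that("an injected entropy shift between pCR groups is detected", {
  co <- make_fake_cohort(entropy_shift = 2.5)
  res <- suppressWarnings(run_screen(co, comparisons = "pcr"))
  expect_lt(res$p["mr_entropy", "pcr"], 0.05)
  # the matching null cohort leaves it unremarkable
  co0 <- make_fake_cohort(entropy_shift = 0)
  res0 <- suppressWarnings(run_screen(co0, comparisons = "pcr"))
  expect_gt(res0$p["mr_entropy", "pcr"], 0.05)
})

test_that("degenerate groups are skipped with a warning, not silently", {
  co <- make_fake_cohort(12)
  co$subtype <- c("HER2pos", rep(c("LuminalA", "TripleNegative"), c(5, 6)))
  co$cerbb2_positive <- co$subtype %in% c("HER2pos", "LuminalB")
  expect_warning(res <- run_screen(co, comparisons = "subtype"), "skipped")
  expect_true(all(is.na(res$p[, "subtype"])))
  expect_identical(res$skipped, "subtype")
})

test_that("Benjamini-Hochberg adjustment is an explicit, labelled extension", {
  co <- make_fake_cohort()
  res <- suppressWarnings(run_screen(co, comparisons = "pcr", adjust = "BH"))
  expect_true(res$uncorrected)
  expect_true(!is.null(res$p_adjusted))
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
  expect_match(res$adjust_method, "extension")
})
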