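#' Classify the molecular subtype from receptor status
#'
#' Rule-based classes from ER/PR expression and c-erbB-2 (HER2) status.
#' Hormone positivity means expression greater than 0%:
#' Luminal A = (ER+ or PR+) and HER2-; Luminal B = (ER+ or PR+) and HER2+;
#' triple-negative = ER- and PR- and HER2-; HER2+ = ER- and PR- and HER2+.
#'
#' @param er_percent,pr_percent receptor expression in percent, in `[0, 100]`
#'   (vectorised).
#' @param cerbb2_positive logical, c-erbB-2 over-expression.
#' @return Character vector with values `"LuminalA"`, `"LuminalB"`,
#'   `"TripleNegative"`, `"HER2pos"`.
#' @examples
#' classify_subtype(70, 0, FALSE)  # LuminalA
#' classify_subtype(0, 0, TRUE)    # HER2pos
#' @export
classify_subtype <- function(er_percent, pr_percent, cerbb2_positive) {
  if (any(er_percent < 0 | er_percent > 100 | pr_percent < 0 |
            pr_percent > 100, na.rm = TRUE))
    stop_lq("lq_argument_error", "receptor percentages must be in [0, 100]")
  hr <- er_percent > 0 | pr_percent > 0
  ifelse(hr & !cerbb2_positive, "LuminalA",
    ifelse(hr & cerbb2_positive, "LuminalB",
      ifelse(!hr & !cerbb2_positive, "TripleNegative", "HER2pos")))
}

# all permutations of 1..n as an (n! x n) matrix (n <= 9)
perm_matrix <- function(n) {
  p <- matrix(1L, 1, 1)
  for (m in 2:n) {
    old <- p
    p <- matrix(0L, nrow(old) * m, m)
    for (pos in seq_len(m)) {
      rows <- (pos - 1) * nrow(old) + seq_len(nrow(old))
      p[rows, pos] <- m
      p[rows, -pos] <- old
    }
  }
  p
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; two-sided p-value from the
#' exhaustive permutation distribution for `n <= exact_n` (default 9), and
#' from the large-sample t approximation otherwise.
#'
#' @param x,y paired samples (pairs with `NA` dropped), n >= 3.
#' @param exact_n sample-size limit for the exact permutation branch.
#' @return List with `rho`, `p`, `n`, `method`, and `undefined = TRUE` (with
#'   `NA` statistics) when either variable is constant.
#' @export
spearman_corr <- function(x, y, exact_n = 9L) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_lq("lq_argument_error", "need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined",
                undefined = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    P <- perm_matrix(n)
    RY <- matrix(ry[P], nrow(P), n)
    cx <- rx - mean(rx)
    num <- as.vector(RY %*% cx)
    den <- sqrt(sum(cx^2) * sum((ry - mean(ry))^2))
    rhos <- num / den
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))$p.value
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method, undefined = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. For total sample sizes up to
#' `exact_total_n` (default 12) the p-value comes from exhaustive enumeration
#' of all group labelings (valid with ties); larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b the two samples (non-empty; `NA` dropped).
#' @param exact_total_n threshold for the exact enumeration branch.
#' @return List with `U` (statistic for group `a`), `p`, `n1`, `n2`,
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact_total_n = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0)
    stop_lq("lq_argument_error", "both groups must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_total_n) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    method <- "normal approximation"
  }
  list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic with chi-square reference on k - 1 degrees of
#' freedom, via [stats::kruskal.test()].
#'
#' @param groups list of two or more non-empty samples, total n >= 3.
#' @return List with `H`, `p`, `df`, and `undefined = TRUE` (NA statistics,
#'   warning) when all values are tied.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_lq("lq_argument_error", "need at least 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0))
    stop_lq("lq_argument_error", "all groups must be non-empty")
  x <- unlist(groups)
  if (length(x) < 3) stop_lq("lq_argument_error", "total n must be >= 3")
  if (length(unique(x)) < 2) {
    warning("all values tied: Kruskal-Wallis statistic undefined",
            call. = FALSE)
    return(list(H = NA_real_, p = NA_real_, df = length(groups) - 1L,
                undefined = TRUE))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), undefined = FALSE)
}

#' Ordinary least-squares fit of one feature on another
#'
#' `y = a x + b` by OLS, reporting the slope, intercept, coefficient of
#' determination and Pearson correlation (`r_squared = correlation^2`).
#'
#' @param x,y paired samples, n >= 3; `x` must not be constant.
#' @return Object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `correlation`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_lq("lq_argument_error", "need at least 3 pairs")
  if (length(unique(x)) < 2)
    stop_lq("lq_degenerate_error", "x is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 correlation = stats::cor(x, y), n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g x + %.4g (R^2 = %.3f, r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$correlation, x$n))
  invisible(x)
}

SCREEN_LABEL_COMPARISONS <- c("er", "pr", "tn", "subtype", "mib1", "pcr")

#' Univariate feature screen of a cohort table
#'
#' Runs the uncorrected univariate screen over a cohort table (one row per
#' lesion, 22 PET + 22 MR feature columns, clinical label columns):
#' \itemize{
#'   \item binary labels (ER status, PR status, triple-negative vs other,
#'     pCR): Mann-Whitney per feature;
#'   \item the four-class molecular subtype: Kruskal-Wallis per feature;
#'   \item continuous labels (MiB-1 index) and matched PET-MR feature pairs:
#'     Spearman correlation.
#' }
#' By design no multiple-comparison correction is applied (the screen is
#' exploratory); `adjust = "BH"` optionally adds Benjamini-Hochberg adjusted
#' values as a clearly labelled extension. A comparison whose groups have
#' fewer than 2 members is skipped with a warning, never silently omitted.
#'
#' @param cohort a data.frame as from [build_cohort_table()]: feature columns
#'   prefixed `pet_` / `mr_`, label columns `er_percent`, `pr_percent`,
#'   `cerbb2_positive`, `mib1_percent`, `pcr`, `subtype`.
#' @param comparisons subset of
#'   `c("pet_vs_mr", "er", "pr", "tn", "subtype", "mib1", "pcr")`.
#' @param adjust `"none"` (default, mirroring the exploratory design) or
#'   `"BH"`.
#' @return Object of class `screen_result`: `p` (feature x comparison matrix
#'   of p-values for the label comparisons), `test` (test name per cell),
#'   `pet_vs_mr` (data.frame of matched-pair Spearman results),
#'   `uncorrected` flag, `p_adjusted` (only if `adjust = "BH"`), `skipped`.
#' @export
run_screen <- function(cohort,
                       comparisons = c("pet_vs_mr", SCREEN_LABEL_COMPARISONS),
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  comparisons <- match.arg(comparisons, several.ok = TRUE,
                           choices = c("pet_vs_mr", SCREEN_LABEL_COMPARISONS))
  feats <- grep("^(pet|mr)_", names(cohort), value = TRUE)
  if (!length(feats)) stop_lq("lq_schema_error", "no feature columns found")
  label_cmp <- intersect(comparisons, SCREEN_LABEL_COMPARISONS)
  p <- matrix(NA_real_, length(feats), length(label_cmp),
              dimnames = list(feats, label_cmp))
  test <- matrix(NA_character_, length(feats), length(label_cmp),
                 dimnames = list(feats, label_cmp))
  skipped <- character(0)
  grouping <- function(cmp) switch(cmp,
    er = cohort$er_percent > 0,
    pr = cohort$pr_percent > 0,
    tn = cohort$subtype == "TripleNegative",
    pcr = cohort$pcr,
    subtype = cohort$subtype,
    mib1 = cohort$mib1_percent)
  for (cmp in label_cmp) {
    g <- grouping(cmp)
    if (cmp == "mib1") {
      for (f in feats) {
        res <- suppressWarnings(spearman_corr(cohort[[f]], g))
        p[f, cmp] <- res$p
        test[f, cmp] <- "Spearman"
      }
    } else if (cmp == "subtype") {
      tab <- table(g)
      if (any(tab < 2) || length(tab) < 2) {
        skipped <- c(skipped, cmp)
        warning(sprintf(
          "comparison '%s' skipped: a group has fewer than 2 members", cmp),
          call. = FALSE)
        next
      }
      for (f in feats) {
        res <- suppressWarnings(
          kruskal_wallis(split(cohort[[f]], g)))
        p[f, cmp] <- res$p
        test[f, cmp] <- "Kruskal-Wallis"
      }
    } else {
      if (sum(g) < 2 || sum(!g) < 2) {
        skipped <- c(skipped, cmp)
        warning(sprintf(
          "comparison '%s' skipped: a group has fewer than 2 members", cmp),
          call. = FALSE)
        next
      }
      for (f in feats) {
        res <- mann_whitney(cohort[[f]][g], cohort[[f]][!g])
        p[f, cmp] <- res$p
        test[f, cmp] <- "Mann-Whitney"
      }
    }
  }
  cross <- NULL
  if ("pet_vs_mr" %in% comparisons) {
    pairs <- matched_feature_pairs(feats)
    cross <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      res <- suppressWarnings(
        spearman_corr(cohort[[pairs$pet[i]]], cohort[[pairs$mr[i]]]))
      data.frame(feature = pairs$name[i], pet = pairs$pet[i],
                 mr = pairs$mr[i], rho = res$rho, p = res$p,
                 test = "Spearman", stringsAsFactors = FALSE)
    }))
  }
  out <- list(p = p, test = test, pet_vs_mr = cross, uncorrected = TRUE,
              skipped = skipped)
  if (adjust == "BH") {
    padj <- p
    padj[] <- stats::p.adjust(as.vector(p), method = "BH")
    out$p_adjusted <- padj
    out$adjust_method <- "BH (extension; the default screen is uncorrected)"
  }
  structure(out, class = "screen_result")
}

# matched PET-MR pairs: macroscopic features pair by position
# (MTV~V_ADC, SUV_mean~ADC_mean, SUV_max~ADC_min, TLG~TLD), first-order and
# shape features by identical base name.
matched_feature_pairs <- function(feats) {
  pet <- paste0("pet_", PET_MACRO_NAMES)
  mr <- paste0("mr_", MR_MACRO_NAMES)
  common <- c(FIRST_ORDER_NAMES, SHAPE_NAMES)
  pairs <- data.frame(
    name = c(paste(PET_MACRO_NAMES, MR_MACRO_NAMES, sep = "~"), common),
    pet = c(pet, paste0("pet_", common)),
    mr = c(mr, paste0("mr_", common)),
    stringsAsFactors = FALSE)
  pairs[pairs$pet %in% feats & pairs$mr %in% feats, , drop = FALSE]
}

#' @export
print.screen_result <- function(x, alpha = 0.05, ...) {
  cat("<screen_result> uncorrected univariate screen\n")
  if (!is.null(x$p) && ncol(x$p)) {
    sig <- which(x$p < alpha, arr.ind = TRUE)
    cat(sprintf("  label comparisons: %d features x %d comparisons, %d cells with p < %.2g\n",
                nrow(x$p), ncol(x$p), nrow(sig), alpha))
    if (nrow(sig) > 0 && nrow(sig) <= 25) {
      for (i in seq_len(nrow(sig)))
        cat(sprintf("    %s vs %s: p = %.4f (%s)\n",
                    rownames(x$p)[sig[i, 1]], colnames(x$p)[sig[i, 2]],
                    x$p[sig[i, 1], sig[i, 2]],
                    x$test[sig[i, 1], sig[i, 2]]))
    }
  }
  if (!is.null(x$pet_vs_mr))
    cat(sprintf("  PET-MR pairs: %d, %d with p < %.2g\n",
                nrow(x$pet_vs_mr), sum(x$pet_vs_mr$p < alpha, na.rm = TRUE),
                alpha))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
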