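# Group comparisons: t-test, one-way ANOVA with Tukey HSD, Pearson
# correlation with Fisher-z CI, and the distance-based permutation
# pseudo-F for multivariate descriptor matrices. All results share the
# `oto_test` S3 shape (statistic, p_value, significance at alpha = 0.05).

.oto_test <- function(test, factor_name, levels, statistic, p_value,
                      alpha = 0.05, details = NULL, extra = list()) {
  structure(c(list(test = test, factor = factor_name, levels = levels,
                   statistic = statistic, p_value = p_value, alpha = alpha,
                   significant = is.finite(p_value) && p_value < alpha,
                   details = details), extra),
            class = "oto_test")
}

#' @export
print.oto_test <- function(x, ...) {
  cat(sprintf("<oto_test> %s on %s (%s): statistic = %.4g, p = %.4g%s\n",
              x$test, x$factor, paste(x$levels, collapse = "/"),
              x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  if (!is.null(x$details)) print(x$details, ...)
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Two-sided Welch t-test by default (pooled-variance optional), used for
#' side (left vs right) and sex comparisons of morphometric variables.
#' If both groups are constant with equal means the comparison is reported
#' as t = 0, p = 1 (degenerate case).
#'
#' @param values numeric vector.
#' @param groups factor-like with exactly 2 levels, aligned with `values`.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param factor_name label for reporting.
#' @return an `oto_test` with `statistic` (t), `df` and `p_value`.
#' @export
unpaired_t <- function(values, groups, var_equal = FALSE,
                       factor_name = "group") {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  sp <- split(values, groups)
  if (any(lengths(sp) < 2L)) stop("each group needs n >= 2")
  if (all(vapply(sp, sd, numeric(1L)) == 0)) {
    if (diff(vapply(sp, mean, numeric(1L))) == 0)
      return(.oto_test("unpaired t (degenerate)", factor_name,
                       levels(groups), 0, 1, extra = list(df = NA_real_)))
    stop("zero variance in both groups with unequal means")
  }
  tt <- t.test(sp[[1L]], sp[[2L]], var.equal = var_equal)
  .oto_test(if (var_equal) "pooled t" else "Welch t", factor_name,
            levels(groups), unname(tt$statistic), tt$p.value,
            extra = list(df = unname(tt$parameter),
                         conf_int = unname(tt$conf.int)))
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' F-test across k groups plus Tukey honest-significant-difference
#' pairwise comparisons with familywise-adjusted p-values and 95%
#' confidence intervals of the differences (the classical per-class
#' comparison table).
#'
#' @param values numeric vector.
#' @param groups factor-like with k >= 2 levels, each n >= 2.
#' @param factor_name label for reporting.
#' @return an `oto_test` with `statistic` (F), `p_value`, and `details`: a
#'   data frame of pairwise differences (`diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups, factor_name = "group") {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  df <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = df)
  sm <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  details <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
  .oto_test("one-way ANOVA + Tukey HSD", factor_name, levels(groups),
            sm[["F value"]][1L], sm[["Pr(>F)"]][1L], details = details)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Correlation between a morphometric variable and a biometric covariate
#' (TL or BW), with the two-sided test and the 95% CI from the Fisher
#' z-transform.
#'
#' @param x,y numeric vectors, n >= 4, both non-constant.
#' @param factor_name label for reporting.
#' @return an `oto_test` with `statistic` (r), `p_value` and `conf_int`.
#' @export
pearson_ci <- function(x, y, factor_name = "correlation") {
  if (length(x) < 4L) stop("need n >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  .oto_test("Pearson r", factor_name, c("x", "y"),
            unname(ct$estimate), ct$p.value,
            extra = list(conf_int = unname(ct$conf.int),
                         df = unname(ct$parameter)))
}

# squared Euclidean distance matrix
.sqdist <- function(X) {
  s <- rowSums(X^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

# pseudo-F from a squared-distance matrix and integer group codes
.pseudo_F <- function(d2, g, k, n) {
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (lev in seq_len(k)) {
    idx <- which(g == lev)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' Distance-based permutation test (ANOVA-like pseudo-F)
#'
#' Multivariate group-difference test on a descriptor matrix: the pseudo-F
#' statistic is the ratio of between- to within-group sums of squared
#' Euclidean distances (PERMANOVA-style), and its null distribution is
#' built by permuting specimen labels. Columns are standardized (centred,
#' unit variance) by default so coefficients on different scales contribute
#' comparably. The p-value uses the add-one convention
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`, so its attainable
#' minimum is `1 / (1 + n_perm)`.
#'
#' @param mat numeric matrix (rows = specimens).
#' @param groups factor-like, >= 2 levels, each n >= 3.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed (permutations are reproducible given it).
#' @param standardize scale columns to unit variance first.
#' @param blocks optional blocking factor (e.g. specimen id when rows are
#'   individual otoliths). For a factor constant within blocks (sex, size
#'   class) the block-level labels are permuted, keeping each block's rows
#'   together; for a factor varying within blocks (side) the labels are
#'   permuted within each block. Guards against pseudo-replication from
#'   paired left/right otoliths.
#' @param factor_name label for reporting.
#' @return an `oto_test` with `statistic` (pseudo-F), `p_value`, and
#'   `perm_F` (the permuted statistics). Degenerate input (all rows
#'   identical) is reported as p = 1 with a `degenerate` flag.
#' @export
permutation_anova <- function(mat, groups, n_perm = 999L, seed = 1L,
                              standardize = TRUE, blocks = NULL,
                              factor_name = "group") {
  mat <- as.matrix(mat)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 3L)) stop("each group needs n >= 3")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  n <- nrow(mat)
  if (standardize) {
    sds <- apply(mat, 2L, sd)
    keep <- sds > 0
    mat <- scale(mat[, keep, drop = FALSE])
  }
  d2 <- .sqdist(mat)
  if (all(d2 < 1e-24))
    return(.oto_test("permutation pseudo-F (degenerate)", factor_name,
                     levels(groups), 0, 1,
                     extra = list(degenerate = TRUE, n_perm = n_perm)))
  g <- as.integer(groups)
  shuffle <- if (is.null(blocks)) {
    function() sample(g)
  } else {
    blocks <- factor(blocks)
    idx <- split(seq_len(n), blocks)
    const <- all(vapply(idx, function(i) length(unique(g[i])) == 1L, logical(1L)))
    if (const) {
      # permute block-level labels, expand back to rows
      blab <- vapply(idx, function(i) g[i[1L]], integer(1L))
      function() {
        newlab <- sample(blab)
        gp <- integer(n)
        for (b in seq_along(idx)) gp[idx[[b]]] <- newlab[b]
        gp
      }
    } else {
      # permute labels within each block
      function() {
        gp <- g
        for (i in idx) gp[i] <- g[sample(i)]
        gp
      }
    }
  }
  Fobs <- .pseudo_F(d2, g, k, n)
  perm_F <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    .pseudo_F(d2, shuffle(), k, n), numeric(1L)))
  p <- (1 + sum(perm_F >= Fobs)) / (1 + n_perm)
  .oto_test("permutation pseudo-F", factor_name, levels(groups),
            Fobs, p, extra = list(perm_F = perm_F, n_perm = n_perm,
                                  degenerate = FALSE))
}
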