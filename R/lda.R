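# Linear discriminant analysis of descriptor / index matrices, with a PCA
# reduction when there are more coefficients than specimens.

#' Linear discriminant analysis with leave-one-out validation
#'
#' Fisher LDA of a descriptor or shape-index matrix against a grouping
#' factor (side, sex or size class). When the number of columns approaches
#' or exceeds the number of specimens the matrix is first reduced by PCA,
#' retaining the components that explain `pca_var` of the variance (capped
#' at `n - k - 1` so the within-class scatter stays invertible). Leave-one-
#' out class predictions give the cross-validated confusion matrix and
#' accuracy.
#'
#' @param mat numeric matrix, rows = specimens.
#' @param groups factor-like, every class with n > 1.
#' @param cv `"loo"` (default) or `"none"`.
#' @param pca_var variance fraction retained by the PCA pre-step.
#' @param factor_name label for reporting.
#' @return an `oto_lda`: discriminant loadings (in original column space),
#'   per-specimen `scores`, in-sample `class_assign`, `confusion`
#'   (rows = true class), `accuracy`, the PCA pre-step (`pca`), and 95%
#'   confidence ellipses per class in the first two discriminant axes.
#' @export
oto_lda <- function(mat, groups, cv = c("loo", "none"), pca_var = 0.95,
                    factor_name = "group") {
  cv <- match.arg(cv)
  mat <- as.matrix(mat)
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("every class needs n > 1")
  k <- nlevels(groups)
  n <- nrow(mat)
  sds <- apply(mat, 2L, sd)
  mat <- mat[, sds > max(sds) * 1e-8, drop = FALSE]
  pca <- NULL
  X <- mat
  within_rank <- function(X) {
    Xc <- X
    for (lev in levels(groups)) {
      idx <- groups == lev
      Xc[idx, ] <- scale(X[idx, , drop = FALSE], scale = FALSE)
    }
    qr(Xc)$rank
  }
  # reduce by PCA when p approaches n or the within-class scatter is
  # rank-deficient (e.g. exact linear constraints among coefficients)
  big_p <- ncol(X) >= n - k
  if (big_p || within_rank(X) < ncol(X)) {
    pca <- prcomp(X, center = TRUE, scale. = FALSE)
    ncomp <- if (big_p) {
      # high-dimensional case: keep the leading share of variance
      cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
      max(2L, min(which(cum >= pca_var)))
    } else ncol(X)  # only shed exact null directions
    ncomp <- min(ncomp, n - k - 1L,
                 sum(pca$sdev > pca$sdev[1L] * 1e-4))
    X <- pca$x[, seq_len(ncomp), drop = FALSE]
  }
  rk <- within_rank(X)
  if (rk < ncol(X))
    stop(sprintf("within-class scatter is rank-deficient even after PCA reduction (rank %d < %d columns)",
                 rk, ncol(X)))
  # rank validity is checked above; relax MASS's absolute within-sd cutoff
  # (wavelet coefficients are legitimately tiny) and silence its
  # collinearity warning, which the PCA step already addresses
  muffle <- function(w) {
    if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
  }
  fit <- withCallingHandlers(
    MASS::lda(X, grouping = groups, tol = 1e-12), warning = muffle)
  pred <- predict(fit)
  loo_class <- if (cv == "loo") withCallingHandlers(
    MASS::lda(X, grouping = groups, tol = 1e-12, CV = TRUE),
    warning = muffle)$class else pred$class
  confusion <- table(true = groups, predicted = loo_class)
  accuracy <- mean(loo_class == groups)
  loadings <- if (is.null(pca)) fit$scaling else
    pca$rotation[, seq_len(ncol(X)), drop = FALSE] %*% fit$scaling
  ell <- NULL
  if (ncol(pred$x) >= 2L) {
    ell <- lapply(levels(groups), function(lev) {
      s <- pred$x[groups == lev, 1:2, drop = FALSE]
      if (nrow(s) < 3L) return(NULL)
      .conf_ellipse(colMeans(s), cov(s), 0.95)
    })
    names(ell) <- levels(groups)
  }
  structure(list(loadings = loadings, scores = pred$x,
                 class_assign = pred$class, confusion = confusion,
                 accuracy = accuracy, cv = cv, groups = groups,
                 pca = pca, factor = factor_name, ellipses = ell,
                 lda_fit = fit),
            class = "oto_lda")
}

.conf_ellipse <- function(mu, S, level = 0.95, n = 120L) {
  r <- sqrt(stats::qchisq(level, df = 2L))
  ang <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(ang), sin(ang)) * r
  ch <- chol(S)
  sweep(circ %*% ch, 2L, mu, "+")
}

#' @export
print.oto_lda <- function(x, ...) {
  cat(sprintf("<oto_lda> %s, %d classes, %d axes; %s accuracy = %.3f\n",
              x$factor, nlevels(x$groups), ncol(x$scores),
              if (x$cv == "loo") "leave-one-out" else "in-sample",
              x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' @export
plot.oto_lda <- function(x, ..., main = NULL) {
  if (ncol(x$scores) < 2L) {
    plot.default(x$scores[, 1L], jitter(rep(0, nrow(x$scores))),
                 col = as.integer(x$groups), xlab = "LD1", ylab = "",
                 main = main %||% x$factor)
  } else {
    plot.default(x$scores[, 1:2], col = as.integer(x$groups),
                 pch = 19, xlab = "LD1", ylab = "LD2",
                 main = main %||% x$factor, ...)
    for (i in seq_along(x$ellipses)) {
      e <- x$ellipses[[i]]
      if (!is.null(e)) lines(e, col = i)
    }
    legend("topright", legend = levels(x$groups), col = seq_along(levels(x$groups)),
           pch = 19, bty = "n")
  }
  invisible(x)
}

#' Binomial test of LDA accuracy against chance
#'
#' One-sided exact binomial test of the leave-one-out accuracy against the
#' chance rate `1 / k` (equal priors).
#'
#' @param fit an [oto_lda()] result.
#' @return an `oto_test` with the accuracy as statistic.
#' @export
lda_accuracy_test <- function(fit) {
  n <- length(fit$groups)
  correct <- round(fit$accuracy * n)
  bt <- binom.test(correct, n, p = 1 / nlevels(fit$groups),
                   alternative = "greater")
  .oto_test("LOO accuracy vs chance (binomial)", fit$factor,
            levels(fit$groups), fit$accuracy, bt$p.value)
}
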