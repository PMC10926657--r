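# Allometric adjustment: remove fish-length dependence from descriptor
# coefficients before group comparison, so differences reflect shape, not
# size.

#' Adjust descriptor coefficients for fish length
#'
#' For each coefficient column, fits a simple linear regression on TL. If
#' the slope is significant at `alpha`, the column is replaced by its
#' residuals plus the column's grand mean (so the column keeps its location
#' but loses its TL trend); otherwise it is left unchanged. Constant
#' columns are flagged and left unchanged. Applying the adjustment twice
#' equals applying it once: residual columns have zero slope against TL.
#'
#' @param mat numeric descriptor matrix, rows aligned with `TLs` (n >= 10).
#' @param TLs fish total lengths, mm.
#' @param alpha significance level for the per-coefficient slope test.
#' @return an `oto_adjustment`: list with `adjusted` (matrix, same shape),
#'   and `report` (data frame: `coefficient`, `slope`, `p_value`,
#'   `adjusted` flag, `constant` flag).
#' @export
adjust_for_length <- function(mat, TLs, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (nrow(mat) != length(TLs)) stop("rows of mat must align with TLs")
  if (nrow(mat) < 10L) stop("need at least 10 specimens for adjustment")
  if (sd(TLs) == 0) stop("TL is constant; slope undefined")
  out <- mat
  p <- ncol(mat)
  slope <- pval <- rep(NA_real_, p)
  applied <- constant <- logical(p)
  for (j in seq_len(p)) {
    y <- mat[, j]
    if (sd(y) == 0) { constant[j] <- TRUE; next }
    fit <- lm(y ~ TLs)
    sm <- summary(fit)$coefficients
    slope[j] <- sm["TLs", "Estimate"]
    pval[j] <- sm["TLs", "Pr(>|t|)"]
    if (pval[j] < alpha) {
      out[, j] <- fit$residuals + mean(y)
      applied[j] <- TRUE
    }
  }
  structure(list(
    adjusted = out,
    report = data.frame(
      coefficient = colnames(mat) %||% paste0("V", seq_len(p)),
      slope = slope, p_value = pval,
      adjusted = applied, constant = constant,
      stringsAsFactors = FALSE)),
    class = "oto_adjustment")
}

#' @export
print.oto_adjustment <- function(x, ...) {
  cat(sprintf("<oto_adjustment> %d coefficients: %d adjusted, %d constant\n",
              nrow(x$report), sum(x$report$adjusted), sum(x$report$constant)))
  invisible(x)
}
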