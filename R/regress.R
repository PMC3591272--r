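#' F-test between nested least-squares regression models
#'
#' Fits the reduced and full models (both with an intercept) by ordinary
#' least squares and tests whether the extra predictors of the full model
#' significantly reduce the residual sum of squares:
#' `F = ((RSS_reduced - RSS_full) / d_extra) / (RSS_full / (n - df_full))`
#' with the p-value from the F distribution on
#' `(d_extra, n - df_full)` degrees of freedom. This is the standard way
#' to ask whether one regulatory region's measurements add explanatory
#' power on top of another's.
#'
#' @param y response vector.
#' @param x_reduced matrix/data.frame of reduced-model predictors (may
#'   have 0 columns for an intercept-only reduced model).
#' @param x_full matrix/data.frame whose columns are a superset of
#'   `x_reduced`'s (matched by name).
#' @return object of class `NestedFitResult`: list with `n`,
#'   `df_reduced`, `df_full` (model degrees of freedom including the
#'   intercept), `rss_reduced`, `rss_full`, `r2_reduced`, `r2_full`, `F`,
#'   `p`. A perfect full-model fit yields `F = Inf`, `p = 0`.
#' @export
nested_regression_ftest <- function(y, x_reduced, x_full) {
  y <- as.numeric(y)
  n <- length(y)
  xr <- as.matrix(x_reduced)
  xf <- as.matrix(x_full)
  if (is.null(colnames(xf))) colnames(xf) <- paste0("x", seq_len(ncol(xf)))
  if (ncol(xr) && is.null(colnames(xr))) {
    # unnamed reduced predictors: match by column identity
    matched <- vapply(seq_len(ncol(xr)), function(j) {
      hit <- which(vapply(seq_len(ncol(xf)), function(i) {
        isTRUE(all.equal(xf[, i], unname(xr[, j])))
      }, TRUE))
      if (!length(hit)) NA_integer_ else hit[1L]
    }, 0L)
    if (anyNA(matched)) {
      stop_format("x_reduced must be a subset of x_full")
    }
    colnames(xr) <- colnames(xf)[matched]
  }
  if (!all(colnames(xr) %in% colnames(xf))) {
    stop_format("x_reduced columns must be a subset of x_full columns")
  }
  df_reduced <- ncol(xr) + 1L
  df_full <- ncol(xf) + 1L
  d_extra <- df_full - df_reduced
  if (d_extra == 0L) stop_format("full model adds no predictors")
  if (n <= df_full) stop_format("need n > df_full observations")
  Xf <- cbind(`(Intercept)` = 1, xf)
  if (qr(Xf)$rank < ncol(Xf)) stop_format("collinear: full design matrix is rank-deficient")
  Xr <- cbind(`(Intercept)` = 1, xr)
  rss <- function(X) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_r <- rss(Xr)
  rss_f <- rss(Xf)
  tss <- sum((y - mean(y))^2)
  Fstat <- ((rss_r - rss_f) / d_extra) / (rss_f / (n - df_full))
  p <- pf(Fstat, d_extra, n - df_full, lower.tail = FALSE)
  structure(
    list(n = n, df_reduced = df_reduced, df_full = df_full,
         rss_reduced = rss_r, rss_full = rss_f,
         r2_reduced = 1 - rss_r / tss, r2_full = 1 - rss_f / tss,
         F = Fstat, p = p),
    class = "NestedFitResult"
  )
}

#' @export
print.NestedFitResult <- function(x, ...) {
  cat(sprintf("<NestedFitResult> n = %d: R2 %.3f -> %.3f, F(%d, %d) = %.4g, p = %.4g\n",
              x$n, x$r2_reduced, x$r2_full, x$df_full - x$df_reduced,
              x$n - x$df_full, x$F, x$p))
  invisible(x)
}

#' Compare expression between convergent and tandem constructs
#'
#' Tests whether the orientation of the downstream neighboring gene
#' (tandem: same strand; convergent: opposing) shifts the expression
#' distribution -- which would implicate the downstream promoter rather
#' than the 3'UTR itself -- and, within each orientation group, whether
#' expression tracks covariates such as the intergenic length or the
#' downstream gene's expression.
#'
#' @param constructs list of [construct()]s with expression and
#'   orientation, or a data.frame with columns `expression`,
#'   `orientation` and any covariate columns.
#' @param covariates character vector of covariate column names
#'   (default `"intergenic_length"`).
#' @return list with `rank_sum` (Wilcoxon rank-sum test), `ecdf`
#'   (Kolmogorov-Smirnov max-ECDF-distance test), and `by_group`
#'   (data.frame: group, covariate, n, rho, p; `rho` is `NA` for a
#'   constant covariate).
#' @export
orientation_group_compare <- function(constructs,
                                      covariates = "intergenic_length") {
  df <- if (is.data.frame(constructs)) constructs else construct_table(constructs)
  stopifnot(all(c("expression", "orientation") %in% names(df)))
  groups <- split(df, df$orientation)
  if (!all(c("tandem", "convergent") %in% names(groups))) {
    stop_format("both orientation groups must be nonempty")
  }
  e1 <- groups$tandem$expression
  e2 <- groups$convergent$expression
  rank_sum <- suppressWarnings(wilcox.test(e1, e2))
  ecdf_test <- suppressWarnings(ks.test(e1, e2))
  rows <- list()
  for (g in names(groups)) {
    for (cv in covariates) {
      if (!cv %in% names(df)) stop_format("covariate '%s' not found", cv)
      x <- groups[[g]][[cv]]
      y <- groups[[g]]$expression
      if (sd(x) == 0 || sd(y) == 0) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(cor.test(y, x, method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, covariate = cv, n = length(y), rho = rho, p = p)
    }
  }
  list(rank_sum = rank_sum, ecdf = ecdf_test,
       by_group = do.call(rbind, rows))
}
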