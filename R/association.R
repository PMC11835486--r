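#' Pearson correlation with least-squares regression summary
#'
#' Correlates a predictor (typically the BPP AUC score) with a response
#' (typically log10 expression) and reports the Pearson r with its
#' two-tailed p-value (t-distributed with n - 2 df) alongside the
#' ordinary-least-squares intercept, slope and slope standard error.
#'
#' @param x,y paired finite numeric vectors, length >= 3, each with
#'   non-zero variance.
#' @return An `association_result`: list with `n`, `r`, `p`, `intercept`,
#'   `slope`, `slope_se`.
#' @export
#' @examples
#' pearson_with_regression(c(0, 1, 2, 3), c(1, 1, 3, 3))
pearson_with_regression <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact collinear input; a zero SE is a valid
  # degenerate summary here, not a user error
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(n = n, r = unname(ct$estimate), p = ct$p.value,
                 intercept = unname(sm[1L, 1L]),
                 slope = unname(sm[2L, 1L]),
                 slope_se = unname(sm[2L, 2L])),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> n=%d  r=%.4f (p=%.3g)  slope=%.4g +/- %.4g\n",
    x$n, x$r, x$p, x$slope, x$slope_se))
  invisible(x)
}

#' Two-tailed p-value of a t statistic
#'
#' @param t t statistic.
#' @param df degrees of freedom.
#' @return Two-tailed p in (0, 1].
#' @export
#' @examples
#' two_tailed_t_pvalue(-2.720971, 84) # 0.00791
two_tailed_t_pvalue <- function(t, df) {
  stopifnot(is.finite(t), df > 0)
  2 * stats::pt(-abs(t), df)
}

#' Compare two regression slopes
#'
#' Tests whether two independently fitted regression slopes differ. The
#' default `"printed"` variant uses the denominator `SE_a + SE_b` — the
#' sum, not the usual quadrature combination — reproducing the statistic
#' as published for this analysis; since
#' `SE_a + SE_b >= sqrt(SE_a^2 + SE_b^2)` it is conservative. The
#' `"quadrature"` variant uses the standard
#' `sqrt(SE_a^2 + SE_b^2)`. Degrees of freedom are
#' `n_a + n_b - 4` (two parameters estimated per regression).
#'
#' @param a,b `association_result` objects from
#'   [pearson_with_regression()].
#' @param variant `"printed"` or `"quadrature"`.
#' @return A `slope_comparison`: list with `t`, `df`, `p`, `variant`.
#' @export
slope_ttest <- function(a, b, variant = c("printed", "quadrature")) {
  stopifnot(inherits(a, "association_result"),
            inherits(b, "association_result"))
  variant <- match.arg(variant)
  den <- switch(variant,
                printed = a$slope_se + b$slope_se,
                quadrature = sqrt(a$slope_se^2 + b$slope_se^2))
  if (den == 0) stop("slope standard errors are both zero", call. = FALSE)
  t <- (a$slope - b$slope) / den
  df <- a$n + b$n - 4L
  structure(list(t = t, df = df, p = two_tailed_t_pvalue(t, df),
                 variant = variant),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> t=%.4f, df=%d, p=%.4g (%s)\n",
              x$t, x$df, x$p, x$variant))
  invisible(x)
}

#' Per-genotype log10-expression regression on AUC scores
#'
#' Joins an expression table with AUC scores on miRNA id, drops
#' non-positive expression values (log10 undefined; ids recorded in the
#' `"excluded"` attribute) and regresses log10 expression on AUC.
#'
#' @param expr data.frame with an `id` column and one numeric expression
#'   column per condition.
#' @param aucs data.frame with columns `id` and `auc` (e.g. from
#'   [hairpin_bpp_auc()]).
#' @param condition name of the expression column to analyse.
#' @return An `association_result` with the excluded ids attached as the
#'   `"excluded"` attribute.
#' @export
expression_auc_regression <- function(expr, aucs, condition) {
  stopifnot(is.data.frame(expr), "id" %in% names(expr),
            condition %in% names(expr),
            all(c("id", "auc") %in% names(aucs)))
  merged <- merge(expr[, c("id", condition)], aucs[, c("id", "auc")],
                  by = "id")
  e <- merged[[condition]]
  if (any(e < 0, na.rm = TRUE)) {
    stop("negative expression values", call. = FALSE)
  }
  ok <- is.finite(e) & e > 0
  res <- pearson_with_regression(merged$auc[ok], log10(e[ok]))
  attr(res, "excluded") <- merged$id[!ok]
  res
}

#' Association of expression fold change with AUC, with outlier removal
#'
#' Computes each miRNA's expression fold change `condition / reference`,
#' removes fold changes above `outlier_cap` (the cap applies to this
#' fold-change analysis only, not to the per-genotype regressions), and
#' correlates the surviving fold changes with the AUC score.
#'
#' @inheritParams expression_auc_regression
#' @param condition,reference names of the two expression columns.
#' @param outlier_cap remove miRNAs with fold change above this value;
#'   `Inf` disables the filter.
#' @return An `association_result`; the analysed per-miRNA table (columns
#'   `id`, `auc`, `fold_change`, `filtered`) is attached as the
#'   `"table"` attribute.
#' @export
fold_change_association <- function(expr, aucs, condition, reference,
                                    outlier_cap = 4) {
  stopifnot(is.data.frame(expr), all(c(condition, reference) %in% names(expr)))
  merged <- merge(expr[, c("id", condition, reference)],
                  aucs[, c("id", "auc")], by = "id")
  if (!nrow(merged)) stop("no overlapping ids", call. = FALSE)
  refv <- merged[[reference]]
  ok <- is.finite(refv) & refv > 0
  merged <- merged[ok, ]
  fc <- merged[[condition]] / merged[[reference]]
  filtered <- fc > outlier_cap
  if (sum(!filtered) < 3L) {
    stop("fewer than 3 miRNAs survive the fold-change filter", call. = FALSE)
  }
  res <- pearson_with_regression(merged$auc[!filtered], fc[!filtered])
  attr(res, "table") <- data.frame(id = merged$id, auc = merged$auc,
                                   fold_change = fc, filtered = filtered)
  res
}
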