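#' Coverage breadth of an alignment
#'
#' Coverage breadth is the proportion of positions for which a base was
#' present in a sample. Returns both per-sample proportions and the
#' per-site count of non-missing samples.
#'
#' @param aln a [haplo_alignment()].
#' @return a list of class `coverage_profile` with `per_sample` (named
#'   proportions in `[0,1]`) and `per_site` (integer counts).
#' @export
coverage_proportion <- function(aln) {
  m <- aln_mat(aln)
  if (ncol(m) == 0L) input_error("zero-length alignment")
  called <- m != "N"
  structure(list(
    per_sample = rowMeans(called),
    per_site = colSums(called)
  ), class = "coverage_profile")
}

#' Default coverage-breadth thresholds
#'
#' Eleven proportions, 5% to 50% in 5% steps plus 65%, the grid used to
#' build nested datasets of increasing minimum coverage.
#' @export
default_thresholds <- function() {
  c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50, 0.65)
}

#' Subset an alignment into coverage-threshold datasets
#'
#' For each threshold, retains exactly the samples whose coverage breadth is
#' greater than or equal to the threshold (inclusive semantics); columns are
#' untouched. Thresholds above every sample's coverage yield an empty
#' dataset, returned as `NULL` with a warning rather than an error.
#'
#' @param aln a [haplo_alignment()].
#' @param thresholds proportions in `[0,1]`; defaults to
#'   [default_thresholds()].
#' @return a named list (names = threshold values) of [haplo_alignment()]s
#'   or `NULL` for empty subsets.
#' @export
threshold_subsets <- function(aln, thresholds = default_thresholds()) {
  if (!length(thresholds)) input_error("threshold list must be non-empty")
  if (any(thresholds < 0) || any(thresholds > 1)) {
    input_error("thresholds must lie in [0, 1]")
  }
  cov <- coverage_proportion(aln)$per_sample
  out <- lapply(thresholds, function(th) {
    keep <- which(cov >= th)
    if (!length(keep)) {
      warning(sprintf("no samples reach coverage threshold %.2f", th))
      return(NULL)
    }
    aln_subset(aln, keep)
  })
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' Window coverage filter (COI-style)
#'
#' Retains samples whose non-missing proportion within a window is at least
#' `min_cov`, and trims the alignment to that window — the rule used to
#' screen partial marker sequences such as the first 653 bp of COI at 65%
#' coverage.
#'
#' @param aln a [haplo_alignment()].
#' @param start 0-based window start.
#' @param length window length in bp.
#' @param min_cov minimum within-window coverage proportion.
#' @return a [haplo_alignment()] trimmed to the window.
#' @export
window_filter <- function(aln, start, length, min_cov) {
  m <- aln_mat(aln)
  if (start < 0 || length < 1 || start + length > ncol(m)) {
    input_error("window out of alignment bounds")
  }
  cols <- (start + 1L):(start + length)
  w <- m[, cols, drop = FALSE]
  keep <- rowMeans(w != "N") >= min_cov
  if (!any(keep)) {
    warning("window filter retained no samples")
    return(NULL)
  }
  haplo_alignment(w[keep, , drop = FALSE])
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression with slope, intercept, coefficient of
#' determination and the two-sided p-value of the slope t-test. Used for
#' coverage-vs-covariate checks (e.g. coverage against a sequencing-effort
#' proxy) and for the admixture-vs-composition summary. A constant response
#' is reported with `r_squared = 0` rather than NaN.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    input_error("need equal-length x and y with at least 3 points")
  }
  if (stats::sd(x) == 0) input_error("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  # exact linear relationships are legitimate inputs here; summary.lm's
  # "essentially perfect fit" warning is noise for this use
  sm <- suppressWarnings(summary(fit))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else sm$r.squared
  pv <- if (sst == 0) 1 else sm$coefficients["x", "Pr(>|t|)"]
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = r2,
    p_value = pv
  ), class = "regression_result")
}

#' Per-threshold manifest and coverage tables
#'
#' @param subsets output of [threshold_subsets()].
#' @return data.frame with columns `threshold`, `n_retained`, `sample_ids`
#'   (semicolon-joined).
#' @export
threshold_manifest <- function(subsets) {
  data.frame(
    threshold = as.numeric(names(subsets)),
    n_retained = vapply(subsets, function(s) if (is.null(s)) 0L else nrow(s),
                        integer(1)),
    sample_ids = vapply(subsets, function(s) {
      if (is.null(s)) "" else paste(rownames(s), collapse = ";")
    }, character(1)),
    row.names = NULL
  )
}
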