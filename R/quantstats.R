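#' EdU labelling fraction
#'
#' Proliferation index: EdU-positive cells over all DAPI-counterstained
#' cells.
#'
#' @param n_positive EdU-positive count, `0 <= n_positive <= n_total`.
#' @param n_total Total cell count, > 0.
#' @return Fraction in \[0, 1\].
#' @examples
#' edu_fraction(10, 40)  # 0.25
#' @export
edu_fraction <- function(n_positive, n_total) {
  check_scalar(n_positive, "n_positive", nonneg = TRUE)
  check_scalar(n_total, "n_total")
  if (n_total <= 0) stop_field("n_total", "must be > 0")
  if (n_positive > n_total)
    stop_field("n_positive", "cannot exceed n_total")
  n_positive / n_total
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample and gene: `dCt = Ct_gene - Ct_ref` (reference gene, default
#' Rpl19); `ddCt = dCt - mean dCt` over the calibrator group (per gene);
#' `fold = 2^-ddCt`.  The calibrator group's fold changes therefore have
#' geometric mean 1 for every gene.
#'
#' @param ct Data.frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (threshold cycles, > 0).
#' @param reference_gene Normalizer gene name present for every sample.
#' @param calibrator_group Group whose mean dCt defines the baseline.
#' @return Data.frame: `sample_id`, `group`, `gene`, `delta_ct`, `ddct`,
#'   `fold_change`, for all non-reference genes.
#' @export
ddct_fold_change <- function(ct, reference_gene = "Rpl19",
                             calibrator_group) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("`ct` must have columns sample_id, group, gene, ct")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be positive and finite")
  if (!calibrator_group %in% ct$group)
    stop(sprintf("calibrator group '%s' not present", calibrator_group))
  ref <- ct[ct$gene == reference_gene, ]
  if (anyDuplicated(ref$sample_id))
    stop("multiple reference-gene Ct values per sample")
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  goi <- ct[ct$gene != reference_gene, , drop = FALSE]
  if (any(!(goi$sample_id %in% names(ref_ct))))
    stop(sprintf("missing reference gene (%s) Ct for some samples",
                 reference_gene))
  goi$delta_ct <- goi$ct - ref_ct[goi$sample_id]
  goi$ddct <- NA_real_
  for (g in unique(goi$gene)) {
    sel <- goi$gene == g
    cal <- goi$delta_ct[sel & goi$group == calibrator_group]
    if (!length(cal))
      stop(sprintf("no calibrator samples for gene '%s'", g))
    goi$ddct[sel] <- goi$delta_ct[sel] - mean(cal)
  }
  goi$fold_change <- 2^(-goi$ddct)
  rownames(goi) <- NULL
  goi[, c("sample_id", "group", "gene", "delta_ct", "ddct", "fold_change")]
}

#' Percent change relative to a reference mean
#'
#' `100 * (mean_ref - mean_test) / mean_ref`: positive values are
#' reductions relative to the reference, matching the "X% decrease"
#' phrasing of group comparisons; negative values are increases.
#'
#' @param mean_ref Reference (e.g. control) mean, non-zero.
#' @param mean_test Test (e.g. treated) mean.
#' @return Percent change (positive = reduction).
#' @examples
#' percent_change(323.2, 242.6)  # ~25% volume decrease
#' @export
percent_change <- function(mean_ref, mean_test) {
  check_scalar(mean_ref, "mean_ref")
  check_scalar(mean_test, "mean_test")
  if (mean_ref == 0) stop_field("mean_ref", "must be non-zero")
  100 * (mean_ref - mean_test) / mean_ref
}

#' Group summary (mean and SEM)
#'
#' Mean and standard error of the mean (`sd / sqrt(n)`, sample sd).  With
#' a single observation the SEM is undefined and reported as `NA`, never
#' as 0.
#'
#' @param values Numeric vector, n >= 1.
#' @param label Group label.
#' @return A one-row data.frame: `label`, `n`, `mean`, `sem`.
#' @export
summarize_group <- function(values, label = "group") {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  n <- length(values)
  data.frame(label = label, n = n, mean = mean(values),
             sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
             stringsAsFactors = FALSE)
}

#' One- and two-sample two-tailed t-tests with effect report
#'
#' Two-sample (default Student's pooled-variance, Welch by `variant`) for
#' group comparisons, one-sample against `mu0` for normalized ratios.
#' Degenerate inputs in which both groups are constant with equal means
#' (where the t statistic is 0/0) are reported as `t = 0, p = 1`.
#'
#' @param x Numeric vector (first/reference group), n >= 2.
#' @param y Optional second group (two-sample test), n >= 2.
#' @param mu0 Null value for the one-sample test (required when `y` is
#'   missing).
#' @param variant `"student"` (pooled variance) or `"welch"`; two-sample
#'   only.
#' @return An object of class `effect_report`: `percent_change`
#'   (reference = `x` mean for two-sample, `mu0` for one-sample), `t`,
#'   `df`, `p`, `test`, `variant`.
#' @examples
#' t_test_report(c(0.5, 0.6, 0.4, 0.5), mu0 = 1)
#' @export
t_test_report <- function(x, y = NULL, mu0 = NULL,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need n >= 2 in each group")
  if (is.null(y)) {
    if (is.null(mu0)) stop("one-sample test needs `mu0`")
    if (stats::sd(x) == 0) {
      t <- if (mean(x) == mu0) 0 else sign(mean(x) - mu0) * Inf
      p <- if (mean(x) == mu0) 1 else 0
      res <- list(statistic = t, parameter = length(x) - 1, p.value = p)
    } else {
      ht <- stats::t.test(x, mu = mu0, alternative = "two.sided")
      res <- list(statistic = unname(ht$statistic),
                  parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    pc <- percent_change(mu0, mean(x))
    test <- "one_sample"
  } else {
    y <- as.numeric(y)
    if (length(y) < 2) stop("need n >= 2 in each group")
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      res <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                  p.value = 1)
    } else {
      ht <- stats::t.test(x, y, var.equal = (variant == "student"),
                          alternative = "two.sided")
      res <- list(statistic = unname(ht$statistic),
                  parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    pc <- percent_change(mean(x), mean(y))
    test <- "two_sample"
  }
  structure(list(percent_change = pc, t = res$statistic,
                 df = res$parameter, p = res$p.value,
                 test = test, variant = if (test == "two_sample") variant
                                        else NA_character_),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("%s t-test%s: t = %.4g, df = %.4g, p = %.4g; percent change %.2f%%\n",
              gsub("_", "-", x$test),
              if (!is.na(x$variant)) sprintf(" (%s)", x$variant) else "",
              x$t, x$df, x$p, x$percent_change))
  invisible(x)
}
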