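#' 2x2 confusion matrix for remyelination detection
#'
#' The positive class is remyelination throughout: \code{tp} = remyelinated
#' on both MRI and histology, \code{fn} = missed remyelination, \code{fp} =
#' MRI-remyelinated but demyelinated on histology, \code{tn} = concordant
#' demyelinated.
#'
#' @param tp,fn,fp,tn nonnegative counts.
#' @return object of class \code{confusion_matrix_2x2}.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion matrix counts must be nonnegative")
  structure(as.list(counts), total = sum(counts), class = "confusion_matrix_2x2")
}

#' @export
print.confusion_matrix_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(histology = c("demyelinated", "remyelinated"),
                              MRI = c("demyelinated", "remyelinated")))
  print(m)
  invisible(x)
}

#' Collapse 3-class MRI/histology labels to the remyelination confusion matrix
#'
#' Early active and chronic demyelinated collapse to "demyelinated"; rows
#' without a histology label are excluded (with a message giving the count).
#'
#' @param table data.frame with columns \code{mri_category} and
#'   \code{histo_category} (values in the three-level class set; NA histology
#'   allowed and excluded).
#' @return a [confusion_matrix()]; attribute \code{excluded} holds the number
#'   of rows dropped for missing histology.
#' @export
binarize_and_tabulate <- function(table) {
  stopifnot(all(c("mri_category", "histo_category") %in% names(table)))
  miss <- is.na(table$histo_category)
  if (any(miss))
    message(sum(miss), " lesion(s) excluded for missing histology")
  tb <- table[!miss, , drop = FALSE]
  mri_pos <- tb$mri_category == "remyelinated"
  his_pos <- tb$histo_category == "remyelinated"
  cm <- confusion_matrix(tp = sum(mri_pos & his_pos),
                         fn = sum(!mri_pos & his_pos),
                         fp = sum(mri_pos & !his_pos),
                         tn = sum(!mri_pos & !his_pos))
  attr(cm, "excluded") <- sum(miss)
  cm
}

#' Sensitivity and specificity of remyelination detection
#'
#' @param cm a [confusion_matrix()].
#' @return list(sensitivity, specificity) with sensitivity = tp/(tp+fn) and
#'   specificity = tn/(tn+fp).
#' @export
sensitivity_specificity <- function(cm) {
  if (cm$tp + cm$fn == 0) stop("sensitivity undefined: no positive (remyelinated) cases")
  if (cm$tn + cm$fp == 0) stop("specificity undefined: no negative (demyelinated) cases")
  list(sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp))
}

#' Concordance summary with the specificity/accuracy distinction flagged
#'
#' Reports sensitivity, specificity and overall accuracy from the confusion
#' matrix. A published specificity can be supplied for comparison; when the
#' table-derived specificity differs from it by more than half a percentage
#' point the summary carries a discrepancy note (overall accuracy is the
#' usual source of such differences).
#'
#' @param cm a [confusion_matrix()].
#' @param published_specificity_pct optional published value, percent.
#' @return list: sensitivity_pct, specificity_pct, accuracy_pct, n, and
#'   optionally published_specificity_pct + discrepancy (logical) + note.
#' @export
concordance_summary <- function(cm, published_specificity_pct = NULL) {
  ss <- sensitivity_specificity(cm)
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  out <- list(sensitivity_pct = 100 * ss$sensitivity,
              specificity_pct = 100 * ss$specificity,
              accuracy_pct = 100 * (cm$tp + cm$tn) / n,
              n = n)
  if (!is.null(published_specificity_pct)) {
    out$published_specificity_pct <- published_specificity_pct
    out$discrepancy <- abs(out$specificity_pct - published_specificity_pct) > 0.5
    if (out$discrepancy)
      out$note <- sprintf(paste0("table-derived specificity %.1f%% differs from ",
                                 "the published %.1f%%; overall accuracy is %.1f%%"),
                          out$specificity_pct, published_specificity_pct,
                          out$accuracy_pct)
  }
  out
}

#' Cohen's kappa for two raters' categorical labels
#'
#' kappa = (p_o - p_e) / (1 - p_e), with p_o the observed agreement and p_e
#' the chance agreement from the product of marginals. When both are 1
#' (single shared category), kappa = 1 by convention.
#'
#' @param labels_a,labels_b equal-length vectors of categorical labels.
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 rated items")
  levs <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = levs)
  b <- factor(labels_b, levels = levs)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - p_e) < 1e-12) return(if (p_o >= 1 - 1e-12) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Point-biserial correlation with t-based p-value
#'
#' Pearson correlation between a 0/1-coded binary variable and an outcome
#' (continuous or binary-coded), with the two-sided p-value from the t
#' transform on n-2 degrees of freedom.
#'
#' @param binary vector coercible to 0/1 (logical or numeric).
#' @param outcome numeric vector of the same length.
#' @return list(r, p, n).
#' @export
point_biserial <- function(binary, outcome) {
  x <- as.numeric(binary)
  y <- as.numeric(outcome)
  if (length(x) != length(y)) stop("inputs differ in length")
  if (!all(x %in% c(0, 1))) stop("binary variable must be 0/1 coded")
  if (sum(x == 0) == 0 || sum(x == 1) == 0) stop("both groups must be nonempty")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Exact permutation p-value for a binary-binary point-biserial correlation
#'
#' For two binary variables the permutation distribution of |r| depends only
#' on the number of successes falling in group 1, which is hypergeometric
#' under exchangeability; the two-sided p-value is the exact tail sum over
#' tables with |r| >= |r_observed|. Serves as an independent oracle for the
#' t-approximation in [point_biserial()].
#'
#' @param binary 0/1 group indicator.
#' @param outcome 0/1 outcome.
#' @return exact two-sided permutation p-value.
#' @export
point_biserial_exact_p <- function(binary, outcome) {
  x <- as.numeric(binary); y <- as.numeric(outcome)
  stopifnot(length(x) == length(y), all(x %in% c(0, 1)), all(y %in% c(0, 1)))
  n <- length(x); n1 <- sum(x); s <- sum(y)
  r_of_k <- function(k) {  # r when k successes land in group 1
    yy <- c(rep(1, k), rep(0, n1 - k), rep(1, s - k), rep(0, n - n1 - s + k))
    xx <- c(rep(1, n1), rep(0, n - n1))
    if (stats::sd(yy) == 0) return(0)
    stats::cor(xx, yy)
  }
  ks <- max(0, s - (n - n1)):min(n1, s)
  robs <- r_of_k(sum(y[x == 1]))
  pr <- stats::dhyper(ks, s, n - s, n1)
  sum(pr[vapply(ks, function(k) abs(r_of_k(k)) >= abs(robs) - 1e-12, logical(1))])
}

#' Pearson correlation between lesion age and OPC count
#'
#' @param table data.frame with columns \code{lesion_age_weeks} and
#'   \code{opc_count}; rows with NA in either are dropped.
#' @return list(r, p, n).
#' @export
correlate_age_opc <- function(table) {
  stopifnot(all(c("lesion_age_weeks", "opc_count") %in% names(table)))
  ok <- stats::complete.cases(table[, c("lesion_age_weeks", "opc_count")])
  tb <- table[ok, , drop = FALSE]
  if (nrow(tb) < 3) stop("need at least 3 lesions with age and OPC count")
  ct <- stats::cor.test(tb$lesion_age_weeks, tb$opc_count)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(tb))
}

#' Two-sample t-test or one-way ANOVA across groups
#'
#' \code{t_test} uses Welch's unequal-variance test by default (set
#' \code{var_equal = TRUE} for the pooled-variance version); \code{anova} is
#' the classic one-way fixed-effects ANOVA.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param test "t_test" (exactly 2 groups) or "anova" (>= 2 groups).
#' @param var_equal pooled variance for the t-test / classic ANOVA.
#' @return list(statistic, p, test).
#' @export
group_compare <- function(values_by_group, test = c("t_test", "anova"),
                          var_equal = FALSE) {
  test <- match.arg(test)
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (any(vapply(values_by_group, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  if (test == "t_test") {
    if (length(values_by_group) != 2) stop("t_test requires exactly 2 groups")
    ht <- stats::t.test(values_by_group[[1]], values_by_group[[2]],
                        var.equal = var_equal)
    return(list(statistic = unname(ht$statistic), p = ht$p.value, test = "t_test"))
  }
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_group),
                  vapply(values_by_group, length, integer(1))))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value, test = "anova")
}
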