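# Per-patient ROC analysis of Z-maps against ground-truth lesion masks and
# the Friedman / Wilcoxon / Holm inter-method comparison of AUCs.

#' ROC curve of a Z-map against a lesion mask
#'
#' Sweeps cutoffs over the observed Z range; a voxel is called positive when
#' its Z lies beyond the cutoff in the abnormal direction (`low_abnormal`
#' for quantities that fall in lesions, `high_abnormal` for quantities that
#' rise, `abs` for a two-sided |Z| sweep).  TPR is the fraction of lesion
#' voxels called positive, FPR the fraction of non-lesion analysis voxels
#' called positive; AUC by trapezoidal integration.
#'
#' @param z Z array.
#' @param lesion_mask logical array, subset of `analysis_mask`, non-empty.
#' @param analysis_mask logical array of voxels entering the sweep.
#' @param direction `"low_abnormal"`, `"high_abnormal"` or `"abs"`.
#' @param max_thresholds use all unique Z values up to this count, else
#'   quantile-spaced cutoffs.
#' @param subject_id,modality labels carried into the result.
#' @return list of class `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `direction`, `subject_id`, `modality`, `n_lesion`, `n_background`.
#' @export
roc_curve <- function(z, lesion_mask, analysis_mask,
                      direction = c("low_abnormal", "high_abnormal", "abs"),
                      max_thresholds = 512, subject_id = "subj",
                      modality = "") {
  direction <- match.arg(direction)
  if (!any(lesion_mask)) stop("empty lesion mask: ROC undefined")
  if (any(lesion_mask & !analysis_mask))
    stop("lesion mask must be a subset of the analysis mask")
  zv <- z[analysis_mask]
  lab <- lesion_mask[analysis_mask]
  ok <- is.finite(zv)
  zv <- zv[ok]; lab <- lab[ok]
  if (!any(lab) || all(lab)) stop("need both lesion and non-lesion voxels")
  score <- switch(direction, low_abnormal = -zv, high_abnormal = zv,
                  abs = abs(zv))               # larger score = more abnormal
  u <- sort(unique(score))
  thr <- if (length(u) <= max_thresholds) u else
    unique(quantile(score, probs = seq(0, 1, length.out = max_thresholds),
                    names = FALSE, type = 1))
  np <- sum(lab); nn <- sum(!lab)
  ord <- order(score, decreasing = TRUE)
  cs_p <- cumsum(lab[ord]); cs_n <- cumsum(!lab[ord])
  ss <- score[ord]
  # positives at cutoff t: score >= t; use right-open boundaries on the
  # sorted scores to evaluate every threshold in one pass
  pos_at <- function(t) {
    k <- findInterval(-t, -ss)    # number of scores >= t
    if (k == 0) c(0, 0) else c(cs_p[k], cs_n[k])
  }
  counts <- vapply(sort(thr, decreasing = TRUE), pos_at, numeric(2))
  tpr <- c(0, counts[1, ] / np, 1)
  fpr <- c(0, counts[2, ] / nn, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, sort(thr, decreasing = TRUE), -Inf),
                 fpr = fpr, tpr = tpr, auc = auc, direction = direction,
                 subject_id = subject_id, modality = modality,
                 n_lesion = np, n_background = nn), class = "roc_result")
}

#' Vertically averaged ROC curve at fixed FPR values
#'
#' Linearly interpolates each subject's TPR at the grid FPRs and averages
#' across subjects.
#'
#' @param rocs list of `roc_result`s.
#' @param fpr_grid FPR evaluation points in [0, 1].
#' @return data.frame `fpr`, `tpr` (mean), `n`.
#' @export
average_roc_at_fixed_fpr <- function(rocs, fpr_grid = seq(0, 1, by = 0.02)) {
  stopifnot(length(rocs) >= 1)
  tprs <- vapply(rocs, function(r)
    stats::approx(r$fpr, r$tpr, xout = fpr_grid, ties = max,
                  yleft = 0, yright = 1)$y, numeric(length(fpr_grid)))
  tprs <- matrix(tprs, nrow = length(fpr_grid))
  data.frame(fpr = fpr_grid, tpr = rowMeans(tprs), n = length(rocs))
}

#' Friedman rank test across methods
#'
#' Ranks the `k` methods within each subject (average ranks on ties) and
#' computes `chi2 = 12 n / (k (k+1)) * sum_j (Rbar_j - (k+1)/2)^2` with
#' `k - 1` degrees of freedom.
#'
#' @param auc_matrix numeric matrix, subjects x methods, no missing cells.
#' @return list `chi2`, `df`, `p`, `mean_ranks`.
#' @export
friedman_test <- function(auc_matrix) {
  X <- as.matrix(auc_matrix)
  k <- ncol(X); n <- nrow(X)
  if (k < 3) stop("need at least 3 methods; use wilcoxon_signed_rank for 2")
  if (anyNA(X)) stop("missing cells in the AUC matrix")
  R <- t(apply(X, 1, rank))
  rbar <- colMeans(R)
  chi2 <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  list(chi2 = chi2, df = k - 1, p = pchisq(chi2, k - 1, lower.tail = FALSE),
       mean_ranks = rbar)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Drops zero differences, ranks |differences| (average ranks on ties) and
#' sums the ranks of positive differences (`W`).  The two-sided p-value is
#' exact (signed-rank null distribution) for n <= 25 without ties, else a
#' normal approximation with tie correction.
#'
#' @param x,y paired numeric vectors.
#' @return list `W`, `n` (non-zero pairs), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, n = 0L, p = 1, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # exact: P(W+ <= w) from the signed-rank distribution
    p_low <- psignrank(W, n)
    p_high <- psignrank(n * (n + 1) / 2 - W, n)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r[duplicated(abs(d)) | duplicated(abs(d), fromLast = TRUE)])
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    if (ties) {
      tt <- table(abs(d))
      sig2 <- sig2 - sum(tt^3 - tt) / 48
    }
    zstat <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(zstat))
    method <- "normal"
  }
  list(W = W, n = as.integer(n), p = min(1, p), method = method)
}

#' Bonferroni-Holm step-down correction
#'
#' @param p_raw vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_correct <- function(p_raw) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  m <- length(p_raw)
  o <- order(p_raw)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p_raw[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare lesion-detection AUCs across methods
#'
#' Friedman omnibus over the complete AUC matrix, all pairwise Wilcoxon
#' signed-rank tests Holm-corrected across the pairs, and per-method
#' summary statistics (mean, SD, min, max).  Subjects with any missing
#' modality are excluded (with a message), mirroring complete-case
#' inter-method comparisons.
#'
#' @param auc_matrix subjects x methods matrix (column names = methods).
#' @return list of class `auc_comparison`: `auc`, `friedman`, `pairwise`
#'   (data.frame), `summary` (data.frame), `n_subjects`, `excluded`.
#' @export
compare_methods <- function(auc_matrix) {
  X <- as.matrix(auc_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("method", seq_len(ncol(X)))
  complete <- complete.cases(X)
  if (any(!complete))
    message(sum(!complete), " subject(s) excluded for missing modalities")
  X <- X[complete, , drop = FALSE]
  fr <- friedman_test(X)
  k <- ncol(X)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(method_a = colnames(X)[pairs[1, ]],
                   method_b = colnames(X)[pairs[2, ]],
                   W = NA_real_, p_raw = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    wt <- wilcoxon_signed_rank(X[, pairs[1, j]], X[, pairs[2, j]])
    pw$W[j] <- wt$W; pw$p_raw[j] <- wt$p
  }
  pw$p_holm <- holm_correct(pw$p_raw)
  summary <- data.frame(method = colnames(X),
                        mean_auc = colMeans(X),
                        sd_auc = apply(X, 2, sd),
                        min_auc = apply(X, 2, min),
                        max_auc = apply(X, 2, max),
                        mean_rank = fr$mean_ranks,
                        row.names = NULL)
  structure(list(auc = X, friedman = fr, pairwise = pw, summary = summary,
                 n_subjects = nrow(X), excluded = sum(!complete)),
            class = "auc_comparison")
}
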