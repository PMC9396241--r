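#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney concordance probability — the
#' probability that a random positive outranks a random negative, ties
#' counted one half — which equals the area under the empirical ROC curve.
#' ROC points are produced at every distinct threshold.
#'
#' @param probs Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return List of class `roc_result` with `auc` and a tibble
#'   `roc_points` `(threshold, fpr, tpr, sensitivity, specificity)`,
#'   ordered from the strictest threshold (0, 0) to the laxest (1, 1).
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.logical(labels)
  if (length(probs) != length(labels) || any(is.na(probs)) || any(is.na(labels))) {
    stop_contract("`probs` and `labels` must be aligned and NA-free")
  }
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) {
    stop_contract("both classes must be present to compute a ROC curve")
  }
  r <- rank(probs)  # midranks handle ties at 1/2
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)

  thr <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probs >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(probs >= t & !labels) / nn, numeric(1))
  pts <- tibble::tibble(
    threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr)
  )
  pts$sensitivity <- pts$tpr
  pts$specificity <- 1 - pts$fpr
  structure(list(auc = auc, roc_points = pts, n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d positives / %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$roc_points)))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' @param auc Point AUC.
#' @param n_pos,n_neg Class sizes.
#' @return Approximate standard error.
#' @export
auc_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Percentile bootstrap confidence interval for an AUC
#'
#' Case resampling: eyes are resampled with replacement, the AUC is
#' recomputed on each resample and the 2.5/97.5 percentiles form the 95%
#' interval. Resamples containing a single class are redrawn.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_auc_ci <- function(probs, labels, n_boot = 1000, seed = 1,
                             conf = 0.95) {
  labels <- as.logical(labels)
  n <- length(probs)
  aucs <- numeric(n_boot)
  with_eye_rng(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (any(labels[idx]) && any(!labels[idx])) break
      }
      r <- rank(probs[idx])
      np <- sum(labels[idx]); nn <- n - np
      aucs[b] <- (sum(r[labels[idx]]) - np * (np + 1) / 2) / (np * nn)
    }
  })
  q <- quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Operating points on a ROC curve
#'
#' `youden` maximizes sensitivity + specificity - 1 (ties resolved toward
#' the higher specificity, the conservative choice for interval
#' prediction); `spec80` reports the sensitivity at the smallest
#' specificity of at least 80%.
#'
#' @param roc A `roc_result` or its `roc_points` tibble.
#' @return Tibble `(point, threshold, sensitivity, specificity)`.
#' @export
operating_points <- function(roc) {
  pts <- if (inherits(roc, "roc_result")) roc$roc_points else roc
  if (nrow(pts) == 0) stop_contract("empty ROC")
  j <- pts$sensitivity + pts$specificity - 1
  cand <- which(j == max(j))
  yi <- cand[which.max(pts$specificity[cand])]
  ok <- which(pts$specificity >= 0.80)
  tie <- ok[pts$specificity[ok] == min(pts$specificity[ok])]
  si <- tie[which.max(pts$sensitivity[tie])]
  out <- dplyr::bind_rows(
    tibble::tibble(point = "youden", threshold = pts$threshold[yi],
                   sensitivity = pts$sensitivity[yi],
                   specificity = pts$specificity[yi]),
    if (length(si) == 1 && !is.na(si)) {
      tibble::tibble(point = "spec80", threshold = pts$threshold[si],
                     sensitivity = pts$sensitivity[si],
                     specificity = pts$specificity[si])
    }
  )
  out
}
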