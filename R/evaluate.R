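# Agreement and discrimination metrics: Jaccard coefficient between the
# classifier's and the clinicians' positive-decision sets, ROC/AUC, and
# confusion counts.

#' Jaccard agreement between two positive-decision sets
#'
#' `J(A, M) = |A intersect M| / |A union M|` over patient identifier
#' sets, typically the patients the classifier calls positive versus
#' those the clinicians call positive. When both sets are empty the
#' coefficient is defined as 1 (total agreement on an all-negative
#' cohort) and a message is logged.
#'
#' @param ann_positive,md_positive Vectors of patient identifiers
#'   (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard_agreement(c("p1", "p2", "p3"), c("p2", "p3", "p4"))  # 0.5
jaccard_agreement <- function(ann_positive, md_positive) {
  a <- unique(ann_positive); m <- unique(md_positive)
  u <- union(a, m)
  if (length(u) == 0L) {
    message("both decision sets empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(a, m)) / length(u)
}

#' Per-patient agreement rate
#'
#' Companion to [jaccard_agreement()]: the fraction of patients on whom
#' two 0/1 decision vectors agree. Not the default agreement measure.
#'
#' @param ann,md Aligned 0/1 decision vectors.
#' @return Fraction in `[0, 1]`.
#' @export
decision_agreement <- function(ann, md) {
  if (length(ann) != length(md)) stop("decision vectors must align")
  mean(ann == md)
}

#' ROC curve and AUC
#'
#' The ROC is traced over all score thresholds; the AUC is computed from
#' midranks (the Mann-Whitney statistic, ties handled by midrank), which
#' agrees with trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels must align")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present for ROC/AUC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s)                 # one ROC point per distinct threshold
  tp <- cumsum(l); fp <- cumsum(1L - l)
  idx <- c(which(keep)[-1] - 1L, length(s))
  roc <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fp[idx] / n0),
                    tpr = c(0, tp[idx] / n1))
  list(roc = roc, auc = auc)
}

#' Evaluation report for a classifier run
#'
#' Bundles the Jaccard agreement between predicted-positive and
#' reference-positive patient sets, the ROC/AUC of the scores, and the
#' confusion counts at the decision threshold.
#'
#' @param scores Predicted probabilities.
#' @param labels Reference 0/1 labels (the clinicians' final diagnoses).
#' @param patients Patient identifiers aligned with `scores`.
#' @param threshold Decision threshold; default 0.5.
#' @return Object of class `evaluation_report`.
#' @export
evaluation_report <- function(scores, labels, patients = seq_along(scores),
                              threshold = 0.5) {
  labels <- as.integer(labels)
  decisions <- as.integer(scores >= threshold)
  ra <- roc_auc(scores, labels)
  structure(list(
    jaccard = jaccard_agreement(patients[decisions == 1L],
                                patients[labels == 1L]),
    auc = ra$auc, roc_points = ra$roc,
    confusion = c(TP = sum(decisions == 1L & labels == 1L),
                  FP = sum(decisions == 1L & labels == 0L),
                  TN = sum(decisions == 0L & labels == 0L),
                  FN = sum(decisions == 0L & labels == 1L)),
    threshold = threshold, n = length(labels)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d patients: AUC %.3f, Jaccard %.3f\n",
              x$n, x$auc, x$jaccard))
  cat(sprintf("  confusion TP %d FP %d TN %d FN %d (threshold %.2f)\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"], x$threshold))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' A flat JSON file with the scalar metrics and confusion counts, plus a
#' CSV of ROC points alongside (same stem, `_roc.csv` suffix) when
#' `roc_csv` is `TRUE`.
#'
#' @param report An [evaluation_report()].
#' @param path JSON output path.
#' @param roc_csv Also write the ROC points.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, roc_csv = TRUE) {
  out <- list(n = report$n, auc = report$auc, jaccard = report$jaccard,
              threshold = report$threshold,
              TP = unname(report$confusion["TP"]),
              FP = unname(report$confusion["FP"]),
              TN = unname(report$confusion["TN"]),
              FN = unname(report$confusion["FN"]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (roc_csv) {
    utils::write.csv(report$roc_points,
                     sub("\\.json$", "_roc.csv", path), row.names = FALSE)
  }
  invisible(path)
}
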