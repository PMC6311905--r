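#' @title Classification metrics
#' @name evaluation
#' @description
#' Confusion-matrix summary statistics for hot-spot prediction: accuracy,
#' specificity, recall (sensitivity), precision, F1 and the Matthews
#' correlation coefficient, plus threshold-free ROC/AUC. The positive class
#' is `"hot"` throughout.
NULL

#' Tabulate a confusion matrix
#'
#' @param predicted,actual vectors (character or factor) of `"hot"` /
#'   `"nonhot"` labels, same length.
#' @param positive the positive-class label, default `"hot"`.
#' @return object of class `confusion_matrix`: list with integer counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, actual, positive = "hot") {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (length(predicted) == 0L) stop("empty prediction vector")
  structure(list(tp = sum(predicted == positive & actual == positive),
                 fp = sum(predicted == positive & actual != positive),
                 tn = sum(predicted != positive & actual != positive),
                 fn = sum(predicted != positive & actual == positive)),
            class = "confusion_matrix")
}

#' Metrics from a confusion matrix
#'
#' Computes ACC = (TP+TN)/total, SPE = TN/(TN+FP), RECALL (= SEN) =
#' TP/(TP+FN), PRE = TP/(TP+FP), F1 = 2*PRE*RECALL/(PRE+RECALL) and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' Any metric with a zero denominator is reported as 0 and its name is
#' recorded in the `undefined` field, so ranking over degenerate base
#' classifiers never fails.
#'
#' @param cm a [confusion_matrix], or a list with fields `tp`,`fp`,`tn`,`fn`.
#' @return object of class `metrics_report`: list with fields `acc`, `spe`,
#'   `recall`, `pre`, `f1`, `mcc` and `undefined` (character vector).
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0L) stop("empty confusion matrix")
  undef <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { undef <<- c(undef, what); 0 } else num / den
  }
  acc <- (tp + tn) / total
  spe <- safe(tn, tn + fp, "spe")
  recall <- safe(tp, tp + fn, "recall")
  pre <- safe(tp, tp + fp, "pre")
  f1 <- if (pre + recall == 0) { undef <- c(undef, "f1"); 0 }
        else 2 * pre * recall / (pre + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { undef <- c(undef, "mcc"); 0 }
         else (tp * tn - fp * fn) / mcc_den
  structure(list(acc = acc, spe = spe, recall = recall, pre = pre,
                 f1 = f1, mcc = mcc, undefined = undef),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  SPE %.4f  RECALL %.4f  PRE %.4f  F1 %.4f  MCC %.4f\n",
              x$acc, x$spe, x$recall, x$pre, x$f1, x$mcc))
  if (length(x$undefined))
    cat("undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Convenience: metrics from label vectors
#' @inheritParams confusion_matrix
#' @return a `metrics_report`.
#' @export
metrics_from_predictions <- function(predicted, actual, positive = "hot") {
  compute_metrics(confusion_matrix(predicted, actual, positive))
}

#' ROC curve and AUC
#'
#' AUC is computed in the tie-corrected Mann-Whitney rank form
#' (mid-ranks; equivalent to counting score pairs with ties at 1/2), and
#' the ROC curve is traced over every distinct score threshold.
#'
#' @param scores numeric scores, larger meaning more hot-like.
#' @param labels `"hot"`/`"nonhot"` labels aligned with `scores`.
#' @param positive positive-class label.
#' @return list with `auc` and `roc` (data.frame `fpr`, `tpr`, from (0,0)
#'   to (1,1)).
#' @export
roc_auc <- function(scores, labels, positive = "hot") {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores)) stop("non-finite scores")
  pos <- labels == positive
  p <- sum(pos); n <- sum(!pos)
  if (p == 0L || n == 0L)
    stop("roc_auc needs at least one positive and one negative")
  r <- rank(scores)               # mid-ranks handle ties
  auc <- (sum(r[pos]) - p * (p + 1) / 2) / (p * n)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / p, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n, numeric(1))
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

#' Write a metrics table as TSV
#'
#' One row per dataset with the column layout `dataset ACC SPE RECALL PRE
#' F1 MCC [AUC]`.
#'
#' @param metrics a named list of `metrics_report` objects (names become the
#'   `dataset` column), or a single report.
#' @param path output path.
#' @param auc optional named numeric vector of AUC values aligned with
#'   `metrics`.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path, auc = NULL) {
  if (inherits(metrics, "metrics_report")) metrics <- list(dataset = metrics)
  df <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(dataset = nm, ACC = m$acc, SPE = m$spe, RECALL = m$recall,
               PRE = m$pre, F1 = m$f1, MCC = m$mcc)
  }))
  if (!is.null(auc)) df$AUC <- as.numeric(auc[df$dataset])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Permutation-null F1 distribution
#'
#' The F1 scores obtained when predictions carry no information: the label
#' vector is permuted uniformly at random and scored against itself
#' unpermuted, once per replicate. Used to check that pipelines trained on
#' signal-free data do not beat chance.
#'
#' @param labels `"hot"`/`"nonhot"` vector.
#' @param n_perm number of permutation replicates.
#' @param seed RNG seed.
#' @return numeric vector of `n_perm` F1 values.
#' @export
permutation_null_f1 <- function(labels, n_perm = 20L, seed = 1L) {
  labels <- as.character(labels)
  with_seed(seed, vapply(seq_len(n_perm), function(i)
    metrics_from_predictions(sample(labels), labels)$f1, numeric(1)))
}

# Evaluate thunk with a private RNG stream, restoring global state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
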