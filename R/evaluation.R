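# Performance measures: overall accuracy, per-class sensitivity,
# specificity, positive predictive value and Matthews correlation
# coefficient, with mean(SD) aggregation over cross-validation folds.

#' One-vs-rest confusion counts
#'
#' @param true_labels,predicted_labels equal-length character vectors whose
#'   values are all in `classes`.
#' @param classes class universe (fixed order).
#' @return Object of class `confusion_counts`: data.frame with one row per
#'   class and columns TP, FP, TN, FN; attribute `n` is the number of
#'   evaluated instances.
#' @export
confusion_counts <- function(true_labels, predicted_labels,
                             classes = COMPARTMENTS) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors have different lengths")
  }
  bad <- setdiff(c(true_labels, predicted_labels), classes)
  if (length(bad)) stop("label(s) not in classes: ", paste(bad, collapse = ", "))
  n <- length(true_labels)
  out <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    tn <- n - tp - fp - fn
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               stringsAsFactors = FALSE)
  }))
  structure(out, n = n, class = c("confusion_counts", "data.frame"))
}

#' Per-class SN, SP, PPV and MCC
#'
#' Sensitivity SN = TP/(TP+FN) x 100, specificity SP = TN/(TN+FP) x 100,
#' positive predictive value PPV = TP/(TP+FP) x 100, and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric whose denominator is zero is reported as 0 and flagged in the
#' logical `undefined` column — a class that is never predicted prints as 0,
#' not as an error.
#'
#' @param counts a `confusion_counts` object.
#' @return data.frame with columns class, SN, SP, PPV, MCC, undefined.
#' @export
class_metrics <- function(counts) {
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  with(counts, {
    sn <- safe_div(TP, TP + FN) * 100
    sp <- safe_div(TN, TN + FP) * 100
    ppv <- safe_div(TP, TP + FP) * 100
    denom2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    mcc <- ifelse(denom2 == 0, 0,
                  (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2))
    undefined <- (TP + FN) == 0 | (TN + FP) == 0 | (TP + FP) == 0 |
      denom2 == 0
    data.frame(class = class, SN = sn, SP = sp, PPV = ppv, MCC = mcc,
               undefined = undefined, stringsAsFactors = FALSE)
  })
}

#' Overall accuracy
#'
#' Fraction of correctly assigned instances over all classes,
#' sum(TP_i) / sum(TP_i + FN_i) x 100 — micro-averaged recall.
#'
#' @param counts a `confusion_counts` object.
#' @return Percent in \[0, 100\].
#' @export
overall_accuracy <- function(counts) {
  total <- sum(counts$TP + counts$FN)
  if (total == 0) stop("empty evaluation set")
  sum(counts$TP) / total * 100
}

#' Aggregate per-fold metric reports as mean(SD)
#'
#' @param per_fold list of data.frames as returned by [class_metrics()],
#'   one per fold, identical class column; each may carry an `acc`
#'   attribute with the fold's overall accuracy.
#' @return List with `per_class` (class, metric, mean, sd) and, when fold
#'   accuracies are present, `acc_mean` / `acc_sd`.  Sample SD (n - 1
#'   denominator); a single fold reports SD 0.
#' @export
aggregate_folds <- function(per_fold) {
  stopifnot(length(per_fold) >= 1L)
  metrics <- c("SN", "SP", "PPV", "MCC")
  classes <- per_fold[[1]]$class
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  per_class <- do.call(rbind, lapply(metrics, function(m) {
    vals <- sapply(per_fold, function(df) df[[m]])  # classes x folds
    vals <- matrix(vals, nrow = length(classes))
    data.frame(class = classes, metric = m,
               mean = rowMeans(vals), sd = apply(vals, 1, sd0),
               stringsAsFactors = FALSE)
  }))
  out <- list(per_class = per_class)
  accs <- unlist(lapply(per_fold, attr, "acc"))
  if (length(accs)) {
    out$acc_mean <- mean(accs)
    out$acc_sd <- sd0(accs)
  }
  out
}

#' Write an aggregated metrics report
#'
#' TSV layout mirrors the per-class "mean(SD)" presentation: one row per
#' metric, one column per class.  JSON holds the raw numbers.
#'
#' @param report list from [aggregate_folds()].
#' @param path output path; format chosen by extension (`.json` or TSV).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    pc <- report$per_class
    classes <- unique(pc$class)
    rows <- lapply(unique(pc$metric), function(m) {
      sub <- pc[pc$metric == m, ]
      cells <- sprintf("%.3g(%.3g)", sub$mean, sub$sd)
      setNames(c(m, cells), c("metric", classes))
    })
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    if (!is.null(report$acc_mean)) {
      acc_row <- c("acc", sprintf("%.3g(%.3g)", report$acc_mean,
                                  report$acc_sd),
                   rep("", length(classes) - 1L))
      tab <- rbind(tab, setNames(as.list(acc_row), names(tab)))
    }
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
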