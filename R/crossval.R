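# Leave-one-subject-out cross-validation of the FoG classifier.

confusion_counts <- function(predicted, truth) {
  c(
    tp = sum(predicted == "fog" & truth == "fog"),
    fn = sum(predicted == "normal" & truth == "fog"),
    tn = sum(predicted == "normal" & truth == "normal"),
    fp = sum(predicted == "fog" & truth == "normal")
  )
}

confusion_metrics <- function(cm) {
  sens <- if (cm["tp"] + cm["fn"] > 0) {
    100 * cm["tp"] / (cm["tp"] + cm["fn"])
  } else {
    NA_real_
  }
  spec <- if (cm["tn"] + cm["fp"] > 0) {
    100 * cm["tn"] / (cm["tn"] + cm["fp"])
  } else {
    NA_real_
  }
  acc <- 100 * (cm["tp"] + cm["tn"]) / sum(cm)
  c(sensitivity = unname(sens), specificity = unname(spec),
    accuracy = unname(acc))
}

#' Leave-one-subject-out cross-validation
#'
#' Trains the AdaBoost classifier once per subject on all other subjects and
#' evaluates on the held-out subject. Per-fold AUC (rank statistic on the
#' vote score), sensitivity, specificity and accuracy are aggregated as
#' mean and standard deviation across folds, and additionally as a total
#' computed from the summed confusion matrix. Folds whose test set contains
#' a single class have no defined AUC and are excluded from the AUC average
#' with a warning.
#'
#' @param data data frame with numeric feature columns, plus the grouping
#'   and label columns below.
#' @param subject_col name of the subject id column.
#' @param label_col name of the label column (`"normal"` / `"fog"`).
#' @param config a [classifier_config()].
#' @return an object of class `fog_cv`: list with `folds` (per-fold tibble),
#'   `summary` (mean/sd per metric, percent), `confusion` (summed counts)
#'   and `total` (metrics from the summed confusion matrix).
#' @export
loso_cv <- function(data, subject_col = "subject", label_col = "label",
                    config = classifier_config()) {
  data <- tibble::as_tibble(data)
  if (!subject_col %in% names(data) || !label_col %in% names(data)) {
    stop_invalid("data must contain '", subject_col, "' and '", label_col, "'")
  }
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 2L) {
    stop_invalid("leave-one-subject-out needs at least 2 subjects")
  }
  feat_cols <- setdiff(
    names(data), c(subject_col, label_col, "trial", "start", "end", "degraded")
  )
  folds <- vector("list", length(subjects))
  total_cm <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  single_class_folds <- 0L
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    train_idx <- data[[subject_col]] != s
    model <- fog_train(
      data[train_idx, feat_cols], data[[label_col]][train_idx], config
    )
    test <- data[!train_idx, feat_cols]
    truth <- data[[label_col]][!train_idx]
    pred <- predict(model, test)
    cm <- confusion_counts(pred$label, truth)
    total_cm <- total_cm + cm
    auc <- rank_auc(pred$score, truth, positive = "fog")
    if (is.na(auc)) {
      single_class_folds <- single_class_folds + 1L
    }
    m <- confusion_metrics(cm)
    folds[[k]] <- tibble::tibble(
      subject = s, n_test = length(truth),
      auc = 100 * auc,
      sensitivity = unname(m["sensitivity"]),
      specificity = unname(m["specificity"]),
      accuracy = unname(m["accuracy"]),
      tp = unname(cm["tp"]), fn = unname(cm["fn"]),
      tn = unname(cm["tn"]), fp = unname(cm["fp"])
    )
  }
  if (single_class_folds > 0L) {
    warning(
      single_class_folds,
      " fold(s) had a single-class test set; AUC undefined there"
    )
  }
  folds <- dplyr::bind_rows(folds)
  metrics <- list(
    auc = folds$auc, sensitivity = folds$sensitivity,
    specificity = folds$specificity, accuracy = folds$accuracy
  )
  summary <- tibble::tibble(
    metric = names(metrics),
    mean = vapply(metrics, function(v) mean(v, na.rm = TRUE), 0,
      USE.NAMES = FALSE
    ),
    sd = vapply(metrics, function(v) stats::sd(v, na.rm = TRUE), 0,
      USE.NAMES = FALSE
    )
  )
  structure(
    list(
      folds = folds, summary = summary, confusion = total_cm,
      total = confusion_metrics(total_cm), config = config
    ),
    class = "fog_cv"
  )
}

#' @export
print.fog_cv <- function(x, ...) {
  cat("<fog_cv> leave-one-subject-out over", nrow(x$folds), "subjects\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf(
      "  %-11s %5.1f%% +/- %4.1f%%\n",
      x$summary$metric[i], x$summary$mean[i], x$summary$sd[i]
    ))
  }
  cat(sprintf(
    "  total (summed confusion): sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
    x$total["sensitivity"], x$total["specificity"], x$total["accuracy"]
  ))
  invisible(x)
}
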