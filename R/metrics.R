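# Rank-based ROC AUC with midrank tie handling (equivalent to the
# trapezoid rule on the ROC curve with ties averaged).
binary_auc <- function(truth, score) {
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Area under the precision-recall curve by the trapezoid rule over the
# points swept at each distinct score threshold (descending), starting at
# (recall 0, precision 1).
binary_aupr <- function(truth, score) {
  n_pos <- sum(truth)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  score <- score[ord]
  cum_tp <- cumsum(truth)
  cum_n <- seq_along(truth)
  last_of_group <- which(score != c(score[-1L], NA) | cum_n == length(score))
  prec <- cum_tp[last_of_group] / cum_n[last_of_group]
  rec <- cum_tp[last_of_group] / n_pos
  prec <- c(1, prec)
  rec <- c(0, rec)
  sum(diff(rec) * (prec[-1L] + prec[-length(prec)]) / 2)
}

#' Evaluate multi-class DDI predictions
#'
#' Builds the multi-class confusion matrix, per-class precision and recall,
#' micro-averaged scores (pooled TP/FP/FN counts), macro-averaged scores
#' (per-class precision and recall averaged, F1 taken as the harmonic mean
#' of macro precision and macro recall -- not the mean of per-class F1),
#' and one-vs-rest ROC AUC / precision-recall AUC, both micro (flattened
#' over the in-scope classes) and macro (per-class mean).
#'
#' With the default `classes = "positives_only"` the Negative class is
#' excluded from the averaging scope (the DDIExtraction benchmark
#' convention); `classes = "all"` pools every class, in which case micro
#' precision equals micro recall.
#'
#' @param gold Character/factor vector of true labels.
#' @param pred Character/factor vector of predicted labels.
#' @param scores Optional `n x m` score matrix (columns in `class_levels`
#'   order) for AUC/AUPR.
#' @param classes Averaging scope: `"positives_only"` or `"all"`.
#' @param class_levels Class order; defaults to [ddi_classes()].
#' @return A `ddi_eval` object; see [tidy.ddi_eval()], [glance.ddi_eval()].
#' @export
ddi_evaluate <- function(gold, pred, scores = NULL,
                         classes = c("positives_only", "all"),
                         class_levels = ddi_classes()) {
  classes <- match.arg(classes)
  gold <- as.character(gold)
  pred <- as.character(pred)
  stopifnot(length(gold) == length(pred))
  if (!all(gold %in% class_levels) || !all(pred %in% class_levels)) {
    rlang::abort("labels outside class_levels")
  }
  cm <- table(factor(gold, class_levels), factor(pred, class_levels))

  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  absent <- (tp + fn) == 0 & (tp + fp) == 0
  if (any(absent)) {
    rlang::warn(sprintf(
      "class(es) %s absent from gold and predictions; precision/recall set to 0",
      paste(class_levels[absent], collapse = ", ")))
  }
  prec_i <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_i <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1_i <- ifelse(prec_i + rec_i > 0, 2 * prec_i * rec_i / (prec_i + rec_i), 0)

  scope <- if (classes == "positives_only") {
    setdiff(class_levels, "Negative")
  } else {
    class_levels
  }
  si <- match(scope, class_levels)

  micro_p <- if (sum(tp[si] + fp[si]) > 0) {
    sum(tp[si]) / sum(tp[si] + fp[si])
  } else 0
  micro_r <- if (sum(tp[si] + fn[si]) > 0) {
    sum(tp[si]) / sum(tp[si] + fn[si])
  } else 0
  micro_f1 <- if (micro_p + micro_r > 0) {
    2 * micro_p * micro_r / (micro_p + micro_r)
  } else 0
  macro_p <- mean(prec_i[si])
  macro_r <- mean(rec_i[si])
  macro_f1 <- if (macro_p + macro_r > 0) {
    2 * macro_p * macro_r / (macro_p + macro_r)
  } else 0

  auc_i <- aupr_i <- rep(NA_real_, length(class_levels))
  micro_auc <- micro_aupr <- macro_auc <- macro_aupr <- NA_real_
  if (!is.null(scores)) {
    stopifnot(nrow(scores) == length(gold),
              ncol(scores) == length(class_levels))
    for (j in seq_along(class_levels)) {
      truth <- gold == class_levels[j]
      auc_i[j] <- binary_auc(truth, scores[, j])
      aupr_i[j] <- binary_aupr(truth, scores[, j])
    }
    flat_truth <- as.vector(vapply(si, function(j) gold == class_levels[j],
                                   logical(length(gold))))
    flat_score <- as.vector(scores[, si])
    micro_auc <- binary_auc(flat_truth, flat_score)
    micro_aupr <- binary_aupr(flat_truth, flat_score)
    macro_auc <- mean(auc_i[si], na.rm = TRUE)
    macro_aupr <- mean(aupr_i[si], na.rm = TRUE)
  }

  per_class <- tibble::tibble(
    class = class_levels,
    support = as.integer(tp + fn),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = as.numeric(prec_i), recall = as.numeric(rec_i),
    f1 = as.numeric(f1_i), auc = auc_i, aupr = aupr_i,
    in_scope = class_levels %in% scope
  )
  structure(
    list(per_class = per_class,
         micro = c(precision = micro_p, recall = micro_r, f1 = micro_f1,
                   auc = micro_auc, aupr = micro_aupr),
         macro = c(precision = macro_p, recall = macro_r, f1 = macro_f1,
                   auc = macro_auc, aupr = macro_aupr),
         confusion = cm, scope = classes),
    class = "ddi_eval"
  )
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat(sprintf("<ddi_eval> scope: %s\n", x$scope))
  cat(sprintf("  micro P/R/F1: %.4f / %.4f / %.4f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  cat(sprintf("  macro P/R/F1: %.4f / %.4f / %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' Tidy a DDI evaluation report
#'
#' @param x A `ddi_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per class.
#' @export
tidy.ddi_eval <- function(x, ...) x$per_class

#' One-row summary of a DDI evaluation report
#'
#' @param x A `ddi_eval` object.
#' @param ... Unused.
#' @return One-row tibble of micro/macro precision, recall, F1, AUC, AUPR.
#' @export
glance.ddi_eval <- function(x, ...) {
  tibble::tibble(
    micro_precision = x$micro[["precision"]],
    micro_recall = x$micro[["recall"]],
    micro_f1 = x$micro[["f1"]],
    micro_auc = x$micro[["auc"]],
    micro_aupr = x$micro[["aupr"]],
    macro_precision = x$macro[["precision"]],
    macro_recall = x$macro[["recall"]],
    macro_f1 = x$macro[["f1"]],
    macro_auc = x$macro[["auc"]],
    macro_aupr = x$macro[["aupr"]]
  )
}

#' Plot the confusion matrix of an evaluation report
#'
#' @param object A `ddi_eval` object.
#' @param normalize Row-normalize counts (recall view).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddi_eval <- function(object, normalize = FALSE, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("gold", "pred", "n")
  if (normalize) {
    df <- df |>
      dplyr::group_by(.data$gold) |>
      dplyr::mutate(n = ifelse(sum(.data$n) > 0, .data$n / sum(.data$n), 0)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$gold,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.2f", .data$n) else .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "gold",
                  fill = if (normalize) "rate" else "count") +
    ggplot2::theme_minimal()
}

#' Precision-recall and ROC curve points
#'
#' One-vs-rest sweep over each class's score column: at every distinct
#' threshold, the precision, recall, true-positive rate and false-positive
#' rate of predicting the class when its score is at or above the
#' threshold.
#'
#' @param gold True labels.
#' @param scores `n x m` score matrix.
#' @param class_levels Class order.
#' @return Tibble with `class`, `threshold`, `precision`, `recall`, `tpr`,
#'   `fpr`.
#' @export
score_curves <- function(gold, scores, class_levels = ddi_classes()) {
  gold <- as.character(gold)
  purrr::map_dfr(seq_along(class_levels), function(j) {
    truth <- gold == class_levels[j]
    s <- scores[, j]
    thr <- sort(unique(s), decreasing = TRUE)
    purrr::map_dfr(thr, function(t) {
      sel <- s >= t
      tp <- sum(sel & truth); fp <- sum(sel & !truth)
      fn <- sum(!sel & truth); tn <- sum(!sel & !truth)
      tibble::tibble(
        class = class_levels[j], threshold = t,
        precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
        recall = ifelse(tp + fn > 0, tp / (tp + fn), 0),
        tpr = ifelse(tp + fn > 0, tp / (tp + fn), 0),
        fpr = ifelse(fp + tn > 0, fp / (fp + tn), 0)
      )
    })
  })
}

#' Write an evaluation report to JSON and TSV
#'
#' @param x A `ddi_eval` object.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_eval_report <- function(x, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_class = x$per_class, micro = as.list(x$micro),
           macro = as.list(x$macro), scope = x$scope,
           confusion = as.data.frame(x$confusion)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  if (!is.null(tsv_path)) {
    utils::write.table(x$per_class, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(x)
}
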