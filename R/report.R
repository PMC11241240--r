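#' Rendering metric reports
#'
#' Display rounding follows the field's reporting conventions: metrics to 2
#' decimals, hit rate to 1 decimal.
#'
#' @name report
NULL

#' Render a metrics report with its confusion matrix
#'
#' @param metrics a \code{gifp_metrics} object.
#' @param cm the \code{gifp_confusion} matrix it came from.
#' @param format "text" or "json"; both renderings agree on all numbers.
#' @return character vector of lines (text) or a JSON string.
#' @export
render_report <- function(metrics, cm, format = c("text", "json")) {
  format <- match.arg(format)
  acc <- round(metrics$accuracy, 2)
  hr <- if (is.na(metrics$hit_rate)) NA else round(metrics$hit_rate, 1)
  if (format == "json") {
    return(jsonlite::toJSON(list(
      confusion = list(labels = rownames(cm),
                       matrix = unclass(unname(cm))),
      accuracy = acc, precision = acc, recall = acc,
      hit_rate = hr, n = metrics$n),
      auto_unbox = TRUE, digits = NA, na = "null"))
  }
  wid <- max(nchar(c(rownames(cm), colnames(cm), as.character(cm)))) + 2L
  pad <- function(x) formatC(x, width = wid)
  lines <- c("Confusion matrix (rows actual, columns predicted)",
             paste0(pad(""), paste(pad(colnames(cm)), collapse = "")))
  for (r in rownames(cm)) {
    lines <- c(lines, paste0(pad(r), paste(pad(cm[r, ]), collapse = "")))
  }
  lines <- c(lines, "Classifier performance metrics",
             sprintf("accuracy %.2f", acc),
             sprintf("precision %.2f", acc),
             sprintf("recall %.2f", acc),
             if (is.na(hr)) "hit rate (%) NA"
             else sprintf("hit rate (%%) %.1f", hr))
  lines
}

#' End-to-end virtual-screening workflow
#'
#' Predicts 4-class ligand function for every docked pose, collapses pose
#' groups by majority rule (when grouping columns are present), merges the
#' active classes, and returns a candidate report sorted with predicted
#' actives first.
#'
#' @param features feature table of the screening candidates (one row per
#'   docked pose; optional model_id / ligand_id columns define pose groups).
#' @param bundle a trained \code{gifp_classifier}.
#' @param group_by pose-grouping columns; groups are used only when all are
#'   present in \code{features}.
#' @return data.frame: group keys (or complex_id), four-class label, merged
#'   active/inactive call, group probability of the called class.
#' @export
run_screening_workflow <- function(features, bundle,
                                   group_by = c("model_id", "ligand_id")) {
  preds <- predict_classifier(bundle, features)
  if (nrow(preds) == 0L) {
    warning("no candidates supplied; empty report")
    return(data.frame())
  }
  if (all(group_by %in% names(preds))) {
    preds <- majority_vote(preds, group_by)
  }
  preds$merged_label <- merge_active(preds$pred_label)
  pcols <- grep("^prob_", names(preds), value = TRUE)
  preds$call_probability <- vapply(seq_len(nrow(preds)), function(i) {
    preds[[paste0("prob_", preds$pred_label[i])]][i]
  }, 1.0)
  preds[order(preds$merged_label != "active", -preds$call_probability), ,
        drop = FALSE]
}
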