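#' Multiclass confusion matrix
#'
#' Rows are the notated (true) classes, columns the predicted classes,
#' in the fixed order of `labels`.
#'
#' @param y_true,y_pred equal-length label vectors drawn from `labels`.
#' @param labels class order (default [mi_classes()]).
#' @return integer matrix of class `confusion_matrix` with `labels` as
#'   dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = mi_classes()) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  bad <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(notated = labels, predicted = labels))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Round half away from zero (display convention for metric tables)
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-class accuracy, sensitivity, specificity (one-vs-rest)
#'
#' For each class: `TP` is the diagonal entry, `FN` the rest of its row,
#' `FP` the rest of its column, `TN` everything else; then
#' `ACC = (TP+TN)/total`, `SEN = TP/(TP+FN)`, `SPE = TN/(FP+TN)`, in
#' percent.  Sensitivity is `NA` for a class with no notated beats.
#' Values are full precision; use [round_half_up()] for display.
#'
#' @param cm a square count matrix (rows = notated, columns = predicted).
#' @return data.frame with columns `class`, `tp`, `fn`, `fp`, `tn`,
#'   `acc`, `sen`, `spe`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sen <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  data.frame(class = rownames(cm),
             tp = as.integer(tp), fn = as.integer(fn),
             fp = as.integer(fp), tn = as.integer(tn),
             acc = 100 * (tp + tn) / total,
             sen = sen,
             spe = 100 * tn / (fp + tn),
             row.names = NULL)
}

#' Overall metrics: micro accuracy and macro sensitivity/specificity
#'
#' Micro accuracy is `100 * trace / total`; overall sensitivity and
#' specificity are the unweighted means of the per-class one-vs-rest
#' values (classes with undefined sensitivity are excluded from the
#' mean).
#'
#' @param cm a square count matrix.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent,
#'   full precision).
#' @export
overall_metrics <- function(cm) {
  pc <- per_class_metrics(cm)
  cm <- unclass(cm)
  list(accuracy = 100 * sum(diag(cm)) / sum(cm),
       sensitivity = mean(pc$sen, na.rm = TRUE),
       specificity = mean(pc$spe, na.rm = TRUE))
}

#' Full metrics report for a confusion matrix
#'
#' @param cm a square count matrix.
#' @return list of class `metrics_report` with `per_class` (data.frame)
#'   and `overall` (list); print method shows values rounded half-up to
#'   2 decimals.
#' @export
metrics_report <- function(cm) {
  structure(list(per_class = per_class_metrics(cm),
                 overall = overall_metrics(cm),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pc <- x$per_class
  tab <- data.frame(class = pc$class,
                    ACC = round_half_up(pc$acc),
                    SEN = round_half_up(pc$sen),
                    SPE = round_half_up(pc$spe))
  print(tab, row.names = FALSE)
  ov <- x$overall
  cat(sprintf("overall: ACC %.2f%%  SEN %.2f%%  SPE %.2f%%\n",
              round_half_up(ov$accuracy), round_half_up(ov$sensitivity),
              round_half_up(ov$specificity)))
  invisible(x)
}

#' Read a confusion matrix from delimited text
#'
#' Expects a header row of predicted-class names and one row per notated
#' class, first column the class name; extra annotation columns (e.g.
#' totals or reference metric values) are returned in the `"extra"`
#' attribute rather than the matrix.
#'
#' @param path TSV/CSV file path.
#' @return integer `confusion_matrix`; any annotation columns as
#'   attribute `"extra"` (data.frame).
#' @export
read_confusion_delim <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          sep = if (grepl("\\.csv$", path)) "," else "\t")
  labels <- df[[1L]]
  pred_cols <- intersect(labels, colnames(df))
  if (length(pred_cols) != length(labels))
    stop("column names do not cover all notated classes in ", path)
  cm <- as.matrix(df[, labels, drop = FALSE])
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(notated = labels, predicted = labels)
  class(cm) <- c("confusion_matrix", class(cm))
  extra <- df[, setdiff(colnames(df), c(colnames(df)[1L], labels)),
              drop = FALSE]
  if (ncol(extra)) attr(cm, "extra") <- extra
  cm
}

#' Write a confusion matrix as delimited text
#' @param cm a confusion matrix.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_confusion_delim <- function(cm, path) {
  df <- data.frame(class = rownames(cm), unclass(cm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
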