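#' Confusion matrix of predicted vs. true labels
#'
#' Exact cross-tabulation with rows = predicted class and columns = true
#' class, so entry `(i, j)` counts samples of true class `j` predicted as
#' class `i`. Labels are integers in `[0, m)`.
#'
#' @param true_labels,pred_labels Equal-length integer vectors.
#' @param m Number of classes (default 2).
#' @return An `m x m` integer matrix of class `confusion_matrix`, with
#'   dimnames `predicted` / `true`.
#' @export
confusion_counts <- function(true_labels, pred_labels, m = 2L) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(true_labels) < 1L) stop("no samples", call. = FALSE)
  labs <- c(true_labels, pred_labels)
  if (anyNA(labs) || any(labs < 0L) || any(labs >= m))
    stop("labels must lie in [0, m)", call. = FALSE)
  cls <- 0:(m - 1L)
  counts <- table(predicted = factor(pred_labels, levels = cls),
                  true = factor(true_labels, levels = cls))
  structure(matrix(as.integer(counts), nrow = m,
                   dimnames = list(predicted = cls, true = cls)),
            class = c("confusion_matrix", "matrix"))
}

as_confusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0))
    stop("expected a square nonnegative confusion matrix", call. = FALSE)
  if (sum(cm) < 1) stop("empty confusion matrix", call. = FALSE)
  unclass(cm)
}

#' Overall accuracy
#'
#' Fraction of samples on the confusion-matrix diagonal,
#' `p_c = sum_i n_ii / N`.
#'
#' @param cm A square count matrix (e.g. from [confusion_counts()]).
#' @return A fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_confusion(cm)
  sum(diag(cm)) / sum(cm)
}

#' Proportion form of a confusion matrix
#'
#' `p_ij = n_ij / N`; entries sum to 1.
#'
#' @inheritParams overall_accuracy
#' @return An `m x m` matrix of fractions.
#' @export
proportion_matrix <- function(cm) {
  cm <- as_confusion(cm)
  cm / sum(cm)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement,
#' `k = (N * sum_i n_ii - sum_i n_i. * n_.i) / (N^2 - sum_i n_i. * n_.i)`.
#' Any predictor that outputs a single class scores exactly 0 regardless of
#' class prevalence; a degenerate matrix with all mass in one
#' true-and-predicted cell (denominator 0) is reported as 0.
#'
#' @inheritParams overall_accuracy
#' @return A coefficient in `(-1, 1]`.
#' @export
kappa_coefficient <- function(cm) {
  cm <- as_confusion(cm)
  N <- sum(cm)
  chance <- sum(rowSums(cm) * colSums(cm))
  denom <- N^2 - chance
  if (denom == 0) return(0)
  (N * sum(diag(cm)) - chance) / denom
}

#' Per-class user and producer accuracy
#'
#' User accuracy of class `i` is the row-normalized diagonal `n_ii / n_i.`
#' (commission: of the pixels *predicted* as class `i`, how many are right);
#' producer accuracy is the column-normalized `n_ii / n_.i` (omission: of
#' the pixels *truly* in class `i`, how many are found). An empty margin
#' makes the corresponding accuracy undefined and it is reported as `NA`.
#'
#' @inheritParams overall_accuracy
#' @return A data frame with columns `class`, `user`, `producer`.
#' @export
user_producer_accuracy <- function(cm) {
  cm <- as_confusion(cm)
  m <- nrow(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  data.frame(class = 0:(m - 1L),
             user = ifelse(rs > 0, diag(cm) / rs, NA_real_),
             producer = ifelse(cs > 0, diag(cm) / cs, NA_real_))
}

#' Qualitative rating of a kappa coefficient
#'
#' Standard rating bands: Very poor (< 0), Poor `[0, 0.2)`, Average
#' `[0.2, 0.4)`, Good `[0.4, 0.6)`, Very good `[0.6, 0.8)`, Excellent
#' `[0.8, 1]`. Shared band endpoints are assigned to the upper band.
#'
#' @param k Kappa coefficient(s), each at most 1.
#' @return Character vector of rating labels.
#' @export
rate_kappa <- function(k) {
  if (any(k > 1)) stop("kappa cannot exceed 1", call. = FALSE)
  labels <- c("Very poor", "Poor", "Average", "Good", "Very good", "Excellent")
  as.character(cut(k, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
                   labels = labels, right = FALSE))
}

#' Full accuracy-assessment report for a confusion matrix
#'
#' Bundles counts, proportions, overall accuracy, kappa with its rating, and
#' per-class user/producer accuracy -- the standard remote-sensing accuracy
#' assessment layout.
#'
#' @inheritParams overall_accuracy
#' @return A list of class `assessment` with elements `counts`,
#'   `proportions`, `overall_accuracy`, `kappa`, `rating`, `per_class`.
#' @export
assessment_report <- function(cm) {
  k <- kappa_coefficient(cm)
  structure(list(counts = cm,
                 proportions = proportion_matrix(cm),
                 overall_accuracy = overall_accuracy(cm),
                 kappa = k,
                 rating = rate_kappa(k),
                 per_class = user_producer_accuracy(cm)),
            class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat("Accuracy assessment\n")
  cat(sprintf("  overall accuracy: %.4f\n", x$overall_accuracy))
  cat(sprintf("  kappa: %.4f (%s)\n", x$kappa, x$rating))
  cat("  per-class accuracy:\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write an assessment report to CSV and plain text
#'
#' Writes `<path>.csv` (per-class table plus overall rows) and
#' `<path>.txt` (the pretty-printed report).
#'
#' @param report An `assessment` from [assessment_report()].
#' @param path Path prefix (no extension).
#' @export
write_assessment <- function(report, path) {
  stopifnot(inherits(report, "assessment"))
  df <- report$per_class
  df$overall_accuracy <- report$overall_accuracy
  df$kappa <- report$kappa
  df$rating <- report$rating
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
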