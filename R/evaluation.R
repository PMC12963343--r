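#' Classification metrics
#'
#' Accuracy, macro-averaged precision, and macro-averaged F1, all in
#' percent. Precision/recall/F1 are computed per class from the confusion
#' matrix and averaged without class weights (macro), which is the
#' appropriate convention under class imbalance; classes absent from both
#' `y_true` and `y_pred` are excluded from the macro mean. A class with an
#' undefined precision or recall (zero denominator) contributes 0 for that
#' component.
#'
#' @param y_true,y_pred Equal-length label vectors (integer codes
#'   `0 .. num_classes - 1`).
#' @param num_classes Number of classes.
#' @return List with `accuracy`, `precision`, `f1` (percent) and the
#'   per-class data frame `per_class`; `averaging = "macro"` is recorded.
#' @export
classification_metrics <- function(y_true, y_pred, num_classes) {
  if (length(y_true) == 0L) stop("empty label vectors")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  cls <- seq_len(num_classes) - 1L
  cm <- table(factor(y_true, levels = cls), factor(y_pred, levels = cls))
  present <- which(rowSums(cm) + colSums(cm) > 0)
  prec <- rec <- f1 <- numeric(length(present))
  for (i in seq_along(present)) {
    j <- present[i]
    tp <- cm[j, j]
    prec[i] <- if (sum(cm[, j]) > 0) tp / sum(cm[, j]) else 0
    rec[i] <- if (sum(cm[j, ]) > 0) tp / sum(cm[j, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(accuracy = 100 * mean(y_true == y_pred),
       precision = 100 * mean(prec),
       f1 = 100 * mean(f1),
       per_class = data.frame(class = cls[present],
                              precision = 100 * prec, recall = 100 * rec,
                              f1 = 100 * f1),
       averaging = "macro")
}

#' Per-class percentage distribution
#'
#' `100 * count / total` for each class, rounded half-up to 2 decimals (the
#' convention of printed dataset tables).
#'
#' @param counts Non-negative per-class counts (named or not) with a
#'   positive total, or a manifest data frame with a `label` column.
#' @return Numeric vector of percentages.
#' @export
class_distribution <- function(counts) {
  if (is.data.frame(counts)) {
    tb <- table(counts$label)
    counts <- stats::setNames(as.numeric(tb), names(tb))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  round_half_up(100 * counts / total, 2)
}

#' Results table
#'
#' A methods-by-datasets matrix of accuracy percentages, as printed in
#' cross-method comparison tables.
#'
#' @param values Numeric matrix (or data frame) with unique row (method)
#'   and column (dataset) names, values in `[0, 100]`.
#' @return Object of class `results_table`.
#' @export
results_table <- function(values) {
  m <- as.matrix(values)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("results table needs method row names and dataset column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("method/dataset labels must be unique")
  if (any(m < 0 | m > 100)) stop("accuracies must lie in [0, 100]")
  structure(m, class = c("results_table", class(m)))
}

#' Read a results table from a long-format CSV
#'
#' @param path CSV with columns `method`, `dataset`, `accuracy`.
#' @return A [results_table()].
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("method", "dataset", "accuracy") %in% names(df)))
  methods <- unique(df$method)
  datasets <- unique(df$dataset)
  m <- matrix(NA_real_, length(methods), length(datasets),
              dimnames = list(methods, datasets))
  m[cbind(match(df$method, methods), match(df$dataset, datasets))] <-
    df$accuracy
  results_table(m)
}

#' Pairwise margins and cross-dataset ranges
#'
#' For every ordered method pair and dataset, the margin
#' `accuracy(A, d) - accuracy(B, d)`; for every method, the range
#' `max - min` of its accuracies across datasets (a cross-dataset stability
#' measure).
#'
#' @param table A [results_table()].
#' @return List with `margins` (data frame: `method_a`, `method_b`,
#'   `dataset`, `margin`) and `ranges` (named vector per method).
#' @export
results_margins <- function(table) {
  stopifnot(inherits(table, "results_table"))
  methods <- rownames(table)
  datasets <- colnames(table)
  grid <- expand.grid(method_a = methods, method_b = methods,
                      dataset = datasets, stringsAsFactors = FALSE)
  grid <- grid[grid$method_a != grid$method_b, ]
  grid$margin <- table[cbind(grid$method_a, grid$dataset)] -
    table[cbind(grid$method_b, grid$dataset)]
  ranges <- apply(table, 1, function(r) max(r) - min(r))
  rownames(grid) <- NULL
  list(margins = grid, ranges = ranges)
}

#' Look up one margin
#'
#' @param table A [results_table()].
#' @param method_a,method_b Method row labels.
#' @param dataset Dataset column label.
#' @return `accuracy(method_a) - accuracy(method_b)` on `dataset`.
#' @export
margin_between <- function(table, method_a, method_b, dataset) {
  stopifnot(inherits(table, "results_table"))
  for (m in c(method_a, method_b))
    if (!m %in% rownames(table)) stop("unknown method: ", m)
  if (!dataset %in% colnames(table)) stop("unknown dataset: ", dataset)
  unname(table[method_a, dataset] - table[method_b, dataset])
}
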