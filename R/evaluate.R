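# Evaluation: confusion matrices, per-class precision/recall/F1, accuracy,
# one-vs-rest ROC/AUC with tie grouping, Pearson correlation, and boxplot
# summary statistics.

#' Confusion matrix
#'
#' K x K counts with rows = true class, columns = predicted class, in the
#' declared label order.
#'
#' @param truth,pred Equal-length label vectors drawn from `labels`.
#' @param labels Ordered class labels; defaults to the union of observed
#'   labels.
#' @return A `stress_confusion` object (integer matrix).
#' @export
confusion <- function(truth, pred, labels = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths (", length(truth), " vs ",
         length(pred), ")", call. = FALSE)
  }
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (is.null(labels)) labels <- sort(unique(c(truth, pred)))
  unknown <- setdiff(unique(c(truth, pred)), labels)
  if (length(unknown) > 0) {
    stop("unknown label '", unknown[1], "'", call. = FALSE)
  }
  m <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(truth = labels, pred = labels))
  structure(m, class = c("stress_confusion", "matrix"))
}

#' Build a confusion matrix directly from counts
#'
#' @param counts K x K integer matrix (rows = truth, columns = predicted).
#' @param labels Ordered class labels.
#' @return A `stress_confusion` object.
#' @export
confusion_from_counts <- function(counts, labels) {
  m <- matrix(as.integer(counts), nrow = length(labels),
              dimnames = list(truth = labels, pred = labels))
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(m, class = c("stress_confusion", "matrix"))
}

#' @export
print.stress_confusion <- function(x, ...) {
  cat("<confusion matrix> n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' `precision = diag/colsum`, `recall = diag/rowsum` (0 when the
#' denominator is empty), F1 their harmonic mean (0 when both are 0),
#' accuracy = trace/total.
#'
#' @param cm A [confusion()] matrix.
#' @return A `stress_metrics` object: a per-class tibble (`class,
#'   precision, recall, f1, support`) with `accuracy` and `n` attributes.
#'   Use [generics::tidy()] / [generics::glance()] to extract.
#' @export
class_metrics <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  d <- diag(m)
  col_s <- colSums(m)
  row_s <- rowSums(m)
  precision <- ifelse(col_s > 0, d / col_s, 0)
  recall <- ifelse(row_s > 0, d / row_s, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  out <- tibble::tibble(class = rownames(m), precision = unname(precision),
                        recall = unname(recall), f1 = unname(f1),
                        support = unname(as.integer(row_s)))
  structure(out, accuracy = sum(d) / total, n = total,
            class = c("stress_metrics", class(out)))
}

#' @export
print.stress_metrics <- function(x, ...) {
  cat("accuracy:", sprintf("%.2f", attr(x, "accuracy")),
      " (n =", attr(x, "n"), ")\n")
  NextMethod()
}

# One-vs-rest ROC points by threshold sweep with tied scores grouped into a
# single step; AUC by trapezoid.
roc_binary <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    return(list(points = NULL, auc = NA_real_))
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- positive[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  pts <- tibble::tibble(
    threshold = c(Inf, s[grp_end]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps the decision threshold over the unique values of
#' that class's score (ties grouped into one step) treating the class as
#' positive and the rest as negative; AUC is the trapezoidal area, which
#' equals the Mann-Whitney rank statistic (pairs won plus half the ties,
#' over all positive-negative pairs). A class absent from the truth gets an
#' `NA` AUC.
#'
#' @param scores Data frame or matrix of per-class scores; columns either
#'   named after the classes or `score_<class>`.
#' @param truth Vector of true class labels.
#' @param labels Ordered class labels; defaults to the score columns.
#' @return A `stress_roc` object: list with `points` (tibble `class,
#'   threshold, fpr, tpr`) and `auc` (named vector).
#' @export
roc_ovr <- function(scores, truth, labels = NULL) {
  scores <- as.data.frame(scores)
  names(scores) <- sub("^score_", "", names(scores))
  if (is.null(labels)) labels <- names(scores)
  missing_cols <- setdiff(labels, names(scores))
  if (length(missing_cols) > 0) {
    stop("no score column for class '", missing_cols[1], "'", call. = FALSE)
  }
  if (nrow(scores) != length(truth)) {
    stop("scores and truth have different lengths", call. = FALSE)
  }
  truth <- as.character(truth)
  res <- lapply(labels, function(cl) roc_binary(scores[[cl]], truth == cl))
  names(res) <- labels
  points <- purrr::map_dfr(labels, function(cl) {
    p <- res[[cl]]$points
    if (is.null(p)) return(NULL)
    dplyr::mutate(p, class = cl, .before = 1)
  })
  auc <- vapply(res, function(r) r$auc, numeric(1))
  structure(list(points = points, auc = auc), class = "stress_roc")
}

#' @export
print.stress_roc <- function(x, ...) {
  cat("<one-vs-rest ROC>\n")
  for (cl in names(x$auc)) {
    cat(sprintf("  %-10s AUC = %s\n", cl,
                ifelse(is.na(x$auc[[cl]]), "NA (single-class truth)",
                       sprintf("%.3f", x$auc[[cl]]))))
  }
  invisible(x)
}

#' Pearson correlation with a two-sided t test
#'
#' Sample Pearson r between two series, with the two-sided p value from
#' `t = r*sqrt(n-2)/sqrt(1-r^2)` on `n-2` degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, nonzero variance.
#' @return A one-row tibble: `r, statistic, p_value, n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y have different lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the inputs", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 p_value = ct$p.value, n = length(x))
}

#' Boxplot summary statistics
#'
#' Median (midpoint convention for even n), mean, and quartiles by linear
#' interpolation (`stats::quantile()` type 7 — the convention the package's
#' boxplot edges use).
#'
#' @param values Nonempty numeric vector.
#' @return A one-row tibble: `n, median, mean, q1, q3, iqr`.
#' @export
summary_stats <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(values), median = stats::median(values),
                 mean = mean(values), q1 = q[1], q3 = q[2],
                 iqr = q[2] - q[1])
}

# ---- broom-style accessors -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.stress_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)) |>
    rlang::set_names(c("truth", "pred", "n"))
}

#' @export
glance.stress_confusion <- function(x, ...) {
  glance(class_metrics(x))
}

#' @export
tidy.stress_metrics <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.stress_metrics <- function(x, ...) {
  tibble::tibble(accuracy = attr(x, "accuracy"),
                 macro_f1 = mean(x$f1),
                 n = attr(x, "n"))
}

#' @export
tidy.stress_roc <- function(x, ...) {
  x$points
}

#' @export
glance.stress_roc <- function(x, ...) {
  tibble::as_tibble(as.list(stats::setNames(x$auc, paste0("auc_", names(x$auc)))))
}
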