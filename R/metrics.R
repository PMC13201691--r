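#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUROC equals the probability that a random positive's score exceeds a
#' random negative's, counting ties one half, computed via midranks.
#'
#' @param scores numeric score vector (higher = more positive)
#' @param labels binary 0/1 vector of the same length
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 and match scores in length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: need at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Class-wise and average AUROC evaluation report
#'
#' Per-class AUROC for a multi-label score matrix; classes lacking both a
#' positive and a negative example are undefined and skipped (with a
#' warning); the average is the arithmetic mean of the defined per-class
#' values.
#'
#' @param scores numeric matrix `n x L`
#' @param labels binary matrix `n x L`
#' @param class_names optional class names (defaults to column names)
#' @return an object of class `squeezevit_eval`: tibble `per_class`
#'   (class, auroc, n_pos, n_neg), `average` AUROC
#' @export
classwise_auroc <- function(scores, labels, class_names = colnames(scores)) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels))) {
    stop("scores and labels must be conformable matrices", call. = FALSE)
  }
  L <- ncol(scores)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(L))
  vals <- numeric(L); npos <- integer(L); nneg <- integer(L)
  for (k in seq_len(L)) {
    npos[k] <- sum(labels[, k] == 1)
    nneg[k] <- sum(labels[, k] == 0)
    vals[k] <- if (npos[k] == 0L || nneg[k] == 0L) NA_real_
               else auroc(scores[, k], labels[, k])
  }
  if (anyNA(vals)) {
    warning("AUROC undefined for class(es) ",
            paste(class_names[is.na(vals)], collapse = ", "),
            "; skipped in the average", call. = FALSE)
  }
  if (all(is.na(vals))) {
    stop("no class has both positive and negative examples", call. = FALSE)
  }
  structure(list(
    per_class = tibble::tibble(class = class_names, auroc = vals,
                               n_pos = npos, n_neg = nneg),
    average = mean(vals, na.rm = TRUE)
  ), class = "squeezevit_eval")
}

#' @export
print.squeezevit_eval <- function(x, ...) {
  cat("Evaluation report: average AUROC ", round(x$average, 4), " over ",
      sum(!is.na(x$per_class$auroc)), " classes\n", sep = "")
  print(x$per_class, n = nrow(x$per_class))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a `squeezevit_eval` report into its per-class tibble
#' @param x a `squeezevit_eval`
#' @param ... unused
#' @return the per-class tibble
#' @export
tidy.squeezevit_eval <- function(x, ...) x$per_class

#' Macro-averaged F1 at a fixed threshold
#'
#' Per-class F1 of thresholded sigmoid scores, macro-averaged; a class with
#' zero predicted positives and zero true positives contributes F1 = 0.
#'
#' @param scores probability matrix `n x L`
#' @param labels binary matrix `n x L`
#' @param threshold decision threshold in (0, 1), default 0.5
#' @return macro-averaged F1 in `[0, 1]`
#' @export
f1_average <- function(scores, labels, threshold = 0.5) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels))) {
    stop("scores and labels must be conformable matrices", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  pred <- scores >= threshold
  f1 <- vapply(seq_len(ncol(scores)), function(k) {
    tp <- sum(pred[, k] & labels[, k] == 1)
    fp <- sum(pred[, k] & labels[, k] == 0)
    fn <- sum(!pred[, k] & labels[, k] == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  mean(f1)
}

#' Percentile bootstrap confidence interval for AUROC
#'
#' Nonparametric case-resampling bootstrap: draws `B` resamples of the
#' (score, label) pairs, recomputes AUROC on each, and returns the
#' `alpha/2` and `1 - alpha/2` percentiles. Resamples on which AUROC is
#' undefined (single-class draws) are redrawn up to 10 times, then skipped;
#' the skip count is attached as an attribute.
#'
#' @param scores numeric score vector
#' @param labels binary 0/1 vector
#' @param B number of bootstrap replicates (default 2000; < 100 warns)
#' @param alpha 1 - confidence level (default 0.05 for a 95% CI)
#' @param seed RNG seed (intervals are seed-deterministic)
#' @return numeric `c(low, high)` with attributes `point` (the plug-in
#'   AUROC) and `skipped`
#' @export
bootstrap_ci <- function(scores, labels, B = 2000L, alpha = 0.05,
                         seed = 1L) {
  if (B < 100L) warning("B < 100 gives unstable percentile intervals",
                        call. = FALSE)
  point <- auroc(scores, labels)   # also validates inputs
  n <- length(scores)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  labels <- as.integer(labels)
  stat <- numeric(B)
  skipped <- 0L
  for (b in seq_len(B)) {
    v <- NA_real_
    for (att in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx] == 1L) && any(labels[idx] == 0L)) {
        v <- auroc(scores[idx], labels[idx])
        break
      }
    }
    if (is.na(v)) skipped <- skipped + 1L
    stat[b] <- v
  }
  stat <- stat[!is.na(stat)]
  ci <- unname(quantile(stat, c(alpha / 2, 1 - alpha / 2), type = 7))
  attr(ci, "point") <- point
  attr(ci, "skipped") <- skipped
  ci
}
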