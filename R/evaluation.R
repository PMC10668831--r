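#' Rank-based AUC for presence-background scores
#'
#' The Mann-Whitney probability that a randomly drawn presence scores
#' higher than a randomly drawn background point, with ties counted one
#' half. Background points serve as pseudo-absences.
#'
#' @param presence_scores,background_scores Non-empty finite numeric
#'   vectors of predicted suitability.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  check_scores(presence_scores, background_scores)
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' True skill statistic maximized over a threshold grid
#'
#' Scans thresholds t in 0, 0.01, ..., 1; sensitivity is the fraction of
#' presences scoring at least t and specificity the fraction of
#' background points scoring below t. Returns the maximum of
#' `sensitivity + specificity - 1` and the smallest maximizing threshold.
#'
#' @inheritParams auc
#' @param step Threshold grid step (default 0.01).
#' @return List with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss <- function(presence_scores, background_scores, step = 0.01) {
  check_scores(presence_scores, background_scores)
  grid <- seq(0, 1, by = step)
  sens <- vapply(grid, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(grid, function(t) mean(background_scores < t), numeric(1))
  val <- sens + spec - 1
  i <- which.max(val)  # ties: smallest threshold wins
  list(tss = val[i], threshold = grid[i],
       sensitivity = sens[i], specificity = spec[i])
}

check_scores <- function(p, b) {
  if (length(p) == 0 || length(b) == 0) stop("score sets must be non-empty")
  if (any(!is.finite(p)) || any(!is.finite(b))) stop("scores must be finite")
  invisible(TRUE)
}

#' Evaluate a fitted model on train/test presences
#'
#' @param model A `maxent_model`.
#' @param train,test Presence value matrices (test may be NULL).
#' @param bg Background value matrix.
#' @return An `eval_report` list: `train_auc`, `test_auc`, `tss`,
#'   `threshold`, `sensitivity`, `specificity` (TSS on the test split
#'   when present, else on the training presences).
#' @export
evaluate_model <- function(model, train, bg, test = NULL) {
  sb <- predict(model, bg, transform = "cloglog")
  st <- predict(model, train, transform = "cloglog")
  train_auc <- auc(st, sb)
  if (!is.null(test) && nrow(as_value_matrix(test)) > 0) {
    se <- predict(model, test, transform = "cloglog")
    test_auc <- auc(se, sb)
    ts <- tss(se, sb)
  } else {
    test_auc <- NA_real_
    ts <- tss(st, sb)
  }
  structure(
    list(train_auc = train_auc, test_auc = test_auc, tss = ts$tss,
         threshold = ts$threshold, sensitivity = ts$sensitivity,
         specificity = ts$specificity),
    class = "eval_report"
  )
}

#' Summarize replicate evaluation reports
#'
#' @param reports List of `eval_report`s.
#' @return Data.frame with mean and sd of each metric, matching the
#'   `mean +/- sd` reporting convention.
#' @export
summarize_evals <- function(reports) {
  pull <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  metrics <- c("train_auc", "test_auc", "tss")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(f) mean(pull(f), na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(f) stats::sd(pull(f), na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
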