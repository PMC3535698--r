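#' ROC curve under partial score coverage
#'
#' Prediction tools only report scores for pairs passing their internal
#' cutoffs, so many records carry no score at all. Such records are treated
#' as "never called": they contribute to the denominators (total positives
#' and negatives) at every threshold but can never enter the called set.
#' The realized curve therefore stops at `max_reachable_fpr`, the fraction
#' of negatives the tool scores at all; with `extrapolate = TRUE` a final
#' straight (dashed, when plotted) segment connects the last realized point
#' to (1, 1), which is exactly the concordance value of breaking the
#' remaining ties at random. Ties in the score enter and leave the called
#' set together. AUC is the trapezoid area over the realized (plus
#' extrapolated) curve.
#'
#' @param score numeric scores, NA for records the tool did not score.
#' @param label binary labels (1 = positive).
#' @param direction +1 if higher scores rank first (default), -1 if lower
#'   scores do.
#' @param extrapolate connect the last realized point to (1, 1).
#' @return Object of class `mirfuse_roc`: list with `points` (data frame
#'   fpr/tpr), `auc`, `max_reachable_fpr`, `extrapolated`.
#' @export
roc_curve <- function(score, label, direction = 1, extrapolate = TRUE) {
  if (length(score) != length(label)) stop("score/label length mismatch")
  label <- as.integer(label)
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative label")
  }
  s <- if (direction < 0) -as.numeric(score) else as.numeric(score)
  present <- !is.na(s)
  fpr <- 0
  tpr <- 0
  if (any(present)) {
    o <- order(s[present], decreasing = TRUE)
    sp <- s[present][o]
    lp <- label[present][o]
    ends <- c(sp[-1L] != sp[-length(sp)], TRUE)
    tpr <- c(0, cumsum(lp == 1L)[ends] / n_pos)
    fpr <- c(0, cumsum(lp == 0L)[ends] / n_neg)
  }
  max_fpr <- sum(present & label == 0L) / n_neg
  last <- length(fpr)
  extrapolated <- FALSE
  if (extrapolate && (fpr[last] < 1 || tpr[last] < 1)) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
    extrapolated <- TRUE
  }
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 max_reachable_fpr = max_fpr, extrapolated = extrapolated),
            class = "mirfuse_roc")
}

#' @export
print.mirfuse_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f over %d points; reachable FPR up to %.4f%s\n",
              x$auc, nrow(x$points), x$max_reachable_fpr,
              if (x$extrapolated) " (extrapolated to (1,1))" else ""))
  invisible(x)
}

#' @export
plot.mirfuse_roc <- function(x, main = "ROC", add = FALSE, col = 1, ...) {
  p <- x$points
  n <- nrow(p)
  solid <- if (x$extrapolated) seq_len(n - 1L) else seq_len(n)
  if (!add) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
         ylab = "True positive rate", main = main, ...)
    graphics::abline(0, 1, col = "grey80")
  }
  graphics::lines(p$fpr[solid], p$tpr[solid], col = col)
  if (x$extrapolated) {
    graphics::lines(p$fpr[(n - 1L):n], p$tpr[(n - 1L):n], lty = 2, col = col)
  }
  invisible(x)
}

#' Stratified k-fold cross-validated fusion
#'
#' Splits the labeled records into k folds, stratified by class so every
#' training split contains both classes; each fold's posteriors are
#' predicted by a model trained on the remaining folds, and the pooled
#' out-of-fold posteriors give one ROC curve. The partition is seeded and
#' deterministic.
#'
#' @param table labeled `score_table` with at least k records per class.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold partition.
#' @param ... passed to [mirfuse()] (family map, prior override, ...).
#' @return Object of class `mirfuse_cv`: list with `posterior` (out-of-fold,
#'   in input order), `fold` assignments, `roc`, and `auc`.
#' @export
cv_fuse <- function(table, k = 5L, seed = 1L, ...) {
  stopifnot(inherits(table, "score_table"))
  lab <- table$label
  if (is.null(lab) || any(is.na(lab))) {
    stop("cross-validation needs a fully labeled table")
  }
  if (sum(lab == 1L) < k || sum(lab == 0L) < k) {
    stop("each class needs at least k = ", k, " records")
  }
  fold <- integer(nrow(table))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(lab == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  posterior <- numeric(nrow(table))
  df <- as.data.frame(table)
  tools <- attr(table, "tool_names")
  for (f in seq_len(k)) {
    test <- fold == f
    train_tab <- score_table(df$mirna[!test], df$gene[!test],
                             as.matrix(df[!test, tools, drop = FALSE]),
                             tool_names = tools, label = lab[!test])
    test_tab <- score_table(df$mirna[test], df$gene[test],
                            as.matrix(df[test, tools, drop = FALSE]),
                            tool_names = tools, label = lab[test])
    fit <- mirfuse(train_tab, ...)
    posterior[test] <- predict(fit, test_tab)
  }
  roc <- roc_curve(posterior, lab)
  structure(list(posterior = posterior, fold = fold, roc = roc,
                 auc = roc$auc, k = k, seed = seed),
            class = "mirfuse_cv")
}

#' @export
print.mirfuse_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated fusion: pooled AUC %.4f\n",
              x$k, x$auc))
  invisible(x)
}

#' Cumulative fold-change curve over a ranked prediction list
#'
#' For a prediction list ranked by descending confidence, c(t) is the
#' running sum of the protein fold changes of the top-t genes and A(n) the
#' area under c up to rank n (the double sum of the first n fold changes).
#' Since protein repression is the primary mode of miRNA regulation, a
#' better ranking puts strongly down-regulated proteins first and A(n) is
#' more negative. Genes absent from the fold-change table are skipped
#' without consuming rank positions.
#'
#' @param ranked_genes character vector of gene ids, best prediction first.
#' @param fc a `fold_change_table` (or data frame with columns `gene`,
#'   `fold_change`).
#' @param n ranks at which to report A(n); default `c(100, 200, 300, 400,
#'   500)`. Every requested n must be within the usable list length.
#' @return Object of class `cumulative_curve`: list with `c` (cumulative
#'   sums), `A` (named vector of A(n)), `genes` (the usable ranked genes).
#' @export
cumulative_downfold <- function(ranked_genes, fc,
                                n = c(100, 200, 300, 400, 500)) {
  stopifnot(is.data.frame(fc), all(c("gene", "fold_change") %in% names(fc)))
  usable <- ranked_genes[ranked_genes %in% fc$gene]
  f <- fc$fold_change[match(usable, fc$gene)]
  if (length(f) == 0L) stop("no ranked gene appears in the fold-change table")
  if (any(n > length(f))) {
    stop("requested rank ", max(n), " exceeds the usable list length ",
         length(f))
  }
  cvec <- cumsum(f)
  avec <- cumsum(cvec)
  structure(list(c = cvec, A = stats::setNames(avec[n], n),
                 genes = usable),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat("Cumulative down-fold curve over", length(x$c), "ranked genes\n")
  print(round(x$A, 2))
  invisible(x)
}

#' @export
plot.cumulative_curve <- function(x, main = "Cumulative protein fold change",
                                  ...) {
  plot(seq_along(x$c), x$c, type = "l", xlab = "Prediction rank",
       ylab = "Cumulative fold change", main = main, ...)
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}

#' Average cumulative down-fold across miRNA tests
#'
#' F(n) summarizes consistency across several miRNA proteomics tests as the
#' average of the per-miRNA areas A_i(n). With `table6 = TRUE` the sum is
#' divided by twice the number of curves instead, matching an alternative
#' convention seen in published summary tables.
#'
#' @param curves list of `cumulative_curve` objects.
#' @param n rank at which to average; A(n) must be available in every curve.
#' @param table6 divide by 2M instead of M.
#' @return Scalar F(n).
#' @export
average_downfold <- function(curves, n, table6 = FALSE) {
  stopifnot(length(curves) >= 1L)
  vals <- vapply(curves, function(cu) {
    stopifnot(inherits(cu, "cumulative_curve"))
    v <- cu$A[as.character(n)]
    if (is.na(v)) stop("A(", n, ") is not available in every curve")
    unname(v)
  }, numeric(1))
  sum(vals) / (length(vals) * (1L + table6))
}
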