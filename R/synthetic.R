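#' Generate a labeled score table from a fusion model
#'
#' Draws records with exactly the statistical structure the fusion model
#' assumes: for each record the class y is Bernoulli(prior); independently
#' per tool the score indicator s_i is Bernoulli(tpr) for positives and
#' Bernoulli(fpr) for negatives; present scores are drawn from the tool's
#' class conditional density, absent ones are NA. A `mirfuse` model thus
#' doubles as its own generator specification, which is what lets the
#' training/fusion/evaluation pipeline be exercised end to end without any
#' external data. Fully reproducible from the seed.
#'
#' @param model a `mirfuse` model (the generating specification).
#' @param n number of records (at least 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param mirna_id miRNA identifier stamped on every record.
#' @return A labeled `score_table` with `n` records.
#' @export
generate_score_table <- function(model, n, seed = 1L,
                                 mirna_id = "miR-sim") {
  stopifnot(inherits(model, "mirfuse"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive record count")
  }
  n <- as.integer(n)
  K <- length(model$tools)
  with_seed(seed, {
    y <- as.integer(runif(n) < model$prior)
    scores <- matrix(NA_real_, n, K,
                     dimnames = list(NULL, names(model$tools)))
    for (j in seq_len(K)) {
      t <- model$tools[[j]]
      p_report <- ifelse(y == 1L, t$tpr, t$fpr)
      s <- runif(n) < p_report
      if (any(s & y == 1L)) {
        scores[s & y == 1L, j] <- rcond_density(t$pos, sum(s & y == 1L))
      }
      if (any(s & y == 0L)) {
        scores[s & y == 0L, j] <- rcond_density(t$neg, sum(s & y == 0L))
      }
    }
    score_table(rep(mirna_id, n), sprintf("G%06d", seq_len(n)), scores,
                label = y)
  })
}

#' Simulate score tables from a fusion model
#'
#' `simulate()` method wrapping [generate_score_table()].
#'
#' @param object a `mirfuse` model.
#' @param nsim number of tables to generate.
#' @param seed integer seed; table i uses `seed + i - 1`.
#' @param n records per table.
#' @param ... passed to [generate_score_table()].
#' @return A `score_table` if `nsim = 1`, otherwise a list of them.
#' @export
simulate.mirfuse <- function(object, nsim = 1, seed = 1L, n = 1000L, ...) {
  tabs <- lapply(seq_len(nsim), function(i) {
    generate_score_table(object, n = n, seed = seed + i - 1L, ...)
  })
  if (nsim == 1) tabs[[1L]] else tabs
}
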