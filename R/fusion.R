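clamp_rate <- function(p, floor = 1e-9) pmin(pmax(p, floor), 1 - floor)

#' Construct a fusion model directly from its components
#'
#' The fusion model is a Bayesian network over the target indicator y, the
#' per-tool score indicators s_i (does tool i report a score at all) and the
#' scores x_i. Given y the tools are conditionally independent, so the joint
#' likelihood factorizes over tools; each tool contributes either its fitted
#' score density times the probability of reporting, or — when the score is
#' missing — the probability of not reporting. This constructor is the
#' low-level entry point; [mirfuse()] builds the same object from a labeled
#' score table.
#'
#' @param prior prior target probability p(y = 1), in the open interval
#'   (0, 1).
#' @param tools list with one entry per tool, each a list with elements
#'   `name`, `pos` (a `cond_density` for the positive class), `neg` (for the
#'   negative class), `tpr` = p(s = 1 | y = 1), `fpr` = p(s = 1 | y = 0), and
#'   optionally `direction` (+1 if a higher raw score means a stronger
#'   predicted target, -1 otherwise; used only for single-tool ROC ranking).
#' @param rate_floor reporting rates are clamped to
#'   `[rate_floor, 1 - rate_floor]` before logs are taken, so a degenerate
#'   empirical rate of exactly 0 or 1 never produces an infinite log factor.
#' @return An object of class `mirfuse`.
#' @export
fusion_model <- function(prior, tools, rate_floor = 1e-9) {
  if (!is.numeric(prior) || length(prior) != 1L || prior <= 0 || prior >= 1) {
    stop("'prior' must be a single probability in (0, 1)")
  }
  tools <- lapply(tools, function(t) {
    stopifnot(is.character(t$name),
              inherits(t$pos, "cond_density"),
              inherits(t$neg, "cond_density"))
    if (t$tpr < 0 || t$tpr > 1 || t$fpr < 0 || t$fpr > 1) {
      stop("reporting rates must be in [0, 1] for tool ", t$name)
    }
    t$tpr <- clamp_rate(t$tpr, rate_floor)
    t$fpr <- clamp_rate(t$fpr, rate_floor)
    t$fnr <- 1 - t$tpr
    t$tnr <- 1 - t$fpr
    if (is.null(t$direction)) t$direction <- 1
    t
  })
  names(tools) <- vapply(tools, `[[`, character(1), "name")
  if (anyDuplicated(names(tools))) stop("duplicate tool names")
  structure(list(prior = prior, tools = tools, rate_floor = rate_floor,
                 call = sys.call(-1)),
            class = "mirfuse")
}

#' Per-tool log factor of the fusion likelihood
#'
#' The tool's contribution to log p(x_i | y): for a present score this is
#' log of the class score density times the class reporting rate; for a
#' missing score it is log of the class non-reporting rate. Exactly one term
#' of the marginalization over the score indicator survives, because a
#' reported score is impossible under s_i = 0 and a missing one is
#' impossible under s_i = 1.
#'
#' @param model a `mirfuse` model.
#' @param tool_index tool position in the model's canonical order.
#' @param score a single score, or NA for a missing score.
#' @param y class, 1 (target) or 0 (non-target).
#' @return Scalar log factor.
#' @export
tool_log_factor <- function(model, tool_index, score, y) {
  stopifnot(inherits(model, "mirfuse"), y %in% c(0, 1))
  t <- model$tools[[tool_index]]
  if (is.na(score)) {
    log(if (y == 1) t$fnr else t$tnr)
  } else {
    dens <- dcond(if (y == 1) t$pos else t$neg, score)
    log(dens) + log(if (y == 1) t$tpr else t$fpr)
  }
}

# Column-wise log factors for a score matrix; returns n x K matrices for
# both classes.
log_factor_matrix <- function(model, m) {
  K <- length(model$tools)
  L1 <- matrix(0, nrow(m), K)
  L0 <- matrix(0, nrow(m), K)
  for (j in seq_len(K)) {
    t <- model$tools[[j]]
    x <- m[, j]
    miss <- is.na(x)
    L1[miss, j] <- log(t$fnr)
    L0[miss, j] <- log(t$tnr)
    if (any(!miss)) {
      L1[!miss, j] <- log(dcond(t$pos, x[!miss])) + log(t$tpr)
      L0[!miss, j] <- log(dcond(t$neg, x[!miss])) + log(t$fpr)
    }
  }
  list(L1 = L1, L0 = L0)
}

posterior_from_logliks <- function(prior, l1, l0) {
  a <- log(prior) + l1
  b <- log1p(-prior) + l0
  m <- pmax(a, b)
  exp(a - m) / (exp(a - m) + exp(b - m))
}

#' Posterior target probability with per-tool detail
#'
#' Computes, for a single score vector, the posterior p(y = 1 | x) together
#' with the class log-likelihoods and each tool's log factors. All products
#' are taken as sums of logs with a log-sum-exp normalization, so six small
#' density factors cannot underflow.
#'
#' @param model a `mirfuse` model.
#' @param scores numeric vector with one entry per model tool; NA marks a
#'   missing score. The vector must cover every tool — missingness is
#'   informative, so an absent column cannot be defaulted.
#' @return A list with `posterior`, `loglik_pos`, `loglik_neg` and a
#'   `factors` data frame (tool, log_factor_pos, log_factor_neg).
#' @export
posterior_detail <- function(model, scores) {
  stopifnot(inherits(model, "mirfuse"))
  if (length(scores) != length(model$tools)) {
    stop("need one score (or NA) per model tool: expected ",
         length(model$tools), ", got ", length(scores))
  }
  L <- log_factor_matrix(model, matrix(as.numeric(scores), nrow = 1L))
  l1 <- sum(L$L1)
  l0 <- sum(L$L0)
  list(posterior = posterior_from_logliks(model$prior, l1, l0),
       loglik_pos = l1, loglik_neg = l0,
       factors = data.frame(tool = names(model$tools),
                            log_factor_pos = as.numeric(L$L1),
                            log_factor_neg = as.numeric(L$L0),
                            stringsAsFactors = FALSE))
}

#' Predict fused target posteriors for a score table
#'
#' @param object a `mirfuse` model.
#' @param newdata a `score_table` whose tool columns match the model's tools
#'   by name and order.
#' @param type `"posterior"` (default) returns the vector of posterior
#'   probabilities; `"loglik"` returns a two-column matrix of class
#'   log-likelihoods (excluding the prior).
#' @param ... unused.
#' @return Numeric vector (or matrix for `type = "loglik"`), one row/entry
#'   per record, in input order.
#' @export
predict.mirfuse <- function(object, newdata, type = c("posterior", "loglik"),
                            ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "score_table"))
  tools <- attr(newdata, "tool_names")
  if (!identical(tools, names(object$tools))) {
    stop("tool columns of 'newdata' (", paste(tools, collapse = ", "),
         ") do not match the model's tools (",
         paste(names(object$tools), collapse = ", "), ")")
  }
  m <- score_matrix(newdata)
  if (nrow(m) == 0L) {
    return(if (type == "posterior") numeric(0) else
      matrix(0, 0, 2, dimnames = list(NULL, c("loglik_pos", "loglik_neg"))))
  }
  L <- log_factor_matrix(object, m)
  l1 <- rowSums(L$L1)
  l0 <- rowSums(L$L0)
  if (type == "loglik") {
    return(cbind(loglik_pos = l1, loglik_neg = l0))
  }
  posterior_from_logliks(object$prior, l1, l0)
}

#' @export
print.mirfuse <- function(x, ...) {
  cat("Bayesian fusion model over", length(x$tools), "prediction tools\n")
  cat("  prior p(y=1):", format(x$prior), "\n")
  for (t in x$tools) {
    cat(sprintf("  %-14s pos: %-19s neg: %-19s tpr %.4f fpr %.4f\n",
                t$name, t$pos$family, t$neg$family, t$tpr, t$fpr))
  }
  invisible(x)
}

#' @export
summary.mirfuse <- function(object, ...) {
  rates <- coef(object)
  structure(list(prior = object$prior, rates = rates,
                 families = data.frame(
                   tool = names(object$tools),
                   positive = vapply(object$tools,
                                     function(t) t$pos$family, character(1)),
                   negative = vapply(object$tools,
                                     function(t) t$neg$family, character(1)),
                   n_fit_pos = vapply(object$tools,
                                      function(t) t$pos$n_fit, integer(1)),
                   n_fit_neg = vapply(object$tools,
                                      function(t) t$neg$n_fit, integer(1)),
                   row.names = NULL, stringsAsFactors = FALSE)),
            class = "summary.mirfuse")
}

#' @export
print.summary.mirfuse <- function(x, ...) {
  cat("Fusion model summary\n  prior p(y=1):", format(x$prior), "\n")
  cat("\nReporting rates p(s|y):\n")
  print(x$rates, digits = 4)
  cat("\nConditional density families:\n")
  print(x$families)
  invisible(x)
}

#' Model coefficients: prior and reporting rates
#'
#' @param object a `mirfuse` model.
#' @param ... unused.
#' @return A matrix with one row per tool (tpr, fnr, fpr, tnr) and the prior
#'   as attribute `prior`.
#' @export
coef.mirfuse <- function(object, ...) {
  m <- t(vapply(object$tools,
                function(t) c(tpr = t$tpr, fnr = t$fnr,
                              fpr = t$fpr, tnr = t$tnr),
                numeric(4)))
  attr(m, "prior") <- object$prior
  m
}

cond_to_list <- function(fc) {
  list(family = fc$family, params = lapply(fc$params, as.numeric),
       transform = lapply(fc$transform, as.numeric),
       n_fit = fc$n_fit, floor = fc$floor)
}

cond_from_list <- function(l) {
  new_cond_density(l$family, l$params, transform = l$transform %||% list(),
                   n_fit = l$n_fit %||% NA_integer_,
                   floor = l$floor %||% 1e-12)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fusion model to a human-readable YAML file
#'
#' @param model a `mirfuse` model.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mirfuse"))
  obj <- list(prior = model$prior, rate_floor = model$rate_floor,
              tools = lapply(unname(model$tools), function(t) {
                list(name = t$name, tpr = t$tpr, fpr = t$fpr,
                     direction = t$direction,
                     positive = cond_to_list(t$pos),
                     negative = cond_to_list(t$neg))
              }))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a fusion model written by [write_model()]
#'
#' @param path model file path.
#' @return A `mirfuse` model.
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  tools <- lapply(obj$tools, function(t) {
    list(name = t$name, tpr = t$tpr, fpr = t$fpr,
         direction = t$direction %||% 1,
         pos = cond_from_list(t$positive), neg = cond_from_list(t$negative))
  })
  fusion_model(obj$prior, tools, rate_floor = obj$rate_floor %||% 1e-9)
}
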