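#' Canonical tool order
#'
#' The six upstream prediction algorithms in the canonical order used
#' throughout the package: TargetScan, miRanda, PicTar, mirTarget, PITA,
#' Diana-microT. Serialized models and score tables are unambiguous only
#' under a fixed ordering, so this order is used everywhere a default is
#' needed.
#'
#' @return Character vector of length 6.
#' @export
mirfuse_tools <- function() {
  c("TargetScan", "miRanda", "PicTar", "mirTarget", "PITA", "Diana-microT")
}

#' Construct a score table
#'
#' A score table holds one row per (miRNA, gene) pair with one numeric score
#' column per prediction tool. A missing score (NA) means the tool did not
#' report the pair at all; missingness is informative in the fusion model and
#' is therefore part of the data, not an artifact to be imputed. An optional
#' label marks pairs with known target status (1 = target, 0 = non-target,
#' NA = unknown).
#'
#' @param mirna character vector of miRNA identifiers.
#' @param gene character vector of gene identifiers.
#' @param scores numeric matrix, one column per tool; NA marks a missing
#'   score. No infinities are allowed.
#' @param tool_names column (tool) names; defaults to `colnames(scores)`.
#' @param label optional vector of 0/1/NA class labels.
#' @return An object of class `score_table` (a data frame with columns
#'   `mirna`, `gene`, one per tool, and optionally `label`, plus a
#'   `tool_names` attribute).
#' @export
score_table <- function(mirna, gene, scores, tool_names = colnames(scores),
                        label = NULL) {
  scores <- as.matrix(scores)
  if (is.null(tool_names) || length(tool_names) != ncol(scores)) {
    stop("'tool_names' must name every score column")
  }
  mirna <- as.character(mirna)
  gene <- as.character(gene)
  if (length(mirna) != nrow(scores) || length(gene) != nrow(scores)) {
    stop("'mirna', 'gene' and 'scores' must have matching lengths")
  }
  storage.mode(scores) <- "double"
  if (any(is.infinite(scores))) stop("scores must be finite or NA")
  key <- paste(mirna, gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (miRNA, gene) pair: ", gsub("\r", " / ", dup))
  }
  df <- data.frame(mirna = mirna, gene = gene, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(tool_names)) df[[tool_names[j]]] <- scores[, j]
  if (!is.null(label)) {
    label <- as.integer(label)
    if (any(!label %in% c(0L, 1L) & !is.na(label))) {
      stop("labels must be 0, 1 or NA")
    }
    df$label <- label
  }
  structure(df, tool_names = as.character(tool_names),
            class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  tools <- attr(x, "tool_names")
  cat("Score table:", nrow(x), "pairs,", length(tools), "tools\n")
  cat("  tools:", paste(tools, collapse = ", "), "\n")
  if (!is.null(x$label)) {
    cat("  labels:", sum(x$label == 1L, na.rm = TRUE), "positive,",
        sum(x$label == 0L, na.rm = TRUE), "negative,",
        sum(is.na(x$label)), "unknown\n")
  }
  miss <- vapply(tools, function(t) mean(is.na(x[[t]])), numeric(1))
  cat("  missing fraction per tool:",
      paste(sprintf("%s %.2f", tools, miss), collapse = ", "), "\n")
  invisible(x)
}

#' Tool score columns as a matrix
#'
#' @param table a `score_table`.
#' @return Numeric matrix with one column per tool, NA for missing scores.
#' @export
score_matrix <- function(table) {
  stopifnot(inherits(table, "score_table"))
  m <- as.matrix(as.data.frame(table)[, attr(table, "tool_names"),
                                      drop = FALSE])
  rownames(m) <- NULL
  m
}

split_fields <- function(lines, path) {
  strsplit(lines, "\t", fixed = TRUE)
}

parse_score_cell <- function(cell, missing_tokens, line, column) {
  if (cell %in% missing_tokens) return(NA_real_)
  v <- suppressWarnings(as.numeric(cell))
  if (is.na(v) || !is.finite(v)) {
    stop(sprintf("line %d, column '%s': non-numeric score '%s'",
                 line, column, cell))
  }
  v
}

#' Read a tab-separated score table
#'
#' Expects a header line whose first two columns are the miRNA and gene
#' identifiers, followed by one column per tool and optionally a trailing
#' `label` column with values 0/1. Any cell equal to one of
#' `missing_tokens` becomes a missing score.
#'
#' @param path file path.
#' @param tool_names expected tool columns in order; if NULL they are taken
#'   from the header (all columns between the identifiers and any `label`
#'   column).
#' @param missing_tokens character vector of tokens that denote a missing
#'   score. Default `c("NA", "NaN", "")`.
#' @return A [score_table].
#' @export
read_score_table <- function(path, tool_names = NULL,
                             missing_tokens = c("NA", "NaN", "")) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  fields <- split_fields(lines, path)
  header <- fields[[1L]]
  if (length(header) < 3L) {
    stop("header must contain two identifier columns and at least one tool")
  }
  has_label <- header[length(header)] == "label"
  file_tools <- header[seq(3L, length(header) - has_label)]
  if (is.null(tool_names)) {
    tool_names <- file_tools
  } else if (!identical(as.character(tool_names), file_tools)) {
    stop("tool columns in file (", paste(file_tools, collapse = ", "),
         ") do not match 'tool_names'")
  }
  n <- length(lines) - 1L
  K <- length(tool_names)
  mirna <- character(n)
  gene <- character(n)
  scores <- matrix(NA_real_, n, K, dimnames = list(NULL, tool_names))
  label <- if (has_label) rep(NA_integer_, n) else NULL
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != length(header)) {
      stop(sprintf("line %d: expected %d columns, found %d",
                   i + 1L, length(header), length(f)))
    }
    mirna[i] <- f[1L]
    gene[i] <- f[2L]
    for (j in seq_len(K)) {
      scores[i, j] <- parse_score_cell(f[2L + j], missing_tokens,
                                       i + 1L, tool_names[j])
    }
    if (has_label) {
      lab <- f[length(f)]
      if (lab %in% missing_tokens) {
        label[i] <- NA_integer_
      } else if (lab %in% c("0", "1")) {
        label[i] <- as.integer(lab)
      } else {
        stop(sprintf("line %d: label must be 0 or 1, found '%s'", i + 1L, lab))
      }
    }
  }
  score_table(mirna, gene, scores, tool_names = tool_names, label = label)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))

#' Write a score table
#'
#' Writes the TSV format read by [read_score_table()]; numeric values keep
#' 15 significant digits so a write/read round trip is lossless to well
#' beyond 12 significant digits.
#'
#' @param table a `score_table`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  tools <- attr(table, "tool_names")
  has_label <- !is.null(table$label)
  header <- c("mirna", "gene", tools, if (has_label) "label")
  m <- score_matrix(table)
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(table$mirna[i], table$gene[i], fmt_num(m[i, ]),
            if (has_label) ifelse(is.na(table$label[i]), "NA",
                                  as.character(table$label[i]))),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Write predictions alongside the input scores
#'
#' Appends a `posterior` column (the fused target probability) to the score
#' table and writes the result as TSV.
#'
#' @param table a `score_table`.
#' @param posteriors numeric vector of posterior probabilities in \[0, 1\],
#'   one per record.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(table, posteriors, path) {
  stopifnot(inherits(table, "score_table"))
  if (length(posteriors) != nrow(table)) {
    stop("need one posterior per record: got ", length(posteriors),
         " for ", nrow(table), " records")
  }
  if (any(!is.finite(posteriors)) || any(posteriors < 0 | posteriors > 1)) {
    stop("posteriors must be finite and in [0, 1]")
  }
  tools <- attr(table, "tool_names")
  has_label <- !is.null(table$label)
  header <- c("mirna", "gene", tools, if (has_label) "label", "posterior")
  m <- score_matrix(table)
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(table$mirna[i], table$gene[i], fmt_num(m[i, ]),
            if (has_label) ifelse(is.na(table$label[i]), "NA",
                                  as.character(table$label[i])),
            sprintf("%.10g", posteriors[i])),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a gene-to-fold-change table
#'
#' Two tab-separated columns: gene identifier and (typically log-scale)
#' protein fold change. Used by the ranked cumulative down-fold evaluation.
#'
#' @param path file path.
#' @return A data frame of class `fold_change_table` with columns `gene`
#'   and `fold_change`.
#' @export
read_fold_change_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  fields <- split_fields(lines, path)
  n <- length(lines) - 1L
  gene <- character(n)
  fc <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != 2L) {
      stop(sprintf("line %d: expected 2 columns, found %d", i + 1L, length(f)))
    }
    gene[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(v) || !is.finite(v)) {
      stop(sprintf("line %d: non-finite fold change '%s'", i + 1L, f[2L]))
    }
    fc[i] <- v
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene: ", gene[duplicated(gene)][1L])
  }
  structure(data.frame(gene = gene, fold_change = fc,
                       stringsAsFactors = FALSE),
            class = c("fold_change_table", "data.frame"))
}
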