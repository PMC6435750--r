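## Pairwise percent identity over aligned V4 sequences, inter-/intra-clade
## identity summaries and the OTU identity-threshold lumping analysis.

## round half-up, to match the one-decimal convention of reported
## identities (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent identity of two aligned sequences
#'
#' In `all_columns` mode the denominator is the full alignment length and a
#' column matches when both sequences carry the same character (including
#' gap-gap). In `ungapped_pair_columns` mode (the common metabarcoding
#' convention, the default) columns where either sequence has a gap are
#' excluded from numerator and denominator.
#'
#' @param a,b Aligned sequences (equal-length strings); case-insensitive.
#' @param gap_mode `"ungapped_pair_columns"` (default) or `"all_columns"`.
#' @return Percent identity in `[0, 100]`, full precision (round for
#'   reporting with [round_identity()]).
#' @export
percent_identity <- function(a, b,
                             gap_mode = c("ungapped_pair_columns",
                                          "all_columns")) {
  gap_mode <- match.arg(gap_mode)
  if (nchar(a) != nchar(b)) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (gap_mode == "ungapped_pair_columns") {
    keep <- !(ca %in% GAP_CHARS) & !(cb %in% GAP_CHARS)
    if (!any(keep)) {
      stop("no comparable columns (all gapped): identity undefined",
           call. = FALSE)
    }
    100 * sum(ca[keep] == cb[keep]) / sum(keep)
  } else {
    100 * sum(ca == cb) / length(ca)
  }
}

#' Round an identity to the reporting precision
#' @param x Percent identity value(s).
#' @return Value rounded half-up to one decimal.
#' @export
round_identity <- function(x) round_half_up(x, 1)

#' Pairwise identity matrix over an alignment
#'
#' @param alignment A `pc_alignment` (>= 2 sequences).
#' @param gap_mode Passed to [percent_identity()].
#' @return Symmetric numeric matrix of percent identities with a `gap_mode`
#'   attribute; diagonal is 100.
#' @export
identity_matrix <- function(alignment,
                            gap_mode = c("ungapped_pair_columns",
                                         "all_columns")) {
  gap_mode <- match.arg(gap_mode)
  n <- length(alignment)
  if (n < 2) stop("identity matrix needs >= 2 sequences", call. = FALSE)
  ids <- names(alignment)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- percent_identity(alignment[[i]], alignment[[j]], gap_mode)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  attr(m, "gap_mode") <- gap_mode
  m
}

#' Between- and within-clade identity summary
#'
#' @param matrix An [identity_matrix()] result.
#' @param labels Named character vector, sequence id -> clade; every id in
#'   the matrix must be labelled.
#' @return List of class `clade_identity_summary` with `between` (data.frame
#'   `clade_a`, `clade_b`, `max_identity`, `mean_identity` over all
#'   cross-clade pairs) and `within` (data.frame `clade`, `n`,
#'   `min_identity`; `NA` for singleton clades, by contract distinct from 0).
#' @export
clade_identity_summary <- function(matrix, labels) {
  ids <- rownames(matrix)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) stop("unlabelled sequence id(s): ",
                         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  cl <- labels[ids]
  clades <- sort(unique(cl))
  between <- NULL
  if (length(clades) >= 2) {
    pairs <- utils::combn(clades, 2)
    between <- data.frame(
      clade_a = pairs[1, ], clade_b = pairs[2, ],
      max_identity = NA_real_, mean_identity = NA_real_,
      stringsAsFactors = FALSE
    )
    for (k in seq_len(ncol(pairs))) {
      v <- matrix[cl == pairs[1, k], cl == pairs[2, k], drop = FALSE]
      between$max_identity[k] <- max(v)
      between$mean_identity[k] <- mean(v)
    }
  }
  within <- data.frame(clade = clades,
                       n = as.integer(table(cl)[clades]),
                       min_identity = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(clades)) {
    sub <- matrix[cl == clades[k], cl == clades[k], drop = FALSE]
    if (nrow(sub) >= 2) {
      within$min_identity[k] <- min(sub[upper.tri(sub)])
    }
  }
  structure(list(between = between, within = within),
            class = "clade_identity_summary")
}

#' @export
print.clade_identity_summary <- function(x, ...) {
  cat("clade identity summary\n between-clade pairs:\n")
  print(x$between, row.names = FALSE)
  cat(" within-clade:\n")
  print(x$within, row.names = FALSE)
  invisible(x)
}

#' OTU-threshold lumping report
#'
#' A clade pair is "lumped" at a given OTU identity threshold when the
#' maximum identity over any cross-clade sequence pair reaches the threshold
#' (single-linkage criterion, mirroring greedy OTU clustering): such clades
#' cannot be discriminated by OTUs built at that threshold.
#'
#' @param summary A [clade_identity_summary()] result.
#' @param threshold_pct Identity threshold in percent (default 99).
#' @return data.frame `clade_a`, `clade_b`, `max_between_identity`,
#'   `lumped`, with attribute `threshold_pct`.
#' @export
otu_lumping <- function(summary, threshold_pct = 99.0) {
  b <- summary$between
  if (is.null(b)) stop("summary has fewer than 2 clades", call. = FALSE)
  res <- data.frame(clade_a = b$clade_a, clade_b = b$clade_b,
                    max_between_identity = b$max_identity,
                    lumped = b$max_identity >= threshold_pct,
                    stringsAsFactors = FALSE)
  attr(res, "threshold_pct") <- threshold_pct
  res
}
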