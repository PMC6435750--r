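## ASV core: read quality filters, exact-sequence dereplication into
## amplicon single variants (ASVs), major-ASV selection, cross-dataset
## confirmation, and read grouping by taxon.

#' Quality-filter amplicon reads
#'
#' Retains reads strictly longer than `min_len` and free of ambiguities.
#' By default only `N`/`n` counts as an ambiguity, matching the usual
#' metabarcoding filter; `ambiguity = "any"` extends the rule to every
#' IUPAC degeneracy code.
#'
#' @param reads Named character vector of read sequences.
#' @param min_len Minimum length; reads of exactly `min_len` are removed
#'   (the criterion is "longer than").
#' @param ambiguity `"N"` (default) or `"any"`.
#' @return List with `reads` (retained, order preserved) and `log`, a
#'   data.frame of removal counts by reason (`ambiguous`, `too_short`) plus
#'   the retained count. A read failing both tests is counted once, under
#'   `ambiguous`.
#' @export
quality_filter <- function(reads, min_len = 300, ambiguity = c("N", "any")) {
  ambiguity <- match.arg(ambiguity)
  pat <- if (ambiguity == "N") "[Nn]" else "[^ACGTUacgtu.-]"
  has_amb <- grepl(pat, reads)
  too_short <- nchar(reads) <= min_len
  keep <- !has_amb & !too_short
  log <- data.frame(
    reason = c("ambiguous", "too_short", "retained"),
    n = c(sum(has_amb), sum(too_short & !has_amb), sum(keep))
  )
  pc_log("quality_filter: %d reads in, %d retained (%d ambiguous, %d too short)",
         length(reads), sum(keep), sum(has_amb), sum(too_short & !has_amb))
  list(reads = reads[keep], log = log)
}

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA `U` to `T` and strips gap characters (`-`, `.`).
#' Idempotent. Errors on any character outside the IUPAC alphabet.
#'
#' @param sequence Character vector of sequences.
#' @return Normalized sequences (names preserved).
#' @export
normalize_sequence <- function(sequence) {
  out <- gsub("[.-]", "", toupper(sequence))
  out <- chartr("U", "T", out)
  .check_iupac(setNames(out, names(sequence)))
  setNames(out, names(sequence))
}

#' Dereplicate reads into an ASV table
#'
#' One ASV per distinct (already normalized) sequence; per-sample counts are
#' the multiplicity of that sequence in that sample. ASV ids are assigned by
#' descending total reads, ties broken by sequence lexicographic order, and
#' formatted `ASV_<dataset>_<rank>` with a zero-padded rank.
#'
#' @param reads Character vector of normalized read sequences.
#' @param samples Character vector of sample ids, parallel to `reads`.
#' @param dataset_label Dataset tag, e.g. `"LGC"`.
#' @return An `asv_table`: list with `dataset_label`, `sequences` (named by
#'   asv_id), `counts` (integer matrix asv x sample) and optional
#'   `assignment`.
#' @export
dereplicate <- function(reads, samples, dataset_label) {
  stopifnot(length(reads) == length(samples))
  if (length(reads) == 0) {
    return(asv_table(dataset_label, character(0),
                     matrix(0L, 0, 0, dimnames = list(NULL, NULL))))
  }
  tab <- table(factor(reads), factor(samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  tot <- rowSums(counts)
  ord <- order(-tot, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  seqs <- rownames(counts)
  ids <- sprintf("ASV_%s_%05d", dataset_label, seq_along(seqs))
  rownames(counts) <- ids
  pc_log("dereplicate: %d reads -> %d ASVs (%s)", length(reads),
         length(ids), dataset_label)
  asv_table(dataset_label, setNames(seqs, ids), counts)
}

#' Construct an ASV table
#' @param dataset_label Dataset tag.
#' @param sequences Named character vector, names = asv ids; must be unique.
#' @param counts Integer matrix asv x sample, rownames = asv ids.
#' @param assignment Optional named character vector, asv id -> taxon path.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(dataset_label, sequences, counts, assignment = NULL) {
  if (length(sequences) && anyDuplicated(sequences)) {
    stop("duplicate sequence in ASV table", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative count in ASV table", call. = FALSE)
  if (length(sequences) && !identical(names(sequences), rownames(counts))) {
    stop("sequence names and count rownames disagree", call. = FALSE)
  }
  structure(list(dataset_label = dataset_label, sequences = sequences,
                 counts = counts, assignment = assignment),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table '%s': %d ASVs x %d samples, %d reads\n",
              x$dataset_label, nrow(x$counts), ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Total reads per ASV
#' @param x An `asv_table` or a count matrix.
#' @return Named numeric vector of row totals.
#' @export
asv_totals <- function(x) {
  counts <- if (inherits(x, "asv_table")) x$counts else x
  rowSums(counts)
}

#' Select major ASVs by total read count
#'
#' Retains ASVs whose total reads are greater than or equal to `min_reads`
#' (inclusive boundary), reordered by descending total.
#'
#' @param table An `asv_table` or a count matrix (rows = ASVs).
#' @param min_reads Inclusive minimum total reads (default 200).
#' @return Subset of the same type, ordered by descending total reads.
#' @export
select_major <- function(table, min_reads = 200) {
  counts <- if (inherits(table, "asv_table")) table$counts else table
  tot <- rowSums(counts)
  keep <- which(tot >= min_reads)
  keep <- keep[order(-tot[keep], rownames(counts)[keep])]
  pc_log("select_major: %d of %d ASVs at >= %d reads", length(keep),
         nrow(counts), min_reads)
  if (inherits(table, "asv_table")) {
    asv_table(table$dataset_label, table$sequences[keep],
              counts[keep, , drop = FALSE],
              if (!is.null(table$assignment)) {
                table$assignment[intersect(names(table$assignment),
                                           rownames(counts)[keep])]
              })
  } else {
    counts[keep, , drop = FALSE]
  }
}

#' Confirm ASVs across two independently processed datasets
#'
#' In `exact` mode an ASV is confirmed iff a strictly identical sequence
#' exists in the other table. `containment` mode also accepts one sequence
#' being a substring of the other, tolerating trimming differences between
#' independently processed datasets.
#'
#' @param major An `asv_table` of (typically major) ASVs to confirm.
#' @param other The other dataset's `asv_table`.
#' @param mode `"exact"` (default) or `"containment"`.
#' @return data.frame with `asv_id`, `confirmed`, and `matches`
#'   (comma-separated ids of matching ASVs in `other`).
#' @export
cross_confirm <- function(major, other, mode = c("exact", "containment")) {
  mode <- match.arg(mode)
  qs <- major$sequences
  os <- other$sequences
  matches <- lapply(qs, function(s) {
    if (mode == "exact") {
      names(os)[os == s]
    } else {
      hit <- vapply(os, function(o) {
        grepl(s, o, fixed = TRUE) || grepl(o, s, fixed = TRUE)
      }, logical(1))
      names(os)[hit]
    }
  })
  res <- data.frame(
    asv_id = names(qs),
    confirmed = lengths(matches) > 0,
    matches = vapply(matches, paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pc_log("cross_confirm (%s): %d of %d confirmed", mode,
         sum(res$confirmed), nrow(res))
  res
}

#' Sum ASV reads by taxon label
#'
#' @param table An `asv_table` or count matrix (rows = ASV ids).
#' @param labels Named character vector, asv id -> taxon label. Every row of
#'   `table` must be labelled.
#' @return Named numeric vector of total reads per taxon.
#' @export
group_reads_by_taxon <- function(table, labels) {
  counts <- if (inherits(table, "asv_table")) table$counts else table
  ids <- rownames(counts)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) {
    stop("unlabelled ASV id(s): ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  tot <- rowSums(counts)
  tapply(tot, factor(labels[ids]), sum)[]
}
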