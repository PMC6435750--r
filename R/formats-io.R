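## Readers and writers for the external formats the pipeline touches:
## FASTA / aligned FASTA, TSV count tables, TSV sample metadata, newick
## trees with support labels, and a flat key=value config dialect.
## All alignment positions in the external contract are 1-based columns.

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
GAP_CHARS <- c("-", ".")

## gap chars placed unescaped at the end of the class ('-' last)
.seq_regex <- paste0("^[", paste(IUPAC_CODES, collapse = ""), ".-]*$")

.check_iupac <- function(seqs, where = "sequence") {
  up <- toupper(seqs)
  bad <- !grepl(.seq_regex, up)
  if (any(bad)) {
    id <- names(seqs)[which(bad)[1]]
    chars <- strsplit(up[which(bad)[1]], "")[[1]]
    pos <- which(!chars %in% c(IUPAC_CODES, GAP_CHARS))[1]
    stop(sprintf("non-IUPAC character '%s' in %s '%s' at position %d",
                 chars[pos], where, if (is.null(id)) "?" else id, pos),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' Reads plain or aligned FASTA. Records are preserved verbatim (case and
#' order kept; normalisation is a separate step, see [normalize_sequence()]).
#' With `aligned = TRUE` all sequences must have equal length and the result
#' carries the alignment length as an attribute.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; if `TRUE`, enforce equal sequence lengths and
#'   return an alignment.
#' @return A named character vector of sequences. When `aligned = TRUE` it
#'   has class `pc_alignment` and an attribute `aln_length` (columns).
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1], call. = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence in ", path, call. = FALSE)
  .check_iupac(seqs)
  if (aligned) seqs <- as_alignment(seqs) else seqs
}

#' Coerce named sequences to an alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return The vector with class `pc_alignment` and attribute `aln_length`.
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) == 0) stop("empty alignment", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop(sprintf("alignment shape error: sequence lengths differ (%s)",
                 paste(sort(w), collapse = ", ")), call. = FALSE)
  }
  structure(seqs, class = c("pc_alignment", "character"), aln_length = w)
}

#' Alignment length in columns
#' @param aln A `pc_alignment`.
#' @return Integer number of columns.
#' @export
aln_length <- function(aln) {
  w <- attr(aln, "aln_length")
  if (is.null(w)) w <- unique(nchar(aln))
  as.integer(w)
}

## character matrix view of an alignment (rows = sequences, uppercase)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(unclass(aln)), ""))
  rownames(m) <- names(aln)
  m
}

#' Write sequences to FASTA
#' @param seqs Named character vector (aligned or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(setNames(unclass(seqs), names(seqs)))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a TSV read-count table
#'
#' First column holds sequence (ASV) ids, remaining columns one sample each.
#' Empty cells are read as 0. Cells must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, rows = sequence ids, columns = samples.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L) stop("count table needs an id column plus >=1 sample",
                          call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate sequence id in count table: ",
                               ids[duplicated(ids)][1], call. = FALSE)
  samples <- colnames(df)[-1]
  m <- matrix(0L, nrow = nrow(df), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cell <- trimws(df[[j + 1L]])
    cell[cell == "" | is.na(cell)] <- "0"
    num <- suppressWarnings(as.numeric(cell))
    bad <- is.na(num) | num < 0 | num != floor(num)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "count table format error: cell (row '%s', sample '%s') = '%s' is not a non-negative integer",
        ids[i], samples[j], cell[i]), call. = FALSE)
    }
    m[, j] <- as.integer(num)
  }
  m
}

#' Write a count matrix as TSV
#' @param counts Integer matrix, rows = sequence ids, columns = samples.
#' @param path Output path.
#' @param id_col Name for the id column header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_col = "asv_id") {
  ids <- rownames(counts)
  if (is.null(ids)) ids <- character(0)
  df <- data.frame(ids, counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects tab-separated columns `sample_id`, `latitude`, `longitude`,
#' `group_total_reads`, and optionally logical flags `med_sea` and `lagoon`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with validated columns.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "latitude", "longitude", "group_total_reads")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata",
                                        call. = FALSE)
  if (any(abs(df$latitude) > 90)) stop("latitude out of [-90, 90]",
                                       call. = FALSE)
  if (any(abs(df$longitude) > 180)) stop("longitude out of [-180, 180]",
                                         call. = FALSE)
  if (any(df$group_total_reads < 0)) stop("negative group_total_reads",
                                          call. = FALSE)
  df
}

#' Read a newick tree with optional support labels
#'
#' Internal node labels parseable as numbers are interpreted as edge supports
#' (bootstrap percents or posterior probabilities; the scale is declared by
#' the caller, never guessed from the values).
#'
#' @param path Path to a newick file.
#' @param scale Support scale: `"percent"` (bootstrap, 0-100) or
#'   `"probability"` (posterior, 0-1).
#' @return A `supported_tree`: list with elements `phylo` (an [ape::read.tree]
#'   phylo object) and `scale`.
#' @export
read_newick <- function(path, scale = c("percent", "probability")) {
  scale <- match.arg(scale)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("newick parse error in ", path, call. = FALSE)
  supported_tree(tr, scale)
}

#' Construct a supported tree from a phylo object
#' @param phylo An [ape] `phylo` object; numeric internal node labels are
#'   taken as supports.
#' @param scale `"percent"` or `"probability"`.
#' @return A `supported_tree` object.
#' @export
supported_tree <- function(phylo, scale = c("percent", "probability")) {
  scale <- match.arg(scale)
  if (!inherits(phylo, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(phylo$tip.label)) {
    stop("duplicate leaf name: ",
         phylo$tip.label[duplicated(phylo$tip.label)][1], call. = FALSE)
  }
  structure(list(phylo = phylo, scale = scale), class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  sup <- node_supports(x)
  cat(sprintf("supported_tree: %d leaves, %d internal supports (%s scale)\n",
              length(x$phylo$tip.label), sum(!is.na(sup)), x$scale))
  invisible(x)
}

## numeric support per internal node (NA where no parseable label)
node_supports <- function(tree) {
  ph <- tree$phylo
  n_int <- ph$Nnode
  lab <- ph$node.label
  if (is.null(lab)) return(rep(NA_real_, n_int))
  suppressWarnings(as.numeric(lab))
}

#' Write a supported tree to newick
#' @param tree A `supported_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Pipeline configuration with the study's default thresholds
#'
#' Defaults are the thresholds used throughout the analysis: ASVs are major
#' at >= 200 total reads, samples retained at >= 100 group reads, presence
#' at >= 1% relative abundance, clade support demanded above 70% bootstrap,
#' OTU lumping judged at the 99% identity threshold.
#'
#' @param min_asv_reads Minimum total reads for a major ASV (inclusive).
#' @param min_sample_group_reads Minimum group reads for a retained sample
#'   (inclusive).
#' @param presence_threshold_pct Relative-abundance presence threshold, in
#'   percent (inclusive boundary).
#' @param min_bootstrap Bootstrap threshold in percent (strict, i.e. support
#'   must exceed it).
#' @param otu_identity_threshold_pct OTU identity threshold in percent.
#' @param random_seed Integer seed for the synthetic-data generators.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_asv_reads = 200,
                            min_sample_group_reads = 100,
                            presence_threshold_pct = 1.0,
                            min_bootstrap = 70,
                            otu_identity_threshold_pct = 99.0,
                            random_seed = 42L) {
  cfg <- list(min_asv_reads = min_asv_reads,
              min_sample_group_reads = min_sample_group_reads,
              presence_threshold_pct = presence_threshold_pct,
              min_bootstrap = min_bootstrap,
              otu_identity_threshold_pct = otu_identity_threshold_pct,
              random_seed = as.integer(random_seed))
  num <- unlist(cfg[1:5])
  if (any(num < 0)) stop("config thresholds must be non-negative",
                         call. = FALSE)
  pct <- c(cfg$presence_threshold_pct, cfg$min_bootstrap,
           cfg$otu_identity_threshold_pct)
  if (any(pct > 100)) stop("config percents must be in [0, 100]",
                           call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value config file
#'
#' Lines of the form `key = value`; `#` starts a comment; unknown keys are
#' an error. Values override the defaults of [pipeline_config()].
#'
#' @param path Path to the config file.
#' @param base Config to override (default [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, base = pipeline_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- as.list(unclass(base))
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("config syntax error: '", ln, "'",
                               call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(vals)) stop("unknown config key: ", key,
                                    call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("config value for ", key, " is not numeric",
                         call. = FALSE)
    vals[[key]] <- num
  }
  do.call(pipeline_config, vals)
}
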