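#' Published major Mamiellophyceae ASV summary table
#'
#' The published per-ASV read totals and taxonomic assignments of the major
#' Mamiellophyceae ASVs (>= 200 reads) of the two 2014 Ocean Sampling Day
#' V4 renditions (LGC and LW), shipped as a plain-text fixture. Serves as
#' the worked input for the table-parsing, major-ASV selection and
#' taxon-grouping path.
#'
#' @param dataset `"LGC"`, `"LW"` or `"both"` (default).
#' @return List with `counts` (integer matrix, one `reads` column) and
#'   `taxa` (data.frame `asv_id`, `dataset`, `genus`, `taxon`), restricted
#'   to the requested dataset.
#' @export
major_asv_table <- function(dataset = c("both", "LGC", "LW")) {
  dataset <- match.arg(dataset)
  counts <- read_count_table(system.file(
    "extdata", "mamiello_major_asv_counts.tsv", package = "picoclade",
    mustWork = TRUE))
  taxa <- read.delim(system.file(
    "extdata", "mamiello_major_asv_taxa.tsv", package = "picoclade",
    mustWork = TRUE), sep = "\t", stringsAsFactors = FALSE)
  if (dataset != "both") {
    taxa <- taxa[taxa$dataset == dataset, , drop = FALSE]
    counts <- counts[taxa$asv_id, , drop = FALSE]
  }
  list(counts = counts, taxa = taxa)
}
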