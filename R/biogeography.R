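## Relative-abundance biogeography: sample floor, percent-of-group-reads
## abundances, presence masks, prevalence counts and latitudinal habitat
## summaries.

#' Filter samples by group read total
#'
#' Retains samples with at least `min_group_reads` group (e.g.
#' Mamiellophyceae) reads. The boundary is inclusive.
#'
#' @param meta Sample metadata data.frame (see [read_sample_meta()]).
#' @param min_group_reads Inclusive floor (default 100).
#' @return Subset of `meta`.
#' @export
filter_samples <- function(meta, min_group_reads = 100) {
  keep <- meta$group_total_reads >= min_group_reads
  pc_log("filter_samples: %d of %d samples at >= %d group reads",
         sum(keep), nrow(meta), min_group_reads)
  meta[keep, , drop = FALSE]
}

#' Relative abundance as percent of group reads
#'
#' Percent of each ASV's (or taxon's) reads relative to the sample's total
#' group reads. Samples must be pre-filtered; a zero group total among them
#' is an error, not a silent NaN.
#'
#' @param counts Numeric matrix, ASV/taxon x sample read counts.
#' @param group_totals Named numeric vector of group totals; names must
#'   cover the columns of `counts` and each total must be at least the
#'   column sum.
#' @return Numeric matrix of percents in `[0, 100]`, class
#'   `abundance_table`.
#' @export
relative_abundance <- function(counts, group_totals) {
  samples <- colnames(counts)
  miss <- setdiff(samples, names(group_totals))
  if (length(miss)) stop("missing group total for sample: ", miss[1],
                         call. = FALSE)
  gt <- group_totals[samples]
  if (any(gt == 0)) {
    stop("group total is 0 for sample '", samples[which(gt == 0)[1]],
         "' - it should have been filtered out", call. = FALSE)
  }
  if (any(colSums(counts) > gt + 1e-9)) {
    bad <- samples[which(colSums(counts) > gt + 1e-9)[1]]
    stop("counts exceed group total in sample '", bad, "'", call. = FALSE)
  }
  ab <- sweep(counts, 2, gt, "/") * 100
  structure(ab, class = c("abundance_table", class(ab)))
}

#' Pool ASV abundances by taxon
#'
#' Sums per-ASV percents into per-taxon percents (e.g. the three
#' *O. tauri* ASVs viewed as one species). Pooling happens before presence
#' thresholding by default in the downstream summary.
#'
#' @param abundance Matrix from [relative_abundance()] (or counts).
#' @param labels Named character vector, row id -> taxon.
#' @return Matrix taxon x sample.
#' @export
pool_by_taxon <- function(abundance, labels) {
  ids <- rownames(abundance)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) stop("unlabelled row id(s): ",
                         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  grp <- factor(labels[ids])
  out <- rowsum(unclass(abundance), grp)
  out[levels(grp), , drop = FALSE]
}

#' Presence mask at a relative-abundance threshold
#'
#' Present iff abundance is at least `threshold_pct`: contributions "lower
#' than" the threshold are marked absent, so an abundance exactly at the
#' boundary counts as present.
#'
#' @param table Matrix of percent abundances.
#' @param threshold_pct Presence threshold in percent (default 1).
#' @return Logical matrix of the same shape.
#' @export
presence_mask <- function(table, threshold_pct = 1.0) {
  m <- unclass(table) >= threshold_pct
  attr(m, "threshold_pct") <- threshold_pct
  m
}

#' Prevalence: number of samples where each taxon is present
#'
#' @param mask Logical matrix from [presence_mask()].
#' @return Named integer vector of per-taxon sample counts.
#' @export
prevalence <- function(mask) {
  res <- rowSums(mask)
  storage.mode(res) <- "integer"
  res
}

#' Default latitudinal band edges (degrees absolute latitude)
#'
#' Conventional oceanographic cut-offs; these edges are an implementation
#' choice, not taken from any reference: polar at and above 66.5 deg
#' (the polar circles), subpolar 55-66.5, temperate 35-55, tropical
#' below 35.
#' @return Named numeric vector of lower edges for polar, subpolar and
#'   temperate bands.
#' @export
default_band_edges <- function() c(polar = 66.5, subpolar = 55, temperate = 35)

#' Assign absolute latitudes to bands
#' @param latitude Numeric latitudes in degrees.
#' @param band_edges Lower edges as in [default_band_edges()].
#' @return Factor with levels polar, subpolar, temperate, tropical.
#' @export
latitude_band <- function(latitude, band_edges = default_band_edges()) {
  a <- abs(latitude)
  band <- ifelse(a >= band_edges[["polar"]], "polar",
          ifelse(a >= band_edges[["subpolar"]], "subpolar",
          ifelse(a >= band_edges[["temperate"]], "temperate", "tropical")))
  factor(band, levels = c("polar", "subpolar", "temperate", "tropical"))
}

#' Habitat summary per taxon
#'
#' For each taxon: the number of samples where it is present (above the
#' presence threshold), the latitudinal bands those samples span (by
#' absolute latitude, both hemispheres treated alike), and Mediterranean /
#' lagoon flags taken from optional metadata columns `med_sea` and
#' `lagoon` (never inferred from coordinates).
#'
#' @param mask Logical taxon x sample matrix from [presence_mask()].
#' @param meta Sample metadata including `latitude` for every present
#'   sample.
#' @param band_edges Band edges (see [default_band_edges()]).
#' @return data.frame of class `habitat_summary`: `taxon`,
#'   `n_samples_present`, `polar`, `subpolar`, `temperate`, `tropical`,
#'   `med_sea`, `lagoon`.
#' @export
habitat_summary <- function(mask, meta, band_edges = default_band_edges()) {
  samples <- colnames(mask)
  meta_idx <- match(samples, meta$sample_id)
  present_any <- colSums(mask) > 0
  if (any(present_any & is.na(meta_idx))) {
    stop("no metadata (latitude) for present sample '",
         samples[which(present_any & is.na(meta_idx))[1]], "'",
         call. = FALSE)
  }
  lat <- meta$latitude[meta_idx]
  if (any(present_any & is.na(lat))) {
    stop("missing latitude for present sample '",
         samples[which(present_any & is.na(lat))[1]], "'", call. = FALSE)
  }
  band <- latitude_band(lat, band_edges)
  med <- if ("med_sea" %in% colnames(meta)) {
    as.logical(meta$med_sea[meta_idx])
  } else rep(FALSE, length(samples))
  lag <- if ("lagoon" %in% colnames(meta)) {
    as.logical(meta$lagoon[meta_idx])
  } else rep(FALSE, length(samples))
  rows <- lapply(rownames(mask), function(tx) {
    p <- mask[tx, ]
    data.frame(taxon = tx, n_samples_present = sum(p),
               polar = any(p & band == "polar"),
               subpolar = any(p & band == "subpolar"),
               temperate = any(p & band == "temperate"),
               tropical = any(p & band == "tropical"),
               med_sea = any(p & med %in% TRUE),
               lagoon = any(p & lag %in% TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("habitat_summary", "data.frame")
  out
}
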