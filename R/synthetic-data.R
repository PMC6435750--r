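## Synthetic-data generator: reference clades separated by planted
## diagnostic alignment columns, samples with rectangular latitudinal
## niches and sparse co-occurrence, and paired read datasets sharing the
## same true haplotypes with independent per-base substitution errors.
## Every generator is deterministic given its seed and emits ground truth
## for recovery tests.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.BASES <- c("A", "C", "G", "T")

#' Generate a clade-labelled reference alignment with planted signatures
#'
#' Builds `k` clades over a shared random background sequence. Each clade
#' owns `n_diag` diagnostic columns where all its members carry a state
#' found in no other clade; at a column owned by another clade, members
#' alternate between two background states, so each column is diagnostic
#' only for its owner. Intra-clade variation is placed at background
#' columns only. Alignment lengths of real V4 alignments of this kind run
#' about 330-370 columns; the default is 341.
#'
#' @param k Number of clades (>= 2).
#' @param columns Alignment length (default 341).
#' @param n_diag Diagnostic columns per clade (>= 1; `k * n_diag < columns`).
#' @param members_per_clade Reference sequences per clade (>= 2).
#' @param intra_variants Background columns per clade carrying intra-clade
#'   variation (default 2).
#' @param seed Integer seed.
#' @return List with `alignment` (a `pc_alignment`), `labels` (member id ->
#'   clade) and `truth` (class `synthetic_truth`: consensus per clade,
#'   planted `diagnostic_positions`, unique `haplotypes` per clade, seed).
#' @export
gen_reference_clades <- function(k = 5, columns = 341, n_diag = 2,
                                 members_per_clade = 4, intra_variants = 2,
                                 seed = 42L) {
  if (k < 2 || n_diag < 1 || k * n_diag >= columns ||
      members_per_clade < 2 || intra_variants < 0 ||
      k * n_diag + k * intra_variants > columns) {
    stop("infeasible parameter combination", call. = FALSE)
  }
  .with_seed(seed, {
    clades <- paste0("clade_", LETTERS[seq_len(k)])
    base <- sample(.BASES, columns, replace = TRUE)
    special <- sample.int(columns, k * (n_diag + intra_variants))
    diag_cols <- matrix(special[seq_len(k * n_diag)], nrow = k)
    var_cols <- matrix(special[-seq_len(k * n_diag)],
                       nrow = k)[, seq_len(intra_variants), drop = FALSE]
    M <- members_per_clade
    seqs <- list(); labels <- character(0)
    diag_rows <- list()
    consensus <- setNames(character(k), clades)
    for (ci in seq_len(k)) {
      mem <- matrix(rep(base, M), nrow = M, byrow = TRUE)
      cons <- base
      ## own diagnostic columns: exclusive fixed state
      for (col in diag_cols[ci, ]) {
        b <- base[col]
        others <- setdiff(.BASES, b)
        x <- others[1]
        mem[, col] <- x
        cons[col] <- x
        diag_rows[[length(diag_rows) + 1L]] <-
          data.frame(clade = clades[ci], column = col, character = x,
                     stringsAsFactors = FALSE)
      }
      ## other clades' diagnostic columns: alternate two background states
      for (cj in setdiff(seq_len(k), ci)) {
        for (col in diag_cols[cj, ]) {
          b <- base[col]
          alt <- setdiff(.BASES, b)[2]
          mem[, col] <- ifelse(seq_len(M) %% 2 == 1, b, alt)
          cons[col] <- b
        }
      }
      ## intra-clade variation at private background columns
      if (intra_variants > 0) {
        for (col in var_cols[ci, ]) {
          alt <- setdiff(.BASES, base[col])[1]
          mem[seq_len(M) > M / 2, col] <- alt
        }
      }
      ids <- sprintf("%s_m%d", clades[ci], seq_len(M))
      for (m in seq_len(M)) seqs[[ids[m]]] <- paste(mem[m, ], collapse = "")
      labels <- c(labels, setNames(rep(clades[ci], M), ids))
      consensus[ci] <- paste(cons, collapse = "")
    }
    aligned <- as_alignment(unlist(seqs))
    haplotypes <- lapply(split(as.character(aligned), labels[names(aligned)]),
                         unique)
    diagnostic_positions <- do.call(rbind, diag_rows)
    diagnostic_positions <- diagnostic_positions[
      order(diagnostic_positions$clade, diagnostic_positions$column), ]
    rownames(diagnostic_positions) <- NULL
    truth <- structure(list(clades = consensus,
                            diagnostic_positions = diagnostic_positions,
                            haplotypes = haplotypes,
                            columns = columns, seed = seed),
                       class = "synthetic_truth")
    list(alignment = aligned, labels = labels, truth = truth)
  })
}

#' Generate sample metadata and true clade compositions
#'
#' Each clade is given a rectangular latitudinal niche (bands cycled in the
#' order polar, subpolar, temperate, tropical) with an occupancy
#' probability. A clade can only occur in samples whose absolute latitude
#' falls in its band. Within a sample, the composition over occupying
#' clades is drawn from a symmetric Dirichlet with a small concentration,
#' so one or two clades usually dominate and most clades do not co-occur.
#'
#' @param truth A `synthetic_truth` from [gen_reference_clades()].
#' @param n_samples Number of samples (>= 1).
#' @param lat_range Latitude range to sample uniformly (default -75..80).
#' @param depth_mean Mean per-sample group read total (Poisson; default
#'   5000).
#' @param occupancy Probability a clade occupies an in-band sample
#'   (default 0.8).
#' @param concentration Dirichlet concentration for compositions
#'   (default 0.3).
#' @param seed Integer seed.
#' @return List with `meta` (sample metadata data.frame), `proportions`
#'   (clade x sample matrix of target compositions, columns sum to 1) and
#'   `niches` (data.frame clade, band, occupancy).
#' @export
gen_samples <- function(truth, n_samples = 100, lat_range = c(-75, 80),
                        depth_mean = 5000, occupancy = 0.8,
                        concentration = 0.3, seed = 43L) {
  stopifnot(n_samples >= 1)
  clades <- names(truth$clades)
  k <- length(clades)
  bands <- rep(c("polar", "subpolar", "temperate", "tropical"),
               length.out = k)
  .with_seed(seed, {
    sample_id <- sprintf("S%03d", seq_len(n_samples))
    latitude <- runif(n_samples, lat_range[1], lat_range[2])
    longitude <- runif(n_samples, -180, 180)
    sband <- as.character(latitude_band(latitude))
    prop <- matrix(0, nrow = k, ncol = n_samples,
                   dimnames = list(clades, sample_id))
    for (s in seq_len(n_samples)) {
      occ <- bands == sband[s] & runif(k) < occupancy
      if (!any(occ)) {
        inband <- which(bands == sband[s])
        if (!length(inband)) inband <- seq_len(k)
        occ[inband[sample.int(length(inband), 1)]] <- TRUE
      }
      w <- rgamma(sum(occ), shape = concentration)
      if (sum(w) == 0) w <- rep(1, length(w))
      prop[occ, s] <- w / sum(w)
    }
    depth <- pmax(1L, rpois(n_samples, depth_mean))
    meta <- data.frame(sample_id = sample_id, latitude = latitude,
                       longitude = longitude, group_total_reads = depth,
                       stringsAsFactors = FALSE)
    list(meta = meta, proportions = prop,
         niches = data.frame(clade = clades, band = bands,
                             occupancy = occupancy,
                             stringsAsFactors = FALSE))
  })
}

## apply per-base substitution errors to a vector of reads
.add_errors <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0) return(reads)
  L <- nchar(reads[1])
  n_err <- rbinom(length(reads), L, error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(L, n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Generate two independently sequenced read datasets
#'
#' Emulates two renditions of the same water samples processed
#' independently: both datasets draw reads from the same true haplotypes
#' and the same per-sample clade compositions, but sequencing errors
#' (independent per-base substitutions) are drawn independently per
#' dataset. The realized per-clade read fractions (before errors) are
#' returned as the ground truth that an exact pipeline must recover.
#'
#' @param truth A `synthetic_truth`.
#' @param proportions Clade x sample composition matrix from
#'   [gen_samples()].
#' @param meta Sample metadata from [gen_samples()] (depths are
#'   `group_total_reads`).
#' @param error_rate Per-base substitution probability in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return List with `reads` (per dataset `A`/`B`: data.frame `sequence`,
#'   `sample_id`, `clade` - the true source clade of each read) and
#'   `realized` (per dataset: clade x sample matrix of realized read
#'   fractions).
#' @export
gen_reads <- function(truth, proportions, meta, error_rate = 0.005,
                      seed = 44L) {
  if (error_rate < 0 || error_rate > 0.2) {
    stop("error_rate must be in [0, 0.2]", call. = FALSE)
  }
  clades <- names(truth$clades)
  .with_seed(seed, {
    out <- list(reads = list(), realized = list())
    for (ds in c("A", "B")) {
      seq_acc <- list(); samp_acc <- list(); clade_acc <- list()
      realized <- matrix(0, nrow = length(clades), ncol = nrow(meta),
                         dimnames = list(clades, meta$sample_id))
      for (s in seq_len(nrow(meta))) {
        depth <- meta$group_total_reads[s]
        p <- proportions[, s]
        cc <- as.integer(rmultinom(1, depth, p))
        realized[, s] <- cc / depth
        for (ci in which(cc > 0)) {
          haps <- truth$haplotypes[[clades[ci]]]
          hc <- as.integer(rmultinom(1, cc[ci],
                                     rep(1, length(haps)) / length(haps)))
          reads <- rep(haps, hc)
          reads <- .add_errors(reads, error_rate)
          seq_acc[[length(seq_acc) + 1L]] <- reads
          samp_acc[[length(samp_acc) + 1L]] <-
            rep(meta$sample_id[s], length(reads))
          clade_acc[[length(clade_acc) + 1L]] <-
            rep(clades[ci], length(reads))
        }
      }
      out$reads[[ds]] <- data.frame(sequence = unlist(seq_acc),
                                    sample_id = unlist(samp_acc),
                                    clade = unlist(clade_acc),
                                    stringsAsFactors = FALSE)
      out$realized[[ds]] <- realized
    }
    out
  })
}

#' One-call synthetic study
#'
#' Convenience wrapper chaining [gen_reference_clades()], [gen_samples()]
#' and [gen_reads()] with sub-seeds derived from one seed.
#'
#' @param k,columns,n_diag,members_per_clade,intra_variants Passed to
#'   [gen_reference_clades()].
#' @param n_samples,depth_mean,occupancy,concentration Passed to
#'   [gen_samples()].
#' @param error_rate Passed to [gen_reads()].
#' @param seed Master seed; sub-seeds are `seed`, `seed + 1`, `seed + 2`.
#' @return List with `reference` (alignment, labels, truth), `samples`
#'   (meta, proportions, niches) and `reads` (reads, realized).
#' @export
simulate_metabarcoding <- function(k = 5, columns = 341, n_diag = 2,
                                   members_per_clade = 4, intra_variants = 2,
                                   n_samples = 100, depth_mean = 5000,
                                   occupancy = 0.8, concentration = 0.3,
                                   error_rate = 0.005, seed = 42L) {
  ref <- gen_reference_clades(k, columns, n_diag, members_per_clade,
                              intra_variants, seed)
  smp <- gen_samples(ref$truth, n_samples, depth_mean = depth_mean,
                     occupancy = occupancy, concentration = concentration,
                     seed = seed + 1L)
  rds <- gen_reads(ref$truth, smp$proportions, smp$meta, error_rate,
                   seed = seed + 2L)
  list(reference = ref, samples = smp, reads = rds)
}
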