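## In-silico qPCR primer/probe screening: degenerate-aware mismatch
## counting against target sequences, with 3'-terminal-window annotation.
## Binding is modelled ungapped (sliding-window placement, no indels).

#' Do two IUPAC codes match?
#'
#' True iff the base sets of the two codes intersect (so degenerate codes
#' match every base they cover; `N` matches everything; gap matches only
#' gap).
#'
#' @param a,b IUPAC nucleotide codes (vectorized, recycled).
#' @return Logical vector.
#' @export
iupac_match <- function(a, b) {
  mapply(function(x, y) length(intersect(iupac_set(x), iupac_set(y))) > 0,
         a, b, USE.NAMES = FALSE)
}

#' Reverse complement of an IUPAC sequence
#' @param x Character vector of IUPAC sequences (no gaps).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Locate an oligo on a target and count mismatches
#'
#' Slides the oligo along the (normalized, ungapped) target and keeps the
#' placement with the fewest degenerate-aware mismatches; ties go to the
#' leftmost site. For `orientation = "antisense"` the oligo is compared
#' against the reverse complement of the target (reverse primers are given
#' 5'->3' on the reverse strand).
#'
#' @param oligo IUPAC oligo, 5'->3'.
#' @param target Normalized ungapped target sequence.
#' @param orientation `"sense"` (default) or `"antisense"`.
#' @return List: `start` (1-based site on the strand searched),
#'   `mismatch_count`, `mismatch_positions` (1-based from the oligo 5' end).
#' @export
locate_and_count <- function(oligo, target,
                             orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  oligo <- toupper(oligo)
  target <- toupper(target)
  if (orientation == "antisense") target <- revcomp(target)
  m <- nchar(oligo)
  L <- nchar(target)
  if (m > L) stop("oligo longer than target", call. = FALSE)
  oc <- strsplit(oligo, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  ## m x base-set compatibility, precomputed per oligo position
  osets <- lapply(oc, iupac_set)
  tsets <- lapply(tc, iupac_set)
  best <- NULL
  for (s in seq_len(L - m + 1L)) {
    mm <- which(!vapply(seq_len(m), function(k) {
      length(intersect(osets[[k]], tsets[[s + k - 1L]])) > 0
    }, logical(1)))
    if (is.null(best) || length(mm) < length(best$mismatch_positions)) {
      best <- list(start = s, mismatch_count = length(mm),
                   mismatch_positions = mm)
      if (length(mm) == 0) break
    }
  }
  best
}

#' Build a qPCR primer/probe set
#' @param name Set name (e.g. `"OI"`).
#' @param forward,probe,reverse IUPAC oligos, each 5'->3' (the reverse
#'   primer in the sense of the reverse strand).
#' @return List of class `primer_set`.
#' @export
primer_set <- function(name, forward, probe, reverse) {
  oligos <- c(forward = forward, probe = probe, reverse = reverse)
  if (any(!nzchar(oligos))) stop("empty oligo", call. = FALSE)
  .check_iupac(oligos, where = "oligo")
  structure(list(name = name, forward = toupper(forward),
                 probe = toupper(probe), reverse = toupper(reverse)),
            class = "primer_set")
}

#' Read primer sets from a TSV file
#' @param path TSV with columns `name`, `forward`, `probe`, `reverse`.
#' @return List of `primer_set` objects, named by set.
#' @export
read_primer_sets <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("name", "forward", "probe", "reverse")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("primer TSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sets <- lapply(seq_len(nrow(df)), function(i) {
    primer_set(df$name[i], df$forward[i], df$probe[i], df$reverse[i])
  })
  setNames(sets, df$name)
}

#' Evaluate a primer/probe set against a target sequence
#'
#' Forward primer and probe are evaluated on the sense strand, the reverse
#' primer antisense. Mismatches falling in the 3'-terminal window of a
#' primer are flagged, as such mismatches are the ones most likely to
#' abolish amplification. If the probe scores fewer mismatches antisense
#' (hydrolysis probes may be designed on either strand), the antisense
#' placement is reported and noted.
#'
#' @param set A `primer_set`.
#' @param target Normalized ungapped target sequence (named or not).
#' @param three_prime_window 3'-terminal window length in bases (default 3).
#' @param probe_fallback Try the probe antisense too and keep the better
#'   strand (default TRUE).
#' @return data.frame of class `mismatch_report`: one row per oligo with
#'   `set`, `oligo`, `orientation`, `binding_site_found`, `mismatch_count`,
#'   `mismatch_positions`, `three_prime_flag`, plus attribute `total`.
#' @export
evaluate_primer_set <- function(set, target, three_prime_window = 3,
                                probe_fallback = TRUE) {
  stopifnot(inherits(set, "primer_set"))
  tgt <- normalize_sequence(unname(target[1]))
  one <- function(oligo, orientation) {
    if (nchar(oligo) > nchar(tgt)) {
      return(list(found = FALSE, hit = NULL, orientation = orientation))
    }
    list(found = TRUE, hit = locate_and_count(oligo, tgt, orientation),
         orientation = orientation)
  }
  fwd <- one(set$forward, "sense")
  prb <- one(set$probe, "sense")
  if (probe_fallback && prb$found) {
    alt <- one(set$probe, "antisense")
    if (alt$found && alt$hit$mismatch_count < prb$hit$mismatch_count) {
      prb <- alt
    }
  }
  rev <- one(set$reverse, "antisense")
  oligos <- list(forward = fwd, probe = prb, reverse = rev)
  lens <- c(forward = nchar(set$forward), probe = nchar(set$probe),
            reverse = nchar(set$reverse))
  rows <- lapply(names(oligos), function(o) {
    r <- oligos[[o]]
    if (!r$found) {
      return(data.frame(set = set$name, oligo = o,
                        orientation = r$orientation,
                        binding_site_found = FALSE,
                        mismatch_count = NA_integer_,
                        mismatch_positions = "",
                        three_prime_flag = NA, stringsAsFactors = FALSE))
    }
    mm <- r$hit$mismatch_positions
    ## primers act from their 3' end; flag the probe too for uniformity
    flag <- any(mm > lens[[o]] - three_prime_window)
    data.frame(set = set$name, oligo = o, orientation = r$orientation,
               binding_site_found = TRUE,
               mismatch_count = r$hit$mismatch_count,
               mismatch_positions = paste(mm, collapse = ","),
               three_prime_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$mismatch_count, na.rm = TRUE)
  class(out) <- c("mismatch_report", "data.frame")
  out
}
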