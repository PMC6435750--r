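## Diagnostic alignment signatures: discovery of clade-delineating columns
## and signature-based clade assignment of query sequences.

## IUPAC base sets (T and U equivalent; gap is its own state)
IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = "-", "." = "-"
)

iupac_set <- function(code) {
  s <- IUPAC_SET[[toupper(code)]]
  if (is.null(s)) stop("invalid IUPAC code: '", code, "'", call. = FALSE)
  s
}

## does observed character `code` (possibly degenerate) carry concrete
## state `state`? with ambiguity_aware = FALSE, only literal identity
.carries <- function(code, state, ambiguity_aware = TRUE) {
  if (!ambiguity_aware) return(toupper(code) == state)
  state %in% iupac_set(code)
}

.state_order <- c("A", "C", "G", "T", "-")

#' Discover diagnostic signature positions for labelled clades
#'
#' A column is a strict signature for a clade when all clade members carry
#' the candidate state there and no member of any other clade carries it.
#' `majority` mode relaxes the within-clade requirement to a fraction
#' `min_fraction` while still demanding zero carriers outside the clade.
#' A gap is a legitimate diagnostic state (indel signatures); disable with
#' `gap_is_state = FALSE`. A member carrying an IUPAC ambiguity code
#' compatible with the candidate state counts as carrying it.
#'
#' @param alignment A `pc_alignment` of labelled reference sequences.
#' @param labels Named character vector, sequence id -> clade (>= 2 clades,
#'   every sequence labelled, no empty clade).
#' @param mode `"strict"` (default) or `"majority"`.
#' @param min_fraction Within-clade carrier fraction required in majority
#'   mode (default 0.9).
#' @param gap_is_state Allow `-` as a diagnostic state (default TRUE).
#' @param ambiguity_aware Treat compatible IUPAC ambiguity codes as carriers
#'   (default TRUE).
#' @return data.frame of class `signature_profiles` with columns `clade`,
#'   `column` (1-based), `character`, `exclusivity`; sorted by clade then
#'   column. Clades with no diagnostic column simply contribute no rows.
#' @export
discover_signatures <- function(alignment, labels,
                                mode = c("strict", "majority"),
                                min_fraction = 0.9, gap_is_state = TRUE,
                                ambiguity_aware = TRUE) {
  mode <- match.arg(mode)
  m <- aln_matrix(alignment)
  ids <- rownames(m)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) stop("unlabelled sequence id(s): ",
                         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  cl <- labels[ids]
  clades <- sort(unique(as.character(labels)))
  if (length(clades) < 2) stop("need >= 2 clades", call. = FALSE)
  empty <- setdiff(clades, cl)
  if (length(empty)) stop("clade with no members: ", empty[1], call. = FALSE)
  states <- if (gap_is_state) .state_order else setdiff(.state_order, "-")
  rows <- list()
  for (clade in clades) {
    inm <- m[cl == clade, , drop = FALSE]
    outm <- m[cl != clade, , drop = FALSE]
    for (col in seq_len(ncol(m))) {
      inc <- inm[, col]
      outc <- outm[, col]
      for (st in states) {
        carry_in <- vapply(inc, .carries, logical(1), state = st,
                           ambiguity_aware = ambiguity_aware)
        frac <- mean(carry_in)
        ok_in <- if (mode == "strict") all(carry_in) else frac >= min_fraction
        if (!ok_in) next
        carry_out <- vapply(outc, .carries, logical(1), state = st,
                            ambiguity_aware = ambiguity_aware)
        if (any(carry_out)) next
        rows[[length(rows) + 1L]] <- data.frame(
          clade = clade, column = col, character = st,
          exclusivity = mode, stringsAsFactors = FALSE)
        break  # first state in canonical order wins for this column
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(clade = character(0), column = integer(0),
               character = character(0), exclusivity = character(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$clade, out$column), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_profiles", "data.frame")
  out
}

#' Assign query sequences to clades by signature match
#'
#' For each clade the match fraction is computed over that clade's signature
#' positions. The winner must have a strictly best fraction at least
#' `min_match_fraction` (default 1: every signature position must match).
#' Ties are reported as `"ambiguous"`, never broken; no qualifying clade
#' gives `"unassigned"`.
#'
#' @param query Named character vector of sequences aligned to the reference
#'   coordinate system.
#' @param profiles A [discover_signatures()] result.
#' @param min_match_fraction Minimum match fraction to qualify (default 1).
#' @return data.frame with `query`, `clade` (or `"unassigned"` /
#'   `"ambiguous"`), `matched`, `total`, `conflicts` (comma-separated
#'   columns contradicting the winning clade).
#' @export
classify_by_signature <- function(query, profiles, min_match_fraction = 1.0) {
  if (nrow(profiles) == 0) stop("empty signature profiles", call. = FALSE)
  maxcol <- max(profiles$column)
  if (is.null(names(query))) names(query) <- paste0("query", seq_along(query))
  res <- lapply(names(query), function(qid) {
    q <- toupper(query[[qid]])
    if (nchar(q) < maxcol) {
      stop(sprintf("query '%s' (%d bp) shorter than last signature column %d",
                   qid, nchar(q), maxcol), call. = FALSE)
    }
    qc <- strsplit(q, "")[[1]]
    per <- split(profiles, profiles$clade)
    score <- lapply(per, function(p) {
      hit <- vapply(seq_len(nrow(p)), function(i) {
        length(intersect(iupac_set(qc[p$column[i]]),
                         iupac_set(p$character[i]))) > 0
      }, logical(1))
      list(matched = sum(hit), total = nrow(p),
           conflicts = p$column[!hit])
    })
    frac <- vapply(score, function(s) s$matched / s$total, numeric(1))
    qual <- names(frac)[frac >= min_match_fraction & frac == max(frac)]
    if (length(qual) == 0) {
      data.frame(query = qid, clade = "unassigned", matched = NA_integer_,
                 total = NA_integer_, conflicts = "",
                 stringsAsFactors = FALSE)
    } else if (length(qual) > 1) {
      data.frame(query = qid, clade = "ambiguous", matched = NA_integer_,
                 total = NA_integer_, conflicts = "",
                 stringsAsFactors = FALSE)
    } else {
      s <- score[[qual]]
      data.frame(query = qid, clade = qual, matched = s$matched,
                 total = s$total,
                 conflicts = paste(s$conflicts, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Tabulate signature positions within a column window
#'
#' @param profiles A [discover_signatures()] result.
#' @param window Integer vector `c(from, to)` of 1-based columns,
#'   `from <= to`.
#' @return data.frame restricted to diagnostic columns inside the window
#'   (`clade`, `column`, `character`), sorted by column then clade.
#' @export
signature_report <- function(profiles, window) {
  if (length(window) != 2 || window[1] > window[2] || window[1] < 1) {
    stop("empty or invalid window", call. = FALSE)
  }
  keep <- profiles$column >= window[1] & profiles$column <= window[2]
  out <- profiles[keep, c("clade", "column", "character"), drop = FALSE]
  out <- out[order(out$column, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  out
}
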