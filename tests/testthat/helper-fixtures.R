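# Fixture builders and independent oracles used across the suite.

# random gappy alignment, deterministic given seed
rand_alignment <- function(n, L, seed, gaps = TRUE) {
  set.seed(seed)
  alph <- if (gaps) c("A", "C", "G", "T", "-") else c("A", "C", "G", "T")
  pr <- if (gaps) c(rep(0.23, 4), 0.08) else rep(0.25, 4)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alph, L, replace = TRUE, prob = pr), collapse = "")
  }, character(1))
  as_alignment(setNames(seqs, sprintf("s%02d", seq_len(n))))
}

# brute-force per-column identity recount, independent of the package's
# vectorised path (walks columns with substr)
oracle_identity <- function(a, b, gap_mode) {
  L <- nchar(a)
  match <- 0L; comp <- 0L
  for (i in seq_len(L)) {
    ca <- toupper(substr(a, i, i)); cb <- toupper(substr(b, i, i))
    if (gap_mode == "ungapped_pair_columns" &&
        (ca %in% c("-", ".") || cb %in% c("-", "."))) next
    comp <- comp + 1L
    if (ca == cb) match <- match + 1L
  }
  100 * match / comp
}

# unrooted monophyly oracle via ape's partition enumeration: a proper leaf
# subset is a clade iff it or its complement appears among the tree's
# bipartitions (pendant edges make singletons and (n-1)-sets trivially so)
oracle_monophyletic <- function(phylo, members) {
  tips <- phylo$tip.label
  n <- length(tips)
  if (length(members) == 1 || length(members) == n - 1) return(TRUE)
  want <- sort(match(members, tips))
  comp <- sort(setdiff(seq_len(n), want))
  pp <- ape::prop.part(phylo)
  any(vapply(pp, function(s) {
    identical(sort(s), want) || identical(sort(s), comp)
  }, logical(1)))
}

# random additive distance matrix from a random tree with branch lengths
rand_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 2))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# classify unique sequences and report read-weighted accuracy against the
# per-read true clades
signature_accuracy <- function(reads_df, profiles) {
  u <- unique(reads_df$sequence)
  cls <- classify_by_signature(setNames(u, paste0("u", seq_along(u))),
                               profiles)
  assigned <- setNames(cls$clade, u)
  mean(assigned[reads_df$sequence] == reads_df$clade)
}
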