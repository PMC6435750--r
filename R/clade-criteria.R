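## Dual-tree clade criteria: a clade must be monophyletic in both the ML
## and the Bayesian tree and carry bootstrap support above the threshold.
## Monophyly is defined on the unrooted tree via edge bipartitions. A small
## neighbor-joining builder makes the criteria testable end to end without
## external tree software.

## descendant tip-index set for every node of a phylo object
.tips_below <- function(ph) {
  n_tip <- length(ph$tip.label)
  sets <- vector("list", n_tip + ph$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(ph, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  }
  sets
}

## shared bipartition search; returns list(monophyletic, node) where `node`
## is the child node of the defining edge (NA when not monophyletic)
.find_defining_edge <- function(tree, members) {
  ph <- tree$phylo
  tips <- ph$tip.label
  unknown <- setdiff(members, tips)
  if (length(unknown)) stop("unknown leaf: ", unknown[1], call. = FALSE)
  if (length(members) >= length(tips)) {
    stop("members must be a proper subset of the leaves (monophyly of the ",
         "full leaf set is undefined on an unrooted tree)", call. = FALSE)
  }
  if (length(members) < 1) stop("empty member set", call. = FALSE)
  want <- sort(match(members, tips))
  comp <- sort(setdiff(seq_along(tips), want))
  sets <- .tips_below(ph)
  root <- length(tips) + 1L
  ## the member set and its complement can each match at most one node;
  ## when both match (the edge incident to a binary root) they are the two
  ## rooted representations of the same unrooted edge
  wantnode <- NA_integer_; compnode <- NA_integer_
  for (v in seq_along(sets)) {
    if (v == root) next
    s <- sort(sets[[v]])
    if (identical(s, want)) wantnode <- v
    else if (identical(s, comp)) compnode <- v
  }
  if (is.na(wantnode) && is.na(compnode)) {
    return(list(monophyletic = FALSE, node = NA_integer_))
  }
  list(monophyletic = TRUE,
       node = if (!is.na(wantnode)) wantnode else compnode,
       altnode = if (!is.na(wantnode)) compnode else NA_integer_)
}

#' Test monophyly of a leaf set on an unrooted tree
#'
#' True iff some edge bipartition separates exactly `members` from the rest
#' (so the test is invariant to rooting).
#'
#' @param tree A `supported_tree`.
#' @param members Character vector of leaf names; a proper non-empty subset
#'   of the tree's leaves.
#' @return List with `monophyletic` (flag) and `node` (internal child node
#'   of the defining edge, `NA` if none).
#' @export
is_monophyletic <- function(tree, members) {
  .find_defining_edge(tree, members)
}

#' Support value of a clade's defining edge
#'
#' @param tree A `supported_tree`.
#' @param members Leaf names forming a monophyletic group in `tree`.
#' @return Numeric support of the bipartition edge, or `NA` when the tree
#'   stores none there (including when the defining edge is a pendant edge).
#' @export
clade_support <- function(tree, members) {
  hit <- .find_defining_edge(tree, members)
  if (!hit$monophyletic) {
    stop("members are not monophyletic; no defining edge", call. = FALSE)
  }
  n_tip <- length(tree$phylo$tip.label)
  sup <- node_supports(tree)
  at <- function(v) {
    if (is.na(v) || v <= n_tip) NA_real_ else sup[v - n_tip]
  }
  s <- at(hit$node)
  ## same unrooted edge may carry its label on the other side of the root
  if (is.na(s) && !is.null(hit$altnode)) s <- at(hit$altnode)
  s
}

#' Evaluate the dual-tree clade criteria
#'
#' A candidate clade passes when it is monophyletic in both the ML and the
#' Bayesian tree and its ML bootstrap support exceeds `min_bootstrap`
#' (strict by default, following the "greater than 70 %" criterion; set
#' `inclusive = TRUE` for >=). No posterior threshold is applied unless
#' `min_posterior` is given (then support_bayes >= min_posterior is also
#' required). Absent ML support fails the support criterion.
#'
#' @param tree_ml `supported_tree` with bootstrap supports (percent scale).
#' @param tree_bayes `supported_tree` with posterior probabilities.
#' @param members Leaf names of the candidate clade; must be present in
#'   both trees.
#' @param min_bootstrap Bootstrap threshold in percent (default 70).
#' @param inclusive If `TRUE`, support equal to the threshold passes.
#' @param min_posterior Optional posterior-probability threshold.
#' @return One-row data.frame (`clade_verdict`): `monophyletic_ml`,
#'   `monophyletic_bayes`, `support_ml`, `support_bayes`, `passes`.
#' @export
evaluate_clade <- function(tree_ml, tree_bayes, members, min_bootstrap = 70,
                           inclusive = FALSE, min_posterior = NULL) {
  for (nm in c("tree_ml", "tree_bayes")) {
    tr <- get(nm)
    missing <- setdiff(members, tr$phylo$tip.label)
    if (length(missing)) {
      stop(sprintf("member '%s' missing from %s", missing[1], nm),
           call. = FALSE)
    }
  }
  ml <- .find_defining_edge(tree_ml, members)
  by <- .find_defining_edge(tree_bayes, members)
  s_ml <- if (ml$monophyletic) clade_support(tree_ml, members) else NA_real_
  s_by <- if (by$monophyletic) clade_support(tree_bayes, members) else NA_real_
  sup_ok <- !is.na(s_ml) &&
    (if (inclusive) s_ml >= min_bootstrap else s_ml > min_bootstrap)
  post_ok <- is.null(min_posterior) ||
    (!is.na(s_by) && s_by >= min_posterior)
  data.frame(monophyletic_ml = ml$monophyletic,
             monophyletic_bayes = by$monophyletic,
             support_ml = s_ml, support_bayes = s_by,
             passes = ml$monophyletic && by$monophyletic && sup_ok && post_ok,
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei with the usual Q criterion). Ties
#' in the Q matrix are broken deterministically by the lexicographically
#' smallest pair of labels (merged nodes are keyed by their smallest
#' contained leaf). On additive distances the path-length matrix of the
#' result reproduces the input exactly.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and row
#'   names (>= 3 labels).
#' @return An unrooted `supported_tree` without support values.
#' @export
nj_tree <- function(distances) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 3) stop("need >= 3 labels", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(D) != 0)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  frag <- rownames(D)      # newick fragment per active node
  key <- rownames(D)       # smallest contained leaf, for tie-breaking
  dimnames(D) <- NULL
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairkey <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(pairkey)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    newkey <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- dk[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dk, deparse.level = 0), c(dk, 0))
    frag <- c(frag[-c(i, j)], newfrag)
    key <- c(key[-c(i, j)], newkey)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  supported_tree(ape::read.tree(text = nwk), "percent")
}
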