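hand_aln <- as_alignment(c(x1 = "ACGTA", x2 = "ACGTA",
                           y1 = "ACCTA", y2 = "ACCTT"))
hand_labels <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y")

test_that("strict discovery finds exactly the hand-enumerated diagnostic columns", {
  prof <- discover_signatures(hand_aln, hand_labels)
  # column 3 is fixed and exclusive in each clade; column 5 is polymorphic
  # in Y and Y's 'A' also occurs in X, so it is diagnostic for neither
  expect_equal(prof[prof$clade == "X", c("column", "character")],
               data.frame(column = 3L, character = "G"),
               ignore_attr = TRUE)
  expect_equal(prof[prof$clade == "Y", c("column", "character")],
               data.frame(column = 3L, character = "C"),
               ignore_attr = TRUE)

  # two identical clades: empty profiles
  same <- as_alignment(c(a1 = "ACGT", a2 = "ACGT",
                         b1 = "ACGT", b2 = "ACGT"))
  expect_equal(nrow(discover_signatures(
    same, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))), 0)

  # a label map naming a clade with no member sequence is an error
  expect_error(discover_signatures(hand_aln, c(hand_labels, zz = "Z")),
               "no members")
  expect_error(discover_signatures(hand_aln, hand_labels[1:3]),
               "unlabelled")
})

test_that("discovery is order-invariant and shrinks when clades gain members", {
  prof0 <- discover_signatures(hand_aln, hand_labels)
  perm <- c(4, 2, 1, 3)
  prof1 <- discover_signatures(as_alignment(unclass(hand_aln)[perm]),
                               hand_labels)
  expect_identical(prof0, prof1)

  # adding a divergent member to X can only shrink X's strict set
  grown <- as_alignment(c(unclass(hand_aln), x3 = "ACCTA"))
  prof2 <- discover_signatures(grown, c(hand_labels, x3 = "X"))
  expect_true(all(prof2$column[prof2$clade == "X"] %in%
                    prof0$column[prof0$clade == "X"]))
})

test_that("gap and IUPAC-ambiguity handling follow the documented conventions", {
  aln <- as_alignment(c(g1 = "AC-TA", g2 = "AC-TA",
                        h1 = "ACGTA", h2 = "ACGTA"))
  labs <- c(g1 = "G", g2 = "G", h1 = "H", h2 = "H")
  prof <- discover_signatures(aln, labs)
  expect_true(any(prof$clade == "G" & prof$column == 3 &
                    prof$character == "-"))
  prof_nogap <- discover_signatures(aln, labs, gap_is_state = FALSE)
  expect_false(any(prof_nogap$character == "-"))

  # an R in the outgroup is compatible with G, blocking G as exclusive
  amb <- as_alignment(c(p1 = "AGA", p2 = "AGA", q1 = "ARA", q2 = "ATA"))
  labp <- c(p1 = "P", p2 = "P", q1 = "Q", q2 = "Q")
  profa <- discover_signatures(amb, labp)
  expect_false(any(profa$clade == "P" & profa$column == 2))
  profl <- discover_signatures(amb, labp, ambiguity_aware = FALSE)
  expect_true(any(profl$clade == "P" & profl$column == 2 &
                    profl$character == "G"))
})

test_that("classification assigns, rejects novel states, and reports ties as ambiguous", {
  prof <- discover_signatures(hand_aln, hand_labels)
  res <- classify_by_signature(c(q1 = "ACGTA", q2 = "ACTTA"), prof)
  expect_equal(res$clade[res$query == "q1"], "X")
  expect_equal(res$matched[res$query == "q1"], 1)
  expect_equal(res$total[res$query == "q1"], 1)
  # novel state at the only diagnostic column: unassigned
  expect_equal(res$clade[res$query == "q2"], "unassigned")

  # two clades sharing identical profiles: forced tie -> ambiguous
  tie <- prof
  tie$clade <- c("U", "V")
  tie$character <- c("G", "G")
  expect_equal(classify_by_signature(c(q = "ACGTA"), tie)$clade,
               "ambiguous")

  expect_error(classify_by_signature(c(short = "AC"), prof), "shorter")
})

test_that("sequences built from a consensus plus its profile classify back to the clade", {
  ref <- gen_reference_clades(k = 4, columns = 60, n_diag = 2,
                              members_per_clade = 4, seed = 11)
  prof <- discover_signatures(ref$alignment, ref$labels)
  cons <- ref$truth$clades
  res <- classify_by_signature(cons, prof)
  expect_equal(res$clade, names(cons))
  expect_true(all(res$matched == res$total))
})

test_that("signature report restricts to the requested 1-based window", {
  prof <- data.frame(clade = c("A", "A", "B"),
                     column = c(10L, 200L, 150L),
                     character = c("G", "T", "-"),
                     exclusivity = "strict", stringsAsFactors = FALSE)
  class(prof) <- c("signature_profiles", "data.frame")
  expect_equal(nrow(signature_report(prof, c(1, 341))), 3)
  win <- signature_report(prof, c(20, 140))
  expect_equal(nrow(win), 0)
  win2 <- signature_report(prof, c(140, 210))
  expect_equal(sort(win2$column), c(150, 200))
  expect_equal(nrow(signature_report(prof, c(1, 1))), 0)
  expect_error(signature_report(prof, c(5, 2)), "window")
})
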