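test_that("quality filter applies the strict >300 bp and no-N rules with a conserving log", {
  mk <- function(L, N = FALSE) {
    s <- paste(rep("A", L), collapse = "")
    if (N) sub("A", "N", s)
  else s
  }
  reads <- c(ok301 = mk(301), edge300 = mk(300), amb = mk(400, N = TRUE),
             ok400 = mk(400))
  res <- quality_filter(reads)
  expect_setequal(names(res$reads), c("ok301", "ok400"))
  expect_equal(res$log$n[res$log$reason == "ambiguous"], 1)
  expect_equal(res$log$n[res$log$reason == "too_short"], 1)
  # conservation: removed + retained = input
  expect_equal(sum(res$log$n), length(reads))

  # "any" mode also drops degeneracy codes other than N
  degen <- c(r = paste0(mk(301), "R"))
  expect_length(quality_filter(degen)$reads, 1)
  expect_length(quality_filter(degen, ambiguity = "any")$reads, 0)
})

test_that("normalization uppercases, strips gaps, maps U to T, and is idempotent", {
  expect_equal(normalize_sequence("acgu"), "ACGT")
  expect_equal(normalize_sequence("AC-GT"), "ACGT")
  expect_error(normalize_sequence("ACXT"), "non-IUPAC")
  set.seed(1)
  for (i in 1:20) {
    x <- paste(sample(c("a", "c", "g", "t", "u", "R", "N", "-", "."),
                      30, replace = TRUE), collapse = "")
    expect_identical(normalize_sequence(normalize_sequence(x)),
                     normalize_sequence(x))
  }
})

test_that("dereplication conserves reads, ranks by abundance and names by rank", {
  tab <- dereplicate(c("ACGT", "ACGT", "ACGA"), c("s1", "s1", "s2"), "LGC")
  expect_equal(nrow(tab$counts), 2)
  expect_equal(tab$counts["ASV_LGC_00001", "s1"], 2L)
  expect_equal(tab$counts["ASV_LGC_00002", "s2"], 1L)
  expect_equal(unname(tab$sequences["ASV_LGC_00001"]), "ACGT")

  # multiset oracle on random reads: per-ASV totals match a direct count
  set.seed(7)
  pool <- replicate(7, paste(sample(c("A", "C", "G", "T"), 25,
                                    replace = TRUE), collapse = ""))
  reads <- sample(pool, 100, replace = TRUE)
  samp <- sample(c("s1", "s2", "s3"), 100, replace = TRUE)
  tab2 <- dereplicate(reads, samp, "X")
  expect_equal(nrow(tab2$counts), length(unique(reads)))
  expect_equal(sum(tab2$counts), 100)
  oracle <- table(reads)
  expect_equal(unname(asv_totals(tab2)[match(names(oracle),
                                             tab2$sequences)]),
               as.numeric(oracle), ignore_attr = TRUE)
  # ties broken lexicographically by sequence
  ord_tot <- asv_totals(tab2)
  expect_true(all(diff(ord_tot) <= 0))

  empty <- dereplicate(character(0), character(0), "X")
  expect_equal(nrow(empty$counts), 0)

  # re-expansion to reads and re-dereplication is a no-op
  reexp <- rep(tab2$sequences, asv_totals(tab2))
  resamp <- unlist(lapply(rownames(tab2$counts), function(id) {
    rep(colnames(tab2$counts), tab2$counts[id, ])
  }))
  tab3 <- dereplicate(unname(reexp), resamp, "X")
  expect_identical(tab3$counts, tab2$counts)
  expect_identical(tab3$sequences, tab2$sequences)
})

test_that("major-ASV selection is inclusive at the threshold", {
  counts <- matrix(c(201, 200, 199), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  kept <- select_major(counts, 200)
  expect_setequal(rownames(kept), c("a", "b"))
  expect_identical(rownames(select_major(counts, 0)), c("a", "b", "c"))
})

test_that("cross-dataset confirmation recovers shared sequences and is symmetric", {
  shared <- replicate(10, paste(sample(c("A", "C", "G", "T"), 30,
                                       replace = TRUE), collapse = ""))
  privA <- c("AAAAACCCCCGGGGGTTTTTAAAAACCCCC")
  privB <- c("TTTTTGGGGGCCCCCAAAAATTTTTGGGGG",
             "GGGGGTTTTTAAAAACCCCCGGGGGTTTTT")
  A <- dereplicate(c(shared, privA), rep("s1", 11), "A")
  B <- dereplicate(c(shared, privB), rep("s1", 12), "B")
  confA <- cross_confirm(A, B, mode = "exact")
  expect_equal(sum(confA$confirmed), 10)
  expect_setequal(unname(A$sequences[confA$asv_id[confA$confirmed]]),
                  shared)
  # symmetry of exact mode
  confB <- cross_confirm(B, A, mode = "exact")
  expect_setequal(unname(B$sequences[confB$asv_id[confB$confirmed]]),
                  unname(A$sequences[confA$asv_id[confA$confirmed]]))
  # containment accepts trimming differences that exact mode rejects
  Btrim <- dereplicate(substr(shared, 3, 28), rep("s1", 10), "Bt")
  expect_equal(sum(cross_confirm(A, Btrim, "exact")$confirmed), 0)
  confC <- cross_confirm(A, Btrim, "containment")
  expect_equal(sum(confC$confirmed), 10)
})

test_that("taxon grouping sums published LGC read totals exactly", {
  tb <- major_asv_table("LGC")
  lab <- setNames(tb$taxa$taxon, tb$taxa$asv_id)
  g <- group_reads_by_taxon(tb$counts, lab)
  expect_equal(unname(g[["Ostreococcus lucimarinus"]]), 23119)
  expect_equal(unname(g[["Micromonas clade B5"]]), 6296)
  genus <- group_reads_by_taxon(tb$counts,
                                setNames(tb$taxa$genus, tb$taxa$asv_id))
  expect_equal(unname(genus[["Mantoniella"]]), 8570)
  # grouping conserves the labelled total
  expect_equal(sum(g), sum(tb$counts))
  expect_error(group_reads_by_taxon(tb$counts, lab[-1]), "unlabelled")
  # single-row group is that row's count
  expect_equal(unname(g[["Bathycoccus prasinos"]]), 16750)
})
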