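test_that("generators are deterministic given a seed", {
  r1 <- gen_reference_clades(k = 3, columns = 80, n_diag = 2, seed = 5)
  r2 <- gen_reference_clades(k = 3, columns = 80, n_diag = 2, seed = 5)
  expect_identical(r1, r2)
  r3 <- gen_reference_clades(k = 3, columns = 80, n_diag = 2, seed = 6)
  expect_false(identical(r1$alignment, r3$alignment))

  s1 <- gen_samples(r1$truth, n_samples = 30, seed = 9)
  s2 <- gen_samples(r1$truth, n_samples = 30, seed = 9)
  expect_identical(s1, s2)
  g1 <- gen_reads(r1$truth, s1$proportions, s1$meta, 0.01, seed = 3)
  g2 <- gen_reads(r1$truth, s1$proportions, s1$meta, 0.01, seed = 3)
  expect_identical(g1, g2)
})

test_that("planted diagnostic columns are recovered exactly by strict discovery", {
  # minimal case: 2 clades, 1 diagnostic column each
  ref2 <- gen_reference_clades(k = 2, columns = 10, n_diag = 1,
                               members_per_clade = 3, intra_variants = 1,
                               seed = 17)
  prof2 <- discover_signatures(ref2$alignment, ref2$labels)
  truth2 <- ref2$truth$diagnostic_positions
  expect_equal(prof2[, c("clade", "column", "character")],
               truth2[, c("clade", "column", "character")],
               ignore_attr = TRUE)

  # study-scale case
  ref5 <- gen_reference_clades(k = 5, columns = 341, n_diag = 2,
                               members_per_clade = 4, seed = 23)
  prof5 <- discover_signatures(ref5$alignment, ref5$labels)
  expect_equal(prof5[, c("clade", "column", "character")],
               ref5$truth$diagnostic_positions[, c("clade", "column",
                                                   "character")],
               ignore_attr = TRUE)
})

test_that("consensus sequences respect the pairwise-identity construction bound", {
  ref <- gen_reference_clades(k = 5, columns = 341, n_diag = 2, seed = 31)
  cons <- as_alignment(ref$truth$clades)
  m <- identity_matrix(cons, "all_columns")
  bound <- 100 * (1 - 2 * 2 / 341)
  expect_true(all(m[upper.tri(m)] >= bound))

  expect_error(gen_reference_clades(k = 5, columns = 8, n_diag = 2),
               "infeasible")
})

test_that("latitudinal niches confine clades to their bands", {
  ref <- gen_reference_clades(k = 5, columns = 60, n_diag = 1, seed = 2)
  smp <- gen_samples(ref$truth, n_samples = 120, seed = 12)
  # clades are banded polar, subpolar, temperate, tropical, polar in turn
  polar_clades <- smp$niches$clade[smp$niches$band == "polar"]
  off_band <- abs(smp$meta$latitude) < 66.5
  for (cl in polar_clades) {
    expect_true(all(smp$proportions[cl, off_band] == 0))
  }
  # compositions are proper: columns sum to 1
  expect_equal(unname(colSums(smp$proportions)), rep(1, 120),
               tolerance = 1e-12)
  # occupancy 1 everywhere-in-band: clade present in every in-band sample
  smp1 <- gen_samples(ref$truth, n_samples = 120, occupancy = 1, seed = 12)
  in_polar <- abs(smp1$meta$latitude) >= 66.5
  for (cl in polar_clades) {
    expect_true(all(smp1$proportions[cl, in_polar] > 0))
  }
})

test_that("observed prevalence tracks the expected occupancy at scale", {
  ref <- gen_reference_clades(k = 4, columns = 60, n_diag = 1, seed = 4)
  smp <- gen_samples(ref$truth, n_samples = 200, occupancy = 0.8,
                     seed = 40)
  band_of <- setNames(smp$niches$band, smp$niches$clade)
  sband <- as.character(latitude_band(smp$meta$latitude))
  for (cl in rownames(smp$proportions)) {
    n_in_band <- sum(sband == band_of[[cl]])
    expected <- 0.8 * n_in_band
    observed <- sum(smp$proportions[cl, ] > 0)
    expect_lt(abs(observed - expected), 0.1 * 200 + 3)
  }
})

test_that("error-free reads dereplicate to exactly the planted haplotypes", {
  sim <- simulate_metabarcoding(k = 3, columns = 80, n_diag = 2,
                                n_samples = 12, depth_mean = 400,
                                error_rate = 0, seed = 77)
  for (ds in c("A", "B")) {
    reads <- sim$reads$reads[[ds]]
    der <- dereplicate(reads$sequence, reads$sample_id, ds)
    planted <- unique(unlist(sim$reference$truth$haplotypes))
    present <- planted[planted %in% reads$sequence]
    expect_setequal(unname(der$sequences), present)
    expect_equal(sum(der$counts), nrow(reads))
  }
})

test_that("sequencing errors spawn only low-count spurious ASVs removed by major selection", {
  sim <- simulate_metabarcoding(k = 3, columns = 120, n_diag = 2,
                                n_samples = 12, depth_mean = 1500,
                                error_rate = 0.01, seed = 99)
  reads <- sim$reads$reads$A
  der <- dereplicate(reads$sequence, reads$sample_id, "A")
  planted <- unique(unlist(sim$reference$truth$haplotypes))
  spurious <- !(der$sequences %in% planted)
  expect_gt(sum(spurious), 0)
  # every spurious ASV is below the 200-read major threshold
  expect_true(all(asv_totals(der)[spurious] < 200))
  # selection removes >= 99% of error-generated ASVs
  sel <- select_major(der, 200)
  kept_spurious <- sum(!(sel$sequences %in% planted))
  expect_lte(kept_spurious, 0.01 * sum(spurious))
})

test_that("cross-dataset confirmation flags exactly the shared planted haplotypes", {
  sim <- simulate_metabarcoding(k = 3, columns = 80, n_diag = 2,
                                n_samples = 12, depth_mean = 1500,
                                error_rate = 0.005, seed = 55)
  derA <- dereplicate(sim$reads$reads$A$sequence,
                      sim$reads$reads$A$sample_id, "A")
  derB <- dereplicate(sim$reads$reads$B$sequence,
                      sim$reads$reads$B$sample_id, "B")
  majA <- select_major(derA, 200)
  conf <- cross_confirm(majA, derB, mode = "exact")
  planted <- unique(unlist(sim$reference$truth$haplotypes))
  truthy <- majA$sequences %in% planted &
    majA$sequences %in% derB$sequences
  expect_identical(conf$confirmed, unname(truthy))
  # all planted majors shared between datasets are confirmed
  expect_true(all(conf$confirmed[majA$sequences %in% planted]))
})
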