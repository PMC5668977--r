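test_that("simulate_genome honours seed, length, alphabet and GC target", {
  g1 <- simulate_genome(10000, 0.4, seed = 7)
  g2 <- simulate_genome(10000, 0.4, seed = 7)
  expect_identical(g1[[1]], g2[[1]])

  g <- simulate_genome(1000, 0.5, seed = 1)
  expect_equal(nchar(g[[1]]), 1000L)
  expect_false(grepl("[^ACGT]", g[[1]]))

  # binomial oracle: sd of the GC fraction at n = 1e5, p = 0.35 is ~0.0015,
  # so [0.33, 0.37] is a generous multi-sigma band
  gl <- simulate_genome(100000, 0.35, seed = 3)
  gc <- nchar(gsub("[AT]", "", gl[[1]])) / 100000
  expect_gt(gc, 0.33)
  expect_lt(gc, 0.37)

  expect_error(simulate_genome(-5, 0.4, 1), "length")
  expect_error(simulate_genome(500, 0.4, 1), "length")
})

test_that("plant_hairpin constructs a discoverable stem-loop at the stated locus", {
  g <- simulate_genome(10000, 0.4, seed = 11)
  mat <- "TGACAGAAGAGAGTGAGCACA"  # 21 nt
  pl <- plant_hairpin(g, mat, 500, arm = "5p", locus_id = "L1", seed = 2)
  hp <- pl$hairpin
  expect_equal(hp$start0, 500L)
  # 5p arm: the precursor's first arm contains the mature verbatim
  expect_equal(substr(hp$precursor, hp$mature_offset0 + 1L,
                      hp$mature_offset0 + nchar(mat)), mat)
  expect_equal(substr(pl$genome[[1]], 501L, 500L + hp$precursor_len), hp$precursor)
  expect_true(hp$precursor_len >= 61 && hp$precursor_len <= 218)

  # the planted precursor folds so that the mature arm is >= 80% paired
  f <- fold_rna(hp$precursor)
  pt <- pairing_table(f$dotbracket)
  m <- (hp$mature_offset0 + 1L):(hp$mature_offset0 + nchar(mat))
  expect_gte(mean(!is.na(pt[m])), 0.8)

  # star geometry: 2-nt 3' overhangs relative to the mature in the duplex
  N <- hp$precursor_len; p <- hp$mature_offset0; L <- nchar(mat)
  expect_equal(hp$star_offset0, N - p - L + 2L)
  expect_equal(hp$star_seq,
               substr(hp$precursor, hp$star_offset0 + 1L, hp$star_offset0 + L))

  # overlap with an existing locus is refused
  expect_error(plant_hairpin(pl$genome, "TTTGGATTGAAGGGAGCTCTA", 510,
                             locus_id = "L2", seed = 3), "overlap")
  # out-of-range placement is refused
  expect_error(plant_hairpin(g, mat, 9990, seed = 1), "fit")
})

test_that("3p-arm planting mirrors the 5p geometry", {
  g <- simulate_genome(5000, 0.4, seed = 5)
  mat <- "TTTGGATTGAAGGGAGCTCTA"
  hp <- plant_hairpin(g, mat, 1000, arm = "3p", locus_id = "L", seed = 6)$hairpin
  L <- nchar(mat); N <- hp$precursor_len
  expect_equal(substr(hp$precursor, hp$mature_offset0 + 1L,
                      hp$mature_offset0 + L), mat)
  # 3p geometry: star at p - 2 and mature at N - p - L, so
  # mature_offset0 = N - star_offset0 - 2 - L
  expect_equal(hp$mature_offset0, N - hp$star_offset0 - 2L - L)
  f <- fold_rna(hp$precursor)
  ev <- evaluate_hairpin(f$dotbracket, hp$mature_offset0, L)
  expect_true(ev$pass)
})

test_that("simulate_libraries respects depth, count model and composition", {
  g <- simulate_genome(20000, 0.4, seed = 9)
  pl <- plant_hairpin(g, "TGACAGAAGAGAGTGAGCACA", 3000, locus_id = "locA", seed = 1)
  hps <- list(pl$hairpin)
  designs <- make_library_designs(depth = 200000L, contaminant_fraction = 0.1)[1]
  truth <- data.table::data.table(locus_id = "locA",
                                  library_id = designs$library_id,
                                  expected_tpm = 500, true_fc = 1)
  contam <- make_contaminants(seed = 4)
  sim <- simulate_libraries(pl$genome, hps, truth, designs, contam, seed = 21)
  reads <- sim$reads[[1]]
  expect_length(reads, 200000L)  # depth contract, exactly

  # Poisson oracle: expected mature count = 500 * 200000 / 1e6 = 100, 3 sigma = 30
  n_mat <- sim$counts$mature_count
  expect_gt(n_mat, 100 - 30)
  expect_lt(n_mat, 100 + 30)
  # every mature read is insert + adapter truncated to the read length
  expected_read <- substr(paste0("TGACAGAAGAGAGTGAGCACA", designs$adapter3), 1, 51)
  expect_equal(sum(reads == expected_read), n_mat)

  # binomial oracle for the contaminant fraction: 3 sigma of 0.1 at n = 2e5
  sd3 <- 3 * sqrt(0.1 * 0.9 / 200000)
  expect_lt(abs(sim$lib_stats$n_contaminant / 200000 - 0.1), sd3)

  # unknown locus in the truth table is a consistency error
  bad <- data.table::copy(truth); bad$locus_id <- "ghost"
  expect_error(simulate_libraries(pl$genome, hps, bad, designs, contam, seed = 1),
               "unknown locus")
})

test_that("library simulation is byte-identical under a fixed seed", {
  g <- simulate_genome(5000, 0.4, seed = 2)
  pl <- plant_hairpin(g, "TGAAGCTGCCAGCATGATCTA", 1000, locus_id = "locA", seed = 1)
  designs <- make_library_designs(depth = 5000L)[1:2]
  truth <- make_expression_truth(list(pl$hairpin), designs, seed = 3)
  contam <- make_contaminants(seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_libraries(pl$genome, list(pl$hairpin), truth, designs, contam,
                     seed = 33, out_dir = d1)
  simulate_libraries(pl$genome, list(pl$hairpin), truth, designs, contam,
                     seed = 33, out_dir = d2)
  for (f in list.files(file.path(d1, "fastq"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, "fastq", f))),
                     unname(tools::md5sum(file.path(d2, "fastq", f))))
  }
})

test_that("expression truth applies the heat-stress effect to responsive loci only", {
  g <- simulate_genome(5000, 0.4, seed = 2)
  pl1 <- plant_hairpin(g, "TGAAGCTGCCAGCATGATCTA", 1000, locus_id = "a", seed = 1)
  pl2 <- plant_hairpin(pl1$genome, "TGACAGAAGAGAGTGAGCACA", 2000,
                       locus_id = "b", seed = 2)
  hps <- list(pl1$hairpin, pl2$hairpin)
  designs <- make_library_designs(depth = 1000L)
  tr <- make_expression_truth(hps, designs, responsive = "b", hs_fc = 0.25, seed = 5)
  wide <- data.table::dcast(tr, locus_id ~ library_id, value.var = "expected_tpm")
  hs_cols <- designs$library_id[designs$condition == "HS"]
  ck_cols <- designs$library_id[designs$condition == "CK"]
  a <- wide[wide$locus_id == "a"]; b <- wide[wide$locus_id == "b"]
  expect_equal(unlist(a[, ..hs_cols]) / unlist(a[, ..ck_cols]),
               rep(1, 8), ignore_attr = TRUE)
  expect_equal(unlist(b[, ..hs_cols]) / unlist(b[, ..ck_cols]),
               rep(0.25, 8), ignore_attr = TRUE)
  expect_true(all(tr$expected_tpm >= 0))
  expect_error(make_expression_truth(hps, designs, responsive = "zzz"),
               "unknown")
})
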