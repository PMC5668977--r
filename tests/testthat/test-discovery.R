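test_that("map_exact finds planted tags and nothing else", {
  tp <- tiny_planted(seed = 7)
  mat <- tp$matures[1]
  hp <- tp$hairpins[[1]]
  hits <- map_exact(c(mat, "ACGTACGTACGTACGTAA"), tp$genome)
  h1 <- hits[[mat]]
  # planted mature occurs on the + strand at its locus, and its reverse
  # complement occurs on the star arm of the same hairpin
  expect_true(any(h1$start0 == hp$mature_start0 & h1$strand == "+"))
  expect_equal(nrow(hits[["ACGTACGTACGTACGTAA"]]), 0L)
})

test_that("map_exact equals the naive full-scan oracle, both strands", {
  set.seed(13)
  g <- simulate_genome(50000, 0.42, seed = 13)
  # plant a tag 25 times to exercise multi-hit reporting
  tag25 <- "TGCCAAGGATGACTTGCCGAT"
  gseq <- g[[1]]
  pos <- seq(100, 49000, length.out = 25)
  for (p in pos) substr(gseq, p, p + nchar(tag25) - 1) <- tag25
  g[[1]] <- gseq
  tags <- c(tag25, vapply(1:40, function(i) random_dna_str(sample(18:30, 1)), ""),
            # genuine genomic substrings (guaranteed hits)
            vapply(seq(1, 45000, length.out = 20), function(s)
              substr(gseq, s, s + 21), ""))
  hits <- map_exact(tags, g)
  expect_equal(nrow(hits[[tag25]]), 25L)
  for (tg in unique(toupper(tags))) {
    expect_equal(as.data.frame(hits[[tg]]), as.data.frame(naive_map(tg, g)),
                 info = tg)
  }
})

test_that("mapping against the reverse-complemented genome mirrors coordinates", {
  g <- simulate_genome(2000, 0.4, seed = 3)
  tag <- substr(g[[1]], 501, 521)
  grc <- setNames(revcomp(g[[1]]), names(g))
  h <- map_exact(tag, g)[[tag]]
  hrc <- map_exact(tag, grc)[[tag]]
  n <- nchar(g[[1]])
  expect_equal(hrc$strand, chartr("+-", "-+", h$strand))
  expect_equal(sort(hrc$start0), sort(n - h$end0))
})

test_that("candidate selection applies TPM, length and hit-count rules", {
  tags <- data.table::data.table(
    sequence = c(strrep("ACGTAGGTCAAGTGCATGCATGAC", 1),  # 24 nt
                 "ACGTACGTACGTACGT",                      # 16 nt
                 "TTGCATGCAAGGTCAGTCAGT"),                # 21 nt
    tpm.l1 = c(15, 1000, 9), tpm.l2 = c(2, 500, 9.9))
  sel <- select_candidates(tags, NULL, min_tpm = 10, len_range = c(18, 30))
  expect_equal(sel$sequence, tags$sequence[1])   # 16-nt tag excluded despite TPM
  hm <- list(data.table::data.table(chrom = "c", start0 = 1:3, end0 = 2:4,
                                    strand = "+"))
  names(hm) <- tags$sequence[1]
  sel2 <- select_candidates(tags, hm, min_tpm = 10, len_range = c(18, 30),
                            max_hits = 20)
  expect_equal(sel2$n_hits, 3L)
  hm25 <- list(data.table::data.table(chrom = "c", start0 = 1:25, end0 = 2:26,
                                      strand = "+"))
  names(hm25) <- tags$sequence[1]
  expect_equal(nrow(select_candidates(tags, hm25, 10, c(18, 30), 20)), 0L)
})

test_that("precursor extraction clips flanks and handles the minus strand", {
  g <- setNames(paste(rep("ACGT", 250), collapse = ""), "chr1")  # 1000 bp
  hit <- list(chrom = "chr1", start0 = 500L, end0 = 521L, strand = "+")
  pre <- extract_precursor(hit, g, flank = 200)
  expect_equal(c(pre$wstart0, pre$wend0), c(300L, 721L))
  expect_equal(nchar(pre$seq), 421L)
  expect_equal(pre$mature_offset0, 200L)

  hit2 <- list(chrom = "chr1", start0 = 10L, end0 = 31L, strand = "+")
  pre2 <- extract_precursor(hit2, g, flank = 200)
  expect_equal(c(pre2$wstart0, pre2$wend0), c(0L, 231L))

  hitm <- list(chrom = "chr1", start0 = 500L, end0 = 521L, strand = "-")
  prem <- extract_precursor(hitm, g, flank = 50)
  manual <- revcomp(substr(g[[1]], 451, 571))
  expect_equal(prem$seq, chartr("T", "U", manual))
  expect_equal(prem$mature_offset0, 50L)
  # the mature slice of a minus-strand window is the tag's reverse complement
  expect_equal(substr(chartr("U", "T", prem$seq), 51, 71),
               revcomp(substr(g[[1]], 501, 521)))
})

test_that("hairpin criteria pass ideal stems and report each violation", {
  # perfectly complementary 22-bp stem, 10-nt loop, mature on the 5p arm
  stem <- "GCTAGGTCAAGTGCATGATCCA"
  pre <- paste0(stem, strrep("A", 10), revcomp(stem))
  f <- fold_rna(pre)
  expect_true(evaluate_hairpin(f$dotbracket, 0L, 22L)$pass)

  # mature spanning the terminal loop
  ev <- evaluate_hairpin(f$dotbracket, 15L, 22L)
  expect_false(ev$pass)
  expect_true("mature_in_loop" %in% ev$reasons)

  # six unpaired mature bases (dot-bracket oracle, hand-built)
  db <- paste0(".....", strrep("(", 14), strrep(".", 6), "....",
               strrep(")", 14), ".....")
  ev2 <- evaluate_hairpin(db, 5L, 20L)
  expect_false(ev2$pass)
  expect_true("too_many_mispairs" %in% ev2$reasons)

  # asymmetric bulge of 4 nt inside the duplex
  db3 <- paste0(strrep("(", 10), "....", strrep("(", 10), "....",
                strrep(")", 20))
  ev3 <- evaluate_hairpin(db3, 0L, 24L)
  expect_false(ev3$pass)
  expect_true("large_bulge" %in% ev3$reasons)
})

test_that("known classification tolerates up to two mismatches, sliding ends", {
  ref <- setNames(c("TGACAGAAGAGAGTGAGCACA", "TTGACAGAAGATAGAGAGCAC"),
                  c("miR160a", "miR395a"))
  attr(ref, "family") <- c("miR160", "miR395")
  hit <- classify_known("TGACAGAAGAGAGTGAGCACA", ref)
  expect_equal(hit$name, "miR160a")
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$family, "miR160")

  two <- "TGACAGAACAGAGTGAGCACT"  # 2 substitutions vs miR160a
  expect_equal(classify_known(two, ref)$mismatches, 2L)
  three <- "TGACAGAACAGAGTGACCACT"
  expect_null(classify_known(three, ref))

  # 1-nt longer query: overhang counts as one mismatch
  longer <- paste0("TGACAGAAGAGAGTGAGCACA", "G")
  expect_equal(classify_known(longer, ref)$mismatches, 1L)
  expect_error(classify_known("ACGT", character(0)), "empty")
})

test_that("novel validation needs stability and an opposite-arm star", {
  tp <- tiny_planted(seed = 7)
  hp <- tp$hairpins[[1]]
  f <- fold_rna(hp$precursor)
  v <- validate_novel(f, chartr("T", "U", hp$precursor), hp$mature_offset0,
                      nchar(hp$mature_seq), tag_seqs = hp$star_seq)
  expect_true(v$novel)
  expect_true(v$star_supported)
  expect_equal(v$star_seq, hp$star_seq)
  expect_equal(v$star_offset0, hp$star_offset0)

  weak <- list(dotbracket = f$dotbracket, mfe = -10)
  v2 <- validate_novel(weak, chartr("T", "U", hp$precursor), hp$mature_offset0,
                       nchar(hp$mature_seq))
  expect_false(v2$novel)
  expect_true("mfe_above_threshold" %in% v2$reasons)

  v3 <- validate_novel(f, chartr("T", "U", hp$precursor), hp$mature_offset0,
                       nchar(hp$mature_seq), tag_seqs = "AAAA",
                       require_star_read = TRUE)
  expect_false(v3$novel)
  expect_true("star_not_sequenced" %in% v3$reasons)
})

test_that("family grouping is single-linkage with an all-pairs oracle", {
  a <- "TGACAGAAGAGAGTGAGCACA"
  b <- a; substr(b, 3, 3) <- "T"; substr(b, 10, 10) <- "C"  # distance 2
  g <- group_families(c(a, a))
  expect_equal(g$group[1], g$group[2])
  g2 <- group_families(c(a, b), max_mismatch = 3)
  expect_equal(g2$group[1], g2$group[2])

  far <- c("TGACAGAAGAGAGTGAGCACA", "ACCGTTAGGCAATTCCGGATC",
           "GGGTCCAAATTTGGGCCCAAT")
  d <- outer(far, far, Vectorize(function(x, y) heatmir:::sliding_distance(x, y)))
  expect_true(all(d[upper.tri(d)] > 3))  # oracle: all pairs distant
  g3 <- group_families(far, max_mismatch = 3)
  expect_true(all(is.na(g3$group)))      # three singletons, no groups
  expect_error(group_families(character(0)), "at least one")
})

test_that("discovery recovers planted loci with correct precedence", {
  tp <- tiny_planted(seed = 7)
  ref <- setNames(tp$matures[1], "syn-miR0001a")  # locus 1 seeded from reference
  attr(ref, "family") <- "miR0001"
  # tag table: the three matures, one star (sequenced), one random tag
  hp <- tp$hairpins
  seqs <- c(tp$matures, hp[[2]]$star_seq, hp[[3]]$star_seq,
            "TTGCATGCAAGGTCAGTCAGT")
  tags <- data.table::data.table(sequence = seqs)
  tags[, count.l1 := c(500L, 400L, 300L, 20L, 15L, 5L)]
  tags <- tpm_normalize(tags, c(l1 = 1e5))
  cat <- discover_mirnas(tags, tp$genome, ref)
  m <- match(tp$matures, cat$sequence)
  expect_false(any(is.na(m)))
  expect_equal(cat$status[m], c("known", "novel", "novel"))
  expect_equal(cat$name[m[1]], "syn-miR0001a")
  expect_equal(cat$mismatches_to_ref[m[1]], 0L)
  # precedence: a 1-mismatch variant of the reference is never novel
  v <- tp$matures[1]; substr(v, 5, 5) <- "C"
  g2 <- plant_hairpin(tp$genome, v, 18000, locus_id = "L4", seed = 4)
  tags2 <- data.table::data.table(sequence = v, count.l1 = 100L)
  tags2 <- tpm_normalize(tags2, c(l1 = 1e5))
  cat2 <- discover_mirnas(tags2, g2$genome, ref)
  expect_equal(cat2$status, "known")
  expect_equal(cat2$mismatches_to_ref, 1L)
})
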