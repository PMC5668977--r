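# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, sharing no code with the package
# internals they check.

## Textbook closed form of the 2x2 Pearson chi-square:
## N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on [[a, b], [c, d]].
chi2_closed <- function(count_a, total_a, count_b, total_b) {
  a <- as.numeric(count_a); b <- as.numeric(total_a) - a
  c <- as.numeric(count_b); d <- as.numeric(total_b) - c
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

## Exhaustive enumeration of all nested secondary structures (min loop 3)
## under the same pair/stack scoring, via first-pair decomposition. `ctx`
## is TRUE when positions i-1 and j+1 form a pair (stacking context).
pair_sc <- function(a, b) {
  switch(paste0(a, b), GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1, -Inf)
}
enum_best_score <- function(v, i = 1L, j = length(v), ctx = FALSE) {
  if (j - i + 1L < 5L) return(0)
  best <- enum_best_score(v, i + 1L, j, FALSE)  # i unpaired
  for (k in (i + 4L):j) {
    s <- pair_sc(v[i], v[k])
    if (!is.finite(s)) next
    bonus <- if (ctx && k == j) 1 else 0
    tot <- s + bonus + enum_best_score(v, i + 1L, k - 1L, TRUE) +
      (if (k < j) enum_best_score(v, k + 1L, j, FALSE) else 0)
    if (tot > best) best <- tot
  }
  best
}

## Naive full-scan exact mapper: every occurrence of the tag (forward) and of
## its reverse complement (reported as strand "-") on every chromosome.
naive_map <- function(tag, genome) {
  out <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  for (ch in names(genome)) {
    for (q in list(c(tag, "+"), c(rc, "-"))) {
      # manual scan (gregexpr misses overlapping occurrences)
      starts <- integer(0)
      from <- 1L
      while (TRUE) {
        hit <- regexpr(q[1], substr(genome[[ch]], from, nchar(genome[[ch]])),
                       fixed = TRUE)
        if (hit < 0) break
        starts <- c(starts, from + hit - 1L)
        from <- from + hit  # allow overlaps
      }
      if (length(starts))
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = ch, start0 = starts - 1L,
          end0 = starts - 1L + nchar(tag), strand = q[2])
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(0), start0 = integer(0),
                                  end0 = integer(0), strand = character(0)))
  h <- data.table::rbindlist(out)
  data.table::setorder(h, chrom, start0, strand)
  h
}

## score a dot-bracket structure under the engine's scheme, independently of
## the DP (pair table + stack counting)
score_structure <- function(seq, db) {
  v <- strsplit(seq, "")[[1]]
  pt <- pairing_table(db)
  sc <- 0
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (is.na(j) || j < i) next
    sc <- sc + pair_sc(v[i], v[j])
    if (i > 1 && !is.na(pt[i - 1]) && pt[i - 1] == j + 1) sc <- sc + 1
  }
  sc
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## a tiny deterministic planted-genome fixture shared by discovery tests
tiny_planted <- function(seed = 7, n_loci = 3, glen = 20000) {
  g <- simulate_genome(glen, 0.4, seed = seed)
  mats <- c("TGACAGAAGAGAGTGAGCACA", "TTTGGATTGAAGGGAGCTCTA",
            "TGAAGCTGCCAGCATGATCTA")[seq_len(n_loci)]
  hps <- list()
  pos <- c(2000, 8000, 14000)
  arms <- c("5p", "3p", "5p")
  for (i in seq_len(n_loci)) {
    pl <- plant_hairpin(g, mats[i], pos[i], arm = arms[i],
                        locus_id = paste0("L", i), seed = seed + i)
    g <- pl$genome
    hps[[i]] <- pl$hairpin
  }
  list(genome = g, hairpins = hps, matures = mats)
}
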