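## Synthetic sRNA-seq data with planted ground truth. The generator emulates
## the study design it is meant to exercise: 16 libraries (stamen/pistil x
## CK/HS x 2d/12d x 2 replicates), 15-40 nt inserts plus a 3' adapter,
## structural-RNA contaminants, genomic degradation background, and
## heat-stress down-regulation of a chosen subset of planted miRNA loci.

DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"

#' Simulate a random genome sequence
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; identical inputs give identical sequences.
#' @param chrom_id chromosome name.
#' @return named character vector of length 1 (the chromosome), with an empty
#'   `planted_loci` attribute ready for [plant_hairpin()].
#' @export
simulate_genome <- function(length, gc = 0.4, seed = 1, chrom_id = "chr1") {
  if (!is.numeric(length) || length < 1000)
    stop("simulate_genome: length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("simulate_genome: gc must be in (0, 1)")
  seq <- with_seed(seed, random_dna(as.integer(length), gc))
  genome <- setNames(seq, chrom_id)
  attr(genome, "planted_loci") <- data.table::data.table(
    locus_id = character(), chrom = character(),
    start0 = integer(), end0 = integer())
  genome
}

## Construct a stem-loop precursor around a mature sequence.
## Geometry (5p arm): [lower stem][mature][upper stem] LOOP [revcomp arm],
## so the star (the passenger strand, 2-nt 3' overhangs on both duplex ends)
## sits at N - p - L + 2 for a mature at offset p in a precursor of length N.
build_hairpin <- function(mature_seq, arm = c("5p", "3p"),
                          lower_stem = 10L, upper_stem = 5L, loop_len = 12L,
                          star_mismatches = 0L, gc = 0.5) {
  arm <- match.arg(arm)
  mature <- toupper(rna_to_dna(mature_seq))
  L <- nchar(mature)
  if (L < 18L || L > 26L) stop("build_hairpin: mature must be 18-26 nt")
  if (lower_stem < 2L) stop("build_hairpin: lower_stem must be >= 2")
  if (loop_len < 8L) stop("build_hairpin: loop must be >= 8 nt")
  p <- lower_stem
  arm5_core <- if (arm == "5p") mature else revcomp(mature)
  arm5 <- paste0(random_dna(lower_stem, gc), arm5_core, random_dna(upper_stem, gc))
  loop <- random_dna(loop_len, 0.2)  # AU-rich loop folds weakly
  precursor <- paste0(arm5, loop, revcomp(arm5))
  N <- nchar(precursor)
  if (arm == "5p") {
    mature_offset0 <- p
    star_offset0 <- N - p - L + 2L
  } else {
    mature_offset0 <- N - p - L
    star_offset0 <- p - 2L
  }
  if (star_mismatches > 0L) {
    pre <- strsplit(precursor, "", fixed = TRUE)[[1]]
    interior <- (star_offset0 + 3L):(star_offset0 + L - 2L)
    pos <- sample(interior, min(star_mismatches, length(interior)))
    for (i in pos) pre[i] <- sample(setdiff(c("A", "C", "G", "T"), pre[i]), 1L)
    precursor <- paste(pre, collapse = "")
  }
  star_seq <- substr(precursor, star_offset0 + 1L, star_offset0 + L)
  list(precursor = precursor, arm = arm, mature_seq = mature,
       star_seq = star_seq, loop_seq = loop,
       mature_offset0 = mature_offset0, star_offset0 = star_offset0)
}

#' Plant a miRNA hairpin locus into a genome
#'
#' Builds a stem-loop precursor whose one arm carries `mature_seq` (the other
#' arm carries the star with 2-nt 3' overhangs in the duplex) and writes it
#' into the genome at `position`. The constructed precursor is folded and
#' checked against the default hairpin criteria before being emitted, so
#' planted loci are guaranteed discoverable.
#'
#' @param genome genome from [simulate_genome()] (or any named character
#'   vector carrying a `planted_loci` attribute).
#' @param mature_seq mature miRNA, 18-26 nt (RNA or DNA alphabet).
#' @param position 0-based start of the precursor on the chromosome.
#' @param arm `"5p"` or `"3p"`: which precursor arm carries the mature.
#' @param locus_id identifier for the locus.
#' @param chrom chromosome name (default: first).
#' @param seed optional seed for the random stem flanks and loop.
#' @param star_mismatches number of mutations placed on the star arm.
#' @param lower_stem,upper_stem,loop_len hairpin geometry (nt).
#' @return list with elements `genome` (modified) and `hairpin` (the planted
#'   locus record).
#' @export
plant_hairpin <- function(genome, mature_seq, position, arm = c("5p", "3p"),
                          locus_id = "locus1", chrom = names(genome)[1],
                          seed = NULL, star_mismatches = 0L,
                          lower_stem = 10L, upper_stem = 5L, loop_len = 12L) {
  arm <- match.arg(arm)
  hp <- with_seed(seed, build_hairpin(mature_seq, arm, lower_stem, upper_stem,
                                      loop_len, star_mismatches))
  N <- nchar(hp$precursor)
  gseq <- genome[[chrom]]
  if (position < 0 || position + N > nchar(gseq))
    stop("plant_hairpin: precursor does not fit the genome at position ", position)
  loci <- attr(genome, "planted_loci")
  if (!is.null(loci) && nrow(loci) > 0) {
    clash <- loci[loci$chrom == chrom &
                    position < loci$end0 & (position + N) > loci$start0, ]
    if (nrow(clash) > 0)
      stop("plant_hairpin: placement overlaps planted locus ", clash$locus_id[1])
  }
  fold <- fold_rna(hp$precursor)
  verdict <- evaluate_hairpin(fold$dotbracket, hp$mature_offset0, nchar(hp$mature_seq))
  if (!verdict$pass)
    stop("plant_hairpin: constructed precursor fails hairpin criteria: ",
         paste(verdict$reasons, collapse = ", "))
  substr(gseq, position + 1L, position + N) <- hp$precursor
  genome[[chrom]] <- gseq
  rec <- c(hp, list(
    locus_id = locus_id, chrom = chrom, start0 = as.integer(position),
    strand = "+", precursor_len = N,
    mature_start0 = as.integer(position + hp$mature_offset0),
    star_start0 = as.integer(position + hp$star_offset0),
    mfe = fold$mfe, dotbracket = fold$dotbracket))
  attr(genome, "planted_loci") <- data.table::rbindlist(list(
    loci, data.table::data.table(locus_id = locus_id, chrom = chrom,
                                 start0 = as.integer(position),
                                 end0 = as.integer(position + N))))
  list(genome = genome, hairpin = rec)
}

#' The 16-library study design
#'
#' Stamen and pistil tissue under control (CK, 25 C) and heat stress (HS,
#' 35 C), sampled at 2 d and 12 d with two biological replicates each.
#'
#' @param depth reads per library.
#' @param adapter3 3' adapter ligated to every insert.
#' @param contaminant_fraction fraction of reads drawn from structural RNAs.
#' @param background_fraction nominal fraction of genomic degradation reads
#'   (the actual background fills the depth remaining after miRNA and
#'   contaminant reads).
#' @return data.table, one row per library.
#' @export
make_library_designs <- function(depth = 200000L, adapter3 = DEFAULT_ADAPTER3,
                                 contaminant_fraction = 0.45,
                                 background_fraction = 0.53) {
  if (depth <= 0) stop("make_library_designs: depth must be > 0")
  if (contaminant_fraction + background_fraction > 1)
    stop("make_library_designs: fractions must sum to <= 1")
  d <- data.table::CJ(replicate = c(1L, 2L), timepoint = c("2d", "12d"),
                      condition = c("CK", "HS"), tissue = c("stamen", "pistil"),
                      sorted = FALSE)
  d <- d[, c("tissue", "condition", "timepoint", "replicate"), with = FALSE]
  data.table::setorder(d, tissue, condition, timepoint, replicate)
  d[, `:=`(library_id = paste(tissue, condition, timepoint,
                              paste0("r", replicate), sep = "_"),
           depth = as.integer(depth), adapter3 = adapter3,
           contaminant_fraction = contaminant_fraction,
           background_fraction = background_fraction)]
  d[]
}

#' Synthetic structural-RNA contaminant set
#'
#' Random sequences standing in for the rRNA/tRNA/snoRNA/snRNA catalog a
#' user would normally supply (e.g. Rfam-derived). Names carry the class as
#' prefix (`rRNA_1`, `tRNA_3`, ...), which [filter_contaminants()] parses.
#'
#' @param seed integer seed.
#' @return named character vector of DNA sequences.
#' @export
make_contaminants <- function(seed = 1) {
  with_seed(seed, {
    lens <- c(rRNA_1 = 1800L, rRNA_2 = 3200L, tRNA_1 = 76L, tRNA_2 = 75L,
              tRNA_3 = 88L, tRNA_4 = 76L, snoRNA_1 = 140L, snoRNA_2 = 210L,
              snRNA_1 = 165L, snRNA_2 = 190L)
    setNames(vapply(lens, function(n) random_dna(n, 0.52), ""), names(lens))
  })
}

#' Synthetic reference mature-miRNA catalog
#'
#' Stands in for a miRBase-style mature FASTA; headers are `name family`.
#' Families are mutually distant (sliding distance > 4) so known/novel
#' classification on synthetic data is unambiguous.
#'
#' @param n number of entries.
#' @param seed integer seed.
#' @return named character vector (DNA form); `attr(, "family")` gives the
#'   family of each entry.
#' @export
make_reference_mirnas <- function(n = 40L, seed = 1) {
  with_seed(seed, {
    seqs <- character(0); fams <- character(0); nms <- character(0)
    fam_i <- 0L
    while (length(seqs) < n) {
      fam_i <- fam_i + 1L
      cand <- random_mature(sample(20:22, 1L))
      if (length(seqs) && min(vapply(seqs, sliding_distance, 0, b = cand)) <= 4) next
      fam <- sprintf("miR%04d", fam_i)
      seqs <- c(seqs, cand); fams <- c(fams, fam)
      nms <- c(nms, paste0("syn-", fam, "a"))
      # every third family gets a second, 1-mismatch member
      if (fam_i %% 3L == 0L && length(seqs) < n) {
        v <- strsplit(cand, "")[[1]]
        i <- sample(3:(length(v) - 2L), 1L)
        v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
        seqs <- c(seqs, paste(v, collapse = ""))
        fams <- c(fams, fam); nms <- c(nms, paste0("syn-", fam, "b"))
      }
    }
    out <- setNames(seqs[seq_len(n)], nms[seq_len(n)])
    attr(out, "family") <- fams[seq_len(n)]
    out
  })
}

## Random mature with the 5'-nucleotide bias seen in AGO1-loaded plant sRNAs
## (U-rich 5' terminal, C-poor).
random_mature <- function(len) {
  first <- sample(c("T", "A", "G", "C"), 1L, prob = c(0.50, 0.25, 0.16, 0.09))
  paste0(first, random_dna(len - 1L, 0.48))
}

#' Expression truth table for planted loci
#'
#' Per-locus baseline abundance (TPM, log-uniform) with a multiplicative
#' heat-stress effect on the responsive loci: expected TPM is
#' `base_tpm * hs_fc` in every HS library and `base_tpm` otherwise, so the
#' true HS/CK fold change is `hs_fc` for responsive loci and 1 for the rest.
#'
#' @param hairpins list of planted hairpin records.
#' @param designs library design table from [make_library_designs()].
#' @param responsive character vector of locus ids that respond to HS.
#' @param hs_fc true HS/CK fold change of responsive loci (default 0.25,
#'   i.e. 4-fold down-regulation).
#' @param base_tpm optional named numeric of baseline TPM per locus;
#'   defaults to log-uniform draws on `base_tpm_range`.
#' @param base_tpm_range range of baseline TPM draws.
#' @param seed integer seed.
#' @return data.table (locus_id, library_id, expected_tpm, true_fc).
#' @export
make_expression_truth <- function(hairpins, designs, responsive = character(0),
                                  hs_fc = 0.25, base_tpm = NULL,
                                  base_tpm_range = c(50, 5000), seed = 1) {
  ids <- vapply(hairpins, `[[`, "", "locus_id")
  if (!all(responsive %in% ids))
    stop("make_expression_truth: unknown responsive locus id")
  if (is.null(base_tpm)) {
    base_tpm <- with_seed(seed, setNames(
      exp(runif(length(ids), log(base_tpm_range[1]), log(base_tpm_range[2]))), ids))
  }
  if (!all(ids %in% names(base_tpm)))
    stop("make_expression_truth: base_tpm must cover every locus")
  g <- data.table::CJ(locus_id = ids, library_id = designs$library_id,
                      unique = FALSE, sorted = FALSE)
  g <- merge(g, designs[, c("library_id", "condition")], by = "library_id",
             sort = FALSE)
  g[, true_fc := ifelse(locus_id %in% responsive, hs_fc, 1)]
  g[, expected_tpm := base_tpm[locus_id] * ifelse(condition == "HS", true_fc, 1)]
  g[, condition := NULL]
  data.table::setcolorder(g, c("locus_id", "library_id", "expected_tpm", "true_fc"))
  data.table::setorder(g, locus_id, library_id)
  g[]
}

#' Simulate the small-RNA libraries
#'
#' Each read is an insert followed by the 3' adapter, truncated to the read
#' length (Phred+33 quality `"I"` throughout). Mature and star read counts
#' are Poisson around `expected_tpm * depth / 1e6` (negative binomial when
#' `nb_size` is set); contaminant reads are 15-40 nt windows of the supplied
#' structural RNAs; the remaining depth is filled with random genomic
#' degradation fragments (15-40 nt). Output is byte-identical for identical
#' inputs and seed.
#'
#' @param genome genome (named character vector).
#' @param hairpins list of planted hairpin records from [plant_hairpin()].
#' @param truth table from [make_expression_truth()].
#' @param designs table from [make_library_designs()].
#' @param contaminants named character vector of structural RNAs.
#' @param seed integer seed.
#' @param read_length sequencing read length (single-end).
#' @param star_fraction star read abundance as a fraction of mature.
#' @param nb_size optional negative-binomial size (overdispersion); `NULL`
#'   keeps pure Poisson counts.
#' @param out_dir if given, FASTQ (one per library), the truth table
#'   (`truth.tsv`) and the planted-locus GFF3 are written there and reads are
#'   not kept in memory.
#' @return list: `reads` (named list of character vectors, or NULL when
#'   written to disk), `fastq` (paths or NULL), `counts` (true per-library
#'   mature/star counts), `lib_stats` (per-library composition), `truth`.
#' @export
simulate_libraries <- function(genome, hairpins, truth, designs, contaminants,
                               seed = 1, read_length = 51L, star_fraction = 0.05,
                               nb_size = NULL, out_dir = NULL) {
  ids <- vapply(hairpins, `[[`, "", "locus_id")
  if (!all(truth$locus_id %in% ids))
    stop("simulate_libraries: truth names unknown locus: ",
         paste(setdiff(unique(truth$locus_id), ids), collapse = ", "))
  mature <- setNames(vapply(hairpins, `[[`, "", "mature_seq"), ids)
  star <- setNames(vapply(hairpins, `[[`, "", "star_seq"), ids)
  if (!is.null(out_dir)) dir.create(file.path(out_dir, "fastq"),
                                    recursive = TRUE, showWarnings = FALSE)
  keep <- is.null(out_dir)
  reads_out <- if (keep) vector("list", nrow(designs)) else NULL
  fastq <- character(0)
  counts <- vector("list", nrow(designs))
  stats <- vector("list", nrow(designs))
  gl <- nchar(genome)
  with_seed(seed, {
    for (r in seq_len(nrow(designs))) {
      d <- designs[r]
      tl <- truth[truth$library_id == d$library_id, ]
      tl <- tl[match(ids, tl$locus_id), ]
      lam <- tl$expected_tpm * d$depth / 1e6
      draw <- function(mu) {
        if (is.null(nb_size)) rpois(length(mu), mu)
        else stats::rnbinom(length(mu), mu = mu, size = nb_size)
      }
      n_mat <- draw(lam)
      n_star <- draw(star_fraction * lam)
      n_contam <- rbinom(1L, d$depth, d$contaminant_fraction)
      n_bg <- d$depth - sum(n_mat) - sum(n_star) - n_contam
      if (n_bg < 0)
        stop("simulate_libraries: depth too small for the requested abundances")
      ci <- sample(length(contaminants), n_contam, replace = TRUE,
                   prob = nchar(contaminants))
      clen <- sample(15:40, n_contam, replace = TRUE)
      cstart <- floor(runif(n_contam) * (nchar(contaminants)[ci] - clen + 1)) + 1L
      contam_ins <- substring(contaminants[ci], cstart, cstart + clen - 1L)
      gi <- sample(length(genome), n_bg, replace = TRUE, prob = gl)
      blen <- sample(15:40, n_bg, replace = TRUE)
      bstart <- floor(runif(n_bg) * (gl[gi] - blen + 1)) + 1L
      bg_ins <- substring(genome[gi], bstart, bstart + blen - 1L)
      inserts <- c(rep(mature, n_mat), rep(star, n_star), contam_ins, bg_ins)
      inserts <- inserts[sample(length(inserts))]
      reads <- substr(paste0(inserts, d$adapter3), 1L, read_length)
      counts[[r]] <- data.table::data.table(
        locus_id = ids, library_id = d$library_id,
        mature_count = n_mat, star_count = n_star)
      stats[[r]] <- data.table::data.table(
        library_id = d$library_id, depth = d$depth, n_mirna = sum(n_mat),
        n_star = sum(n_star), n_contaminant = n_contam, n_background = n_bg)
      if (keep) {
        reads_out[[r]] <- reads
      } else {
        fp <- file.path(out_dir, "fastq", paste0(d$library_id, ".fastq"))
        write_fastq(reads, paste0(d$library_id, ":", seq_along(reads)), fp)
        fastq <- c(fastq, fp)
      }
    }
  })
  if (keep) names(reads_out) <- designs$library_id else names(fastq) <- designs$library_id
  if (!is.null(out_dir)) {
    data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
    write_gff3(hairpins, file.path(out_dir, "planted_loci.gff3"))
  }
  list(reads = reads_out, fastq = if (keep) NULL else fastq,
       counts = data.table::rbindlist(counts),
       lib_stats = data.table::rbindlist(stats), truth = truth)
}

## Plain FASTQ writer (Phred+33, constant quality "I").
write_fastq <- function(reads, ids, path) {
  qual <- strrep("I", nchar(reads))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), con)
  invisible(path)
}

#' Write planted loci (or a discovered catalog) as GFF3
#'
#' Coordinates are 1-based inclusive in the file (0-based half-open
#' internally).
#'
#' @param hairpins list of hairpin records, or a data.table with columns
#'   chrom, start0, end0, strand, locus_id.
#' @param path output file.
#' @export
write_gff3 <- function(hairpins, path) {
  if (is.list(hairpins) && !is.data.frame(hairpins)) {
    tab <- data.table::data.table(
      chrom = vapply(hairpins, `[[`, "", "chrom"),
      start0 = vapply(hairpins, `[[`, 0L, "start0"),
      end0 = vapply(hairpins, `[[`, 0L, "start0") +
        vapply(hairpins, `[[`, 0L, "precursor_len"),
      strand = vapply(hairpins, `[[`, "", "strand"),
      locus_id = vapply(hairpins, `[[`, "", "locus_id"))
  } else tab <- data.table::as.data.table(hairpins)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start0 + 1L, end = tab$end0),
    strand = tab$strand)
  gr$type <- "miRNA_primary_transcript"
  gr$ID <- tab$locus_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
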