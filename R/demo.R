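#' Bundled synthetic demo dataset
#'
#' Builds the default end-to-end study: a 100-kb genome carrying 30 planted
#' hairpin loci (20 whose matures are taken verbatim from the synthetic
#' reference catalog, 10 novel), the 16-library stamen/pistil x CK/HS x
#' 2d/12d x 2-replicate design at 200k reads per library, with 10 loci
#' down-regulated 4-fold under heat stress. Also produces a small synthetic
#' transcript set with embedded target sites for four planted miRNAs and a
#' 5' RACE clone table supporting the first site.
#'
#' @param seed integer seed driving every random choice.
#' @param out_dir if given, all pipeline inputs (genome, contaminant,
#'   reference and transcript FASTA, FASTQ, truth/design/RACE tables) plus a
#'   ready-to-run `config.yaml` are written there.
#' @param genome_length,gc genome size and base composition.
#' @param n_loci,n_known,n_responsive planted locus counts.
#' @param depth reads per library.
#' @param hs_fc true HS/CK fold change at responsive loci.
#' @param base_tpm_range baseline abundance range (log-uniform TPM).
#' @param contaminant_fraction structural-RNA read fraction per library.
#' @param star_fraction star read abundance relative to mature.
#' @return list with the genome, hairpin records, reference set, truth and
#'   design tables, transcripts, target/RACE truth, simulation output, and
#'   (when written) a `config` ready for [run_pipeline()].
#' @export
demo_dataset <- function(seed = 101, out_dir = NULL,
                         genome_length = 1e5, gc = 0.38,
                         n_loci = 30L, n_known = 20L, n_responsive = 10L,
                         depth = 200000L, hs_fc = 0.25,
                         base_tpm_range = c(50, 5000),
                         contaminant_fraction = 0.45, star_fraction = 0.05) {
  stopifnot(n_known <= n_loci, n_responsive <= n_loci)
  reference <- make_reference_mirnas(40L, seed = seed + 1L)
  contaminants <- make_contaminants(seed = seed + 2L)
  genome <- simulate_genome(genome_length, gc, seed = seed + 3L)

  res <- with_seed(seed + 4L, {
    known_mat <- unname(reference[seq_len(n_known)])
    novel_mat <- character(0)
    while (length(novel_mat) < n_loci - n_known) {
      cand <- random_mature(sample(20:22, 1L))
      if (min(vapply(reference, sliding_distance, 0, b = cand)) <= 2) next
      if (length(novel_mat) &&
          min(vapply(novel_mat, sliding_distance, 0, b = cand)) <= 4) next
      novel_mat <- c(novel_mat, cand)
    }
    matures <- c(known_mat, novel_mat)
    status <- rep(c("known", "novel"), c(n_known, n_loci - n_known))
    slots <- floor(seq(1000, genome_length - 1500, length.out = n_loci))
    pos <- as.integer(slots + sample(0:500, n_loci, replace = TRUE))
    arms <- sample(c("5p", "3p"), n_loci, replace = TRUE)
    hairpins <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      pl <- plant_hairpin(genome, matures[i], pos[i], arm = arms[i],
                          locus_id = sprintf("locus%02d", i),
                          lower_stem = sample(8:14, 1L),
                          upper_stem = sample(4:8, 1L),
                          loop_len = sample(10:16, 1L))
      genome <- pl$genome
      hairpins[[i]] <- c(pl$hairpin, list(truth_status = status[i],
                                          ref_name = if (status[i] == "known")
                                            names(reference)[i] else NA_character_))
    }
    responsive <- sort(sample(vapply(hairpins, `[[`, "", "locus_id"), n_responsive))
    list(genome = genome, hairpins = hairpins, responsive = responsive)
  })

  designs <- make_library_designs(depth = depth,
                                  contaminant_fraction = contaminant_fraction)
  truth <- make_expression_truth(res$hairpins, designs,
                                 responsive = res$responsive, hs_fc = hs_fc,
                                 base_tpm_range = base_tpm_range,
                                 seed = seed + 5L)

  trg <- with_seed(seed + 6L, {
    hp_ids <- vapply(res$hairpins, `[[`, "", "locus_id")
    status <- vapply(res$hairpins, `[[`, "", "truth_status")
    # embed target sites for heat-responsive miRNAs (the ones the pipeline's
    # targeting stage scans), preferring a known/novel mix
    rk <- intersect(hp_ids[status == "known"], res$responsive)
    rn <- intersect(hp_ids[status == "novel"], res$responsive)
    pick <- head(unique(c(head(rk, 2L), head(rn, 2L), res$responsive)), 4L)
    tx <- setNames(vapply(1:6, function(i) random_dna(sample(800:1200, 1L), 0.45), ""),
                   sprintf("tx%02d", 1:6))
    site_truth <- data.table::data.table(
      transcript_id = character(), locus_id = character(), mirna_seq = character(),
      site_start0 = integer(), cleavage_pos0 = integer())
    for (k in seq_along(pick)) {
      hp <- res$hairpins[[match(pick[k], hp_ids)]]
      site <- revcomp(hp$mature_seq)
      s0 <- sample(200:600, 1L)
      t <- tx[[k]]
      substr(t, s0 + 1L, s0 + nchar(site)) <- site
      tx[[k]] <- t
      site_truth <- rbind(site_truth, data.table::data.table(
        transcript_id = names(tx)[k], locus_id = pick[k],
        mirna_seq = hp$mature_seq, site_start0 = s0,
        cleavage_pos0 = s0 + nchar(site) - 10L))
    }
    cp <- site_truth$cleavage_pos0[1]
    race <- data.table::data.table(
      transcript_id = site_truth$transcript_id[1],
      position0 = c(rep(cp, 7L), rep(cp + 3L, 2L), cp - 5L),
      clone_id = sprintf("clone%02d", 1:10))
    list(transcripts = tx, site_truth = site_truth, race = race)
  })

  sim <- simulate_libraries(res$genome, res$hairpins, truth, designs,
                            contaminants, seed = seed + 7L,
                            star_fraction = star_fraction, out_dir = out_dir)

  config <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$genome, file.path(out_dir, "genome.fa"))
    write_fasta(contaminants, file.path(out_dir, "contaminants.fa"))
    ref_out <- reference
    names(ref_out) <- paste(names(reference), attr(reference, "family"))
    write_fasta(ref_out, file.path(out_dir, "reference_mirnas.fa"))
    write_fasta(trg$transcripts, file.path(out_dir, "transcripts.fa"))
    data.table::fwrite(trg$race, file.path(out_dir, "race_clones.tsv"), sep = "\t")
    data.table::fwrite(designs, file.path(out_dir, "designs.tsv"), sep = "\t")
    config <- make_pipeline_config(
      genome = file.path(out_dir, "genome.fa"),
      contaminants = file.path(out_dir, "contaminants.fa"),
      reference = file.path(out_dir, "reference_mirnas.fa"),
      transcripts = file.path(out_dir, "transcripts.fa"),
      race_clones = file.path(out_dir, "race_clones.tsv"),
      fastq = as.list(sim$fastq),
      libraries = designs[, c("library_id", "tissue", "condition",
                              "timepoint", "replicate"), with = FALSE],
      adapter3 = DEFAULT_ADAPTER3,
      seed = seed, output_dir = file.path(out_dir, "results"))
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  }

  list(genome = res$genome, hairpins = res$hairpins, reference = reference,
       contaminants = contaminants, designs = designs, truth = truth,
       responsive = res$responsive, transcripts = trg$transcripts,
       target_truth = trg$site_truth, race_clones = trg$race,
       sim = sim, config = config, out_dir = out_dir)
}
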