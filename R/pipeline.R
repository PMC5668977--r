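#' Build a pipeline configuration
#'
#' @param genome,contaminants,reference,transcripts paths to the genome,
#'   contaminant, reference-mature and (optional) transcript FASTA files.
#' @param fastq named list: library id -> FASTQ path.
#' @param libraries data.frame (library_id, tissue, condition, timepoint,
#'   replicate) describing the design.
#' @param adapter3 3' adapter.
#' @param thresholds named list overriding the defaults (min_tpm 10,
#'   min_len 15, max_len 40, len_range 18-30, max_hits 20, flank 200,
#'   mfe_max -16, de_log2fc 1, de_p 0.05, target_cutoff 3).
#' @param seed integer seed recorded in outputs.
#' @param output_dir where [run_pipeline()] writes results.
#' @param race_clones optional RACE clone TSV (transcript_id, position0,
#'   clone_id).
#' @return config list for [run_pipeline()].
#' @export
make_pipeline_config <- function(genome, contaminants, reference, fastq,
                                 libraries, adapter3 = DEFAULT_ADAPTER3,
                                 transcripts = NULL, race_clones = NULL,
                                 thresholds = list(), seed = 1,
                                 output_dir = "heatmir_results") {
  def <- list(min_tpm = 10, min_len = 15L, max_len = 40L,
              len_min = 18L, len_max = 30L, max_hits = 20L, flank = 200L,
              mfe_max = -16.0, de_log2fc = 1, de_p = 0.05, target_cutoff = 3.0)
  def[names(thresholds)] <- thresholds
  list(paths = list(genome = genome, contaminants = contaminants,
                    reference = reference, transcripts = transcripts,
                    race_clones = race_clones, fastq = as.list(fastq)),
       libraries = as.data.frame(libraries),
       adapter3 = adapter3, thresholds = def, seed = as.integer(seed),
       output_dir = output_dir)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    config$libraries <- as.data.frame(config$libraries)
  }
  for (f in c("paths", "libraries", "adapter3", "thresholds", "output_dir"))
    if (is.null(config[[f]])) stop("config: missing field '", f, "'")
  for (f in c("genome", "contaminants", "reference")) {
    p <- config$paths[[f]]
    if (is.null(p)) stop("config: missing path '", f, "'")
    if (!file.exists(p)) stop("config: ", f, " file not found: ", p)
  }
  if (length(config$paths$fastq) == 0L) stop("config: missing path 'fastq'")
  for (lib in names(config$paths$fastq))
    if (!file.exists(config$paths$fastq[[lib]]))
      stop("config: fastq file not found for library ", lib)
  need <- c("library_id", "tissue", "condition", "timepoint", "replicate")
  if (!all(need %in% names(config$libraries)))
    stop("config: libraries table must have columns ",
         paste(need, collapse = ", "))
  if (!setequal(config$libraries$library_id, names(config$paths$fastq)))
    stop("config: libraries table and fastq map name different libraries")
  th <- config$thresholds
  if (th$min_tpm < 0 || th$max_hits < 1 || th$flank < 0 || th$de_p <= 0 ||
      th$de_p > 1 || th$len_min > th$len_max)
    stop("config: thresholds out of range")
  config
}

#' Run the full pipeline
#'
#' simdata inputs (or any user-supplied FASTQ + FASTA set) -> preprocessing
#' -> discovery -> expression/DE -> (optional) targeting, with per-stage
#' logging to stderr and deterministic outputs for a fixed config and seed.
#'
#' @param config config list from [make_pipeline_config()] or the path to a
#'   YAML file with the same structure.
#' @param stages subset of `c("preprocess", "discover", "express", "target")`
#'   to run; later stages reuse intermediates found in `output_dir` when
#'   earlier ones are skipped.
#' @param write logical: write reports/artifacts to `config$output_dir`.
#' @param quiet suppress progress messages.
#' @return list: `report` (run summary), `tags`, `stats`, `catalog`,
#'   `expression`, `correlations`, `de` (all contrasts), `specificity`,
#'   `composition`, `targets`, `race`, and `files` (manifest) when written.
#' @export
run_pipeline <- function(config,
                         stages = c("preprocess", "discover", "express", "target"),
                         write = TRUE, quiet = FALSE) {
  config <- validate_config(config)
  th <- config$thresholds
  libs <- config$libraries$library_id
  say <- function(...) if (!quiet) message("[heatmir ", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  set.seed(config$seed)
  out_dir <- config$output_dir
  if (write) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  t0 <- Sys.time()

  genome <- read_fasta(config$paths$genome)

  if ("preprocess" %in% stages) {
    say("preprocess: trimming and collapsing ", length(libs), " libraries")
    pp <- preprocess_libraries(
      setNames(as.character(config$paths$fastq[libs]), libs),
      adapter3 = config$adapter3,
      contaminants = config$paths$contaminants,
      min_len = th$min_len, max_len = th$max_len)
    res$tags <- pp$tags
    res$stats <- pp$stats
    res$removed_by_class <- pp$removed_by_class
    res$clean_totals <- pp$clean_totals
    if (write) {
      cand <- select_candidates(pp$tags, NULL, th$min_tpm,
                                c(th$len_min, th$len_max))
      data.table::fwrite(cand, file.path(out_dir, "candidate_tags.tsv"), sep = "\t")
      data.table::fwrite(pp$stats, file.path(out_dir, "library_stats.tsv"), sep = "\t")
      data.table::fwrite(
        data.table::data.table(library_id = names(pp$clean_totals),
                               clean_total = as.numeric(pp$clean_totals)),
        file.path(out_dir, "clean_totals.tsv"), sep = "\t")
    }
  } else {
    say("preprocess: skipped, loading intermediates")
    res$tags <- data.table::fread(file.path(out_dir, "candidate_tags.tsv"))
    ct <- data.table::fread(file.path(out_dir, "clean_totals.tsv"))
    res$clean_totals <- setNames(ct$clean_total, ct$library_id)
    data.table::setattr(res$tags, "clean_totals", res$clean_totals)
    res$stats <- data.table::fread(file.path(out_dir, "library_stats.tsv"))
  }

  if ("discover" %in% stages) {
    say("discover: mapping, folding and classifying candidates")
    res$catalog <- discover_mirnas(
      res$tags, genome, read_fasta(config$paths$reference),
      min_tpm = th$min_tpm, len_range = c(th$len_min, th$len_max),
      max_hits = th$max_hits, flank = th$flank, mfe_max = th$mfe_max)
    say("discover: ", sum(res$catalog$status == "known"), " known / ",
        sum(res$catalog$status == "novel"), " novel miRNAs")
    if (write) {
      data.table::fwrite(res$catalog, file.path(out_dir, "mirna_catalog.tsv"),
                         sep = "\t")
    }
  } else if (file.exists(file.path(out_dir, "mirna_catalog.tsv"))) {
    res$catalog <- data.table::fread(file.path(out_dir, "mirna_catalog.tsv"))
  }

  if ("express" %in% stages && !is.null(res$catalog) && nrow(res$catalog) > 0L) {
    say("express: expression matrix, replicate QC and differential calls")
    mat <- build_expression_matrix(res$catalog, res$tags, res$clean_totals)
    res$expression <- mat
    d <- data.table::as.data.table(config$libraries)
    res$correlations <- replicate_correlation(mat, d)
    de <- list()
    for (tis in unique(d$tissue)) for (tp in unique(d$timepoint)) {
      hs <- d[tissue == tis & condition == "HS" & timepoint == tp, library_id]
      ck <- d[tissue == tis & condition == "CK" & timepoint == tp, library_id]
      if (!length(hs) || !length(ck)) next
      de[[length(de) + 1L]] <- call_differential(
        mat, hs, ck, contrast = paste0(tis, "_HS_vs_CK_", tp),
        lfc_min = th$de_log2fc, p_max = th$de_p)
    }
    res$de <- data.table::rbindlist(de)
    res$specificity <- tryCatch(tissue_specificity(mat, d, min_tpm = th$min_tpm,
                                                   lfc_min = th$de_log2fc,
                                                   p_max = th$de_p),
                                error = function(e) NULL)
    res$composition <- composition_stats(res$catalog$sequence)
    if (write) {
      data.table::fwrite(de_matrix_table(mat), file.path(out_dir, "expression_matrix.tsv"),
                         sep = "\t")
      data.table::fwrite(res$de, file.path(out_dir, "de_results.tsv"), sep = "\t")
      data.table::fwrite(res$correlations, file.path(out_dir, "replicate_correlations.tsv"),
                         sep = "\t")
      if (!is.null(res$specificity))
        data.table::fwrite(res$specificity, file.path(out_dir, "tissue_specificity.tsv"),
                           sep = "\t")
      data.table::fwrite(res$composition$length_dist,
                         file.path(out_dir, "length_distribution.tsv"), sep = "\t")
    }
  }

  if ("target" %in% stages && !is.null(config$paths$transcripts) &&
      !is.null(res$catalog) && nrow(res$catalog) > 0L) {
    say("target: scoring miRNA-transcript complementarity")
    tx <- read_fasta(config$paths$transcripts)
    de_mirnas <- if (!is.null(res$de) && nrow(res$de))
      unique(res$de$mirna[res$de$call != "ns"]) else character(0)
    query <- if (length(de_mirnas)) de_mirnas else res$catalog$name
    tg <- lapply(query, function(nm) {
      seq <- res$catalog$sequence[match(nm, res$catalog$name)]
      score_targets(seq, tx, cutoff = th$target_cutoff, mirna = nm)
    })
    res$targets <- data.table::rbindlist(tg)
    if (!is.null(config$paths$race_clones) && nrow(res$targets)) {
      rc <- data.table::fread(config$paths$race_clones)
      tallies <- list()
      for (tid in unique(rc$transcript_id)) {
        st <- res$targets[transcript_id == tid & mode == "cleavage"]
        if (!nrow(st)) next
        tl <- tally_race(st[1], rc[transcript_id == tid, position0])
        tallies[[length(tallies) + 1L]] <- data.table::data.table(
          transcript_id = tid, mirna = st$mirna[1],
          cleavage_pos0 = st$cleavage_pos0[1], n_clones = tl$n_clones,
          at_site = tl$at_site, fraction = tl$fraction_label)
      }
      res$race <- data.table::rbindlist(tallies)
    }
    if (write && nrow(res$targets)) {
      data.table::fwrite(res$targets[, -"alignment"],
                         file.path(out_dir, "target_sites.tsv"), sep = "\t")
      if (!is.null(res$race))
        data.table::fwrite(res$race, file.path(out_dir, "race_tallies.tsv"),
                           sep = "\t")
    }
  }

  res$report <- build_report(res, config, t0)
  if (write) {
    files <- write_reports(res, out_dir)
    res$files <- files
  }
  say("done in ", round(as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      " s")
  res
}

de_matrix_table <- function(mat) {
  out <- data.table::data.table(mirna = rownames(mat$counts))
  for (lib in colnames(mat$counts)) out[, paste0("count.", lib) := mat$counts[, lib]]
  for (lib in colnames(mat$tpm)) out[, paste0("tpm.", lib) := mat$tpm[, lib]]
  out
}

build_report <- function(res, config, t0) {
  catalog <- res$catalog
  de <- res$de
  list(
    seed = config$seed,
    package_version = as.character(packageVersion("heatmir")),
    libraries = nrow(config$libraries),
    stage_counts = res$stats,
    n_known = if (!is.null(catalog)) sum(catalog$status == "known") else NA,
    n_novel = if (!is.null(catalog)) sum(catalog$status == "novel") else NA,
    n_novel_families = if (!is.null(catalog))
      length(unique(stats::na.omit(catalog$family[catalog$status == "novel"]))) else NA,
    de_summary = if (!is.null(de) && nrow(de))
      de[, .(n_up = sum(call == "up"), n_down = sum(call == "down")),
         by = contrast] else NULL,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Write pipeline artifacts and a checksum manifest
#'
#' Writes the miRNA catalog GFF3 + precursor FASTA (dot-bracket in the
#' description line), a plain-text run summary, and `MANIFEST.tsv` with an
#' md5 checksum per artifact.
#'
#' @param res result list from [run_pipeline()].
#' @param output_dir target directory.
#' @return data.table manifest (file, md5).
#' @export
write_reports <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- res$catalog
  if (!is.null(catalog) && nrow(catalog)) {
    write_gff3(data.table::data.table(
      chrom = catalog$chrom, start0 = catalog$precursor_start0,
      end0 = catalog$precursor_end0, strand = catalog$strand,
      locus_id = catalog$name), file.path(output_dir, "precursors.gff3"))
    pre <- setNames(catalog$precursor_seq,
                    paste(catalog$name, catalog$dotbracket,
                          sprintf("MFE=%.2f", catalog$mfe)))
    write_fasta(pre, file.path(output_dir, "precursors.fa"))
  }
  rep <- res$report
  lines <- c(
    paste0("heatmir run summary (seed ", rep$seed, ", v", rep$package_version, ")"),
    paste0("libraries: ", rep$libraries),
    paste0("known miRNAs: ", rep$n_known, "; novel: ", rep$n_novel,
           "; novel families: ", rep$n_novel_families),
    if (!is.null(rep$de_summary)) c(
      "differential expression (|log2FC| and p thresholds per config):",
      utils::capture.output(print(rep$de_summary))),
    paste0("elapsed: ", round(rep$elapsed_s, 1), " s"))
  writeLines(lines, file.path(output_dir, "run_summary.txt"))
  files <- setdiff(list.files(output_dir, recursive = TRUE),
                   "MANIFEST.tsv")
  manifest <- data.table::data.table(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))))
  data.table::fwrite(manifest, file.path(output_dir, "MANIFEST.tsv"), sep = "\t")
  manifest
}
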