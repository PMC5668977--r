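## Candidate mapping, precursor excision, hairpin evaluation and known/novel
## classification. Coordinates are 0-based half-open internally; GFF3 output
## is 1-based inclusive.

#' Map tags to the genome with zero mismatches
#'
#' Native k-mer-seeded exact search (the perfect-match constraint makes a
#' full aligner unnecessary and keeps the operation oracle-testable). Both
#' strands are searched; a hit of the reverse complement on the forward
#' genome is reported as strand `-`. Hits are ordered (chrom, start0,
#' strand).
#'
#' @param tag_seqs character vector of tag sequences (DNA form).
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (capped at the shortest tag).
#' @return named list: tag -> data.table(chrom, start0, end0, strand); tags
#'   absent from the genome get an empty table.
#' @export
map_exact <- function(tag_seqs, genome, k = 12L) {
  tag_seqs <- unique(toupper(tag_seqs))
  if (length(tag_seqs) == 0L) return(list())
  hits <- map_exact_table(tag_seqs, genome, k)
  out <- split(hits[, -"tag"], factor(hits$tag, levels = tag_seqs))
  lapply(out, function(h) h)
}

## Flat-table core of map_exact: one row per (tag, hit), ordered
## (tag, chrom, start0, strand). Used directly by discover_mirnas, where a
## per-tag list would not scale to large candidate sets.
map_exact_table <- function(tag_seqs, genome, k = 12L) {
  k <- min(k, min(nchar(tag_seqs)))
  chrseq <- setNames(toupper(as.character(genome)), names(genome))
  idx <- kmer_index(chrseq, k)
  q <- data.table::data.table(
    tag = rep(tag_seqs, 2L),
    query = c(tag_seqs, revcomp(tag_seqs)),
    strand = rep(c("+", "-"), each = length(tag_seqs)))
  q[, kmer := substr(query, 1L, k)]
  cand <- idx[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  hits <- if (nrow(cand)) {
    cand[, len := nchar(query)]
    cand <- cand[start0 + len <= nchar(chrseq)[chrom]]
    cand <- cand[substr(chrseq[chrom], start0 + 1L, start0 + len) == query]
    cand[, .(tag, chrom, start0, end0 = start0 + len, strand)]
  } else data.table::data.table(tag = character(0), chrom = character(0),
                                start0 = integer(0), end0 = integer(0),
                                strand = character(0))
  data.table::setorder(hits, tag, chrom, start0, strand)
  hits
}

## Rebuilding the index per call is cheap at the genome sizes this package
## targets (a keyed table of every genomic k-mer).
kmer_index <- function(chrseq, k) {
  pieces <- lapply(names(chrseq), function(ch) {
    s <- chrseq[[ch]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
                           chrom = ch, start0 = 0:(n - k))
  })
  idx <- data.table::rbindlist(pieces)
  data.table::setkey(idx, kmer)
  idx
}

#' Select candidate tags for miRNA discovery
#'
#' Kept iff peak TPM across libraries >= `min_tpm`, length within
#' `len_range`, and (when `hit_map` is supplied) 1 to `max_hits` unique
#' genome hits.
#'
#' @param tags tag table with `tpm.<lib>` columns.
#' @param hit_map optional result of [map_exact()]; `NULL` skips the hit
#'   criterion (useful to pre-filter before mapping).
#' @param min_tpm,len_range,max_hits thresholds.
#' @return subset of `tags` (with an `n_hits` column when `hit_map` given).
#' @export
select_candidates <- function(tags, hit_map = NULL, min_tpm = 10,
                              len_range = c(18L, 30L), max_hits = 20L) {
  tcols <- tpm_cols(tags)
  if (length(tcols) == 0L) stop("select_candidates: tags carry no TPM columns")
  peak <- do.call(pmax, as.list(tags[, tcols, with = FALSE]))
  len <- nchar(tags$sequence)
  keep <- peak >= min_tpm & len >= len_range[1] & len <= len_range[2]
  out <- tags[keep]
  if (!is.null(hit_map)) {
    nh <- vapply(hit_map[out$sequence], function(h)
      if (is.null(h)) 0L else nrow(h), 0L)
    out[, n_hits := nh]
    out <- out[n_hits >= 1L & n_hits <= max_hits]
  }
  out[]
}

#' Excise the precursor window around a genome hit
#'
#' The window spans `flank` bp on each side of the hit, clipped at the
#' chromosome ends; minus-strand windows are reverse-complemented so the
#' returned sequence is always the transcribed (mature-containing) strand,
#' with the mature offset recomputed in window coordinates.
#'
#' @param hit one row of a [map_exact()] table (list/data.table with chrom,
#'   start0, end0, strand).
#' @param genome named character vector.
#' @param flank flank size (bp).
#' @return list: `seq` (RNA string), `chrom`, `wstart0`, `wend0` (genome
#'   coordinates of the window), `strand`, `mature_offset0`, `mature_len`.
#' @export
extract_precursor <- function(hit, genome, flank = 200L) {
  ch <- as.character(hit$chrom)
  n <- nchar(genome[[ch]])
  w1 <- max(0L, hit$start0 - flank)
  w2 <- min(n, hit$end0 + flank)
  s <- substr(genome[[ch]], w1 + 1L, w2)
  if (hit$strand == "-") {
    s <- revcomp(s)
    off <- w2 - hit$end0
  } else {
    off <- hit$start0 - w1
  }
  list(seq = dna_to_rna(s), chrom = ch, wstart0 = w1, wend0 = w2,
       strand = as.character(hit$strand), mature_offset0 = as.integer(off),
       mature_len = as.integer(hit$end0 - hit$start0))
}

#' Apply stem-loop (hairpin) criteria to a folded candidate
#'
#' Pass requires, with the default thresholds: the mature entirely on one
#' stem arm outside the terminal loop (all pairing partners on one side,
#' none inside the mature itself); at most `max_unpaired` unpaired mature
#' bases; no asymmetric bulge larger than `max_bulge` nt within the
#' mature/star duplex; and a star-side arm at least as long as the paired
#' extent of the mature. Every violated criterion is reported.
#'
#' @param dotbracket folded structure of the window.
#' @param mature_offset0 0-based mature offset within the window.
#' @param mature_len mature length.
#' @param max_unpaired maximum unpaired mature bases.
#' @param max_bulge maximum asymmetric bulge (nt) in the duplex.
#' @return list: `pass` (logical) and `reasons` (character vector, empty on
#'   pass).
#' @export
evaluate_hairpin <- function(dotbracket, mature_offset0, mature_len,
                             max_unpaired = 4L, max_bulge = 2L) {
  pt <- pairing_table(dotbracket)
  m <- (mature_offset0 + 1L):(mature_offset0 + mature_len)
  if (max(m) > length(pt)) stop("evaluate_hairpin: mature outside the window")
  partners <- pt[m]
  paired <- !is.na(partners)
  reasons <- character(0)
  if (!any(paired)) return(list(pass = FALSE, reasons = "mature_unpaired"))
  pp <- partners[paired]
  inside <- pp >= min(m) & pp <= max(m)
  below <- pp < min(m)
  above <- pp > max(m)
  if (any(inside) || (any(below) && any(above)))
    reasons <- c(reasons, "mature_in_loop")
  if (sum(!paired) > max_unpaired)
    reasons <- c(reasons, "too_many_mispairs")
  if (length(pp) >= 2L && !any(inside)) {
    mi <- m[paired]
    gm <- diff(mi) - 1L
    gs <- abs(diff(pp)) - 1L
    if (any(abs(gm - gs) > max_bulge))
      reasons <- c(reasons, "large_bulge")
  }
  if (!length(reasons)) {
    extent <- max(m[paired]) - min(m[paired]) + 1L
    arm <- max(pp) - min(pp) + 1L
    if (arm < extent - max_bulge) reasons <- c(reasons, "short_arm")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Classify a mature sequence against the reference catalog
#'
#' Ungapped comparison against every reference mature: equal lengths are
#' compared position-wise; lengths differing by up to 2 nt are compared by
#' sliding the shorter along the longer, counting the overhang as
#' mismatches. The best hit (fewest mismatches, ties broken by name) is
#' returned when it has at most `max_mismatch` mismatches.
#'
#' @param mature_seq query sequence (RNA or DNA form).
#' @param reference named character vector of reference matures (optionally
#'   with a `family` attribute or `name family` headers from [read_fasta()]).
#' @param max_mismatch known-miRNA threshold.
#' @return list(name, family, mismatches) or `NULL` when no reference is
#'   within the threshold.
#' @export
classify_known <- function(mature_seq, reference, max_mismatch = 2L) {
  if (length(reference) == 0L) stop("classify_known: empty reference catalog")
  q <- toupper(rna_to_dna(mature_seq))
  refs <- toupper(rna_to_dna(as.character(reference)))
  d <- vapply(refs, sliding_distance, 0, b = q)
  ord <- order(d, names(reference))
  best <- ord[1]
  if (d[best] > max_mismatch) return(NULL)
  fam <- attr(reference, "family")
  if (is.null(fam)) {
    desc <- attr(reference, "desc")
    fam <- if (!is.null(desc)) {
      second <- vapply(strsplit(desc, "\\s+"), function(x)
        if (length(x) >= 2) x[2] else NA_character_, "")
      second
    } else rep(NA_character_, length(reference))
  }
  list(name = names(reference)[best], family = fam[best],
       mismatches = as.integer(d[best]))
}

#' Validate a candidate as a novel miRNA
#'
#' Requires precursor stability (`mfe <= mfe_max`) and a structurally
#' identifiable star on the opposite arm: the region pairing the mature,
#' shifted 2 nt toward the precursor ends so both duplex strands carry 2-nt
#' 3' overhangs. The star is additionally flagged `star_supported` when a
#' sequenced tag matches it exactly.
#'
#' @param fold result of [fold_rna()] on the window.
#' @param window_seq the window sequence (RNA form) that was folded.
#' @param mature_offset0,mature_len mature placement in the window.
#' @param tag_seqs character vector of sequenced tag sequences (DNA form).
#' @param mfe_max precursor stability threshold (default -16 kcal/mol, just
#'   above the least stable plant precursors reported for this class).
#' @param require_star_read logical: additionally demand that the star was
#'   actually sequenced (`star_supported`) for a novel verdict. Off here by
#'   default; [discover_mirnas()] turns it on (see its documentation).
#' @return list: `novel` (logical), `reasons`, `star_seq` (DNA form),
#'   `star_offset0`, `star_supported`.
#' @export
validate_novel <- function(fold, window_seq, mature_offset0, mature_len,
                           tag_seqs = character(0), mfe_max = -16.0,
                           require_star_read = FALSE) {
  reasons <- character(0)
  if (fold$mfe > mfe_max) reasons <- c(reasons, "mfe_above_threshold")
  st <- star_from_structure(fold$dotbracket, mature_offset0, mature_len)
  if (is.null(st)) {
    reasons <- c(reasons, "no_star_arm")
    return(list(novel = FALSE, reasons = reasons, star_seq = NA_character_,
                star_offset0 = NA_integer_, star_supported = FALSE))
  }
  star_seq <- rna_to_dna(substr(window_seq, st + 1L, st + mature_len))
  # tag_seqs is expected in uppercase DNA form (the clean-tag convention);
  # %chin% keeps this a fast C-level membership test on large tag tables
  supported <- star_seq %chin% tag_seqs
  if (require_star_read && !supported)
    reasons <- c(reasons, "star_not_sequenced")
  list(novel = length(reasons) == 0L, reasons = reasons,
       star_seq = star_seq, star_offset0 = st, star_supported = supported)
}

## 0-based star start from the pairing table: the region pairing the mature,
## shifted by 2 nt so both duplex strands carry 2-nt 3' overhangs. Unpaired
## mature end bases are extrapolated so the star has mature length.
star_from_structure <- function(dotbracket, mature_offset0, mature_len) {
  pt <- pairing_table(dotbracket)
  m <- (mature_offset0 + 1L):(mature_offset0 + mature_len)
  paired <- which(!is.na(pt[m]))
  if (length(paired) < 2L) return(NULL)
  p1 <- pt[m[min(paired)]]
  if (p1 >= min(m) && p1 <= max(m)) return(NULL)
  e2 <- mature_len - max(paired)          # trailing unpaired mature bases
  p2_full <- pt[m[max(paired)]] - e2      # est. partner of the mature 3' end
  # 1-based star start: partner of the mature 3' end, +2 when the star arm
  # is downstream of the mature, -2 when it is upstream.
  star1 <- if (p1 > max(m)) p2_full + 2L else p2_full - 2L
  star0 <- as.integer(star1 - 1L)
  if (star0 < 0L || star0 + mature_len > length(pt)) return(NULL)
  # the star must sit on the opposite arm: no overlap with the mature
  if (star0 < mature_offset0 + mature_len && star0 + mature_len > mature_offset0)
    return(NULL)
  star0
}

#' Group novel matures into families by sequence similarity
#'
#' Single-linkage clustering on the ungapped sliding Hamming distance (the
#' same measure as [classify_known()]); pairs at distance <= `max_mismatch`
#' join the same group. Groups are numbered in order of their first member;
#' singletons get `NA`.
#'
#' @param mature_seqs character vector (named or not) of mature sequences.
#' @param max_mismatch linkage threshold.
#' @return data.table(sequence, group) where group is `fam##` or NA for
#'   singletons.
#' @export
group_families <- function(mature_seqs, max_mismatch = 3L) {
  n <- length(mature_seqs)
  if (n == 0L) stop("group_families: need at least one record")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (sliding_distance(mature_seqs[i], mature_seqs[j]) <= max_mismatch) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  sizes <- table(root)
  multi <- sort(as.integer(names(sizes)[sizes > 1L]))
  lab <- setNames(sprintf("fam%02d", seq_along(multi)), multi)
  data.table::data.table(
    sequence = unname(mature_seqs),
    group = ifelse(as.character(root) %in% names(lab),
                   lab[as.character(root)], NA_character_))
}

#' Discover known and novel miRNAs from clean tags
#'
#' Full discovery stage: TPM/length selection, exact mapping, hit-count
#' filter, precursor excision and folding, hairpin criteria, reference
#' classification, novel validation (star + MFE), and family grouping of
#' novel matures. One catalog record is emitted per distinct mature
#' sequence (the hit with the first genome coordinate is kept when a tag
#' maps to several qualifying loci).
#'
#' Before folding, windows are screened for an antisense arm that could pair
#' the mature within the hairpin-criteria budget (`prescreen`); windows
#' without one cannot pass [evaluate_hairpin()] and are rejected without the
#' cubic-time fold.
#'
#' @param tags clean tag table with counts and TPM columns.
#' @param genome named character vector.
#' @param reference reference mature catalog (named character vector).
#' @param min_tpm,len_range,max_hits candidate selection thresholds.
#' @param flank precursor flank (bp).
#' @param mfe_max novel-miRNA stability threshold (kcal/mol).
#' @param max_unpaired,max_bulge hairpin criteria.
#' @param engine folding engine, see [fold_rna()].
#' @param prescreen logical; apply the star-arm screen before folding.
#' @param require_star_read logical (default TRUE): a novel call additionally
#'   requires the star sequence to occur among the sequenced clean tags.
#'   Star evidence is the conventional stringent criterion for novel plant
#'   miRNA annotation and controls the false discovery rate among the many
#'   low-count candidate tags that clear the TPM filter.
#' @return data.table catalog: name, sequence, length, status, family,
#'   mismatches_to_ref, locus coordinates, precursor sequence/structure/MFE,
#'   star fields, n_hits, and per-library `tpm.<lib>` columns. Attribute
#'   `"rejected"` records candidates that failed with their reasons.
#' @export
discover_mirnas <- function(tags, genome, reference, min_tpm = 10,
                            len_range = c(18L, 30L), max_hits = 20L,
                            flank = 200L, mfe_max = -16.0,
                            max_unpaired = 4L, max_bulge = 2L,
                            engine = "builtin", prescreen = TRUE,
                            require_star_read = TRUE) {
  cand <- select_candidates(tags, NULL, min_tpm, len_range)
  if (nrow(cand) == 0L)
    return(empty_catalog(tag_libraries(tags)))
  ht <- map_exact_table(unique(cand$sequence), genome)
  nh <- ht[, .N, by = tag]
  ok_tags <- nh$tag[nh$N >= 1L & nh$N <= max_hits]
  cand <- cand[cand$sequence %in% ok_tags]
  cand[, n_hits := nh$N[match(cand$sequence, nh$tag)]]
  if (nrow(cand) == 0L)
    return(empty_catalog(tag_libraries(tags)))
  ht <- ht[tag %in% cand$sequence]
  tcols <- tpm_cols(tags)

  chrseq <- setNames(toupper(as.character(genome)), names(genome))
  chrlen <- nchar(chrseq)
  ht[, w1 := pmax(0L, start0 - flank)]
  ht[, w2 := pmin(chrlen[chrom], end0 + flank)]
  wseq <- substring(chrseq[ht$chrom], ht$w1 + 1L, ht$w2)
  neg <- ht$strand == "-"
  if (any(neg)) wseq[neg] <- revcomp(wseq[neg])
  ht[, moff := ifelse(neg, w2 - end0, start0 - w1)]
  ht[, mlen := end0 - start0]
  wrna <- chartr("T", "U", wseq)
  pass <- if (prescreen)
    .star_arm_scan_batch_cpp(wrna, ht$moff, ht$mlen, max_unpaired, max_bulge)
  else rep(TRUE, nrow(ht))

  recs <- list(); rej <- list()
  row_idx <- split(seq_len(nrow(ht)), factor(ht$tag, levels = cand$sequence))
  for (tg in cand$sequence) {
    rows <- row_idx[[tg]]
    found <- FALSE
    tag_rej <- 0L
    for (r in rows) {
      if (!pass[r]) next
      pre <- list(seq = wrna[r], chrom = ht$chrom[r], wstart0 = ht$w1[r],
                  wend0 = ht$w2[r], strand = ht$strand[r],
                  mature_offset0 = ht$moff[r], mature_len = ht$mlen[r])
      fold <- fold_rna(pre$seq, engine = engine)
      verdict <- evaluate_hairpin(fold$dotbracket, pre$mature_offset0,
                                  pre$mature_len, max_unpaired, max_bulge)
      if (!verdict$pass) {
        rej[[length(rej) + 1L]] <- data.table::data.table(
          sequence = tg, stage = "hairpin",
          reasons = paste(verdict$reasons, collapse = ";"))
        tag_rej <- tag_rej + 1L
        next
      }
      known <- classify_known(tg, reference)
      star <- validate_novel(fold, pre$seq, pre$mature_offset0,
                             pre$mature_len, tags$sequence, mfe_max,
                             require_star_read = require_star_read)
      if (is.null(known) && !star$novel) {
        rej[[length(rej) + 1L]] <- data.table::data.table(
          sequence = tg, stage = "novel_validation",
          reasons = paste(star$reasons, collapse = ";"))
        tag_rej <- tag_rej + 1L
        next
      }
      trimmed <- trim_precursor(pre, fold, star, engine)
      recs[[length(recs) + 1L]] <- data.table::data.table(
        sequence = tg, length = nchar(tg),
        status = if (!is.null(known)) "known" else "novel",
        ref_name = if (!is.null(known)) known$name else NA_character_,
        family = if (!is.null(known)) known$family else NA_character_,
        mismatches_to_ref = if (!is.null(known)) known$mismatches else NA_integer_,
        chrom = pre$chrom, mature_start0 = ht$start0[r],
        strand = pre$strand,
        precursor_start0 = trimmed$start0, precursor_end0 = trimmed$end0,
        precursor_len = trimmed$end0 - trimmed$start0,
        precursor_seq = trimmed$seq, dotbracket = trimmed$dotbracket,
        mfe = trimmed$mfe,
        star_seq = star$star_seq, star_supported = star$star_supported,
        n_hits = length(rows))
      found <- TRUE
      break  # first qualifying locus per distinct mature
    }
    if (!found && tag_rej == 0L)
      rej[[length(rej) + 1L]] <- data.table::data.table(
        sequence = tg, stage = "prescreen", reasons = "no_star_arm")
  }
  if (!length(recs)) return(empty_catalog(tag_libraries(tags)))
  cat <- data.table::rbindlist(recs)
  data.table::setorder(cat, chrom, mature_start0, strand)
  # names: known keep reference name; novel numbered by coordinate
  cat[, name := ref_name]
  nov <- which(cat$status == "novel")
  cat$name[nov] <- sprintf("novel-mir-%03d", seq_along(nov))
  cat$name <- make.unique(cat$name, sep = "_")
  if (length(nov)) {
    fams <- group_families(cat$sequence[nov])
    cat$family[nov] <- fams$group
  }
  expr <- tags[match(cat$sequence, tags$sequence), tcols, with = FALSE]
  cat <- cbind(cat, expr)
  data.table::setcolorder(cat, c("name", "sequence", "length", "status",
                                 "family", "mismatches_to_ref"))
  data.table::setattr(cat, "rejected",
                      if (length(rej)) data.table::rbindlist(rej)
                      else data.table::data.table(sequence = character(0),
                                                  stage = character(0),
                                                  reasons = character(0)))
  cat[]
}

empty_catalog <- function(libs) {
  cat <- data.table::data.table(
    name = character(0), sequence = character(0), length = integer(0),
    status = character(0), family = character(0),
    mismatches_to_ref = integer(0), chrom = character(0),
    mature_start0 = integer(0), strand = character(0),
    precursor_start0 = integer(0), precursor_end0 = integer(0),
    precursor_len = integer(0), precursor_seq = character(0),
    dotbracket = character(0), mfe = numeric(0), star_seq = character(0),
    star_supported = logical(0), n_hits = integer(0), ref_name = character(0))
  for (lib in libs) cat[, paste0("tpm.", lib) := numeric(0)]
  cat
}

## Trim the 2*flank window down to the reported stem-loop: the span of
## mature and star (when placed), refolded for the reported structure/MFE.
## Genome coordinates of the trimmed precursor are derived from the window.
trim_precursor <- function(pre, fold, star, engine) {
  L <- pre$mature_len
  if (!is.na(star$star_offset0)) {
    a <- min(pre$mature_offset0, star$star_offset0)
    b <- max(pre$mature_offset0, star$star_offset0) + L
  } else {
    a <- pre$mature_offset0; b <- pre$mature_offset0 + L
  }
  seq <- substr(pre$seq, a + 1L, b)
  f <- if (nchar(seq) >= 5L) fold_rna(seq, engine = engine) else fold
  if (pre$strand == "+") {
    g1 <- pre$wstart0 + a; g2 <- pre$wstart0 + b
  } else {
    g1 <- pre$wend0 - b; g2 <- pre$wend0 - a
  }
  list(start0 = as.integer(g1), end0 = as.integer(g2),
       seq = rna_to_dna(seq), dotbracket = f$dotbracket, mfe = f$mfe)
}
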