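#' Trim the 3' adapter and length-filter raw reads
#'
#' The insert is the maximal prefix before the leftmost exact occurrence of
#' the adapter's first `seed_len` bases; reads without that seed still count
#' as matched when the read terminus carries a shorter adapter prefix
#' (>= `min_terminal` nt). Reads with no adapter evidence, trimmed inserts
#' outside `[min_len, max_len]`, inserts containing `N`, or (optionally)
#' poly(A)-dominated inserts are discarded, with per-reason counts reported.
#'
#' @param reads character vector of read sequences (or a file path to a
#'   FASTQ, read via Biostrings).
#' @param adapter3 3' adapter sequence (non-empty).
#' @param min_len,max_len retained insert length range (nt).
#' @param seed_len adapter prefix length for internal matching.
#' @param min_terminal minimum adapter prefix length accepted at the read end.
#' @param polya_filter discard inserts with >= `polya_frac` adenine.
#' @param polya_frac poly(A) threshold.
#' @return list: `clean` (character vector of inserts) and `stats` (named
#'   counts: raw, kept, and discarded by reason `no_adapter`, `too_short`,
#'   `too_long`, `has_n`, `polya`). Conservation: raw = kept + discarded.
#' @export
trim_and_filter <- function(reads, adapter3, min_len = 15L, max_len = 40L,
                            seed_len = 8L, min_terminal = 5L,
                            polya_filter = TRUE, polya_frac = 0.8) {
  if (!nzchar(adapter3)) stop("trim_and_filter: adapter3 must be non-empty")
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- toupper(reads)
  n <- length(reads)
  stats <- c(raw = n, kept = 0L, no_adapter = 0L, too_short = 0L,
             too_long = 0L, has_n = 0L, polya = 0L)
  if (n == 0L) return(list(clean = character(0), stats = stats))
  seed <- substr(adapter3, 1L, min(seed_len, nchar(adapter3)))
  pos <- regexpr(seed, reads, fixed = TRUE)
  insert <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), NA_character_)
  miss <- which(pos < 0L)
  if (length(miss) && nchar(seed) - 1L >= min_terminal) {
    for (k in seq(nchar(seed) - 1L, min_terminal)) {
      if (!length(miss)) break
      hit <- endsWith(reads[miss], substr(adapter3, 1L, k))
      if (any(hit)) {
        idx <- miss[hit]
        insert[idx] <- substr(reads[idx], 1L, nchar(reads[idx]) - k)
        miss <- miss[!hit]
      }
    }
  }
  reason <- rep(NA_character_, n)
  reason[is.na(insert)] <- "no_adapter"
  len <- nchar(insert)
  reason[is.na(reason) & len < min_len] <- "too_short"
  reason[is.na(reason) & len > max_len] <- "too_long"
  reason[is.na(reason) & grepl("N", insert, fixed = TRUE)] <- "has_n"
  if (polya_filter) {
    cand <- which(is.na(reason))
    na_count <- nchar(gsub("[^A]", "", insert[cand]))
    reason[cand[na_count >= polya_frac * len[cand]]] <- "polya"
  }
  keep <- is.na(reason)
  tab <- table(factor(reason[!keep],
                      levels = c("no_adapter", "too_short", "too_long",
                                 "has_n", "polya")))
  stats[names(tab)] <- as.integer(tab)
  stats["kept"] <- sum(keep)
  list(clean = insert[keep], stats = stats)
}

#' Collapse clean reads into distinct tags with per-library counts
#'
#' @param clean_by_lib named list (library id -> character vector of clean
#'   insert sequences).
#' @return data.table with a `sequence` column and one `count.<lib>` column
#'   per library; per-library column sums equal the clean-read counts.
#' @export
collapse_tags <- function(clean_by_lib) {
  stopifnot(is.list(clean_by_lib), !is.null(names(clean_by_lib)))
  long <- data.table::rbindlist(lapply(names(clean_by_lib), function(lib) {
    x <- clean_by_lib[[lib]]
    if (length(x) == 0L)
      return(data.table::data.table(sequence = character(0), library_id = character(0)))
    data.table::data.table(sequence = x, library_id = lib)
  }))
  if (nrow(long) == 0L) {
    tags <- data.table::data.table(sequence = character(0))
    for (lib in names(clean_by_lib)) tags[, paste0("count.", lib) := integer(0)]
    return(tags)
  }
  cnt <- long[, .N, by = .(sequence, library_id)]
  tags <- data.table::dcast(cnt, sequence ~ library_id, value.var = "N", fill = 0L)
  data.table::setnames(tags, setdiff(names(tags), "sequence"),
                       paste0("count.", setdiff(names(tags), "sequence")))
  # guarantee a column for every library, even all-empty ones
  for (lib in names(clean_by_lib)) {
    col <- paste0("count.", lib)
    if (!col %in% names(tags)) tags[, (col) := 0L]
  }
  data.table::setcolorder(tags, c("sequence", paste0("count.", names(clean_by_lib))))
  data.table::setorder(tags, sequence)
  tags[]
}

## column-name helpers
count_cols <- function(tags) grep("^count\\.", names(tags), value = TRUE)
tpm_cols <- function(tags) grep("^tpm\\.", names(tags), value = TRUE)
tag_libraries <- function(tags) sub("^count\\.", "", count_cols(tags))

#' Remove structural-RNA contaminant tags
#'
#' A tag is removed iff it occurs as an exact substring of any contaminant
#' sequence or its reverse complement. The contaminant class is parsed from
#' the FASTA header prefix (text before the first `_` or whitespace).
#'
#' @param tags tag table from [collapse_tags()].
#' @param contaminants named character vector of contaminant sequences, or a
#'   FASTA path.
#' @param min_len,max_len tag length range indexed (must cover the tags).
#' @return list: `kept` and `removed` tag tables, and `removed_by_class`
#'   (read counts removed per contaminant class per library).
#' @export
filter_contaminants <- function(tags, contaminants, min_len = 15L, max_len = 40L) {
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants)) contaminants <- read_fasta(contaminants)
  if (is.null(names(contaminants)) || any(!nzchar(names(contaminants))))
    stop("filter_contaminants: contaminant sequences must be named")
  cls <- sub("[_[:space:]].*$", "", names(contaminants))
  idx <- contaminant_index(contaminants, cls, min_len, max_len)
  hit <- idx[data.table::data.table(sub = tags$sequence), on = "sub", mult = "first"]
  removed <- !is.na(hit$class)
  kept <- tags[!removed]
  rem <- tags[removed]
  if (nrow(rem)) rem[, class := hit$class[removed]]
  by_class <- if (nrow(rem)) {
    m <- rem[, lapply(.SD, sum), by = class, .SDcols = count_cols(tags)]
    data.table::setnames(m, count_cols(tags), tag_libraries(tags))
    m
  } else data.table::data.table(class = character(0))
  list(kept = kept, removed = rem, removed_by_class = by_class)
}

## All substrings of the contaminant set (both strands) in the tag length
## range, with the class of their first source.
contaminant_index <- function(contaminants, cls, min_len, max_len) {
  pieces <- lapply(seq_along(contaminants), function(i) {
    s <- c(contaminants[[i]], revcomp(contaminants[[i]]))
    subs <- unlist(lapply(min_len:max_len, function(L) {
      n <- nchar(s)
      ok <- n >= L
      if (!any(ok)) return(character(0))
      unlist(lapply(s[ok], function(x)
        unique(substring(x, 1:(nchar(x) - L + 1L), L:nchar(x)))))
    }))
    data.table::data.table(sub = unique(subs), class = cls[i])
  })
  idx <- data.table::rbindlist(pieces)
  idx <- unique(idx, by = "sub")
  data.table::setkey(idx, sub)
  idx
}

#' Fill per-library TPM columns
#'
#' `tpm = count / clean_total * 1e6`. By default clean totals are the
#' per-library column sums of `tags` (i.e. TPM over the tags table itself,
#' which then sums to 1e6 per library).
#'
#' @param tags tag table with `count.<lib>` columns.
#' @param totals optional named numeric of clean-read totals per library.
#' @return the tag table with added `tpm.<lib>` columns.
#' @export
tpm_normalize <- function(tags, totals = NULL) {
  libs <- tag_libraries(tags)
  if (is.null(totals))
    totals <- vapply(count_cols(tags), function(cc) sum(as.numeric(tags[[cc]])), 0)
  else totals <- totals[libs]
  names(totals) <- libs
  bad <- libs[is.na(totals) | totals <= 0]
  if (length(bad))
    stop("tpm_normalize: zero or missing clean total for library: ",
         paste(bad, collapse = ", "))
  for (lib in libs)
    tags[, paste0("tpm.", lib) := get(paste0("count.", lib)) / totals[[lib]] * 1e6]
  data.table::setattr(tags, "clean_totals", totals)
  tags[]
}

#' Preprocess raw FASTQ libraries into a clean tag table
#'
#' Runs [trim_and_filter()] per library, [collapse_tags()],
#' [filter_contaminants()] and [tpm_normalize()], and assembles per-library
#' statistics (raw, after trim/filter, contaminant, clean, unique tags).
#'
#' @param fastq named list/vector: library id -> FASTQ path or character
#'   vector of reads.
#' @param adapter3 3' adapter.
#' @param contaminants contaminant FASTA path or named character vector.
#' @param ... passed to [trim_and_filter()].
#' @return list: `tags` (clean tags with counts and TPM), `removed`
#'   (contaminant tags), `stats` (per-library table), `clean_totals`.
#' @export
preprocess_libraries <- function(fastq, adapter3, contaminants, ...) {
  libs <- names(fastq)
  stopifnot(!is.null(libs))
  clean <- vector("list", length(libs))
  names(clean) <- libs
  tstats <- setNames(vector("list", length(libs)), libs)
  for (lib in libs) {
    tf <- trim_and_filter(fastq[[lib]], adapter3, ...)
    clean[[lib]] <- tf$clean
    tstats[[lib]] <- tf$stats
  }
  tags0 <- collapse_tags(clean)
  fc <- filter_contaminants(tags0, contaminants)
  tags <- fc$kept
  ccols <- count_cols(tags)
  clean_totals <- vapply(ccols, function(cc) sum(as.numeric(tags[[cc]])), 0)
  names(clean_totals) <- tag_libraries(tags)
  tags <- tpm_normalize(tags, clean_totals)
  contam_reads <- vapply(libs, function(lib) {
    cc <- paste0("count.", lib)
    if (nrow(fc$removed)) sum(as.numeric(fc$removed[[cc]])) else 0
  }, 0)
  stats <- data.table::data.table(
    library_id = libs,
    raw_reads = vapply(tstats, function(s) as.numeric(s[["raw"]]), 0),
    after_trim_filter = vapply(tstats, function(s) as.numeric(s[["kept"]]), 0),
    contaminant_reads = contam_reads,
    clean_reads = clean_totals[libs],
    unique_tags = vapply(libs, function(lib)
      sum(tags[[paste0("count.", lib)]] > 0L), 0))
  list(tags = tags, removed = fc$removed, removed_by_class = fc$removed_by_class,
       stats = stats, clean_totals = clean_totals)
}
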