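#' Assemble the miRNA expression matrix
#'
#' @param catalog discovery catalog (rows = miRNAs, with a `sequence` column).
#' @param tags clean tag table with `count.<lib>` columns.
#' @param clean_totals named numeric of per-library clean-read totals
#'   (defaults to the `clean_totals` attribute of `tags`).
#' @return list of class `mirna_expression`: `counts` and `tpm` (numeric
#'   matrices, rows = miRNA names), `totals`.
#' @export
build_expression_matrix <- function(catalog, tags, clean_totals = NULL) {
  libs <- tag_libraries(tags)
  clean_totals <- clean_totals %||% attr(tags, "clean_totals")
  if (is.null(clean_totals))
    stop("build_expression_matrix: clean totals unavailable; run tpm_normalize first")
  idx <- match(catalog$sequence, tags$sequence)
  counts <- as.matrix(tags[idx, count_cols(tags), with = FALSE])
  counts[is.na(counts)] <- 0L
  dimnames(counts) <- list(catalog$name, libs)
  tpm <- sweep(counts, 2, as.numeric(clean_totals[libs]), "/") * 1e6
  structure(list(counts = counts, tpm = tpm,
                 totals = setNames(as.numeric(clean_totals[libs]), libs)),
            class = "mirna_expression")
}

#' Pearson correlation between biological replicates
#'
#' Computed on `log2(TPM + 1)` over miRNAs expressed (TPM > 0) in at least
#' one member of the pair. Zero-variance profiles yield an `NA` correlation
#' with `undefined = TRUE` rather than an error.
#'
#' @param mat `mirna_expression` object.
#' @param designs library design table (library_id, tissue, condition,
#'   timepoint, replicate).
#' @return data.table, one row per replicate pair.
#' @export
replicate_correlation <- function(mat, designs) {
  d <- data.table::as.data.table(designs)
  pairs <- d[, if (.N >= 2) data.table::data.table(
    lib1 = library_id[1], lib2 = library_id[2]),
    by = .(tissue, condition, timepoint)]
  if (nrow(pairs) == 0L) stop("replicate_correlation: no replicate pairs")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- mat$tpm[, pairs$lib1[i]]; y <- mat$tpm[, pairs$lib2[i]]
    keep <- x > 0 | y > 0
    lx <- log2(x[keep] + 1); ly <- log2(y[keep] + 1)
    undef <- sum(keep) < 2L || var(lx) == 0 || var(ly) == 0
    data.table::data.table(
      tissue = pairs$tissue[i], condition = pairs$condition[i],
      timepoint = pairs$timepoint[i], lib1 = pairs$lib1[i],
      lib2 = pairs$lib2[i], n_mirnas = sum(keep),
      r = if (undef) NA_real_ else cor(lx, ly), undefined = undef)
  })
  data.table::rbindlist(res)
}

#' Chi-square test on two library counts
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table
#' `[[a, total_a - a], [b, total_b - b]]`; the p-value is the upper tail of
#' the chi-square distribution. Vectorised over the count arguments. A table
#' with both counts zero (or a degenerate margin) returns `chi2 = 0, p = 1`.
#'
#' @param count_a,count_b tag counts in the two libraries.
#' @param total_a,total_b library totals (>= counts).
#' @return list of numeric vectors `chi2` and `p`.
#' @export
chisq_test <- function(count_a, total_a, count_b, total_b) {
  n <- max(length(count_a), length(count_b))
  a <- rep_len(as.numeric(count_a), n); b <- rep_len(as.numeric(count_b), n)
  ta <- rep_len(as.numeric(total_a), n); tb <- rep_len(as.numeric(total_b), n)
  if (any(a > ta) || any(b > tb) || any(a < 0) || any(b < 0))
    stop("chisq_test: counts must satisfy 0 <= count <= total")
  if (any(ta <= 0) || any(tb <= 0)) stop("chisq_test: totals must be > 0")
  chi2 <- numeric(n); p <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(a[i], ta[i] - a[i], b[i], tb[i] - b[i]), nrow = 2,
                  byrow = TRUE)
    if (a[i] + b[i] == 0 || (ta[i] - a[i]) + (tb[i] - b[i]) == 0) {
      chi2[i] <- 0; p[i] <- 1
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2[i] <- unname(ht$statistic); p[i] <- unname(ht$p.value)
    }
  }
  list(chi2 = chi2, p = p)
}

#' Call differentially expressed miRNAs for one contrast
#'
#' Replicates are pooled by summing counts per condition (default); each
#' miRNA is tested with [chisq_test()] on pooled counts against pooled
#' totals. `log2fc = log2((tpm_case + eps_case) / (tpm_ctrl + eps_ctrl))`
#' where each epsilon is the TPM equivalent of one pooled read. A miRNA is
#' called `up`/`down` iff `|log2fc| >= lfc_min` and `p <= p_max` (raw p, as
#' is conventional for this test; a Benjamini-Hochberg `q` column is
#' reported alongside but not used for the calls).
#'
#' @param mat `mirna_expression` object.
#' @param case_libs,control_libs library ids of the two conditions (e.g. HS
#'   and CK). Fold changes are case over control.
#' @param contrast label for the contrast.
#' @param lfc_min,p_max call thresholds.
#' @param replicate_policy `"pool"` (default) or `"per_rep"`: with
#'   `"per_rep"`, matched replicate pairs are tested separately and the
#'   least significant p is kept (conservative).
#' @return data.table of per-miRNA results (mirna, contrast, tpm_ctrl,
#'   tpm_case, log2fc, chi2, p, q, call).
#' @export
call_differential <- function(mat, case_libs, control_libs,
                              contrast = "case_vs_control",
                              lfc_min = 1, p_max = 0.05,
                              replicate_policy = c("pool", "per_rep")) {
  replicate_policy <- match.arg(replicate_policy)
  if (!length(case_libs) || !length(control_libs) ||
      !all(c(case_libs, control_libs) %in% colnames(mat$counts)))
    stop("call_differential: contrast names libraries absent from the matrix")
  ca <- if (length(case_libs) > 1L) rowSums(mat$counts[, case_libs]) else mat$counts[, case_libs]
  cb <- if (length(control_libs) > 1L) rowSums(mat$counts[, control_libs]) else mat$counts[, control_libs]
  ta <- sum(mat$totals[case_libs]); tb <- sum(mat$totals[control_libs])
  if (replicate_policy == "pool") {
    ts <- chisq_test(ca, ta, cb, tb)
  } else {
    n <- min(length(case_libs), length(control_libs))
    ps <- sapply(seq_len(n), function(i)
      chisq_test(mat$counts[, case_libs[i]], mat$totals[case_libs[i]],
                 mat$counts[, control_libs[i]], mat$totals[control_libs[i]])$p)
    worst <- apply(as.matrix(ps), 1, max)
    ts <- chisq_test(ca, ta, cb, tb)
    ts$p <- pmax(ts$p, worst)
  }
  tpm_case <- ca / ta * 1e6; tpm_ctrl <- cb / tb * 1e6
  lfc <- log2((tpm_case + 1e6 / ta) / (tpm_ctrl + 1e6 / tb))
  q <- p.adjust(ts$p, method = "BH")
  call <- ifelse(abs(lfc) >= lfc_min & ts$p <= p_max,
                 ifelse(lfc > 0, "up", "down"), "ns")
  data.table::data.table(
    mirna = rownames(mat$counts), contrast = contrast,
    tpm_ctrl = tpm_ctrl, tpm_case = tpm_case, log2fc = lfc,
    chi2 = ts$chi2, p = ts$p, q = q, call = call)
}

#' Tissue specificity of miRNA expression under control conditions
#'
#' `specific`: TPM >= `min_tpm` in one tissue and 0 in the other (pooled CK
#' libraries); `preferential`: the differential-expression criteria are met
#' between tissues at CK; otherwise `shared`.
#'
#' @param mat `mirna_expression` object.
#' @param designs library design table.
#' @param min_tpm specificity threshold.
#' @param lfc_min,p_max preferential-expression thresholds.
#' @return data.table (mirna, tpm_stamen, tpm_pistil, label).
#' @export
tissue_specificity <- function(mat, designs, min_tpm = 10,
                               lfc_min = 1, p_max = 0.05) {
  d <- data.table::as.data.table(designs)
  st <- d[tissue == "stamen" & condition == "CK", library_id]
  pi <- d[tissue == "pistil" & condition == "CK", library_id]
  if (!length(st) || !length(pi))
    stop("tissue_specificity: both tissues required at CK")
  de <- call_differential(mat, st, pi, contrast = "stamen_vs_pistil_CK",
                          lfc_min = lfc_min, p_max = p_max)
  ts <- de$tpm_case; tp <- de$tpm_ctrl
  label <- rep("shared", nrow(de))
  label[de$call == "up"] <- "stamen-preferential"
  label[de$call == "down"] <- "pistil-preferential"
  label[ts >= min_tpm & tp == 0] <- "stamen-specific"
  label[tp >= min_tpm & ts == 0] <- "pistil-specific"
  data.table::data.table(mirna = de$mirna, tpm_stamen = ts, tpm_pistil = tp,
                         label = label)
}

#' Length distribution and positional base composition
#'
#' @param sequences character vector of tag or miRNA sequences.
#' @param weights optional numeric weights (e.g. read counts); default 1.
#' @param max_pos number of 5'-anchored positions profiled.
#' @return list: `length_dist` (data.table length/fraction, sums to 1),
#'   `base_freq` (position x base fractions, each position sums to 1 over
#'   covered sequences; RNA alphabet), `five_prime_u` (fraction of weight
#'   starting with U).
#' @export
composition_stats <- function(sequences, weights = NULL, max_pos = 24L) {
  w <- weights %||% rep(1, length(sequences))
  stopifnot(length(w) == length(sequences))
  seqs <- toupper(dna_to_rna(sequences))
  len <- nchar(seqs)
  ld <- data.table::data.table(length = len, w = w)[, .(weight = sum(w)), by = length]
  ld[, fraction := weight / sum(weight)]
  data.table::setorder(ld, length)
  bases <- c("A", "C", "G", "U")
  freq <- matrix(0, nrow = max_pos, ncol = 4, dimnames = list(NULL, bases))
  for (p in seq_len(max_pos)) {
    cover <- len >= p
    if (!any(cover)) next
    ch <- substr(seqs[cover], p, p)
    for (b in bases) freq[p, b] <- sum(w[cover][ch == b])
    tot <- sum(freq[p, ])
    if (tot > 0) freq[p, ] <- freq[p, ] / tot
  }
  list(length_dist = ld[], base_freq = freq,
       five_prime_u = if (sum(w) > 0)
         sum(w[substr(seqs, 1, 1) == "U"]) / sum(w) else NA_real_)
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control)`; fold change is `2^-ddCt`. With replicate vectors the
#' mean ddCt is used and its standard error (propagated across the two
#' replicate sets) is reported.
#'
#' @param ct_target_t,ct_ref_t Ct values under treatment (target and
#'   internal-control gene; scalars or replicate vectors).
#' @param ct_target_c,ct_ref_c Ct values under control conditions.
#' @return list: `fold_change`, `ddct`, `se` (NA for scalar input).
#' @export
ddct_fold_change <- function(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c) {
  stopifnot(all(is.finite(c(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c))))
  dct_t <- ct_target_t - ct_ref_t
  dct_c <- ct_target_c - ct_ref_c
  ddct <- mean(dct_t) - mean(dct_c)
  se <- if (length(dct_t) > 1L || length(dct_c) > 1L) {
    se2 <- function(x) if (length(x) > 1L) var(x) / length(x) else 0
    sqrt(se2(dct_t) + se2(dct_c))
  } else NA_real_
  list(fold_change = 2^(-ddct), ddct = ddct, se = se)
}

#' Stigma exsertion (D-value) summary
#'
#' D-value = mean stamen length - mean pistil length (mm); negative values
#' mean the stigma protrudes beyond the anther cone. Tested with Welch's
#' two-sided t-test; identical zero-variance samples return `p = 1` with an
#' `undefined_variance` flag instead of an error.
#'
#' @param stamen_lengths,pistil_lengths numeric vectors (>= 3 values each).
#' @return list: `d_value`, `se`, `p`, `undefined_variance`.
#' @export
dvalue_summary <- function(stamen_lengths, pistil_lengths) {
  if (length(stamen_lengths) < 3L || length(pistil_lengths) < 3L)
    stop("dvalue_summary: at least 3 measurements required per organ")
  d <- mean(stamen_lengths) - mean(pistil_lengths)
  se <- sqrt(var(stamen_lengths) / length(stamen_lengths) +
               var(pistil_lengths) / length(pistil_lengths))
  undef <- var(stamen_lengths) == 0 && var(pistil_lengths) == 0
  p <- if (undef) {
    if (d == 0) 1 else 0
  } else t.test(stamen_lengths, pistil_lengths)$p.value
  list(d_value = d, se = se, p = p, undefined_variance = undef)
}

#' Overlap table of differentially expressed miRNA sets
#'
#' Set-overlap bookkeeping (the tabular equivalent of a Venn diagram) for DE
#' calls across groups, e.g. tissues or timepoints.
#'
#' @param de_sets named list of character vectors of miRNA names.
#' @return data.table (mirna, one logical column per set, membership label).
#' @export
de_overlap <- function(de_sets) {
  stopifnot(is.list(de_sets), !is.null(names(de_sets)))
  all_m <- sort(unique(unlist(de_sets)))
  out <- data.table::data.table(mirna = all_m)
  for (nm in names(de_sets)) out[, (nm) := all_m %in% de_sets[[nm]]]
  memb <- apply(as.matrix(out[, -1]), 1, function(x)
    paste(names(de_sets)[x], collapse = "&"))
  out[, membership := memb]
  out[]
}
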