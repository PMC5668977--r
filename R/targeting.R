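## Plant-style miRNA target prediction: ungapped antisense window scan with
## an Allen-style expectation penalty (mismatch 1, G:U wobble 0.5, gap 2;
## penalties doubled over miRNA positions 2-13), a single 1-nt bulge allowed
## on either strand, expectation cutoff 3.0.

SEED_RANGE <- 2:13

## penalty of miRNA base (5'->3') vs target base (both T-form):
## 0 = Watson-Crick, 0.5 = G:U wobble, 1 = mismatch
base_penalty <- function(mi, tg) {
  wc <- (mi == "A" & tg == "T") | (mi == "T" & tg == "A") |
    (mi == "G" & tg == "C") | (mi == "C" & tg == "G")
  gu <- (mi == "G" & tg == "T") | (mi == "T" & tg == "G")
  ifelse(wc, 0, ifelse(gu, 0.5, 1))
}

#' Score miRNA target sites on a transcript set
#'
#' Scans each transcript with the miRNA antiparallel (miRNA position 1 pairs
#' the 3'-most base of the target span). Per-position penalties: mismatch
#' 1.0, G:U wobble 0.5, gap 2.0, doubled at miRNA positions 2-13 (the seed
#' region); a single 1-nt bulge on either strand is allowed. Sites with
#' expectation <= `cutoff` are reported, sorted by expectation then
#' coordinate; overlapping sites on the same transcript keep the lowest
#' expectation. Mode is `translational` when miRNA positions 9-11 contain a
#' mismatch, `cleavage` otherwise; cleavage sites carry the predicted
#' cleavage coordinate (see [locate_cleavage()]).
#'
#' @param mirna_seq mature miRNA, 18-26 nt (RNA or DNA form, 5'->3').
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param cutoff expectation cutoff.
#' @param mirna name used in the output.
#' @param allow_bulge permit the single 1-nt bulge.
#' @return data.table of class-less target sites: mirna, transcript_id,
#'   start0, end0 (target span, 0-based half-open), expectation, mode,
#'   cleavage_pos0 (NA for translational sites), alignment (three-row text:
#'   target 5'->3', pairing row, miRNA 3'->5').
#' @export
score_targets <- function(mirna_seq, transcripts, cutoff = 3.0,
                          mirna = "mirna", allow_bulge = TRUE) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) transcripts <- read_fasta(transcripts)
  if (length(transcripts) == 0L) stop("score_targets: empty transcript set")
  mi <- toupper(rna_to_dna(mirna_seq))
  L <- nchar(mi)
  if (L < 18L || L > 26L) stop("score_targets: miRNA must be 18-26 nt")
  miv <- strsplit(mi, "", fixed = TRUE)[[1]]
  mult <- ifelse(seq_len(L) %in% SEED_RANGE, 2, 1)
  out <- list()
  for (tid in names(transcripts)) {
    tv <- strsplit(toupper(transcripts[[tid]]), "", fixed = TRUE)[[1]]
    nt <- length(tv)
    variants <- list(list(type = "none", b = 0L, wlen = L))
    if (allow_bulge) {
      for (b in 1:(L - 1L)) {
        variants <- c(variants, list(list(type = "target", b = b, wlen = L + 1L)))
      }
      for (b in 2:(L - 1L)) {
        variants <- c(variants, list(list(type = "mirna", b = b, wlen = L - 1L)))
      }
    }
    for (v in variants) {
      wlen <- v$wlen
      if (nt < wlen) next
      nw <- nt - wlen + 1L
      exp_v <- numeric(nw)
      mm911 <- logical(nw)
      for (i in seq_len(L)) {
        if (v$type == "mirna" && i == v$b) {
          exp_v <- exp_v + 2 * mult[i]  # bulged-out miRNA base = gap
          next
        }
        off <- target_offset(i, v)
        idx <- seq_len(nw) + off
        pen <- base_penalty(miv[i], tv[idx])
        exp_v <- exp_v + pen * mult[i]
        if (i >= 9L && i <= 11L) mm911 <- mm911 | (pen == 1)
      }
      if (v$type == "target") exp_v <- exp_v + 2 * mult[v$b]
      if (v$type == "mirna" && v$b >= 9L && v$b <= 11L) mm911[] <- TRUE
      hit <- which(exp_v <= cutoff)
      for (w in hit) {
        s0 <- w - 1L
        out[[length(out) + 1L]] <- data.table::data.table(
          mirna = mirna, transcript_id = tid, start0 = s0, end0 = s0 + wlen,
          expectation = exp_v[w],
          mode = if (mm911[w]) "translational" else "cleavage",
          t10 = if (mm911[w]) NA_integer_ else
            as.integer(s0 + target_offset(10L, v) + 1L - 1L),
          variant = v$type, bulge_pos = v$b)
      }
    }
  }
  if (!length(out)) return(empty_sites())
  sites <- data.table::rbindlist(out)
  data.table::setorder(sites, expectation, transcript_id, start0)
  # deduplicate overlapping sites per transcript, best expectation first
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(sites)) > i &
                 sites$transcript_id == sites$transcript_id[i] &
                 sites$start0 < sites$end0[i] & sites$end0 > sites$start0[i])
    keep[j] <- FALSE
  }
  sites <- sites[keep]
  sites[, cleavage_pos0 := t10]
  sites[, alignment := vapply(seq_len(.N), function(i)
    render_alignment(miv, mult, transcripts[[sites$transcript_id[i]]],
                     sites[i]), "")]
  sites[, c("t10") := NULL]
  sites[]
}

## 0-based offset (relative to window start) of the target base pairing
## miRNA position i, for an alignment variant. Antiparallel: position 1
## pairs the window's 3'-most base.
target_offset <- function(i, v) {
  wlen <- v$wlen
  if (v$type == "none") return(wlen - i)
  if (v$type == "target") return(if (i <= v$b) wlen - i else wlen - i - 1L)
  # miRNA bulge: miRNA base v$b unpaired
  if (i < v$b) wlen - i else wlen - i + 1L
}

empty_sites <- function() {
  data.table::data.table(
    mirna = character(0), transcript_id = character(0), start0 = integer(0),
    end0 = integer(0), expectation = numeric(0), mode = character(0),
    variant = character(0), bulge_pos = integer(0),
    cleavage_pos0 = integer(0), alignment = character(0))
}

## three-row alignment text: target 5'->3' / pairing / miRNA 3'->5'
render_alignment <- function(miv, mult, tseq, site) {
  tv <- strsplit(toupper(tseq), "", fixed = TRUE)[[1]]
  L <- length(miv)
  v <- list(type = site$variant, b = site$bulge_pos,
            wlen = site$end0 - site$start0)
  tpos <- vapply(seq_len(L), function(i)
    if (v$type == "mirna" && i == v$b) NA_integer_
    else as.integer(site$start0 + target_offset(i, v) + 1L), 0L)
  # build 3'->5' miRNA row and matching target row (target shown 5'->3')
  ord <- rev(seq_len(L))  # miRNA printed 3' -> 5' so target reads 5' -> 3'
  trow <- prow <- mrow <- character(0)
  for (i in ord) {
    if (is.na(tpos[i])) {
      trow <- c(trow, "-"); mrow <- c(mrow, dna_to_rna(miv[i])); prow <- c(prow, " ")
      next
    }
    tb <- tv[tpos[i]]
    pen <- base_penalty(miv[i], tb)
    trow <- c(trow, dna_to_rna(tb))
    mrow <- c(mrow, dna_to_rna(miv[i]))
    prow <- c(prow, if (pen == 0) "|" else if (pen == 0.5) "o" else " ")
    if (v$type == "target" && i > 1L && !is.na(tpos[i - 1L]) &&
        tpos[i - 1L] - tpos[i] == 2L) {
      # unpaired (bulged) target base between this pair and the next
      trow <- c(trow, dna_to_rna(tv[tpos[i] + 1L]))
      mrow <- c(mrow, "-"); prow <- c(prow, " ")
    }
  }
  paste(paste0("5' ", paste(trow, collapse = ""), " 3' (target)"),
        paste0("   ", paste(prow, collapse = "")),
        paste0("3' ", paste(mrow, collapse = ""), " 5' (miRNA)"),
        sep = "\n")
}

#' Predicted cleavage position of a target site
#'
#' The convention is fixed: the cut falls between the target bases pairing
#' miRNA positions 11 and 10, and the reported coordinate is the 0-based
#' transcript index of the base opposite miRNA position 10 (the base 3' of
#' the cut on the target). For an ungapped site spanning `[start0, end0)`
#' this is `end0 - 10`.
#'
#' @param site one row of a [score_targets()] table.
#' @return integer transcript coordinate (0-based).
#' @export
locate_cleavage <- function(site) {
  if (site$mode != "cleavage")
    stop("locate_cleavage: site is translational, no cleavage position")
  as.integer(site$cleavage_pos0)
}

#' Tally 5' RACE clones against a predicted cleavage site
#'
#' @param site one row of a [score_targets()] table (cleavage mode).
#' @param clone_positions integer vector: 0-based transcript positions of the
#'   clones' 5' ends (same convention as [locate_cleavage()]).
#' @return list: `n_clones`, `at_site`, `fraction_label` (e.g. `"7/10"`),
#'   `peaks` (data.table of positions with >= 2 clones), `positions`.
#' @export
tally_race <- function(site, clone_positions) {
  if (length(clone_positions) == 0L)
    stop("tally_race: at least one clone position required")
  cp <- locate_cleavage(site)
  n <- length(clone_positions)
  at <- sum(clone_positions == cp)
  tab <- table(clone_positions)
  peaks <- data.table::data.table(
    position0 = as.integer(names(tab)[tab >= 2L]),
    n = as.integer(tab[tab >= 2L]))
  data.table::setorder(peaks, -n, position0)
  list(n_clones = n, at_site = at,
       fraction_label = paste0(at, "/", n), peaks = peaks,
       positions = as.integer(clone_positions))
}
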