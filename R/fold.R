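#' Fold an RNA sequence into its best nested secondary structure
#'
#' The built-in engine maximises a stacking-aware base-pair score (GC = 3,
#' AU = 2, GU = 1, +1 per stacked pair) over all nested structures with a
#' minimum hairpin loop of 3, by dynamic programming; the score is reported
#' as a pseudo free energy `mfe = -score / 2` (kcal/mol-like units, <= 0).
#' Structure topology, not exact thermodynamics, drives the downstream
#' hairpin criteria; for publication-grade energies a thermodynamic engine
#' (the `RNAfold` executable) can be plugged in with `engine = "vienna"`.
#'
#' @param sequence RNA (or DNA; `T` is read as `U`) string, length >= 5.
#' @param engine `"builtin"` (default) or `"vienna"` (requires `RNAfold` on
#'   the PATH).
#' @return list with elements `dotbracket` (balanced dot-bracket string of
#'   the same length) and `mfe` (numeric, <= 0).
#' @examples
#' fold_rna("GGGAAACCC")$dotbracket  # "(((...)))"
#' @export
fold_rna <- function(sequence, engine = c("builtin", "vienna")) {
  engine <- match.arg(engine)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(dna_to_rna(sequence))
  if (nchar(seq) < 5L)
    stop("fold_rna: sequence must be at least 5 nt")
  if (grepl("[^ACGU]", seq))
    stop("fold_rna: sequence contains characters outside {A,C,G,U,T}")
  if (engine == "vienna") return(fold_vienna(seq))
  res <- .nussinov_fold_cpp(seq)
  list(dotbracket = res$dotbracket, mfe = -res$score / 2)
}

## Adapter around the ViennaRNA RNAfold executable (thermodynamic MFE).
fold_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("fold_rna: RNAfold executable not found on PATH")
  out <- system2(exe, c("--noPS"), input = seq, stdout = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) stop("fold_rna: could not parse RNAfold output: ", line)
  list(dotbracket = m[2], mfe = as.numeric(m[3]))
}

#' Pairing table of a dot-bracket structure
#'
#' @param dotbracket dot-bracket string (balanced `(`/`)` and `.`).
#' @return integer vector: `pt[i]` is the 1-based partner of position `i`,
#'   or `NA` if unpaired.
#' @export
pairing_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("pairing_table: unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("pairing_table: unbalanced dot-bracket")
  pt
}
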