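## Small sequence helpers shared by all stages. Sequences are plain uppercase
## character vectors; DNA ("T") form is the internal convention, RNA ("U")
## form is used only at the folding boundary and in user-facing output where
## stated.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname revcomp
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; sequences are uppercased
#' and names truncated at the first whitespace, with the full header kept in
#' the `"desc"` attribute.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  full <- names(seqs)
  names(seqs) <- sub("\\s.*$", "", full)
  attr(seqs, "desc") <- full
  seqs
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
}

## Deterministic seeding helper: run `expr` under a locally set RNG seed
## without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## random DNA of given length(s) and GC content
random_dna <- function(n_bases, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n_bases, replace = TRUE, prob = p), collapse = "")
}

## Hamming distance between two equal-length strings
hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv)
}

## Ungapped sliding distance between two sequences of length difference <= 2:
## minimum over offsets of (mismatches in overlap + overhanging bases).
sliding_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > 2L) return(Inf)
  if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  d <- lb - la
  best <- Inf
  for (off in 0:d) {
    mm <- hamming(a, substr(b, off + 1L, off + la)) + d
    if (mm < best) best <- mm
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
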