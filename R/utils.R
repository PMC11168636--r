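# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

#' @noRd
is_proportion <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

#' Split a nucleotide string into complete codons
#'
#' The trailing partial codon (the fragment length need not be a multiple of
#' three) is dropped; `frame_offset` bases are skipped at the 5' end.
#' @noRd
split_codons <- function(seq, frame_offset = 0L) {
  s <- substr(seq, frame_offset + 1L, nchar(seq))
  nc <- nchar(s) %/% 3L
  if (nc == 0L) return(character(0))
  substring(s, seq(1L, by = 3L, length.out = nc), seq(3L, by = 3L, length.out = nc))
}

#' Translate nucleotide sequences (complete codons only)
#'
#' Codons containing characters outside A/C/G/T translate to "X".
#' @noRd
translate_nt <- function(seqs, frame_offset = 0L) {
  code <- Biostrings::GENETIC_CODE
  vapply(seqs, function(s) {
    codons <- split_codons(toupper(s), frame_offset)
    if (length(codons) == 0L) return("")
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
}

#' @noRd
has_stop <- function(seqs, frame_offset = 0L) {
  grepl("*", translate_nt(seqs, frame_offset), fixed = TRUE)
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Length of the common prefix / suffix of two strings
#' @noRd
common_prefix_len <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' @noRd
common_suffix_len <- function(a, b) {
  common_prefix_len(paste(rev(strsplit(a, "", fixed = TRUE)[[1]]), collapse = ""),
                    paste(rev(strsplit(b, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Semicolon (de)serialization of allele-id sets, the on-disk convention
#' @noRd
join_alleles <- function(x) vapply(x, function(a) paste(sort(a), collapse = ";"), character(1))

#' @noRd
split_alleles <- function(x) strsplit(x, ";", fixed = TRUE)

#' Allele sets of a genotype table as a named list of character vectors
#'
#' @param genotypes a genotype table as produced by [assign_genotypes()] or
#'   [read_genotypes()] (columns `individual_id` and `alleles`,
#'   semicolon-joined).
#' @return named list, one character vector of allele ids per individual.
#' @export
allele_sets <- function(genotypes) {
  stopifnot(is.data.frame(genotypes),
            all(c("individual_id", "alleles") %in% names(genotypes)))
  setNames(split_alleles(genotypes$alleles), genotypes$individual_id)
}

#' Seed the RNG only when a seed is supplied
#' @noRd
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
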