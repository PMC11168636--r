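# Readers/writers for the package's plain-text interchange formats: FASTA
# allele files, tab-separated genotype/pair/read tables (header rows, '#'
# metadata comments, semicolon-joined allele sets), JSON PBR mask configs.

#' Read an allele FASTA file
#'
#' Accepts mixed-case and line-wrapped records; sequences are upper-cased.
#' Duplicate ids, empty sequences and characters outside \{A,C,G,T,N,-\} are
#' rejected with descriptive errors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("illegal characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), "=", unlist(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Read a genotype table
#'
#' Tab-separated with header; required columns `individual_id` and `alleles`
#' (semicolon-joined allele ids), optional `population_id` and `sex`. Lines
#' starting `#` are metadata comments.
#'
#' @param path TSV file.
#' @param fasta optional named sequence vector (or [allele_pool]); every
#'   allele id must then resolve.
#' @param max_alleles maximum allele-set size (default 4).
#' @return a genotype table (`data.frame`, class `genotype_table`).
#' @export
read_genotypes <- function(path, fasta = NULL, max_alleles = 4L) {
  df <- read_tsv(path)
  need <- c("individual_id", "alleles")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id(s): ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]), collapse = ", "))
  sets <- split_alleles(df$alleles)
  too_many <- lengths(sets) > max_alleles | lengths(sets) < 1L
  if (any(too_many))
    stop("allele set size outside 1..", max_alleles, " for: ",
         paste(df$individual_id[too_many], collapse = ", "))
  if (!is.null(fasta)) {
    seqs <- if (inherits(fasta, "allele_pool")) fasta$sequences else fasta
    unknown <- setdiff(unique(unlist(sets)), names(seqs))
    if (length(unknown))
      stop("allele id(s) not in FASTA: ", paste(unknown, collapse = ", "))
  }
  if (is.null(df$population_id)) df$population_id <- "unknown"
  if (is.null(df$sex)) df$sex <- "unknown"
  df$n_alleles <- lengths(sets)
  class(df) <- c("genotype_table", class(df))
  df
}

#' @rdname read_genotypes
#' @param genotypes table to write.
#' @param meta optional named list written as `# key=value` header comments.
#' @export
write_genotypes <- function(genotypes, path, meta = NULL) {
  cols <- intersect(c("individual_id", "population_id", "sex", "alleles",
                      "n_alleles", "depths"), names(genotypes))
  write_tsv(as.data.frame(genotypes)[, cols], path, meta)
}

#' Read a breeding-pairs table
#'
#' Tab-separated with header columns `male_id`, `female_id`. Referential
#' integrity against a genotype table is enforced; offenders are listed.
#'
#' @param path TSV file.
#' @param genotypes optional genotype table for id resolution.
#' @return `data.frame` with `male_id`, `female_id`.
#' @export
read_pairs <- function(path, genotypes = NULL) {
  df <- read_tsv(path)
  if (!all(c("male_id", "female_id") %in% names(df)))
    stop("pairs table needs columns male_id, female_id")
  if (!is.null(genotypes)) {
    unknown <- setdiff(c(df$male_id, df$female_id), genotypes$individual_id)
    if (length(unknown))
      stop("pair member(s) not in genotype table: ",
           paste(unique(unknown), collapse = ", "))
  }
  df[, c("male_id", "female_id")]
}

#' @rdname read_pairs
#' @param pairs table to write.
#' @param meta optional named list of header comments.
#' @export
write_pairs <- function(pairs, path, meta = NULL) {
  write_tsv(pairs[, c("male_id", "female_id")], path, meta)
}

#' Read / write a read-variant table
#'
#' Tab-separated with columns `individual_id`, `run_id`, `sequence`,
#' `depth`, `mean_quality`.
#' @param path TSV file.
#' @export
read_reads <- function(path) {
  df <- read_tsv(path)
  check_records(df)
  df
}

#' @rdname read_reads
#' @param records table to write.
#' @param meta optional named list of header comments.
#' @export
write_reads <- function(records, path, meta = NULL) {
  check_records(records)
  write_tsv(as.data.frame(records)[, c("individual_id", "run_id", "sequence",
                                       "depth", "mean_quality")], path, meta)
}

#' Read a PBR codon-mask configuration
#'
#' JSON object with `frame_offset` (0-2) and `pbr_codons` (0-based codon
#' indices). A default mask following the classical human DRB peptide-binding
#' positions ships with the package
#' (`system.file("extdata", "pbr_mask_default.json", package = "aukmhc")`)
#' and is an interpretation, editable per study.
#'
#' @param path JSON file.
#' @param total_codons number of complete codons in the fragment (default
#'   99, a 298-nt fragment in frame 0).
#' @return a [codon_partition()].
#' @export
read_pbr_mask <- function(path, total_codons = 99L) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$pbr_codons)) stop("mask config must define pbr_codons")
  codon_partition(cfg$pbr_codons, total_codons,
                  frame_offset = cfg$frame_offset %||% 0L)
}
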