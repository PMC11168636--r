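# Amplicon allele-calling quality control: read/variant/amplicon filters,
# replicate combination and genotype calling.

#' Quality-control configuration for amplicon allele calling
#'
#' Defaults follow the standard Ion Torrent amplicon-filtering parameters for
#' a 298-bp class II B exon-2 fragment: minimum mean Phred quality 30, strict
#' expected length, 0.5% substitution / 1% indel error budgets, 1% minimum
#' per-amplicon variant frequency, 5% parent-frequency floor for chimera
#' detection, >= 200 reads per allele for singly sequenced individuals, and
#' at most four alleles per individual (two duplicated loci).
#'
#' @param min_mean_quality minimum mean Phred quality (reads strictly below
#'   are removed).
#' @param expected_length_nt expected amplicon length; any other length is
#'   anomalous.
#' @param substitution_error_rate,indel_error_rate per-base error budgets
#'   used to merge artefact variants into deeper parents.
#' @param min_amplicon_freq minimum per-amplicon variant frequency
#'   (inclusive).
#' @param chimera_freq_threshold minimum amplicon frequency (inclusive) for a
#'   variant to act as a chimera parent.
#' @param min_singleton_reads minimum summed depth (inclusive) for variants
#'   of individuals sequenced in a single run, and the depth rescue for
#'   single-run variants of replicated individuals.
#' @param max_alleles_per_individual cap on called alleles (depth-ranked).
#' @param frame_offset reading frame for the stop-codon (pseudogene) check.
#' @export
qc_config <- function(min_mean_quality = 30, expected_length_nt = 298L,
                      substitution_error_rate = 0.005, indel_error_rate = 0.01,
                      min_amplicon_freq = 0.01, chimera_freq_threshold = 0.05,
                      min_singleton_reads = 200L,
                      max_alleles_per_individual = 4L, frame_offset = 0L) {
  stopifnot(is.numeric(min_mean_quality), is_count(expected_length_nt),
            is_proportion(substitution_error_rate),
            is_proportion(indel_error_rate), is_proportion(min_amplicon_freq),
            is_proportion(chimera_freq_threshold),
            is_count(min_singleton_reads), is_count(max_alleles_per_individual),
            frame_offset %in% 0:2)
  structure(as.list(environment()), class = "qc_config")
}

check_records <- function(records) {
  need <- c("individual_id", "run_id", "sequence", "depth", "mean_quality")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("read-variant table must have columns: ", paste(need, collapse = ", "))
  invisible(records)
}

#' Remove low-quality and anomalous-length reads
#'
#' Drops variants with mean Phred quality strictly below
#' `cfg$min_mean_quality` or length different from `cfg$expected_length_nt`;
#' otherwise order-stable.
#'
#' @param records read-variant table (`individual_id`, `run_id`, `sequence`,
#'   `depth`, `mean_quality`).
#' @param cfg a [qc_config()].
#' @return the filtered table, with attribute `"dropped"` giving counts per
#'   reason.
#' @export
clean_variants <- function(records, cfg = qc_config()) {
  check_records(records)
  low_q <- records$mean_quality < cfg$min_mean_quality
  bad_len <- nchar(records$sequence) != cfg$expected_length_nt
  out <- records[!(low_q | bad_len), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(low_quality = sum(low_q),
                            anomalous_length = sum(bad_len & !low_q))
  out
}

# substitution / indel distance between two variants; equal lengths take the
# fast Hamming route, otherwise a global pairwise alignment is used
variant_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    c(sub = hamming(a, b), indel = 0L)
  } else {
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        gapOpening = 4, gapExtension = 1)
    ind <- sum(Biostrings::width(Biostrings::insertion(al)[[1]])) +
      sum(Biostrings::width(Biostrings::deletion(al)[[1]]))
    c(sub = Biostrings::nmismatch(al), indel = ind)
  }
}

#' Merge putative error variants into their parent alleles
#'
#' Within every individual x run amplicon, a variant `u` is merged into a
#' deeper variant `v` when `depth(u) < depth(v)` and `u` differs from `v` by
#' at most `max(1, floor(substitution_error_rate * L))` substitutions and
#' `max(1, floor(indel_error_rate * L))` indel bases (L = parent length).
#' Parents are processed from most to least abundant; merged depth is added
#' to the parent so total amplicon depth is conserved.
#'
#' @inheritParams clean_variants
#' @return consolidated table (one row per surviving variant).
#' @export
consolidate_errors <- function(records, cfg = qc_config()) {
  check_records(records)
  if (nrow(records) == 0L) return(records)
  key <- paste(records$individual_id, records$run_id, sep = "\r")
  parts <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    df <- records[idx, , drop = FALSE]
    ord <- order(-df$depth, df$sequence)
    df <- df[ord, , drop = FALSE]
    alive <- rep(TRUE, nrow(df))
    i <- 1L
    while (i <= nrow(df)) {
      if (alive[i]) {
        L <- nchar(df$sequence[i])
        max_sub <- max(1L, floor(cfg$substitution_error_rate * L))
        max_ind <- max(1L, floor(cfg$indel_error_rate * L))
        j <- which(alive & df$depth < df$depth[i])
        j <- j[j != i]
        for (u in j) {
          d <- variant_distance(df$sequence[u], df$sequence[i])
          if (d[["sub"]] <= max_sub && d[["indel"]] <= max_ind) {
            wq <- c(df$depth[i], df$depth[u])
            df$mean_quality[i] <-
              sum(wq * c(df$mean_quality[i], df$mean_quality[u])) / sum(wq)
            df$depth[i] <- df$depth[i] + df$depth[u]
            alive[u] <- FALSE
          }
        }
      }
      i <- i + 1L
    }
    df[alive, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Remove abundant-parent chimeras
#'
#' A variant is flagged chimeric when, within its amplicon, two distinct
#' deeper parents `p1 != p2`, each at amplicon frequency at or above
#' `cfg$chimera_freq_threshold`, yield the variant as an exact
#' single-breakpoint splice `p1[0:b] + p2[b:]` for some breakpoint `b > 0`
#' (and the variant equals neither parent). Chimeras whose parents fall below
#' the frequency floor are deliberately retained ("the most abundant ones").
#'
#' @inheritParams clean_variants
#' @return table minus chimeras; attribute `"n_chimeric"` counts removals.
#' @export
flag_chimeras <- function(records, cfg = qc_config()) {
  check_records(records)
  if (nrow(records) == 0L) return(records)
  key <- paste(records$individual_id, records$run_id, sep = "\r")
  chimeric <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), key)) {
    depth <- records$depth[idx]
    seqs <- records$sequence[idx]
    freq <- depth / sum(depth)
    for (v in seq_along(idx)) {
      L <- nchar(seqs[v])
      pars <- which(freq >= cfg$chimera_freq_threshold & depth > depth[v] &
                      nchar(seqs) == L)
      if (length(pars) < 2L) next
      cpl <- vapply(pars, function(p) common_prefix_len(seqs[v], seqs[p]), integer(1))
      csl <- vapply(pars, function(p) common_suffix_len(seqs[v], seqs[p]), integer(1))
      found <- FALSE
      for (a in seq_along(pars)) {
        if (found) break
        for (b in seq_along(pars)) {
          if (a == b) next
          p1 <- pars[a]; p2 <- pars[b]
          if (seqs[p1] == seqs[v] || seqs[p2] == seqs[v]) next
          # a breakpoint k with 1 <= k <= L-1 exists iff the prefix match with
          # p1 and suffix match with p2 cover the variant
          lo <- max(1L, L - csl[b])
          hi <- min(cpl[a], L - 1L)
          if (lo <= hi) { found <- TRUE; break }
        }
      }
      chimeric[idx[v]] <- found
    }
  }
  out <- records[!chimeric, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_chimeric") <- sum(chimeric)
  out
}

#' Combine replicated sequencing runs
#'
#' Sums variant depth per (individual, sequence) across runs; records which
#' runs each variant was seen in and how many runs the individual was
#' sequenced in overall.
#'
#' @inheritParams clean_variants
#' @return table with columns `individual_id`, `sequence`, `depth`
#'   (summed), `mean_quality` (depth-weighted), `runs` (comma-joined),
#'   `n_runs_present`, `individual_runs`.
#' @export
combine_runs <- function(records, cfg = qc_config()) {
  check_records(records)
  if (nrow(records) == 0L) {
    return(data.frame(individual_id = character(0), sequence = character(0),
                      depth = integer(0), mean_quality = numeric(0),
                      runs = character(0), n_runs_present = integer(0),
                      individual_runs = integer(0)))
  }
  ind_runs <- tapply(records$run_id, records$individual_id,
                     function(r) length(unique(r)))
  key <- paste(records$individual_id, records$sequence, sep = "\r")
  parts <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    d <- records$depth[idx]
    data.frame(
      individual_id = records$individual_id[idx[1]],
      sequence = records$sequence[idx[1]],
      depth = sum(d),
      mean_quality = sum(d * records$mean_quality[idx]) / sum(d),
      runs = paste(sort(unique(records$run_id[idx])), collapse = ","),
      n_runs_present = length(unique(records$run_id[idx])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out$individual_runs <- as.integer(ind_runs[out$individual_id])
  out <- out[order(out$individual_id, -out$depth, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call one individual's genotype from its combined variant table
#'
#' Applies, in order: the inclusive per-amplicon frequency floor
#' (`min_amplicon_freq`, relative to the individual's total combined depth);
#' the replicate-concordance rule (variants of individuals sequenced in a
#' single run need summed depth >= `min_singleton_reads`; variants of
#' replicated individuals must be present in >= 2 runs OR reach that depth);
#' length and open-reading-frame validation (no stop codon at
#' `frame_offset`, pseudogene exclusion); and the depth-ranked cap of
#' `max_alleles_per_individual` (ties broken lexicographically by sequence).
#'
#' @param combined rows of a [combine_runs()] table for one individual.
#' @param cfg a [qc_config()].
#' @param pool optional [allele_pool][generate_allele_pool] or named sequence
#'   vector used to translate called sequences into allele ids; unmatched
#'   sequences receive ids `<individual>.novNN`.
#' @return a list: `called` (logical); when called, `individual_id`,
#'   `allele_ids`, `sequences`, `depths`; otherwise `reason`.
#' @export
call_genotype <- function(combined, cfg = qc_config(), pool = NULL) {
  stopifnot(is.data.frame(combined))
  if (nrow(combined) == 0L)
    return(list(called = FALSE, reason = "no variants"))
  ind <- unique(combined$individual_id)
  if (length(ind) != 1L) stop("call_genotype expects one individual")
  tot <- sum(combined$depth)
  freq_ok <- combined$depth / tot >= cfg$min_amplicon_freq
  single <- combined$individual_runs[1] < 2L
  run_ok <- if (single) combined$depth >= cfg$min_singleton_reads
            else combined$n_runs_present >= 2L |
                 combined$depth >= cfg$min_singleton_reads
  len_ok <- nchar(combined$sequence) == cfg$expected_length_nt
  orf_ok <- len_ok & !has_stop(combined$sequence, cfg$frame_offset)
  keep <- combined[freq_ok & run_ok & orf_ok, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(list(called = FALSE, reason = "no variant passed filters",
                individual_id = ind))
  keep <- keep[order(-keep$depth, keep$sequence), , drop = FALSE]
  keep <- head(keep, cfg$max_alleles_per_individual)
  ids <- if (!is.null(pool)) {
    seqs <- if (inherits(pool, "allele_pool")) pool$sequences else pool
    m <- match(keep$sequence, seqs)
    out_ids <- names(seqs)[m]
    nov <- which(is.na(m))
    out_ids[nov] <- sprintf("%s.nov%02d", ind, seq_along(nov))
    out_ids
  } else sprintf("%s.var%02d", ind, seq_len(nrow(keep)))
  list(called = TRUE, individual_id = ind, allele_ids = ids,
       sequences = keep$sequence, depths = keep$depth)
}

#' Call genotypes for every individual in a combined variant table
#'
#' @param combined a [combine_runs()] table.
#' @param cfg a [qc_config()].
#' @param pool optional allele pool for id assignment (see [call_genotype()]).
#' @param metadata optional `data.frame` with `individual_id`,
#'   `population_id`, `sex` to annotate calls.
#' @return list with `genotypes` (a genotype table) and `rejected`
#'   (`data.frame` of individual ids and reasons).
#' @export
call_genotypes <- function(combined, cfg = qc_config(), pool = NULL,
                           metadata = NULL) {
  calls <- lapply(split(combined, combined$individual_id), call_genotype,
                  cfg = cfg, pool = pool)
  ok <- vapply(calls, `[[`, logical(1), "called")
  gts <- lapply(calls[ok], function(g)
    data.frame(individual_id = g$individual_id,
               population_id = "unknown", sex = "unknown",
               alleles = paste(sort(g$allele_ids), collapse = ";"),
               n_alleles = length(g$allele_ids),
               depths = paste(g$depths[order(g$allele_ids)], collapse = ";"),
               stringsAsFactors = FALSE))
  genotypes <- if (length(gts)) do.call(rbind, gts) else
    data.frame(individual_id = character(0), population_id = character(0),
               sex = character(0), alleles = character(0),
               n_alleles = integer(0), depths = character(0))
  rownames(genotypes) <- NULL
  if (!is.null(metadata) && nrow(genotypes)) {
    m <- match(genotypes$individual_id, metadata$individual_id)
    if ("population_id" %in% names(metadata))
      genotypes$population_id <- ifelse(is.na(m), "unknown",
                                        metadata$population_id[m])
    if ("sex" %in% names(metadata))
      genotypes$sex <- ifelse(is.na(m), "unknown", metadata$sex[m])
  }
  rejected <- data.frame(
    individual_id = vapply(calls[!ok], function(g)
      g$individual_id %||% NA_character_, character(1)),
    reason = vapply(calls[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  rownames(rejected) <- NULL
  class(genotypes) <- c("genotype_table", class(genotypes))
  list(genotypes = genotypes, rejected = rejected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full QC pipeline on a read-variant table
#'
#' Convenience wrapper chaining [clean_variants()], [consolidate_errors()],
#' [flag_chimeras()], [combine_runs()] and [call_genotypes()], collecting a
#' per-filter drop report.
#'
#' @inheritParams call_genotypes
#' @param records raw read-variant table.
#' @return list with `genotypes`, `rejected` and `report` (named counts).
#' @export
qc_pipeline <- function(records, cfg = qc_config(), pool = NULL,
                        metadata = NULL) {
  n0 <- nrow(records)
  cleaned <- clean_variants(records, cfg)
  cons <- consolidate_errors(cleaned, cfg)
  noch <- flag_chimeras(cons, cfg)
  comb <- combine_runs(noch, cfg)
  calls <- call_genotypes(comb, cfg, pool = pool, metadata = metadata)
  report <- c(input_variants = n0,
              dropped_quality_length = n0 - nrow(cleaned),
              merged_error_variants = nrow(cleaned) - nrow(cons),
              removed_chimeras = nrow(cons) - nrow(noch),
              combined_variants = nrow(comb),
              individuals_called = nrow(calls$genotypes),
              individuals_rejected = nrow(calls$rejected))
  c(calls, list(report = report))
}

#' Summaries of a called genotype table
#'
#' Tabulates the distribution of alleles per individual, per-population
#' distinct-allele counts and percentage of population-private alleles, and
#' the global allele frequency spectrum (carrier counts and share of all
#' allele observations).
#'
#' @param genotypes a genotype table.
#' @return list with `allele_number_distribution`, `population_alleles`,
#'   `allele_frequencies`.
#' @export
genotype_summary <- function(genotypes) {
  stopifnot(is.data.frame(genotypes), nrow(genotypes) >= 1L)
  sets <- allele_sets(genotypes)
  sizes <- lengths(sets)
  dist <- as.data.frame(table(n_alleles = factor(sizes)), stringsAsFactors = FALSE)
  names(dist) <- c("n_alleles", "n_individuals")
  dist$n_alleles <- as.integer(dist$n_alleles)
  dist$pct <- 100 * dist$n_individuals / length(sets)

  pop_of <- genotypes$population_id
  by_pop <- split(sets, pop_of)
  pop_alleles <- lapply(by_pop, function(s) unique(unlist(s)))
  pops <- names(pop_alleles)
  uniq_pct <- vapply(pops, function(p) {
    others <- unique(unlist(pop_alleles[setdiff(pops, p)]))
    mine <- pop_alleles[[p]]
    if (length(mine) == 0L) return(NA_real_)
    100 * mean(!mine %in% others)
  }, numeric(1))
  pop_df <- data.frame(population_id = pops,
                       n_individuals = as.integer(table(pop_of)[pops]),
                       n_alleles = lengths(pop_alleles),
                       pct_unique = uniq_pct, stringsAsFactors = FALSE)
  rownames(pop_df) <- NULL

  occ <- unlist(sets, use.names = FALSE)
  carriers <- vapply(split(rep(names(sets), lengths(sets)), occ),
                     function(x) length(unique(x)), integer(1))
  freq_df <- data.frame(allele_id = names(carriers),
                        n_carriers = as.integer(carriers),
                        freq = as.numeric(table(occ)[names(carriers)]) / length(occ),
                        stringsAsFactors = FALSE)
  freq_df <- freq_df[order(-freq_df$n_carriers, freq_df$allele_id), ]
  rownames(freq_df) <- NULL

  list(allele_number_distribution = dist, population_alleles = pop_df,
       allele_frequencies = freq_df)
}
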