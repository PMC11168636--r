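# Umbrella pipeline binding the stages, with a reproducibility manifest.

#' Run configuration for the umbrella pipeline
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param fasta path to the allele FASTA (required for diversity, selection
#'   and amino-acid mate-choice stages).
#' @param genotypes path to a genotype TSV (required for mate choice unless
#'   called from reads).
#' @param pairs path to a breeding-pairs TSV (mate-choice stage).
#' @param reads path to a read-variant TSV (QC stage); stages missing their
#'   inputs are skipped with a logged message.
#' @param mask path to a PBR mask JSON; defaults to the packaged mask.
#' @param qc a [qc_config()]; `NULL` (default) derives the expected amplicon
#'   length from the allele FASTA and keeps the remaining defaults.
#' @param B mate-choice randomization iterations.
#' @param n_bootstrap dN/dS bootstrap replicates.
#' @param R transition/transversion ratio.
#' @param window_nt,step_nt sliding-window parameters for Tajima's D.
#' @param site_handling alignment missing-data convention.
#' @param frame_offset reading frame.
#' @export
run_config <- function(out_dir, seed = 1L, fasta = NULL, genotypes = NULL,
                       pairs = NULL, reads = NULL, mask = NULL,
                       qc = NULL, B = 10000L, n_bootstrap = 1000L,
                       R = 2, window_nt = 25L, step_nt = 5L,
                       site_handling = "complete_deletion", frame_offset = 0L) {
  for (p in c(fasta, genotypes, pairs, reads, mask))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, for whichever inputs are present: the QC allele-calling stage
#' (reads -> genotypes + QC report), the diversity stage (FASTA -> summary
#' statistics and windowed Tajima's D), the selection stage (FASTA + mask ->
#' PBR / non-PBR dN/dS Z-tests), and the mate-choice stage (pairs +
#' genotypes + FASTA -> six randomization tests, null distributions and a
#' sample-size sensitivity table). Every output carries `# key=value`
#' header metadata (seed, config hash) and a JSON manifest records versions,
#' seeds, inputs and stage completion, sufficient to reproduce byte-identical
#' results.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), "out_dir")], auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  meta <- list(seed = config$seed, config_hash = cfg_hash)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  out <- list()

  pool_seqs <- if (!is.null(config$fasta)) read_fasta(config$fasta) else NULL
  if (is.null(config$qc)) {
    config$qc <- if (!is.null(pool_seqs))
      qc_config(expected_length_nt = unique(nchar(pool_seqs))[1]) else qc_config()
  }
  partition <- NULL
  if (!is.null(pool_seqs)) {
    L <- unique(nchar(pool_seqs))
    if (length(L) != 1L) stop("allele FASTA sequences must be of equal length")
    n_codons <- (L - config$frame_offset) %/% 3L
    mask_path <- config$mask %||%
      system.file("extdata", "pbr_mask_default.json", package = "aukmhc")
    partition <- read_pbr_mask(mask_path, total_codons = n_codons)
  }

  genotypes <- if (!is.null(config$genotypes))
    read_genotypes(config$genotypes, fasta = pool_seqs,
                   max_alleles = config$qc$max_alleles_per_individual) else NULL

  # -- QC stage ------------------------------------------------------------
  if (!is.null(config$reads)) {
    records <- read_reads(config$reads)
    qcres <- qc_pipeline(records, config$qc, pool = pool_seqs,
                         metadata = genotypes)
    write_genotypes(qcres$genotypes,
                    file.path(config$out_dir, "called_genotypes.tsv"), meta)
    jsonlite::write_json(
      c(as.list(qcres$report), list(rejected = qcres$rejected)),
      file.path(config$out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    say("qc: %d individuals called, %d rejected",
        qcres$report[["individuals_called"]],
        qcres$report[["individuals_rejected"]])
    out$qc <- qcres
  } else say("qc: skipped (no reads input)")

  # -- diversity stage -----------------------------------------------------
  if (!is.null(pool_seqs)) {
    aln <- allele_alignment(pool_seqs, site_handling = config$site_handling)
    sm <- popgen_summary(aln)
    td <- tajimas_d(aln, window_nt = config$window_nt, step_nt = config$step_nt)
    write_tsv(data.frame(statistic = c("h", "S", "eta", "pi", "theta_w", "K",
                                       "tajimas_D"),
                         value = c(sm$h, sm$S, sm$eta, sm$pi, sm$theta_w, sm$K,
                                   td$D)),
              file.path(config$out_dir, "popgen_summary.tsv"), meta)
    write_tsv(td$windows, file.path(config$out_dir, "tajimas_d_windows.tsv"),
              meta)
    say("popgen: h=%d S=%d eta=%d", sm$h, sm$S, sm$eta)
    out$popgen <- list(summary = sm, tajima = td)
  } else say("popgen: skipped (no FASTA input)")

  # -- selection stage -----------------------------------------------------
  if (!is.null(pool_seqs)) {
    sel <- lapply(c(pbr = "pbr", non_pbr = "non_pbr"), function(rg)
      z_test_positive_selection(pool_seqs, partition, region = rg,
                                R = config$R, n_bootstrap = config$n_bootstrap,
                                seed = config$seed + 101L))
    write_tsv(do.call(rbind, lapply(sel, function(s)
      data.frame(region = s$region, dN = s$dN, dS = s$dS, omega = s$omega,
                 Z = s$Z, p_one_tailed = s$p_one_tailed))),
      file.path(config$out_dir, "selection.tsv"), meta)
    say("selection: omega(pbr)=%.3f omega(non_pbr)=%.3f",
        sel$pbr$omega, sel$non_pbr$omega)
    out$selection <- sel
  } else say("selection: skipped (no FASTA input)")

  # -- mate-choice stage ---------------------------------------------------
  if (!is.null(config$pairs) && !is.null(genotypes) && !is.null(pool_seqs)) {
    pairs <- read_pairs(config$pairs, genotypes)
    pool <- structure(list(sequences = pool_seqs,
                           length_nt = nchar(pool_seqs[[1]]),
                           frame_offset = partition$frame_offset,
                           pbr_codons = partition$pbr,
                           n_codons = partition$total_codons),
                      class = "allele_pool")
    mc <- run_all_tests(pairs, genotypes, pool, partition = partition,
                        B = config$B, seed = config$seed + 201L)
    write_tsv(mc$table, file.path(config$out_dir, "matechoice.tsv"),
              c(meta, list(alpha_adjusted = mc$alpha_adjusted)))
    nulls <- do.call(rbind, lapply(mc$results, function(r)
      data.frame(metric = r$metric, region = r$region, null_mean = r$null_means)))
    write_tsv(nulls, file.path(config$out_dir, "matechoice_nulls.tsv"), meta)
    sens <- sensitivity_curve(pairs, genotypes, "band_sharing", pool,
                              reps_per_n = 10L, B = 999L,
                              seed = config$seed + 301L)
    write_tsv(sens, file.path(config$out_dir, "sensitivity_band_sharing.tsv"),
              meta)
    say("matechoice: %d/%d tests significant after Bonferroni",
        sum(mc$table$significant_bonferroni), nrow(mc$table))
    out$matechoice <- mc
    out$sensitivity <- sens
  } else say("matechoice: skipped (needs pairs + genotypes + FASTA)")

  manifest <- list(
    package = "aukmhc",
    version = as.character(packageVersion("aukmhc")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = cfg_hash,
    config = jsonlite::parse_json(cfg_json),
    log = log_lines,
    created = "run"  # deliberately not a timestamp: outputs stay byte-identical
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
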