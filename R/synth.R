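# Synthetic study populations: allele pools, genotypes, breeding pairs and
# replicated amplicon read tables with known ground truth.

#' Generate a synthetic MHC allele pool
#'
#' Builds `n_alleles` distinct, equal-length, stop-codon-free nucleotide
#' haplotypes emulating an MHC class II B exon-2 allele pool. Alleles share a
#' random ancestral backbone and differ at a restricted set of polymorphic
#' sites, so that a realistic pool (99 alleles of 298 nt) shows on the order
#' of tens of segregating sites and double-digit mean pairwise differences,
#' as observed in highly polymorphic class II fragments, rather than the
#' ~75% divergence of independently random sequences.
#'
#' @param n_alleles number of distinct alleles (>= 2).
#' @param length_nt fragment length in nucleotides (default 298).
#' @param frame_offset reading-frame offset in \{0,1,2\}; the trailing partial
#'   codon is ignored during translation.
#' @param pbr_fraction fraction of codons assigned to the putative
#'   peptide-binding region mask (chosen uniformly without replacement);
#'   `round(pbr_fraction * n_codons)` codons are selected.
#' @param seed integer seed; identical calls with the same seed are
#'   byte-identical.
#' @param variable_fraction fraction of sites allowed to vary between alleles.
#' @param site_mut_prob per-allele probability that a variable site carries
#'   the site's alternative base.
#' @return an object of class `allele_pool`: list with `sequences` (named
#'   character vector, ids `Alal-DAB*NNN`), `length_nt`, `frame_offset`,
#'   `pbr_codons` (0-based codon indices) and `n_codons`.
#' @examples
#' pool <- generate_allele_pool(10, 60, seed = 1)
#' length(pool$sequences)
#' @export
generate_allele_pool <- function(n_alleles, length_nt = 298L, frame_offset = 0L,
                                 pbr_fraction = 0.25, seed = NULL,
                                 variable_fraction = 0.30, site_mut_prob = 0.10) {
  stopifnot(is_count(n_alleles, 2L), is_count(length_nt, 3L),
            frame_offset %in% 0:2, is_proportion(pbr_fraction),
            is_proportion(variable_fraction), is_proportion(site_mut_prob))
  n_codons <- (length_nt - frame_offset) %/% 3L
  if (n_codons < 1L) stop("fragment too short to contain a complete codon")
  # capacity check: 61 sense codons per in-frame codon, 4 free bases elsewhere
  n_free <- length_nt - 3L * n_codons
  log_capacity <- n_codons * log(61) + n_free * log(4)
  if (log_capacity < log(n_alleles)) {
    stop(sprintf(
      "infeasible: cannot place %d distinct stop-free sequences of %d nt",
      n_alleles, length_nt))
  }
  seed_rng(seed)

  draw_stop_free <- function() {
    repeat {
      s <- paste(sample(DNA_BASES, length_nt, replace = TRUE), collapse = "")
      if (!has_stop(s, frame_offset)) return(s)
    }
  }
  ancestor <- draw_stop_free()
  n_var <- max(1L, round(variable_fraction * length_nt))
  var_sites <- sort(sample.int(length_nt, min(n_var, length_nt)))
  anc_chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  alt_base <- vapply(var_sites, function(i)
    sample(setdiff(DNA_BASES, anc_chars[i]), 1L), character(1))

  seqs <- character(0)
  max_tries <- 1000L * n_alleles
  tries <- 0L
  while (length(seqs) < n_alleles) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("infeasible: could not place the requested number of distinct ",
           "stop-free alleles under the configured polymorphism model")
    }
    mut <- runif(length(var_sites)) < site_mut_prob
    chars <- anc_chars
    chars[var_sites[mut]] <- alt_base[mut]
    s <- paste(chars, collapse = "")
    if (s %in% seqs || has_stop(s, frame_offset)) next
    seqs <- c(seqs, s)
  }
  names(seqs) <- sprintf("Alal-DAB*%03d", seq_len(n_alleles))

  n_pbr <- round(pbr_fraction * n_codons)
  pbr <- if (n_pbr > 0L) sort(sample.int(n_codons, n_pbr) - 1L) else integer(0)

  structure(list(sequences = seqs, length_nt = as.integer(length_nt),
                 frame_offset = as.integer(frame_offset),
                 pbr_codons = as.integer(pbr), n_codons = as.integer(n_codons)),
            class = "allele_pool")
}

#' @export
print.allele_pool <- function(x, ...) {
  cat(sprintf("allele_pool: %d alleles x %d nt (frame %d), %d/%d PBR codons\n",
              length(x$sequences), x$length_nt, x$frame_offset,
              length(x$pbr_codons), x$n_codons))
  invisible(x)
}

#' Rank-geometric allele frequencies
#'
#' Frequency of rank `r` is proportional to `skew^r`, renormalized. Small
#' `skew` concentrates mass on the top-ranked alleles; `skew -> 1` approaches
#' the uniform spectrum.
#'
#' @param n_alleles number of ranks.
#' @param skew geometric decay in (0, 1).
#' @return numeric vector of length `n_alleles` summing to 1.
#' @export
rank_geometric_freqs <- function(n_alleles, skew) {
  stopifnot(is_count(n_alleles), is.numeric(skew), skew > 0, skew < 1)
  w <- skew^seq_len(n_alleles)
  w / sum(w)
}

#' Solve the geometric decay for a requested top-k frequency share
#'
#' Finds `skew` such that the top `k` ranks of [rank_geometric_freqs()] carry
#' the requested share of draws (e.g. the four most common alleles carrying
#' ~35% of allelic variation).
#'
#' @param n_alleles pool size.
#' @param share requested cumulative frequency of the top `k` ranks; must lie
#'   strictly between `k / n_alleles` (uniform) and 1.
#' @param k number of top ranks (default 4).
#' @return the decay parameter in (0, 1).
#' @export
solve_freq_skew <- function(n_alleles, share = 0.35, k = 4L) {
  stopifnot(is_count(n_alleles, k + 1L), is_proportion(share), share > k / n_alleles,
            share < 1)
  f <- function(s) sum(rank_geometric_freqs(n_alleles, s)[seq_len(k)]) - share
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Assign multilocus genotypes from a skewed allele pool
#'
#' Each individual draws two alleles per locus (with replacement) from a
#' rank-geometric frequency spectrum; the stored genotype is the set of
#' distinct alleles drawn, so its size lies in `1..2*n_loci` and locus
#' assignment is deliberately unresolved, mirroring amplicon genotyping of
#' duplicated MHC loci. The locus-resolved draws are retained as hidden
#' metadata (attribute `"locus_truth"`) for testing only.
#'
#' @param pool an [allele_pool][generate_allele_pool].
#' @param n_individuals number of individuals (> 0).
#' @param n_loci number of duplicated loci (default 2).
#' @param freq_skew geometric decay of the allele-frequency spectrum; when
#'   `NULL`, solved so the top four alleles carry ~35% of draws.
#' @param seed integer seed.
#' @param populations named numeric vector of population weights (defaults to
#'   the three-colony design 99:12:29).
#' @param sex_ratio proportion of males (sex assigned independently).
#' @return a `data.frame` (class `genotype_table`) with columns
#'   `individual_id`, `population_id`, `sex`, `alleles` (semicolon-joined
#'   allele ids) and `n_alleles`.
#' @export
assign_genotypes <- function(pool, n_individuals, n_loci = 2L, freq_skew = NULL,
                             seed = NULL,
                             populations = c(Spitsbergen = 99, Greenland = 12,
                                             FranzJosefLand = 29),
                             sex_ratio = 0.5) {
  stopifnot(inherits(pool, "allele_pool"), is_count(n_loci))
  if (!is_count(n_individuals)) stop("n_individuals must be a positive integer")
  n_all <- length(pool$sequences)
  seed_rng(seed)
  freqs <- if (n_all == 1L) 1 else {
    if (is.null(freq_skew)) {
      # default: top-4 alleles carry ~35% of draws; for pools so small that a
      # uniform spectrum already exceeds that share, fall back to near-uniform
      freq_skew <- if (0.35 > 4 / n_all + 1e-9) solve_freq_skew(n_all)
                   else 1 - 1e-9
    }
    rank_geometric_freqs(n_all, freq_skew)
  }
  ids <- names(pool$sequences)
  pops <- sample(names(populations), n_individuals, replace = TRUE,
                 prob = populations / sum(populations))
  sexes <- ifelse(runif(n_individuals) < sex_ratio, "male", "female")

  draws <- replicate(n_individuals,
                     matrix(sample(ids, 2L * n_loci, replace = TRUE, prob = freqs),
                            nrow = 2L), simplify = FALSE)
  sets <- lapply(draws, function(m) sort(unique(as.vector(m))))
  out <- data.frame(
    individual_id = sprintf("ind%04d", seq_len(n_individuals)),
    population_id = pops,
    sex = sexes,
    alleles = join_alleles(sets),
    n_alleles = lengths(sets),
    stringsAsFactors = FALSE)
  names(draws) <- out$individual_id
  attr(out, "locus_truth") <- draws
  class(out) <- c("genotype_table", class(out))
  out
}

#' Mating-regime description for [form_pairs()]
#'
#' @param mode `"random"`, `"assortative"` or `"disassortative"`.
#' @param strength non-negative selection intensity on the metric; 0 reduces
#'   any mode to random mating.
#' @param metric_name one of `"het_diff_abs"`, `"band_sharing"`, `"aa_sum"`,
#'   `"aa_max"`.
#' @param region `"whole"` or `"pbr"` context for the amino-acid metrics.
#' @export
mating_regime <- function(mode = c("random", "assortative", "disassortative"),
                          strength = 0, metric_name = "band_sharing",
                          region = c("whole", "pbr")) {
  mode <- match.arg(mode)
  region <- match.arg(region)
  if (!metric_name %in% c("het_diff_abs", "band_sharing", "aa_sum", "aa_max"))
    stop("unknown metric_name: ", metric_name)
  stopifnot(is.numeric(strength), length(strength) == 1L, strength >= 0)
  structure(list(mode = mode, strength = strength, metric_name = metric_name,
                 region = region), class = "mating_regime")
}

#' Form breeding pairs under a mating regime
#'
#' Random mode draws a uniform perfect matching between the sexes.
#' Assortative/disassortative modes build the matching greedily: males are
#' visited in random order and each picks a remaining female with probability
#' proportional to `exp(+/- strength * metric)`, `+` for assortative, `-` for
#' disassortative. `min(n_males, n_females)` pairs are returned and each
#' individual is used at most once.
#'
#' @param genotypes a genotype table with a `sex` column.
#' @param regime a [mating_regime()].
#' @param seed integer seed.
#' @param pool allele pool, required by the amino-acid metrics.
#' @return `data.frame` with columns `male_id`, `female_id`.
#' @export
form_pairs <- function(genotypes, regime = mating_regime("random"), seed = NULL,
                       pool = NULL) {
  stopifnot(inherits(regime, "mating_regime"), is.data.frame(genotypes))
  males <- genotypes$individual_id[genotypes$sex == "male"]
  females <- genotypes$individual_id[genotypes$sex == "female"]
  if (length(males) < 1L || length(females) < 1L)
    stop("need at least one male and one female genotype")
  seed_rng(seed)
  n <- min(length(males), length(females))
  sets <- allele_sets(genotypes)

  if (regime$mode == "random" || regime$strength == 0) {
    m <- sample(males, n)
    f <- sample(females, n)
    return(data.frame(male_id = m, female_id = f, stringsAsFactors = FALSE))
  }

  mfun <- metric_fun(regime$metric_name, pool, region = regime$region)
  sgn <- if (regime$mode == "assortative") 1 else -1
  males <- sample(males, n)
  remaining <- sample(females, length(females))
  out_m <- character(n); out_f <- character(n)
  for (i in seq_len(n)) {
    vals <- vapply(remaining, function(f) mfun(sets[[males[i]]], sets[[f]]),
                   numeric(1))
    w <- exp(sgn * regime$strength * (vals - max(vals)))  # stabilized
    pick <- sample.int(length(remaining), 1L, prob = w)
    out_m[i] <- males[i]; out_f[i] <- remaining[pick]
    remaining <- remaining[-pick]
  }
  data.frame(male_id = out_m, female_id = out_f, stringsAsFactors = FALSE)
}

#' Read-simulation configuration
#'
#' Defaults mirror the error magnitudes of the amplicon-filtering defaults
#' (0.5% per-base substitution rate, 1% per-base indel rate) and a two-run
#' replicated design.
#'
#' @param depth_mean expected reads per true allele per run.
#' @param substitution_error_rate,indel_error_rate per-base error
#'   probabilities in `[0, 1]`.
#' @param chimera_fraction relative abundance of injected chimeric variants.
#' @param n_runs number of independent sequencing runs (>= 1).
#' @param seed integer seed.
#' @export
read_sim_config <- function(depth_mean = 500, substitution_error_rate = 0.005,
                            indel_error_rate = 0.01, chimera_fraction = 0.05,
                            n_runs = 2L, seed = NULL) {
  stopifnot(is.numeric(depth_mean), depth_mean > 0,
            is_proportion(substitution_error_rate),
            is_proportion(indel_error_rate), is_proportion(chimera_fraction),
            is_count(n_runs))
  structure(list(depth_mean = depth_mean,
                 substitution_error_rate = substitution_error_rate,
                 indel_error_rate = indel_error_rate,
                 chimera_fraction = chimera_fraction,
                 n_runs = as.integer(n_runs), seed = seed),
            class = "read_sim_config")
}

# corrupt one read: nsub substitutions at distinct sites, nind indel events
# (deletion or single-base insertion, p = 1/2 each)
corrupt_read <- function(chars, nsub, nind) {
  L <- length(chars)
  if (nsub > 0L) {
    pos <- sample.int(L, min(nsub, L))
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1))
  }
  for (k in seq_len(nind)) {
    p <- sample.int(length(chars), 1L)
    if (runif(1) < 0.5 && length(chars) > 1L) {
      chars <- chars[-p]
    } else {
      chars <- append(chars, sample(DNA_BASES, 1L), after = p)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a replicated amplicon read-variant table
#'
#' For every individual x run, each true allele receives a Poisson read depth
#' around `depth_mean`. Reads are independently corrupted per base at the
#' configured substitution/indel rates; identical corrupted sequences are
#' aggregated into variants. Individuals carrying >= 2 alleles additionally
#' receive one chimeric variant per run (a single-breakpoint prefix+suffix
#' splice of two of their true alleles) with Poisson depth
#' `chimera_fraction * depth_mean`. The true allele sets are recorded
#' immutably in the `"truth"` attribute for recovery experiments.
#'
#' @param genotypes genotype table.
#' @param pool the allele pool the genotypes reference.
#' @param cfg a [read_sim_config()].
#' @return `data.frame` with columns `individual_id`, `run_id`, `sequence`,
#'   `depth`, `mean_quality`; attributes `"truth"` (named list of true allele
#'   ids per individual) and `"config"`.
#' @export
simulate_reads <- function(genotypes, pool, cfg = read_sim_config()) {
  stopifnot(inherits(pool, "allele_pool"), inherits(cfg, "read_sim_config"))
  seed_rng(cfg$seed)
  sets <- allele_sets(genotypes)
  L <- pool$length_nt
  rows <- vector("list", 0L)
  # one template molecule sequenced D times through the error channel
  emit <- function(ind, run_id, s, D) {
    if (D == 0L) return(NULL)
    nsub <- rbinom(D, L, cfg$substitution_error_rate)
    nind <- rbinom(D, L, cfg$indel_error_rate)
    clean <- sum(nsub == 0L & nind == 0L)
    seqs <- if (clean > 0L) s else character(0)
    depths <- if (clean > 0L) clean else integer(0)
    err <- which(nsub > 0L | nind > 0L)
    if (length(err)) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      eseqs <- vapply(err, function(j) corrupt_read(chars, nsub[j], nind[j]),
                      character(1))
      tab <- table(eseqs)
      seqs <- c(seqs, names(tab))
      depths <- c(depths, as.integer(tab))
    }
    data.frame(individual_id = ind, run_id = run_id, sequence = seqs,
               depth = depths, stringsAsFactors = FALSE)
  }
  for (ind in names(sets)) {
    alleles <- sets[[ind]]
    for (run in seq_len(cfg$n_runs)) {
      run_id <- sprintf("run%d", run)
      for (al in alleles) {
        rows[[length(rows) + 1L]] <-
          emit(ind, run_id, pool$sequences[[al]], rpois(1L, cfg$depth_mean))
      }
      if (cfg$chimera_fraction > 0 && length(alleles) >= 2L) {
        # PCR chimera: spliced template, sequenced through the same channel
        par <- sample(alleles, 2L)
        b <- sample.int(L - 1L, 1L)
        chim <- paste0(substr(pool$sequences[[par[1]]], 1L, b),
                       substr(pool$sequences[[par[2]]], b + 1L, L))
        cd <- rpois(1L, cfg$chimera_fraction * cfg$depth_mean)
        if (cd > 0L && !chim %in% pool$sequences[alleles]) {
          rows[[length(rows) + 1L]] <- emit(ind, run_id, chim, cd)
        }
      }
    }
  }
  rows <- Filter(Negate(is.null), rows)
  out <- do.call(rbind, rows)
  # aggregate identical sequences within an amplicon (e.g. error variant
  # coinciding with another allele's read)
  key <- paste(out$individual_id, out$run_id, out$sequence, sep = "\r")
  agg <- rowsum(out$depth, key)
  first <- !duplicated(key)
  out <- out[first, ]
  out$depth <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  out$mean_quality <- round(pmax(31, rnorm(nrow(out), 37, 1.5)), 1)
  rownames(out) <- NULL
  attr(out, "truth") <- sets
  attr(out, "config") <- cfg
  out
}
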