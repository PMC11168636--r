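# MHC-dependent mate-choice analysis: pair-compatibility metrics, Monte
# Carlo re-pairing randomization, Bonferroni control, sample-size
# sensitivity.

MC_METRICS <- c("het_diff_abs", "het_diff_signed", "band_sharing",
                "aa_sum", "aa_max")

#' MHC heterozygosity proxy of a genotype
#'
#' With locus assignment unresolved, the observable heterozygosity of a
#' duplicated-locus amplicon genotype is its number of distinct alleles
#' (1..4 under a two-locus design).
#'
#' @param alleles character vector of allele ids (one individual's set).
#' @return integer count of distinct alleles.
#' @export
heterozygosity <- function(alleles) {
  stopifnot(length(alleles) >= 1L)
  length(unique(alleles))
}

#' Band-sharing coefficient of a breeding pair
#'
#' `2 * Fab / (Fa + Fb)`: twice the number of shared alleles divided by the
#' summed distinct-allele counts of the two mates. 1 for identical sets, 0
#' for disjoint sets.
#'
#' @param a,b character vectors of allele ids (distinct-allele sets of the
#'   two mates).
#' @return value in `[0, 1]`.
#' @export
band_sharing <- function(a, b) {
  a <- unique(a); b <- unique(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Amino-acid difference matrix of an allele pool
#'
#' Pairwise counts of differing amino-acid positions between the pool's
#' translated alleles, over the whole fragment (all complete codons) or the
#' PBR codon subset.
#'
#' @param pool an [allele_pool][generate_allele_pool].
#' @param region `"whole"` or `"pbr"`.
#' @param partition optional [codon_partition()] overriding the pool's own
#'   PBR mask.
#' @return symmetric numeric matrix with allele-id dimnames.
#' @export
aa_diff_matrix <- function(pool, region = c("whole", "pbr"), partition = NULL) {
  region <- match.arg(region)
  stopifnot(inherits(pool, "allele_pool"))
  aa <- translate_nt(pool$sequences, pool$frame_offset)
  mat <- do.call(rbind, strsplit(aa, "", fixed = TRUE))
  rownames(mat) <- names(pool$sequences)
  if (region == "pbr") {
    pbr <- if (!is.null(partition)) partition$pbr else pool$pbr_codons
    if (length(pbr) == 0L) stop("empty PBR mask")
    mat <- mat[, pbr + 1L, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  d
}

#' Amino-acid dissimilarity of a breeding pair
#'
#' Considers every cross-mate allele combination (each of the male's alleles
#' against each of the female's; identical alleles contribute 0, reflecting
#' the all-combinations convention forced by unresolved duplicated loci).
#' `mode = "sum"` totals the amino-acid differences over all combinations;
#' `mode = "max"` returns the largest single-combination difference.
#'
#' @param a,b allele-id sets of the two mates.
#' @inheritParams aa_diff_matrix
#' @param mode `"sum"` or `"max"`.
#' @param aa_mat precomputed [aa_diff_matrix()] (overrides `pool`/`region`).
#' @return non-negative count of amino-acid substitutions.
#' @export
aa_dissimilarity <- function(a, b, pool = NULL, region = c("whole", "pbr"),
                             mode = c("sum", "max"), partition = NULL,
                             aa_mat = NULL) {
  mode <- match.arg(mode)
  if (is.null(aa_mat)) aa_mat <- aa_diff_matrix(pool, region, partition)
  a <- unique(a); b <- unique(b)
  missing <- setdiff(c(a, b), rownames(aa_mat))
  if (length(missing))
    stop("allele(s) absent from pool: ", paste(missing, collapse = ", "))
  sub <- aa_mat[a, b, drop = FALSE]
  if (mode == "sum") sum(sub) else max(sub)
}

# metric closures over allele-id sets; aa metrics capture a precomputed
# difference matrix
metric_fun <- function(metric, pool = NULL, region = "whole", partition = NULL,
                       aa_mat = NULL) {
  if (!metric %in% MC_METRICS) stop("unknown metric: ", metric)
  switch(metric,
    het_diff_abs = function(a, b) abs(heterozygosity(a) - heterozygosity(b)),
    het_diff_signed = function(a, b) heterozygosity(a) - heterozygosity(b),
    band_sharing = band_sharing,
    {
      if (is.null(aa_mat)) {
        if (is.null(pool)) stop("amino-acid metrics require an allele pool")
        aa_mat <- aa_diff_matrix(pool, region, partition)
      }
      mode <- if (metric == "aa_sum") "sum" else "max"
      function(a, b) aa_dissimilarity(a, b, mode = mode, aa_mat = aa_mat)
    })
}

# n x n matrix of metric values for (male i, female j); incidence-matrix
# algebra for the closed-form metrics, elementwise evaluation for aa_max
pair_metric_matrix <- function(pairs, genotypes, metric, pool = NULL,
                               region = "whole", partition = NULL,
                               aa_mat = NULL) {
  sets <- allele_sets(genotypes)
  miss <- setdiff(c(pairs$male_id, pairs$female_id), names(sets))
  if (length(miss))
    stop("pair member(s) missing from genotype table: ",
         paste(miss, collapse = ", "))
  n <- nrow(pairs)
  msets <- sets[pairs$male_id]
  fsets <- sets[pairs$female_id]
  if (metric %in% c("het_diff_abs", "het_diff_signed")) {
    hm <- vapply(msets, function(s) length(unique(s)), numeric(1))
    hf <- vapply(fsets, function(s) length(unique(s)), numeric(1))
    M <- outer(hm, hf, "-")
    if (metric == "het_diff_abs") M <- abs(M)
    dimnames(M) <- NULL
    return(M)
  }
  if (metric %in% c("aa_sum", "aa_max") && is.null(aa_mat)) {
    if (is.null(pool)) stop("amino-acid metrics require an allele pool")
    aa_mat <- aa_diff_matrix(pool, region, partition)
  }
  universe <- if (is.null(aa_mat)) sort(unique(unlist(c(msets, fsets))))
              else rownames(aa_mat)
  incidence <- function(ss) {
    unknown <- setdiff(unique(unlist(ss)), universe)
    if (length(unknown))
      stop("allele(s) absent from pool: ", paste(unknown, collapse = ", "))
    m <- matrix(0, length(ss), length(universe))
    for (i in seq_along(ss)) m[i, match(unique(ss[[i]]), universe)] <- 1
    m
  }
  Im <- incidence(msets); If <- incidence(fsets)
  M <- switch(metric,
    band_sharing = {
      shared <- Im %*% t(If)
      2 * shared / outer(rowSums(Im), rowSums(If), "+")
    },
    aa_sum = Im %*% aa_mat[universe, universe] %*% t(If),
    aa_max = {
      D <- aa_mat[universe, universe]
      out <- matrix(0, n, n)
      idx_m <- lapply(seq_len(n), function(i) which(Im[i, ] > 0))
      idx_f <- lapply(seq_len(n), function(j) which(If[j, ] > 0))
      for (i in seq_len(n)) for (j in seq_len(n))
        out[i, j] <- max(D[idx_m[[i]], idx_f[[j]]])
      out
    },
    stop("unknown metric: ", metric))
  dimnames(M) <- NULL
  M
}

#' Monte Carlo re-pairing randomization test
#'
#' Compares the observed mean of a pair metric over the real breeding pairs
#' with its null distribution under random re-pairing: each of `B`
#' iterations permutes the female list against the fixed male list (a
#' uniform random perfect matching, resampling without replacement) and
#' records the mean metric. The two-sided empirical p-value uses the
#' add-one correction `p = 2 * min(r_low, r_high) / (B + 1)` with
#' `r_low = 1 + #\{null <= observed\}`, `r_high = 1 + #\{null >= observed\}`,
#' capped at 1 (ties count as extreme, p is never 0). The 2.5% and 97.5%
#' empirical percentiles of the null means are reported.
#'
#' @param pairs `data.frame` with `male_id`, `female_id` (>= 3 rows; only
#'   complete pairs enter the test).
#' @param genotypes genotype table covering all pair members.
#' @param metric one of `"het_diff_abs"`, `"het_diff_signed"`,
#'   `"band_sharing"`, `"aa_sum"`, `"aa_max"`.
#' @param pool allele pool (required by the amino-acid metrics).
#' @param region `"whole"` or `"pbr"` (amino-acid metrics only).
#' @param partition optional [codon_partition()] PBR mask override.
#' @param B number of re-pairing iterations (default 10000, >= 99).
#' @param seed integer seed; results are fully reproducible.
#' @return object of class `randomization_result`: `metric`, `region`,
#'   `observed_mean`, `null_means` (length `B`), `p_two_sided`,
#'   `lower_tail_2_5`, `upper_tail_97_5`, `B`, `seed`, `n_pairs`.
#' @export
randomization_test <- function(pairs, genotypes, metric, pool = NULL,
                               region = "whole", partition = NULL,
                               B = 10000L, seed = NULL) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 3L, is_count(B, 99L))
  M <- pair_metric_matrix(pairs, genotypes, metric, pool, region, partition)
  n <- nrow(pairs)
  observed <- mean(M[cbind(seq_len(n), seq_len(n))])
  seed_rng(seed)
  perms <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  null_means <- colMeans(matrix(M[cbind(rep(seq_len(n), B), as.vector(perms))],
                                n, B))
  r_low <- 1L + sum(null_means <= observed)
  r_high <- 1L + sum(null_means >= observed)
  p <- min(1, 2 * min(r_low, r_high) / (B + 1))
  tails <- unname(quantile(null_means, c(0.025, 0.975)))
  structure(list(metric = metric, region = region, observed_mean = observed,
                 null_means = null_means, p_two_sided = p,
                 lower_tail_2_5 = tails[1], upper_tail_97_5 = tails[2],
                 B = as.integer(B), seed = seed, n_pairs = n),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization test: %s [%s], %d pairs, B = %d\n  observed mean = %.4f  null 2.5%%/97.5%% = [%.4f, %.4f]\n  two-sided p = %.4g\n",
    x$metric, x$region, x$n_pairs, x$B, x$observed_mean,
    x$lower_tail_2_5, x$upper_tail_97_5, x$p_two_sided))
  invisible(x)
}

#' The six canonical mate-choice randomization tests
#'
#' Runs absolute heterozygosity difference, band-sharing, and the additive
#' and maximum amino-acid dissimilarities in both the whole-fragment and PBR
#' contexts (six tests), with the family-wise Bonferroni alpha `0.05 / 6`.
#' Direction labels: an observed mean above the 97.5% tail indicates
#' assortative mating for band-sharing (mates more similar than random) and
#' disassortative mating for the dissimilarity metrics; below the 2.5% tail,
#' the reverse.
#'
#' @inheritParams randomization_test
#' @param partition optional PBR mask override.
#' @param alpha family-wise error rate before correction (default 0.05).
#' @return object of class `matechoice_results`: list with `table` (one row
#'   per test: metric, region, observed mean, tails, p, verdict,
#'   significance before/after Bonferroni), `results` (the six
#'   [randomization_test()] objects), `alpha_adjusted`.
#' @export
run_all_tests <- function(pairs, genotypes, pool, partition = NULL,
                          B = 10000L, seed = 1L, alpha = 0.05) {
  specs <- list(
    list(metric = "het_diff_abs", region = "whole"),
    list(metric = "band_sharing", region = "whole"),
    list(metric = "aa_sum", region = "whole"),
    list(metric = "aa_sum", region = "pbr"),
    list(metric = "aa_max", region = "whole"),
    list(metric = "aa_max", region = "pbr"))
  alpha_adj <- alpha / length(specs)
  results <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    results[[i]] <- randomization_test(pairs, genotypes, s$metric, pool,
                                       region = s$region, partition = partition,
                                       B = B, seed = seed + i)
  }
  verdict_of <- function(r) {
    high_is_assortative <- r$metric == "band_sharing"
    if (r$observed_mean > r$upper_tail_97_5)
      if (high_is_assortative) "assortative" else "disassortative"
    else if (r$observed_mean < r$lower_tail_2_5)
      if (high_is_assortative) "disassortative" else "assortative"
    else "random"
  }
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(metric = r$metric, region = r$region,
               observed_mean = r$observed_mean,
               lower_2_5 = r$lower_tail_2_5, upper_97_5 = r$upper_tail_97_5,
               p = r$p_two_sided, verdict = verdict_of(r),
               significant_raw = r$p_two_sided < alpha,
               significant_bonferroni = r$p_two_sided < alpha_adj,
               stringsAsFactors = FALSE)))
  structure(list(table = tab, results = results, alpha = alpha,
                 alpha_adjusted = alpha_adj, B = as.integer(B), seed = seed),
            class = "matechoice_results")
}

#' @export
print.matechoice_results <- function(x, ...) {
  cat(sprintf("mate-choice randomization tests (B = %d, Bonferroni alpha = %.4f)\n",
              x$B, x$alpha_adjusted))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Sample-size sensitivity of a randomization verdict
#'
#' For each candidate sample size, repeatedly subsamples that many pairs
#' without replacement, reruns the randomization test, and reports the
#' proportion of subsamples whose significance verdict (two-sided p below
#' `alpha`) agrees with the full-data verdict.
#'
#' @inheritParams randomization_test
#' @param n_grid vector of subsample sizes (each <= number of pairs, >= 3).
#' @param reps_per_n subsamples per size.
#' @param alpha significance level defining the verdict (raw, default 0.05).
#' @return `data.frame` with `n`, `concordance`; attribute
#'   `"full_significant"`.
#' @export
sensitivity_curve <- function(pairs, genotypes, metric, pool = NULL,
                              region = "whole", partition = NULL,
                              n_grid = NULL, reps_per_n = 20L, B = 999L,
                              seed = 1L, alpha = 0.05) {
  n <- nrow(pairs)
  if (is.null(n_grid)) n_grid <- unique(pmax(3L, round(n * c(1, 0.75, 0.5))))
  stopifnot(all(n_grid <= n), all(n_grid >= 3L), is_count(reps_per_n))
  full <- randomization_test(pairs, genotypes, metric, pool, region,
                             partition, B = B, seed = seed)
  full_sig <- full$p_two_sided < alpha
  seed_rng(seed)
  sub_seeds <- sample.int(2^31 - 1L, length(n_grid) * reps_per_n)
  k <- 0L
  conc <- vapply(n_grid, function(np) {
    hits <- vapply(seq_len(reps_per_n), function(r) {
      k <<- k + 1L
      if (np == n) return(TRUE)  # the only size-n subsample is the data itself
      sub <- pairs[sample.int(n, np), , drop = FALSE]
      rt <- randomization_test(sub, genotypes, metric, pool, region,
                               partition, B = B, seed = sub_seeds[k])
      (rt$p_two_sided < alpha) == full_sig
    }, logical(1))
    mean(hits)
  }, numeric(1))
  out <- data.frame(n = n_grid, concordance = conc)
  attr(out, "full_significant") <- full_sig
  out
}
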