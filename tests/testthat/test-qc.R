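# Allele-calling QC filters, replicate combination, genotype calling.

rec <- function(ind = "i1", run = "run1", seq, depth, q = 35) {
  data.frame(individual_id = ind, run_id = run, sequence = seq,
             depth = depth, mean_quality = q, stringsAsFactors = FALSE)
}

seq_of <- function(L, base = "A") strrep(base, L)

test_that("clean_variants enforces strict Phred and exact length", {
  cfg <- qc_config(expected_length_nt = 298)
  s <- seq_of(298)
  records <- rbind(rec(seq = s, depth = 10, q = 29.9),
                   rec(seq = s, depth = 10, q = 30.0),
                   rec(seq = seq_of(297), depth = 10),
                   rec(seq = seq_of(299), depth = 10))
  out <- clean_variants(records, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_quality, 30.0)
  expect_equal(unname(attr(out, "dropped")), c(1, 2))
  empty <- clean_variants(records[0, ], cfg)
  expect_equal(nrow(empty), 0)
})

test_that("consolidate_errors merges within the stated error budgets", {
  cfg <- qc_config(expected_length_nt = 298)
  L <- 298
  parent <- paste(rep("A", L), collapse = "")
  one_sub <- paste0("C", substr(parent, 2, L))
  two_sub <- paste0("CC", substr(parent, 3, L))
  records <- rbind(rec(seq = parent, depth = 1000),
                   rec(seq = one_sub, depth = 100),
                   rec(seq = two_sub, depth = 50))
  out <- consolidate_errors(records, cfg)
  # budget: max(1, floor(0.005*298)) = 1 substitution
  expect_equal(sort(out$sequence), sort(c(parent, two_sub)))
  expect_equal(out$depth[out$sequence == parent], 1100)
  expect_equal(sum(out$depth), sum(records$depth))  # conservation
})

test_that("consolidation handles indel variants through alignment", {
  cfg <- qc_config(expected_length_nt = 30, indel_error_rate = 0.05)
  base <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  del1 <- paste0(substr(base, 1, 10), substr(base, 12, 30))  # 1-nt deletion
  records <- rbind(rec(seq = base, depth = 500),
                   rec(seq = del1, depth = 20))
  out <- consolidate_errors(records, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$depth, 520)
})

test_that("consolidation is iterated from most- to least-abundant parent", {
  cfg <- qc_config(expected_length_nt = 10)
  a <- "AAAAAAAAAA"
  b <- "CAAAAAAAAA"  # 1 sub from a
  c_ <- "CCAAAAAAAA" # 1 sub from b, 2 from a
  records <- rbind(rec(seq = a, depth = 100),
                   rec(seq = b, depth = 60),
                   rec(seq = c_, depth = 10))
  out <- consolidate_errors(records, cfg)
  # b merges into a first; c then merges into the grown a? no: c is 2 subs
  # from a, so it merges into b only if b survives -- b was absorbed, so c
  # must survive as its own variant
  expect_setequal(out$sequence, c(a, c_))
  expect_equal(sum(out$depth), 170)
})

test_that("flag_chimeras removes abundant-parent splices only", {
  cfg <- qc_config(chimera_freq_threshold = 0.05)
  L <- 40
  p1 <- strrep("A", L)
  p2 <- strrep("C", L)
  chim <- paste0(strrep("A", 15), strrep("C", L - 15))
  records <- rbind(rec(seq = p1, depth = 400),
                   rec(seq = p2, depth = 400),
                   rec(seq = chim, depth = 100))
  out <- flag_chimeras(records, cfg)
  expect_setequal(out$sequence, c(p1, p2))
  expect_equal(attr(out, "n_chimeric"), 1)

  # a non-splice variant is retained
  other <- paste0(strrep("G", 20), strrep("T", 20))
  out2 <- flag_chimeras(rbind(records[1:2, ], rec(seq = other, depth = 100)), cfg)
  expect_true(other %in% out2$sequence)

  # parents below the 5% frequency floor do not convict their splice
  deep <- rec(seq = strrep("G", L), depth = 10000)
  low <- rbind(deep,
               rec(seq = p1, depth = 300), rec(seq = p2, depth = 300),
               rec(seq = chim, depth = 150))
  # p1,p2 at ~2.8% < 5%: chimera retained
  out3 <- flag_chimeras(low, cfg)
  expect_true(chim %in% out3$sequence)
})

test_that("combine_runs sums depths and tracks run presence", {
  cfg <- qc_config()
  s1 <- seq_of(298); s2 <- seq_of(298, "C")
  records <- rbind(rec(run = "run1", seq = s1, depth = 120),
                   rec(run = "run2", seq = s1, depth = 150),
                   rec(run = "run1", seq = s2, depth = 80))
  out <- combine_runs(records, cfg)
  expect_equal(sum(out$depth), sum(records$depth))
  r1 <- out[out$sequence == s1, ]
  expect_equal(r1$depth, 270)
  expect_equal(r1$n_runs_present, 2)
  expect_equal(r1$runs, "run1,run2")
  r2 <- out[out$sequence == s2, ]
  expect_equal(r2$n_runs_present, 1)
  expect_equal(unique(out$individual_runs), 2)
})

make_stop_free <- function(L, seed) {
  set.seed(seed)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    aa <- Biostrings::GENETIC_CODE[substring(s, seq(1, L - 2, 3), seq(3, L, 3))]
    if (!any(aa == "*", na.rm = TRUE)) return(s)
  }
}

test_that("call_genotype applies inclusive depth and frequency thresholds", {
  cfg <- qc_config(expected_length_nt = 30, min_singleton_reads = 200)
  s1 <- make_stop_free(30, 1); s2 <- make_stop_free(30, 2)
  single <- function(d1, d2) data.frame(
    individual_id = "i1", sequence = c(s1, s2), depth = c(d1, d2),
    mean_quality = 35, runs = "run1", n_runs_present = 1L,
    individual_runs = 1L, stringsAsFactors = FALSE)
  # single-run rule: 199 dropped, 200 kept (inclusive)
  g <- call_genotype(single(5000, 199), cfg)
  expect_true(g$called); expect_length(g$sequences, 1)
  g <- call_genotype(single(5000, 200), cfg)
  expect_length(g$sequences, 2)

  # frequency rule at exactly 0.9% vs 1.0% for a two-run individual
  both <- function(d2) data.frame(
    individual_id = "i1", sequence = c(s1, s2), depth = c(10000 - d2, d2),
    mean_quality = 35, runs = "run1,run2", n_runs_present = 2L,
    individual_runs = 2L, stringsAsFactors = FALSE)
  expect_length(call_genotype(both(90), cfg)$sequences, 1)   # 0.9%
  expect_length(call_genotype(both(100), cfg)$sequences, 2)  # 1.0%
})

test_that("two-run individuals need both-runs presence or the depth rescue", {
  cfg <- qc_config(expected_length_nt = 30)
  s1 <- make_stop_free(30, 1); s2 <- make_stop_free(30, 2)
  s3 <- make_stop_free(30, 3)
  comb <- data.frame(
    individual_id = "i1", sequence = c(s1, s2, s3),
    depth = c(5000, 199, 400), mean_quality = 35,
    runs = c("run1,run2", "run1", "run2"),
    n_runs_present = c(2L, 1L, 1L), individual_runs = 2L,
    stringsAsFactors = FALSE)
  g <- call_genotype(comb, cfg)
  # s2: single-run, 199 < 200, dropped; s3: single-run but depth 400 rescued
  expect_setequal(g$sequences, c(s1, s3))
})

test_that("stop-codon variants are excluded and the allele cap is depth-ranked", {
  cfg <- qc_config(expected_length_nt = 30, max_alleles_per_individual = 4)
  good <- vapply(1:5, function(i) make_stop_free(30, i), character(1))
  stopv <- paste0("TAA", substr(good[1], 4, 30))
  comb <- data.frame(
    individual_id = "i1", sequence = c(good, stopv),
    depth = c(900, 800, 700, 600, 500, 950), mean_quality = 35,
    runs = "run1,run2", n_runs_present = 2L, individual_runs = 2L,
    stringsAsFactors = FALSE)
  g <- call_genotype(comb, cfg)
  expect_length(g$sequences, 4)
  expect_false(stopv %in% g$sequences)
  expect_setequal(g$sequences, good[1:4])  # deepest four of the five valid
})

test_that("rejection is a typed outcome", {
  cfg <- qc_config(expected_length_nt = 30)
  bad <- data.frame(individual_id = "i1", sequence = strrep("A", 12),
                    depth = 5, mean_quality = 35, runs = "run1",
                    n_runs_present = 1L, individual_runs = 1L,
                    stringsAsFactors = FALSE)
  g <- call_genotype(bad, cfg)
  expect_false(g$called)
  expect_match(g$reason, "no variant")
})

test_that("raising min_amplicon_freq never increases called alleles", {
  pool <- generate_allele_pool(15, 60, seed = 21)
  g <- assign_genotypes(pool, 10, seed = 22)
  reads <- simulate_reads(g, pool, read_sim_config(
    depth_mean = 150, substitution_error_rate = 0.003,
    indel_error_rate = 0.003, chimera_fraction = 0.05, n_runs = 2, seed = 23))
  base_cfg <- function(f) qc_config(expected_length_nt = 60,
                                    min_amplicon_freq = f,
                                    min_singleton_reads = 50)
  counts <- vapply(c(0.01, 0.05, 0.10, 0.20), function(f) {
    res <- qc_pipeline(reads, base_cfg(f), pool = pool)
    sum(res$genotypes$n_alleles)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calling is idempotent on already-called genotypes", {
  cfg <- qc_config(expected_length_nt = 30)
  s <- vapply(1:3, function(i) make_stop_free(30, i), character(1))
  comb <- data.frame(
    individual_id = "i1", sequence = s, depth = c(4000, 3000, 2000),
    mean_quality = 35, runs = "run1,run2", n_runs_present = 2L,
    individual_runs = 2L, stringsAsFactors = FALSE)
  g1 <- call_genotype(comb, cfg)
  again <- comb[comb$sequence %in% g1$sequences, ]
  g2 <- call_genotype(again, cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$depths, g2$depths)
})

test_that("genotype_summary equals a brute-force tally", {
  pool <- generate_allele_pool(25, 60, seed = 31)
  g <- assign_genotypes(pool, 60, seed = 32)
  sm <- genotype_summary(g)
  sets <- allele_sets(g)
  # distribution of allele counts
  tab <- table(lengths(sets))
  for (k in names(tab))
    expect_equal(sm$allele_number_distribution$n_individuals[
      sm$allele_number_distribution$n_alleles == as.integer(k)],
      unname(as.integer(tab[k])))
  # per-population distinct counts
  for (p in unique(g$population_id)) {
    mine <- unique(unlist(sets[g$individual_id[g$population_id == p]]))
    expect_equal(sm$population_alleles$n_alleles[
      sm$population_alleles$population_id == p], length(mine))
  }
  # carrier counts
  for (al in sm$allele_frequencies$allele_id) {
    expect_equal(sm$allele_frequencies$n_carriers[
      sm$allele_frequencies$allele_id == al],
      sum(vapply(sets, function(s) al %in% s, logical(1))))
  }
  # a single population has 100% unique alleles
  g1 <- g; g1$population_id <- "only"
  sm1 <- genotype_summary(g1)
  expect_equal(sm1$population_alleles$pct_unique, 100)
})
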