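# Modified Nei-Gojobori site counts, pairwise dN/dS, codon-bootstrap Z-test.

test_that("site counts normalize to 3 for all sense codons and several R", {
  for (R in c(0.5, 2, 10)) {
    for (cod in sense_codons()) {
      ns <- ng_site_counts(cod, R)
      expect_equal(unname(ns[["N"]] + ns[["S"]]), 3, tolerance = 1e-12)
      expect_gte(ns[["S"]], 0)
    }
  }
  expect_error(ng_site_counts("TAA"), "stop codon")
})

test_that("TTT at R = 0.5 reproduces the unmodified equal-weight counts", {
  ns <- ng_site_counts("TTT", R = 0.5)
  # positions 1 and 2 fully nonsynonymous; position 3: only TTC synonymous
  expect_equal(unname(ns[["S"]]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(ns[["N"]]), 8 / 3, tolerance = 1e-12)
})

test_that("ATG has no synonymous sites beyond stop-exclusion renormalization", {
  for (R in c(0.5, 2, 10)) {
    ns <- ng_site_counts("ATG", R)
    expect_equal(unname(ns[["S"]]), 0, tolerance = 1e-12)
  }
})

test_that("modified weighting responds to R where transitions are synonymous", {
  # GGG position 3: all three mutants synonymous regardless of weights
  expect_equal(unname(ng_site_counts("GGG", 10)[["S"]]), 1)
  # TTT position 3: transition TTC synonymous, so S grows with R
  s_by_R <- vapply(c(0.5, 2, 10), function(R)
    unname(ng_site_counts("TTT", R)[["S"]]), numeric(1))
  expect_true(all(diff(s_by_R) > 0))
})

test_that("identical sequences give dN = dS = 0", {
  r <- ng_pairwise("ATGGCT", "ATGGCT")
  expect_equal(r$whole$dN, 0)
  expect_equal(r$whole$dS, 0)
})

test_that("a single synonymous third-position change is counted exactly", {
  # 10 codons of GGA vs 9xGGA + GGG (Gly->Gly, synonymous)
  a <- strrep("GGA", 10)
  b <- paste0(strrep("GGA", 9), "GGG")
  r <- ng_pairwise(a, b, R = 0.5)
  S_per_codon <- unname(ng_site_counts("GGA", 0.5)[["S"]])
  S_last <- (unname(ng_site_counts("GGA", 0.5)[["S"]]) +
             unname(ng_site_counts("GGG", 0.5)[["S"]])) / 2
  S_total <- 9 * S_per_codon + S_last
  pS <- 1 / S_total
  expect_equal(r$whole$pN, 0)
  expect_equal(r$whole$pS, pS)
  expect_equal(r$whole$dS, -0.75 * log(1 - 4 * pS / 3))
  expect_equal(r$whole$dN, 0)
})

test_that("two-substitution codon pairs match the path-enumeration oracle", {
  cods <- sense_codons()
  checked <- 0L
  for (c1 in cods) {
    a <- strsplit(c1, "")[[1]]
    for (c2 in cods) {
      if (sum(a != strsplit(c2, "")[[1]]) != 2L) next
      got <- aukmhc:::codon_pair_diffs(c1, c2)
      want <- oracle_codon_path_counts(c1, c2)
      expect_equal(unname(got[["nd"]]), unname(want[["nd"]]), tolerance = 1e-12)
      expect_equal(unname(got[["sd"]]), unname(want[["sd"]]), tolerance = 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 1000)
})

test_that("dN/dS is symmetric and invariant to codon reordering", {
  set.seed(17)
  pool <- generate_allele_pool(6, 30, seed = 17)
  s <- unname(pool$sequences)
  r1 <- ng_pairwise(s[1], s[2])
  r2 <- ng_pairwise(s[2], s[1])
  expect_equal(r1$whole$dN, r2$whole$dN)
  expect_equal(r1$whole$dS, r2$whole$dS)

  # reorder codons consistently in both sequences
  perm <- sample(10)
  reorder <- function(x) paste(split_seq <- substring(x, 3 * perm - 2, 3 * perm),
                               collapse = "")
  r3 <- ng_pairwise(reorder(s[1]), reorder(s[2]))
  expect_equal(r1$whole$dN, r3$whole$dN)
  expect_equal(r1$whole$dS, r3$whole$dS)
})

test_that("saturation is reported as NA, not a number", {
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.9)))
  expect_equal(jc_correct(0), 0)
})

test_that("partition totals: region site counts sum to 3 x codon count", {
  pool <- generate_allele_pool(4, 60, seed = 23)
  part <- pool_partition(pool)
  s <- unname(pool$sequences)
  r <- ng_pairwise(s[1], s[2], partition = part)
  expect_equal(r$pbr$N_sites + r$pbr$S_sites +
               r$non_pbr$N_sites + r$non_pbr$S_sites,
               3 * pool$n_codons, tolerance = 1e-9)
  expect_equal(r$whole$Nd + r$whole$Sd, r$pbr$Nd + r$pbr$Sd +
               r$non_pbr$Nd + r$non_pbr$Sd, tolerance = 1e-9)
})

simulate_divergence <- function(n_seq, n_codons, synonymous, seed,
                                n_subs = 2L) {
  # start from one random sense codon string; derive sequences by applying
  # third-position synonymous changes (4-fold degenerate codons) or
  # first-position nonsynonymous changes
  set.seed(seed)
  four_fold <- c("GC", "GG", "CC", "CT", "TC", "AC", "GT", "CG")
  codons <- paste0(sample(four_fold, n_codons, replace = TRUE),
                   sample(c("A", "C", "G", "T"), n_codons, replace = TRUE))
  vapply(seq_len(n_seq), function(i) {
    cs <- codons
    idx <- sample(n_codons, min(n_subs, n_codons))
    for (j in idx) {
      if (synonymous) {
        substr(cs[j], 3, 3) <- sample(setdiff(c("A","C","G","T"),
                                              substr(cs[j], 3, 3)), 1)
      } else {
        repeat {
          cand <- cs[j]
          substr(cand, 1, 1) <- sample(setdiff(c("A","C","G","T"),
                                               substr(cs[j], 1, 1)), 1)
          aa0 <- Biostrings::GENETIC_CODE[[cs[j]]]
          aa1 <- Biostrings::GENETIC_CODE[cand]
          if (!is.na(aa1) && aa1 != "*" && aa1 != aa0) { cs[j] <- cand; break }
        }
      }
    }
    paste(cs, collapse = "")
  }, character(1))
}

test_that("purely synonymous divergence drives Z below zero", {
  seqs <- simulate_divergence(6, 20, synonymous = TRUE, seed = 3)
  part <- codon_partition(0:6, 20)
  z <- z_test_positive_selection(seqs, part, region = "whole", R = 0.5,
                                 n_bootstrap = 300, seed = 4)
  expect_equal(z$dN, 0)
  expect_lt(z$Z, 0)
  expect_gt(z$p_one_tailed, 0.5)
})

test_that("PBR-restricted nonsynonymous divergence is recovered", {
  set.seed(51)
  n_codons <- 30
  pbr <- 0:9
  # nonsynonymous changes only inside PBR codons, synonymous noise outside
  four_fold <- c("GCA", "GGT", "CCC", "CTG", "TCA", "ACT", "GTC", "CGG")
  codons <- sample(four_fold, n_codons, replace = TRUE)
  seqs <- vapply(1:8, function(i) {
    cs <- codons
    for (j in sample(pbr + 1, 4)) {  # aggressive aa changes in PBR
      repeat {
        cand <- cs[j]
        substr(cand, 1, 1) <- sample(c("A","C","G","T"), 1)
        aa1 <- Biostrings::GENETIC_CODE[cand]
        if (!is.na(aa1) && aa1 != "*" &&
            aa1 != Biostrings::GENETIC_CODE[[cs[j]]]) { cs[j] <- cand; break }
      }
    }
    for (j in sample(setdiff(seq_len(n_codons), pbr + 1), 2)) {
      substr(cs[j], 3, 3) <- sample(setdiff(c("A","C","G","T"),
                                            substr(cs[j], 3, 3)), 1)
    }
    paste(cs, collapse = "")
  }, character(1))
  part <- codon_partition(pbr, n_codons)
  z_pbr <- z_test_positive_selection(seqs, part, "pbr", R = 0.5,
                                     n_bootstrap = 300, seed = 5)
  z_non <- z_test_positive_selection(seqs, part, "non_pbr", R = 0.5,
                                     n_bootstrap = 300, seed = 6)
  expect_gt(z_pbr$Z, 0)
  expect_lt(z_pbr$p_one_tailed, 0.05)
  expect_true(is.na(z_non$Z) || z_non$Z <= 0 || z_non$p_one_tailed > 0.05)
})

test_that("bootstrap p is seed-reproducible and stable in B", {
  pool <- generate_allele_pool(8, 60, seed = 61)
  part <- pool_partition(pool)
  z1 <- z_test_positive_selection(pool$sequences, part, "whole",
                                  n_bootstrap = 400, seed = 7)
  z2 <- z_test_positive_selection(pool$sequences, part, "whole",
                                  n_bootstrap = 400, seed = 7)
  expect_identical(z1$Z, z2$Z)
  expect_identical(z1$p_one_tailed, z2$p_one_tailed)
  z4 <- z_test_positive_selection(pool$sequences, part, "whole",
                                  n_bootstrap = 800, seed = 8)
  expect_lt(abs(z4$p_one_tailed - z1$p_one_tailed), 0.01)
})

test_that("regions with fewer than 3 codons are rejected", {
  part <- codon_partition(0:1, 10)
  pool <- generate_allele_pool(4, 30, seed = 71)
  expect_error(z_test_positive_selection(pool$sequences, part, "pbr"),
               ">= 3 codons")
})
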