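# Modified Nei-Gojobori dN/dS with Jukes-Cantor correction and a
# codon-bootstrap Z-test of positive selection on PBR / non-PBR partitions.

#' Codon partition into PBR and non-PBR subsets
#'
#' @param pbr_codons 0-based codon indices of the putative peptide-binding
#'   region; must lie in `[0, total_codons)`.
#' @param total_codons number of complete codons in the fragment.
#' @param frame_offset reading-frame offset in \{0,1,2\}.
#' @return object of class `codon_partition` with `pbr`, `non_pbr`,
#'   `total_codons`, `frame_offset`.
#' @export
codon_partition <- function(pbr_codons, total_codons, frame_offset = 0L) {
  pbr_codons <- sort(unique(as.integer(pbr_codons)))
  stopifnot(is_count(total_codons), frame_offset %in% 0:2)
  if (length(pbr_codons) && (min(pbr_codons) < 0L || max(pbr_codons) >= total_codons))
    stop("pbr_codons out of range [0, total_codons)")
  structure(list(pbr = pbr_codons,
                 non_pbr = setdiff(seq_len(total_codons) - 1L, pbr_codons),
                 total_codons = as.integer(total_codons),
                 frame_offset = as.integer(frame_offset)),
            class = "codon_partition")
}

#' Partition implied by an allele pool's PBR mask
#' @param pool an [allele_pool][generate_allele_pool].
#' @export
pool_partition <- function(pool) {
  stopifnot(inherits(pool, "allele_pool"))
  codon_partition(pool$pbr_codons, pool$n_codons, pool$frame_offset)
}

#' Potential nonsynonymous/synonymous site counts of a sense codon
#'
#' Each of the three positions contributes one site, split into synonymous
#' and nonsynonymous fractions by the weighted proportion of single-base
#' mutations that preserve the amino acid. Transitions (A<->G, C<->T) are
#' weighted `2R` relative to a weight of 1 per transversion path, so that
#' the expected transition/transversion ratio of the mutation process is
#' `R`; `R = 0.5` recovers the unmodified Nei-Gojobori equal weighting.
#' Mutations creating stop codons are excluded and the position's weights
#' renormalized.
#'
#' @param codon a 3-letter sense codon.
#' @param R transition/transversion ratio (> 0); default 2.
#' @return named numeric vector `c(N = ..., S = ...)` with `N + S = 3`.
#' @export
ng_site_counts <- function(codon, R = 2) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, R > 0)
  if (codon %in% STOP_CODONS) stop("stop codon has no site counts: ", codon)
  code <- Biostrings::GENETIC_CODE
  aa0 <- code[[codon]]
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  s_total <- 0
  for (pos in 1:3) {
    muts <- setdiff(DNA_BASES, chars[pos])
    w <- ifelse(muts == TRANSITION[[chars[pos]]], 2 * R, 1)
    mcod <- vapply(muts, function(b) {
      x <- chars; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    keep <- !(mcod %in% STOP_CODONS)
    if (!any(keep)) next  # position contributes wholly nonsynonymous
    syn <- keep & code[mcod] == aa0
    s_total <- s_total + sum(w[syn]) / sum(w[keep])
  }
  c(N = 3 - s_total, S = s_total)
}

# observed syn/nonsyn differences for one codon pair, averaged over shortest
# mutational paths; paths through stop codons are excluded (if all paths hit
# a stop, all paths are used). Results are memoized per codon pair.
codon_pair_cache <- new.env(parent = emptyenv())

codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(nd = 0, sd = 0))
  key <- paste(c1, c2, sep = "|")
  hit <- codon_pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(a != b)
  perms <- switch(as.character(length(dpos)),
                  "1" = list(dpos),
                  "2" = list(dpos, rev(dpos)),
                  "3" = {
                    p <- list()
                    for (i in 1:3) for (j in 1:3) for (k in 1:3)
                      if (length(unique(c(i, j, k))) == 3L)
                        p[[length(p) + 1L]] <- dpos[c(i, j, k)]
                    p
                  })
  path_counts <- lapply(perms, function(ord) {
    cur <- a; nd <- 0; sd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      cfrom <- paste(cur, collapse = ""); cto <- paste(nxt, collapse = "")
      if (cto %in% STOP_CODONS || cfrom %in% STOP_CODONS) ok <- FALSE
      if (!ok) break
      if (code[[cfrom]] == code[[cto]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(ok = ok, nd = nd, sd = sd)
  })
  valid <- Filter(function(p) p$ok, path_counts)
  if (length(valid) == 0L) {
    # all shortest paths pass through a stop; fall back to equal weighting of
    # every path, classifying each step by amino-acid change (stops counted
    # as nonsynonymous states)
    valid <- lapply(perms, function(ord) {
      cur <- a; nd <- 0; sd <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        same <- identical(code[[paste(cur, collapse = "")]],
                          code[[paste(nxt, collapse = "")]])
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(nd = nd, sd = sd)
    })
  }
  res <- c(nd = mean(vapply(valid, `[[`, numeric(1), "nd")),
           sd = mean(vapply(valid, `[[`, numeric(1), "sd")))
  codon_pair_cache[[key]] <- res
  res
}

#' Jukes-Cantor corrected distance from a proportion of differences
#'
#' Returns `NA` (saturated) when `p >= 3/4`.
#' @param p proportion in `[0, 1]`.
#' @export
jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# per-codon observed differences and potential sites for a sequence pair
pair_codon_tables <- function(codons_a, codons_b, R) {
  nc <- length(codons_a)
  nd <- sd <- ns <- ss <- numeric(nc)
  for (i in seq_len(nc)) {
    ca <- codons_a[i]; cb <- codons_b[i]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) {
      nd[i] <- sd[i] <- ns[i] <- ss[i] <- NA_real_
      next
    }
    if (ca %in% STOP_CODONS || cb %in% STOP_CODONS)
      stop("stop codon in coding sequence (codon ", i - 1L, ")")
    d <- codon_pair_diffs(ca, cb)
    sa <- ng_site_counts(ca, R); sb <- ng_site_counts(cb, R)
    nd[i] <- d[["nd"]]; sd[i] <- d[["sd"]]
    ns[i] <- (sa[["N"]] + sb[["N"]]) / 2
    ss[i] <- (sa[["S"]] + sb[["S"]]) / 2
  }
  list(nd = nd, sd = sd, ns = ns, ss = ss)
}

pool_dnds <- function(nd, sd, ns, ss) {
  ok <- !is.na(nd)
  Nd <- sum(nd[ok]); Sd <- sum(sd[ok])
  N <- sum(ns[ok]); S <- sum(ss[ok])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  list(pN = pN, pS = pS, dN = jc_correct(pN), dS = jc_correct(pS),
       Nd = Nd, Sd = Sd, N_sites = N, S_sites = S)
}

#' Pairwise modified Nei-Gojobori dN/dS between two coding sequences
#'
#' Counts observed synonymous/nonsynonymous differences per codon with equal
#' weighting over shortest mutational paths (paths through stop codons
#' excluded), divides by potential site counts averaged over the two
#' sequences ([ng_site_counts()]), and applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`; proportions `>= 3/4` are reported as `NA`
#' (saturated). With a [codon_partition()] the statistics are returned per
#' region (`pbr`, `non_pbr`) in addition to the whole fragment.
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @param partition optional [codon_partition()].
#' @param R transition/transversion ratio (default 2).
#' @param frame_offset used when `partition` is `NULL`.
#' @return list of regions, each with `pN`, `pS`, `dN`, `dS`, `Nd`, `Sd`,
#'   `N_sites`, `S_sites`.
#' @export
ng_pairwise <- function(seq_a, seq_b, partition = NULL, R = 2,
                        frame_offset = 0L) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be of equal length")
  off <- if (is.null(partition)) frame_offset else partition$frame_offset
  ca <- split_codons(toupper(seq_a), off)
  cb <- split_codons(toupper(seq_b), off)
  if (length(ca) < 1L) stop("no complete codon in frame")
  tab <- pair_codon_tables(ca, cb, R)
  regions <- list(whole = seq_along(ca) - 1L)
  if (!is.null(partition)) {
    if (partition$total_codons > length(ca))
      stop("partition has more codons than the sequences")
    regions$pbr <- partition$pbr
    regions$non_pbr <- partition$non_pbr
  }
  lapply(regions, function(idx) {
    i <- idx + 1L
    pool_dnds(tab$nd[i], tab$sd[i], tab$ns[i], tab$ss[i])
  })
}

#' Codon-bootstrap Z-test of positive selection (dN > dS)
#'
#' Averages pairwise modified Nei-Gojobori `dN` and `dS` over all unordered
#' sequence pairs restricted to the chosen codon subset, then estimates the
#' standard error of `dN - dS` by resampling codon columns with replacement
#' (`n_bootstrap` replicates, seeded). `Z = (dN - dS)/SE`; the one-tailed p
#' is the standard-normal upper tail.
#'
#' @param alignment character vector (or [allele_alignment()]) of
#'   equal-length coding sequences; duplicated sequences are collapsed.
#' @param partition a [codon_partition()].
#' @param region `"pbr"`, `"non_pbr"` or `"whole"`; the region must contain
#'   >= 3 codons.
#' @param R transition/transversion ratio.
#' @param n_bootstrap bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return object of class `dnds_result`: list with `dN`, `dS`, `omega`
#'   (`NA` when `dS = 0`), `Z`, `p_one_tailed`, `n_bootstrap`, `seed`,
#'   `region`, `n_codons`, `n_pairs`.
#' @export
z_test_positive_selection <- function(alignment, partition,
                                      region = c("pbr", "non_pbr", "whole"),
                                      R = 2, n_bootstrap = 1000L, seed = NULL) {
  region <- match.arg(region)
  stopifnot(inherits(partition, "codon_partition"), is_count(n_bootstrap, 100L))
  seqs <- if (inherits(alignment, "allele_alignment")) alignment$sequences
          else toupper(as.character(alignment))
  seqs <- unique(seqs)
  if (length(seqs) < 2L) stop("need >= 2 distinct sequences")
  idx0 <- switch(region, pbr = partition$pbr, non_pbr = partition$non_pbr,
                 whole = seq_len(partition$total_codons) - 1L)
  if (length(idx0) < 3L) stop("region must contain >= 3 codons")
  off <- partition$frame_offset

  codons <- lapply(seqs, split_codons, frame_offset = off)
  nseq <- length(seqs)
  pairs <- utils::combn(nseq, 2L)
  P <- ncol(pairs)
  C <- length(idx0)
  nd <- sd <- ns <- ss <- matrix(NA_real_, P, C)
  for (p in seq_len(P)) {
    ca <- codons[[pairs[1, p]]][idx0 + 1L]
    cb <- codons[[pairs[2, p]]][idx0 + 1L]
    tab <- pair_codon_tables(ca, cb, R)
    nd[p, ] <- tab$nd; sd[p, ] <- tab$sd; ns[p, ] <- tab$ns; ss[p, ] <- tab$ss
  }
  mean_dnds <- function(cols) {
    Nd <- rowSums(nd[, cols, drop = FALSE], na.rm = TRUE)
    Sd <- rowSums(sd[, cols, drop = FALSE], na.rm = TRUE)
    N <- rowSums(ns[, cols, drop = FALSE], na.rm = TRUE)
    S <- rowSums(ss[, cols, drop = FALSE], na.rm = TRUE)
    dN <- jc_correct(ifelse(N > 0, Nd / N, 0))
    dS <- jc_correct(ifelse(S > 0, Sd / S, 0))
    c(dN = mean(dN, na.rm = TRUE), dS = mean(dS, na.rm = TRUE))
  }
  obs <- mean_dnds(seq_len(C))
  seed_rng(seed)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    v <- mean_dnds(sample.int(C, C, replace = TRUE))
    v[["dN"]] - v[["dS"]]
  }, numeric(1))
  se <- stats::sd(boot, na.rm = TRUE)
  Z <- if (is.na(se) || se == 0) NA_real_ else (obs[["dN"]] - obs[["dS"]]) / se
  p <- if (is.na(Z)) NA_real_ else pnorm(Z, lower.tail = FALSE)
  structure(list(dN = obs[["dN"]], dS = obs[["dS"]],
                 omega = if (!is.na(obs[["dS"]]) && obs[["dS"]] > 0)
                   obs[["dN"]] / obs[["dS"]] else NA_real_,
                 Z = Z, p_one_tailed = p, n_bootstrap = as.integer(n_bootstrap),
                 seed = seed, region = region, n_codons = C, n_pairs = P),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "dN/dS Z-test [%s, %d codons, %d pairs]\n  dN = %.4f  dS = %.4f  omega = %s\n  Z = %.3f  one-tailed p = %.4g  (bootstrap B = %d)\n",
    x$region, x$n_codons, x$n_pairs, x$dN, x$dS,
    ifelse(is.na(x$omega), "undefined", sprintf("%.3f", x$omega)),
    x$Z, x$p_one_tailed, x$n_bootstrap))
  invisible(x)
}
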