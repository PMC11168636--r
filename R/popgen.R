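# Diversity statistics on an allele alignment: haplotypes, segregating
# sites, pi, Watterson's theta, mean pairwise differences, Tajima's D.

#' Construct an allele alignment
#'
#' @param sequences named or unnamed character vector of equal-length
#'   sequences over \{A,C,G,T,N,-\} (case-insensitive). `N` and `-` are
#'   treated as missing data.
#' @param site_handling `"complete_deletion"` (drop every column containing
#'   missing data; the DNAsp-style default), `"pairwise_deletion"` (per-pair
#'   effective sites) or `"none"` (full length, missing ignored per site).
#' @return object of class `allele_alignment`.
#' @export
allele_alignment <- function(sequences,
                             site_handling = c("complete_deletion",
                                               "pairwise_deletion", "none")) {
  site_handling <- match.arg(site_handling)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2L) stop("an alignment needs >= 2 sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must be of equal length")
  if (any(grepl("[^ACGTN-]", sequences)))
    stop("alignment alphabet is {A,C,G,T,N,-}")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- names(sequences)
  structure(list(sequences = sequences, matrix = mat, L = L,
                 site_handling = site_handling),
            class = "allele_alignment")
}

as_alignment <- function(x, ...) {
  if (inherits(x, "allele_alignment")) x else allele_alignment(x, ...)
}

# per-column observed nucleotide states (missing excluded)
site_state_counts <- function(mat) {
  apply(mat, 2L, function(col) length(unique(col[col %in% DNA_BASES])))
}

pairwise_diff_stats <- function(mat) {
  n <- nrow(mat)
  diffs <- valid <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] %in% DNA_BASES & mat[j, ] %in% DNA_BASES
      diffs[i, j] <- sum(mat[i, ok] != mat[j, ok])
      valid[i, j] <- sum(ok)
    }
  }
  list(diffs = diffs[upper.tri(diffs)], valid = valid[upper.tri(valid)])
}

#' Diversity summary of an allele alignment
#'
#' Computes the number of distinct haplotypes (`h`), segregating sites (`S`:
#' columns with >= 2 observed nucleotide states), total mutations (`eta`:
#' observed states minus one, summed over columns), mean pairwise nucleotide
#' differences (`K`), per-site nucleotide diversity (`pi`) and Watterson's
#' estimator `theta_w = S / (a_n * L_eff)` with
#' `a_n = sum(1/i, i = 1..n-1)`.
#'
#' Effective length `L_eff` depends on `site_handling`: retained columns
#' under complete deletion; columns with >= 2 non-missing observations under
#' pairwise deletion; the full alignment length otherwise. Under pairwise
#' deletion, `pi` averages per-pair `diffs / valid_sites`.
#'
#' @param alignment an [allele_alignment()] (or a character vector, coerced).
#' @param distinct when `TRUE` (default) duplicated sequences are collapsed
#'   first, i.e. statistics are computed over distinct alleles (haplotypes);
#'   `h` always counts distinct sequences of the input.
#' @param ... passed to [allele_alignment()] on coercion.
#' @return object of class `popgen_summary` (list with `h`, `S`, `eta`,
#'   `pi`, `theta_w`, `K`, `n`, `L`, `L_eff`, `site_handling`).
#' @export
popgen_summary <- function(alignment, distinct = TRUE, ...) {
  aln <- as_alignment(alignment, ...)
  h <- length(unique(aln$sequences))
  mat <- aln$matrix
  if (distinct) mat <- mat[!duplicated(aln$sequences), , drop = FALSE]
  n <- nrow(mat)
  if (n < 2L) {
    # a fully monomorphic distinct set: zero diversity by convention
    return(structure(list(h = h, S = 0L, eta = 0L, pi = 0, theta_w = 0, K = 0,
                          n = n, L = aln$L, L_eff = aln$L,
                          site_handling = aln$site_handling),
                     class = "popgen_summary"))
  }
  miss <- !(mat %in% DNA_BASES)
  dim(miss) <- dim(mat)
  use <- switch(aln$site_handling,
                complete_deletion = colSums(miss) == 0L,
                pairwise_deletion = colSums(!miss) >= 2L,
                none = rep(TRUE, ncol(mat)))
  sub <- mat[, use, drop = FALSE]
  states <- site_state_counts(sub)
  S <- sum(states >= 2L)
  eta <- sum(pmax(states - 1L, 0L))
  pw <- pairwise_diff_stats(sub)
  K <- mean(pw$diffs)
  L_eff <- switch(aln$site_handling,
                  complete_deletion = sum(use),
                  pairwise_deletion = sum(use),
                  none = aln$L)
  pi <- switch(aln$site_handling,
               pairwise_deletion = mean(ifelse(pw$valid > 0, pw$diffs / pw$valid, 0)),
               K / L_eff)
  a_n <- sum(1 / seq_len(n - 1L))
  theta_w <- S / (a_n * L_eff)
  structure(list(h = h, S = S, eta = eta, pi = pi, theta_w = theta_w, K = K,
                 n = n, L = aln$L, L_eff = L_eff,
                 site_handling = aln$site_handling),
            class = "popgen_summary")
}

#' @export
print.popgen_summary <- function(x, ...) {
  cat(sprintf(
    "popgen_summary (n = %d, L = %d, %s)\n  h = %d  S = %d  eta = %d\n  pi = %.5f  theta_w = %.5f  K = %.3f\n",
    x$n, x$L, x$site_handling, x$h, x$S, x$eta, x$pi, x$theta_w, x$K))
  invisible(x)
}

#' Tajima's D constants for sample size n
#' @noRd
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

tajima_d_from_counts <- function(K, S, n) {
  if (S == 0L) return(NA_real_)
  cst <- tajima_constants(n)
  (K - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Tajima's D, overall and in sliding windows
#'
#' `D = (K - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the 1989 variance
#' constants computed from the number of sequences, `K` being the mean
#' pairwise difference count and `S` the number of segregating sites. `D` is
#' `NA` (undefined) when `S = 0`. In windowed mode, windows are 0-based
#' half-open nucleotide intervals `[start, start + window_nt)` advanced by
#' `step_nt` while they fit entirely inside the alignment; per-window `S`,
#' `pi` (per effective site, missing ignored pairwise) and `D` are reported.
#'
#' @inheritParams popgen_summary
#' @param window_nt,step_nt window and step sizes in nucleotides; both
#'   `NULL` for the overall statistic only. The study-design defaults are
#'   25 and 5.
#' @return list with `D` (overall) and, in windowed mode, `windows`
#'   (`data.frame` with `start`, `end`, `S`, `pi`, `D`).
#' @export
tajimas_d <- function(alignment, window_nt = NULL, step_nt = NULL,
                      distinct = TRUE, ...) {
  aln <- as_alignment(alignment, ...)
  mat <- aln$matrix
  if (distinct) mat <- mat[!duplicated(aln$sequences), , drop = FALSE]
  n <- nrow(mat)
  if (n < 4L) warning("Tajima's D variance is unstable for n < 4")
  stats_of <- function(cols) {
    sub <- mat[, cols, drop = FALSE]
    S <- sum(site_state_counts(sub) >= 2L)
    pw <- pairwise_diff_stats(sub)
    valid <- ifelse(pw$valid > 0, pw$valid, NA)
    list(S = S, K = mean(pw$diffs),
         pi = mean(pw$diffs / valid, na.rm = TRUE))
  }
  ov <- stats_of(seq_len(ncol(mat)))
  out <- list(D = tajima_d_from_counts(ov$K, ov$S, n), S = ov$S, n = n)
  if (!is.null(window_nt)) {
    stopifnot(is_count(window_nt), is_count(step_nt), window_nt <= aln$L)
    starts <- seq(0L, aln$L - window_nt, by = step_nt)
    win <- lapply(starts, function(s) {
      st <- stats_of((s + 1L):(s + window_nt))
      data.frame(start = s, end = s + window_nt, S = st$S, pi = st$pi,
                 D = tajima_d_from_counts(st$K, st$S, n))
    })
    out$windows <- do.call(rbind, win)
  }
  out
}
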