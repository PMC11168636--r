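# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (direct enumeration) and share no code with
# the implementations they verify.

# -- diversity statistics by brute-force site/pair enumeration --------------
oracle_popgen <- function(seqs) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  L <- nchar(seqs[1])
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  S <- 0L; eta <- 0L
  for (site in seq_len(L)) {
    states <- unique(vapply(chars, `[[`, character(1), site))
    states <- states[states %in% c("A", "C", "G", "T")]
    if (length(states) >= 2L) S <- S + 1L
    eta <- eta + max(length(states) - 1L, 0L)
  }
  diffs <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    diffs <- c(diffs, sum(chars[[i]] != chars[[j]]))
  K <- mean(diffs)
  a_n <- sum(1 / seq_len(n - 1L))
  list(h = length(unique(seqs)), S = S, eta = eta, K = K, pi = K / L,
       theta_w = S / (a_n * L))
}

# -- independently coded Tajima (1989) constants and D ----------------------
oracle_tajima_d <- function(K, S, n) {
  if (S == 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# -- Nei-Gojobori observed differences by explicit path enumeration ---------
oracle_codon_path_counts <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (length(dpos) == 0) return(c(nd = 0, sd = 0))
  orders <- if (length(dpos) == 1) list(dpos) else {
    perms <- list()
    idx <- seq_along(dpos)
    rec <- function(prefix, left) {
      if (!length(left)) { perms[[length(perms) + 1]] <<- dpos[prefix]; return() }
      for (x in left) rec(c(prefix, x), setdiff(left, x))
    }
    rec(integer(0), idx)
    perms
  }
  walk <- function(ord, allow_stops) {
    cur <- a; nd <- 0; sd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cf <- paste(cur, collapse = ""); ct <- paste(nxt, collapse = "")
      if (!allow_stops && (cf %in% stops || ct %in% stops)) return(NULL)
      if (identical(code[[cf]], code[[ct]])) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  res <- Filter(Negate(is.null), lapply(orders, walk, allow_stops = FALSE))
  if (!length(res)) res <- lapply(orders, walk, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

# enumeration of the 61 sense codons
sense_codons <- function() {
  all <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                           c("A","C","G","T")), 1, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# -- random fixtures --------------------------------------------------------
random_alignment <- function(n, L, n_var = max(1L, round(L * 0.3))) {
  anc <- sample(c("A","C","G","T"), L, replace = TRUE)
  sites <- sample.int(L, n_var)
  vapply(seq_len(n), function(i) {
    x <- anc
    mut <- sites[runif(length(sites)) < 0.4]
    x[mut] <- vapply(x[mut], function(b)
      sample(setdiff(c("A","C","G","T"), b), 1), character(1))
    paste(x, collapse = "")
  }, character(1))
}

# small genotype table built by hand
toy_genotypes <- function(sets, pops = NULL, sexes = NULL) {
  ids <- names(sets)
  data.frame(individual_id = ids,
             population_id = pops %||% rep("popA", length(ids)),
             sex = sexes %||% rep("unknown", length(ids)),
             alleles = vapply(sets, function(a) paste(sort(a), collapse = ";"), ""),
             n_alleles = lengths(sets),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
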