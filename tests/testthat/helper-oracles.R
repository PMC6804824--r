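# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (enumeration / double loops) and share no
# code with the package implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence with point substitutions at given positions
mutate_at <- function(seq, pos, alt) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- alt[i]
  seq
}

# brute-force nucleotide diversity: double loop over pairs and sites,
# pairwise deletion of non-ACGT characters
oracle_pi <- function(seqs) {
  n <- length(seqs)
  ch <- strsplit(seqs, "", fixed = TRUE)
  acgt <- c("A", "C", "G", "T")
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0; L <- 0
    for (kk in seq_along(ch[[i]])) {
      a <- ch[[i]][kk]; b <- ch[[j]][kk]
      if (a %in% acgt && b %in% acgt) {
        L <- L + 1
        if (a != b) d <- d + 1
      }
    }
    tot <- tot + d / L
    np <- np + 1
  }
  tot / np
}

# brute-force haplotype diversity from first principles: probability that an
# ordered draw without replacement yields two different sequences
oracle_hd <- function(seqs) {
  n <- length(seqs)
  diff <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && seqs[i] != seqs[j]) diff <- diff + 1
  }
  diff / (n * (n - 1))
}

# exhaustive affine-gap global alignment score by plain recursion over edit
# operations (no DP tables); feasible only for very short sequences
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  gap_cost <- function(len) if (len == 0) 0 else -(gap_open + gap_extend * len)
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      open <- if (state == "A") 0 else gap_open
      best <- max(best, -(open + gap_extend) + rec(i + 1, j, "A"))
    }
    if (j <= length(bv)) {
      open <- if (state == "B") 0 else gap_open
      best <- max(best, -(open + gap_extend) + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "start")
}

# Deng gray relational degree computed longhand for a single comparison
oracle_grd <- function(ref, cmp, rho) {
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  d <- abs(mm(ref) - mm(cmp))
  xi <- (min(d) + rho * max(d)) / (d + rho * max(d))
  mean(xi)
}
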