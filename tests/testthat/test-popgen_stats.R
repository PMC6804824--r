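test_that("pi matches hand-computed and brute-force values", {
  expect_equal(nucleotide_diversity(c(strrep("A", 100), strrep("A", 100))), 0)

  s1 <- strrep("A", 100)
  s2 <- paste0("T", strrep("A", 99))
  expect_equal(nucleotide_diversity(c(s1, s2)), 0.01)

  # three 50-nt sequences: A, A, and B differing at 2 sites
  a <- strrep("C", 50)
  b <- mutate_at(a, c(10, 20), c("G", "G"))
  expect_equal(nucleotide_diversity(c(a, a, b)), (0 + 2 + 2) / 3 / 50)

  expect_error(nucleotide_diversity("ACGT"), "at least 2")
  expect_error(nucleotide_diversity(c("ACGT", "ACG")), "equal length")
})

test_that("pi equals the brute-force pairwise oracle on random panels", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(3:10, 1)
    L <- sample(50:200, 1)
    base <- random_dna(L)
    panel <- vapply(1:n, function(i) {
      k <- sample(0:5, 1)
      if (k == 0) return(base)
      mutate_at(base, sample(L, k),
                sample(c("A", "C", "G", "T"), k, replace = TRUE))
    }, character(1))
    expect_equal(nucleotide_diversity(panel), oracle_pi(panel))
    # permutation invariance
    expect_equal(nucleotide_diversity(sample(panel)),
                 nucleotide_diversity(panel))
  }
})

test_that("pi agrees with independent raw pairwise distances", {
  skip_if_not_installed("ape")
  set.seed(23)
  base <- random_dna(300)
  panel <- vapply(1:6, function(i) {
    mutate_at(base, sample(300, 4),
              sample(c("A", "C", "G", "T"), 4, replace = TRUE))
  }, character(1))
  dn <- ape::as.DNAbin(t(sapply(strsplit(tolower(panel), ""), identity)))
  d <- ape::dist.dna(dn, model = "raw", pairwise.deletion = TRUE)
  expect_equal(nucleotide_diversity(panel), mean(d))
})

test_that("missing data policies: pairwise keeps more sites than complete deletion", {
  a <- "ACGTACGTAC"
  b <- "ACGTACGTAT"   # 1 diff
  cN <- "NCGTACGTAC"  # N at site 1
  # pairwise: pair (a,b) uses all 10 sites; pairs with cN use 9
  expect_equal(nucleotide_diversity(c(a, b, cN), policy = "pairwise"),
               (1 / 10 + 0 / 9 + 1 / 9) / 3)
  # complete: site 1 dropped for everyone
  expect_equal(nucleotide_diversity(c(a, b, cN), policy = "complete"),
               (1 / 9 + 0 / 9 + 1 / 9) / 3)
})

test_that("haplotype diversity uses the unbiased estimator", {
  expect_equal(haplotype_diversity(c("AAA", "AAA")),
               list(n_haplotypes = 1, hd = 0))
  # two distinct sequences: Hd exactly 1
  expect_equal(haplotype_diversity(c("AAA", "AAT")),
               list(n_haplotypes = 2, hd = 1))
  # n = 4, counts {2, 2}: (4/3) * (1 - 0.5)
  h <- haplotype_diversity(c("AA", "AA", "TT", "TT"))
  expect_equal(h$n_haplotypes, 2)
  expect_equal(h$hd, (4 / 3) * (1 - 0.5))
  expect_error(haplotype_diversity("AAA"), "at least 2")
})

test_that("hd stays in [0,1], equals 1 iff all sequences are distinct, and matches the draw oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    pool <- c("AAAA", "AAAT", "AATT", "ATTT", "TTTT")
    panel <- sample(pool, n, replace = TRUE)
    h <- haplotype_diversity(panel)
    expect_gte(h$hd, 0)
    expect_lte(h$hd, 1)
    expect_equal(h$hd, oracle_hd(panel))
    expect_equal(h$hd == 1, !anyDuplicated(panel) && h$n_haplotypes == n)
  }
})

test_that("segregating sites counts polymorphic columns, ignoring missing bases", {
  a <- strrep("A", 30)
  expect_equal(segregating_sites(c(a, a, a)), 0)
  b <- mutate_at(a, c(3, 17, 25), c("C", "G", "T"))
  expect_equal(segregating_sites(c(a, a, b)), 3)
  # a column where the only alternative base is N does not segregate
  cN <- mutate_at(a, 3, "N")
  expect_equal(segregating_sites(c(a, cN)), 0)
})

test_that("for two sequences pi equals S / L exactly", {
  set.seed(5)
  for (rep in 1:5) {
    L <- sample(40:120, 1)
    a <- random_dna(L)
    k <- sample(1:6, 1)
    b <- a
    pos <- sample(L, k)
    for (p in pos) {
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(a, p, p)), 1)
    }
    pair <- c(a, b)
    expect_equal(nucleotide_diversity(pair),
                 segregating_sites(pair) / L)
  }
})

test_that("mean pi over simulated panels matches its analytic expectation", {
  # per-site substitution with probability p to a uniformly chosen
  # alternative base: two sequences differ at a site with probability
  # 2 p (1 - p) + (2/3) p^2
  p <- 0.005
  expected <- 2 * p * (1 - p) + (2 / 3) * p^2
  set.seed(1234)
  L <- 600
  reps <- 60
  pis <- vapply(seq_len(reps), function(r) {
    base <- random_dna(L)
    panel <- vapply(1:6, function(i) {
      hit <- which(runif(L) < p)
      if (!length(hit)) return(base)
      mutate_at(base, hit, vapply(hit, function(h) {
        sample(setdiff(c("A", "C", "G", "T"), substr(base, h, h)), 1)
      }, character(1)))
    }, character(1))
    nucleotide_diversity(panel)
  }, numeric(1))
  se <- sd(pis) / sqrt(reps)
  expect_lt(abs(mean(pis) - expected), 3 * se)
})

test_that("diversity_stats summarizes a generator panel consistently", {
  cfg <- sim_config(seed = 8, n_cultivars = 8, indel_freq = 0)
  pan <- generate_haplotype_panel(cfg)
  st <- diversity_stats(pan$sequences, group = "LTPS-1")
  expect_equal(st$n, 8)
  expect_equal(st$S, pan$truth$S)
  expect_equal(st$pi, oracle_pi(unname(pan$sequences)))
  expect_lte(st$n_haplotypes, st$n)
  expect_true(st$hd >= 0 && st$hd <= 1)
})
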