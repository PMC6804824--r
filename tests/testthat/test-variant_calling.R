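test_that("find_orf returns the longest ATG-initiated ORF, leftmost on ties", {
  o <- find_orf("ATGAAATGA")
  expect_equal(nchar(o$seq), 9)
  expect_equal(o$protein, "MK")

  # two ORFs, 30 nt and 60 nt, on one sequence: the longer wins
  orf30 <- paste0("ATG", strrep("GCT", 8), "TAA")
  orf60 <- paste0("ATG", strrep("GCA", 18), "TGA")
  seq <- paste0("CC", orf30, "TT", orf60, "AA")
  o2 <- find_orf(seq)
  expect_equal(o2$seq, orf60)

  # protein-length law on a generator ORF
  loc <- generate_locus(sim_config(seed = 2))
  expect_equal(nchar(loc$cdnas$canonical$seq), 1761)
  expect_equal(nchar(find_orf(loc$cdnas$canonical)$protein), 586)

  expect_error(find_orf("CCCTTTCCC", id = "noorf"), "noorf")
})

test_that("global alignment matches an exhaustive enumeration oracle on short sequences", {
  a <- align_pair("ACGTACGT", "ACGTACGT")
  expect_equal(a$identity, 100)
  expect_false(grepl("-", a$aligned_ref))

  set.seed(11)
  cases <- list(
    c("ACGTACGT", "ACGACGT"),   # one deletion
    c("ACGTACGT", "ACGTTACGT"), # one insertion
    c("AAAACCCC", "AAAGCCCC"),  # one substitution
    c("ACACACAC", "ACACAC")
  )
  for (i in 1:6) {
    cases[[length(cases) + 1]] <- c(random_dna(8), random_dna(7))
  }
  for (cs in cases) {
    al <- align_pair(cs[1], cs[2])
    expect_equal(al$score, oracle_align_score(cs[1], cs[2]),
                 info = paste(cs, collapse = " vs "))
  }

  # one deletion appears as exactly one 1-nt gap in the query row
  al <- align_pair("ACGTACGT", "ACGACGT")
  expect_equal(lengths(regmatches(al$aligned_query,
                                  gregexpr("-+", al$aligned_query))), 1)
})

test_that("a block insertion aligns as a single contiguous gap in the reference row", {
  set.seed(3)
  ref <- random_dna(300)
  block <- random_dna(12)
  query <- paste0(substr(ref, 1, 150), block, substr(ref, 151, 300))
  al <- align_pair(ref, query)
  gaps <- regmatches(al$aligned_ref, gregexpr("-+", al$aligned_ref))[[1]]
  expect_equal(nchar(gaps), 12)
})

test_that("variant calling round-trips and left-normalizes InDels", {
  expect_equal(nrow(call_variants("ATGAAACCC", "ATGAAACCC")), 0)

  set.seed(21)
  ref <- random_dna(400)
  q <- mutate_at(ref, 100, setdiff(c("A", "C", "G", "T"),
                                   substr(ref, 100, 100))[1])
  v <- call_variants(ref, q)
  expect_equal(v$kind, "SNP")
  expect_equal(v$pos, 100)
  expect_equal(v$ref, substr(ref, 100, 100))
  expect_identical(apply_variants(ref, v), q)

  # deleting any single base of a homopolymer run yields the same
  # left-normalized record
  ref2 <- paste0(random_dna(50), "G", "AAAAAA", "C", random_dna(50))
  del_at <- function(s, i) paste0(substr(s, 1, i - 1), substr(s, i + 1, nchar(s)))
  recs <- lapply(52:57, function(i) call_variants(ref2, del_at(ref2, i)))
  for (r in recs) {
    expect_equal(r$kind, "deletion")
    expect_equal(r$pos, recs[[1]]$pos)
    expect_equal(r$ref, recs[[1]]$ref)
  }
  expect_equal(recs[[1]]$pos, 52)
})

test_that("random mutated pairs reconstruct exactly through call/apply", {
  set.seed(99)
  for (rep in 1:40) {
    ref <- random_dna(250)
    q <- ref
    # a few substitutions
    for (p in sample(250, 3)) {
      substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(q, p, p)), 1)
    }
    # one insertion or deletion
    if (rep %% 2 == 0) {
      at <- sample(50:150, 1)
      q <- paste0(substr(q, 1, at), random_dna(sample(c(3, 6, 12), 1)),
                  substr(q, at + 1, nchar(q)))
    } else {
      at <- sample(50:150, 1)
      q <- paste0(substr(q, 1, at), substr(q, at + 1 + sample(c(3, 6), 1),
                                           nchar(q)))
    }
    v <- call_variants(ref, q)
    expect_identical(apply_variants(ref, v), q)
  }
})

test_that("coding effects partition SNPs and classify InDels by frame", {
  orf <- paste0("ATG", "CTT", "AAA", "GGG", "TAA")
  # third-position CTT->CTC: both Leu
  expect_equal(annotate_effect(orf, list(pos = 6, kind = "SNP", alt = "C")),
               "synonymous")
  # ATG->ATA: Met -> Ile
  expect_equal(annotate_effect(orf, list(pos = 3, kind = "SNP", alt = "A")),
               "nonsynonymous")
  expect_equal(annotate_effect(orf, list(pos = 4, kind = "insertion",
                                         alt = strrep("A", 12), ref = "")),
               "inframe_indel")
  expect_equal(annotate_effect(orf, list(pos = 4, kind = "deletion",
                                         ref = "AC", alt = "")),
               "frameshift")
  expect_error(annotate_effect(orf, list(pos = 99, kind = "SNP", alt = "A")),
               "outside")

  # every SNP is exactly one of synonymous/nonsynonymous and counts sum
  loc <- generate_locus(sim_config(seed = 13))
  pan <- generate_haplotype_panel(sim_config(seed = 13), loc)
  ref <- loc$cdnas$canonical$seq
  sv <- pan$truth$snp_variants
  effects <- vapply(seq_len(nrow(sv)), function(i) {
    annotate_effect(ref, list(pos = sv$pos[i], kind = "SNP", alt = sv$alt[i]))
  }, character(1))
  expect_true(all(effects %in% c("synonymous", "nonsynonymous")))
  expect_equal(sum(effects == "synonymous") + sum(effects == "nonsynonymous"),
               nrow(sv))
})

test_that("isoform groups are assigned from diagnostic InDel signatures", {
  loc <- generate_locus(sim_config(seed = 2))
  ref <- loc$cdnas$canonical

  empty <- call_variants(ref, ref)
  expect_equal(assign_isoform_group(empty)$label, "LTPS-1")

  v2 <- call_variants(ref, loc$cdnas$alt5)
  expect_equal(v2$kind, "insertion")
  expect_equal(nchar(v2$alt), 12)
  g2 <- assign_isoform_group(v2)
  expect_equal(g2$label, "LTPS-2")
  expect_equal(nrow(g2$evidence), 1)

  v3 <- call_variants(ref, loc$cdnas$alt3)
  expect_equal(v3$kind, "deletion")
  expect_equal(nchar(v3$ref), 114)
  expect_equal(assign_isoform_group(v3)$label, "LTPS-3")

  both <- rbind(v2, v3)
  expect_error(assign_isoform_group(both), "conflict")

  # the alt-3' deletion spans the expected coding region
  expect_equal(v3$pos, loc$truth$del_pos)
  expect_equal(annotate_effect(ref, as.list(v3[1, ])), "inframe_indel")
})

test_that("protein-length law holds across all isoforms", {
  loc <- generate_locus(sim_config(seed = 4))
  for (iso in names(loc$cdnas)) {
    o <- find_orf(loc$cdnas[[iso]])
    expect_equal(nchar(o$protein), nchar(o$seq) / 3 - 1, info = iso)
  }
})

test_that("motif scanning finds constructed and planted TPS motifs", {
  hits <- scan_motifs("AAARRABCDEFGHWAAA",
                      patterns = c(RRX8W = "RR.{8}W"))
  rr <- hits[hits$motif == "RRX8W", ]
  expect_equal(c(rr$start, rr$end), c(4, 14))
  expect_equal(rr$matched, "RRABCDEFGHW")

  dd <- scan_motifs("DDAAD", patterns = c(DDXXD = "DD..D"))
  expect_equal(c(dd$start, dd$end, dd$matched), c("1", "5", "DDAAD"))

  expect_error(scan_motifs("AAA", patterns = c(bad = "([")), "malformed")

  # planted motifs: canonical protein has RRX8W + RX8W + DDXXD + NSE/DTE;
  # the 114-nt-deletion isoform loses RX8W but keeps the rest
  loc <- generate_locus(sim_config(seed = 2))
  p1 <- find_orf(loc$cdnas$canonical)$protein
  p3 <- find_orf(loc$cdnas$alt3)$protein
  expect_equal(nchar(p3), 548)
  m1 <- scan_motifs(p1)
  m3 <- scan_motifs(p3)
  expect_true(all(c("RRX8W", "RX8W", "DDXXD", "NSE/DTE") %in% m1$motif))
  expect_true(all(c("RRX8W", "DDXXD") %in% m3$motif))
  expect_false("RX8W" %in% m3$motif)
  # the upstream transit-like region is reported
  expect_equal(m1$motif[1], "transit_region")
  expect_equal(m1$start[1], 1)
})
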