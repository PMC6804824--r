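#' Simulation configuration
#'
#' Defaults describe a single monoterpene-synthase-like locus: 7 exons and 6
#' GT-AG introns on a 2661-nt genomic sequence, a 1761-nt canonical ORF
#' (586-residue protein), an alternative 5' donor in intron 1 adding 12 nt
#' (insertion site 230 on the canonical ORF) and an alternative 3' acceptor
#' in intron 3 removing 114 nt (positions 874-987). Both offsets are frame
#' preserving. The cultivar panel (default 23, matching a typical
#' association panel) carries independent per-site substitutions and an
#' InDel genotype whose carriers express the alt-5' isoform; one volatile
#' compound's emission depends on that genotype.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param exon_lengths Exon lengths (nt); must sum to a multiple of 3.
#' @param intron_lengths Intron lengths (nt), one fewer than exons, all
#'   >= 40.
#' @param alt5_intron,alt5_offset Intron index and retained donor-side nt of
#'   the alternative 5' splice site (offset divisible by 3).
#' @param alt3_intron,alt3_offset Intron index and additional acceptor-side
#'   nt of the alternative 3' splice site (offset divisible by 3; the exonic
#'   region it removes must be codon-aligned).
#' @param n_cultivars Panel size (>= 2).
#' @param per_site_snp_prob Per-site substitution probability in [0, 1].
#' @param indel_freq Carrier frequency of the alt-5' InDel genotype.
#' @param compounds Volatile compound names.
#' @param causal_compound Compound whose emission depends on the InDel
#'   genotype.
#' @param causal_site Site label of the causal InDel.
#' @param baseline Baseline contents (ug/g), one per compound.
#' @param effect_size Additive genotype effect on the causal compound
#'   (ug/g).
#' @param noise_sd Gaussian noise standard deviation (ug/g).
#' @param is_amount,is_peak_area,sample_weight Internal-standard amount
#'   (ug), IS peak area and sample weight (g) used when back-computing peak
#'   areas.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       exon_lengths = c(229, 270, 374, 240, 280, 200, 168),
                       intron_lengths = c(150, 160, 170, 140, 140, 140),
                       alt5_intron = 1, alt5_offset = 12,
                       alt3_intron = 3, alt3_offset = 114,
                       n_cultivars = 23, per_site_snp_prob = 0.005,
                       indel_freq = 0.3,
                       compounds = c("(E)-beta-ocimene", "myrcene",
                                     "alpha-pinene", "eucalyptol", "linalool"),
                       causal_compound = "(E)-beta-ocimene",
                       causal_site = "ins_230_12",
                       baseline = c(4, 3, 1.5, 2, 1),
                       effect_size = 3, noise_sd = 1,
                       is_amount = 0.8, is_peak_area = 1e6,
                       sample_weight = 1.5) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1,
            all(exon_lengths > 0), all(intron_lengths >= 40),
            sum(exon_lengths) %% 3 == 0,
            alt5_offset %% 3 == 0, alt3_offset %% 3 == 0,
            alt5_intron >= 1, alt5_intron <= length(intron_lengths),
            alt3_intron >= 1, alt3_intron <= length(intron_lengths),
            alt5_offset > 0, alt5_offset + 2 < intron_lengths[alt5_intron],
            per_site_snp_prob >= 0, per_site_snp_prob <= 1,
            indel_freq >= 0, indel_freq <= 1,
            length(baseline) == length(compounds),
            causal_compound %in% compounds,
            n_cultivars >= 2, noise_sd >= 0)
  e3 <- cumsum(exon_lengths)[alt3_intron]
  if (e3 %% 3 != 0) {
    stop("the exon boundary at the alternative 3' site must be codon-aligned")
  }
  if (alt3_offset >= exon_lengths[alt3_intron + 1]) {
    stop("alt3_offset must be shorter than the downstream exon")
  }
  structure(as.list(environment()), class = "sim_config")
}

.sense_codons_no_trp <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA", "TGG"))
}

.aa_codon <- c(R = "CGT", W = "TGG", D = "GAT", N = "AAT", S = "TCT",
               E = "GAA", A = "GCT")

# Plant conserved-motif codons into a codon vector (1-based residue index =
# codon index - 1 relative to protein because codon 1 is ATG/Met = residue 1).
.plant_motifs <- function(codons, del_from, del_to) {
  set_res <- function(i, aa) codons[i] <<- .aa_codon[[aa]]
  # RRX8W at residues 25-35, transit-like region upstream
  set_res(25, "R"); set_res(26, "R"); set_res(35, "W")
  # RX8W inside the alternatively spliced (deleted) region, when it fits
  if (del_to - del_from + 1 >= 11) {
    s <- del_from + 3
    set_res(s - 1, "A")  # avoid an accidental RRX8W here
    set_res(s, "R"); set_res(s + 9, "W")
  }
  # DDXXD and NSE/DTE downstream of the deleted region
  dd <- del_to + 20
  set_res(dd, "D"); set_res(dd + 1, "D"); set_res(dd + 4, "D")
  ns <- dd + 20
  set_res(ns, "N"); set_res(ns + 1, "D"); set_res(ns + 4, "S")
  set_res(ns + 8, "E")
  codons
}

#' Generate a synthetic gene locus with splice isoforms
#'
#' Builds a random protein-coding ORF (no internal stops; tryptophan codons
#' appear only at planted motif positions so conserved-motif presence and
#' absence is deterministic), splits it across the configured exons,
#' interleaves GT-AG introns, and derives three splice isoforms: the
#' canonical transcript, an alt-5' isoform retaining the first
#' `alt5_offset` nt of the designated intron (that intron carries a second
#' GT donor just downstream so both placements are canonical), and an
#' alt-3' isoform whose designated intron's acceptor lies `alt3_offset` nt
#' further downstream (the removed exonic region ends in AG). All three
#' isoforms contain valid ORFs.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_locus`: `gdna` (list `id`,`seq`), `cdnas`
#'   (named list of `id`,`seq` records: canonical, alt5, alt3), `truth`
#'   (exon/intron coordinates per isoform, insertion/deletion coordinates
#'   and sequences, ORF lengths), `config`.
#' @export
generate_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ex <- config$exon_lengths
  int <- config$intron_lengths
  n_nt <- sum(ex)
  n_codons <- n_nt / 3
  e1 <- cumsum(ex)[config$alt5_intron]        # insertion lands after this cDNA pos
  e3 <- cumsum(ex)[config$alt3_intron]        # deletion starts after this cDNA pos
  del_from_codon <- e3 / 3 + 1
  del_to_codon <- (e3 + config$alt3_offset) / 3

  pool <- .sense_codons_no_trp()
  codons <- sample(pool, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  codons <- .plant_motifs(codons, del_from_codon, del_to_codon)
  # the removed exonic region must end in AG so the alternative acceptor is
  # canonical; xAG codons: CAG/AAG/GAG (TAG is a stop)
  codons[del_to_codon] <- "CAG"
  orf <- paste(codons, collapse = "")
  stopifnot(!grepl("\\*", substr(translate_cds(orf), 1, n_codons - 1)))

  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  introns <- character(length(int))
  for (j in seq_along(int)) {
    s <- rand_dna(int[j])
    substr(s, 1, 2) <- "GT"
    substr(s, int[j] - 1, int[j]) <- "AG"
    introns[j] <- s
  }
  # intron carrying the alternative donor: a second GT right after the
  # retained prefix, and a retained prefix that introduces no in-frame stop
  j5 <- config$alt5_intron
  off5 <- config$alt5_offset
  for (try in 1:200) {
    s <- introns[j5]
    substr(s, off5 + 1, off5 + 2) <- "GT"
    prefix <- s
    substr(prefix, 1, 2) <- "GT"
    ins_seq <- substr(prefix, 1, off5)
    alt5_cdna <- paste0(substr(orf, 1, e1), ins_seq,
                        substr(orf, e1 + 1, n_nt))
    prot <- translate_cds(alt5_cdna)
    if (!grepl("\\*", prot)) { introns[j5] <- prefix; break }
    body <- rand_dna(off5 - 2)
    introns[j5] <- paste0("GT", body, substr(introns[j5], off5 + 1, int[j5]))
    if (try == 200) stop("could not generate a stop-free alternative donor")
  }
  ins_seq <- substr(introns[j5], 1, off5)
  alt5_cdna <- paste0(substr(orf, 1, e1), ins_seq, substr(orf, e1 + 1, n_nt))
  alt3_cdna <- paste0(substr(orf, 1, e3),
                      substr(orf, e3 + config$alt3_offset + 1, n_nt))

  exon_seqs <- substring(orf, c(1, cumsum(ex)[-length(ex)] + 1), cumsum(ex))
  gdna <- paste0(paste0(exon_seqs[-length(ex)], introns, collapse = ""),
                 exon_seqs[length(ex)])

  # genomic coordinates of the canonical model
  starts <- integer(length(ex)); ends <- integer(length(ex))
  pos <- 1L
  istarts <- integer(length(int)); iends <- integer(length(int))
  for (i in seq_along(ex)) {
    starts[i] <- pos
    ends[i] <- pos + ex[i] - 1L
    pos <- ends[i] + 1L
    if (i <= length(int)) {
      istarts[i] <- pos
      iends[i] <- pos + int[i] - 1L
      pos <- iends[i] + 1L
    }
  }
  canonical <- list(exons = data.frame(start = starts, end = ends),
                    introns = data.frame(start = istarts, end = iends))
  alt5 <- canonical
  alt5$exons$end[j5] <- alt5$exons$end[j5] + off5
  alt5$introns$start[j5] <- alt5$introns$start[j5] + off5
  j3 <- config$alt3_intron
  alt3 <- canonical
  alt3$introns$end[j3] <- alt3$introns$end[j3] + config$alt3_offset
  alt3$exons$start[j3 + 1] <- alt3$exons$start[j3 + 1] + config$alt3_offset

  structure(list(
    gdna = list(id = "synthetic_locus", seq = gdna),
    cdnas = list(canonical = list(id = "isoform_canonical", seq = orf),
                 alt5 = list(id = "isoform_alt5", seq = alt5_cdna),
                 alt3 = list(id = "isoform_alt3", seq = alt3_cdna)),
    truth = list(models = list(canonical = canonical, alt5 = alt5,
                               alt3 = alt3),
                 ins_pos = e1 + 1L, ins_seq = ins_seq,
                 del_pos = e3 + 1L,
                 del_seq = substr(orf, e3 + 1, e3 + config$alt3_offset),
                 orf_nt = c(canonical = n_nt,
                            alt5 = n_nt + off5,
                            alt3 = n_nt - config$alt3_offset)),
    config = config), class = "sim_locus")
}

#' Generate a cultivar haplotype panel with planted variants
#'
#' Each cultivar's coding sequence derives from the canonical ORF by
#' independent per-site substitution (uniform choice among the three
#' alternative bases); InDel carriers additionally express the alt-5'
#' isoform, i.e. carry the 12-nt insertion. Ground truth records every
#' planted variant, the site-incidence matrix, isoform group labels and the
#' panel's segregating-site count.
#'
#' @param config A [sim_config()].
#' @param locus Optional precomputed [generate_locus()] result (regenerated
#'   from `config` when `NULL`).
#' @return List of class `sim_panel`: `sequences` (named character),
#'   `truth` (list: `incidence` cultivar x site 0/1 matrix, `snp_variants`
#'   data frame, `carriers`, `groups`, `S`, `snp_positions`), `locus`,
#'   `config`.
#' @export
generate_haplotype_panel <- function(config = sim_config(), locus = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(locus)) locus <- generate_locus(config)
  set.seed(config$seed + 1L)
  orf <- locus$cdnas$canonical$seq
  L <- nchar(orf)
  n <- config$n_cultivars
  ids <- sprintf("cv%02d", seq_len(n))
  ref <- strsplit(orf, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")

  mat <- matrix(rep(ref, each = n), nrow = n)
  hit <- matrix(stats::runif(n * L) < config$per_site_snp_prob, nrow = n)
  idx <- which(hit, arr.ind = TRUE)
  snp_rows <- list()
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; pos <- idx[r, 2]
      alt <- sample(setdiff(bases, ref[pos]), 1)
      mat[i, pos] <- alt
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        cultivar = ids[i], pos = pos, ref = ref[pos], alt = alt,
        stringsAsFactors = FALSE)
    }
  }
  snp_variants <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(cultivar = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  carriers <- stats::runif(n) < config$indel_freq

  seqs <- apply(mat, 1, paste, collapse = "")
  ins_at <- locus$truth$ins_pos
  seqs[carriers] <- paste0(substr(seqs[carriers], 1, ins_at - 1),
                           locus$truth$ins_seq,
                           substr(seqs[carriers], ins_at, L))
  names(seqs) <- ids

  # site incidence: one column per distinct (pos, alt) plus the InDel site
  site_labels <- character(0)
  incidence <- NULL
  if (nrow(snp_variants)) {
    key <- sprintf("s%04d_%s>%s", snp_variants$pos, snp_variants$ref,
                   snp_variants$alt)
    for (kk in sort(unique(key))) {
      carriers_k <- unique(snp_variants$cultivar[key == kk])
      incidence <- cbind(incidence, as.integer(ids %in% carriers_k))
      site_labels <- c(site_labels, kk)
    }
  }
  incidence <- cbind(incidence, as.integer(carriers))
  site_labels <- c(site_labels, config$causal_site)
  dimnames(incidence) <- list(ids, site_labels)

  # segregating sites among the SNP-bearing (canonical-length) columns
  S <- sum(vapply(seq_len(L), function(p) length(unique(mat[, p])) >= 2,
                  logical(1)))

  structure(list(
    sequences = seqs,
    truth = list(incidence = incidence, snp_variants = snp_variants,
                 carriers = setNames(carriers, ids),
                 groups = setNames(ifelse(carriers, "LTPS-2", "LTPS-1"), ids),
                 S = S,
                 snp_positions = sort(unique(snp_variants$pos))),
    locus = locus, config = config), class = "sim_panel")
}

#' Generate emissions and GC-MS peak tables with a planted association
#'
#' The causal compound's content is `baseline + effect_size * genotype +
#' N(0, noise_sd)`, truncated at zero; all other compounds are independent
#' of genotype. Peak areas are back-computed from the intended contents so
#' that [quantify_content()] recovers them exactly.
#'
#' @param config A [sim_config()].
#' @param panel Optional precomputed [generate_haplotype_panel()] result.
#' @return List of class `sim_emissions`: `peaks` (long-format data frame
#'   as read by [read_peak_tables()]), `emissions` (cultivar x compound
#'   content matrix, ug/g), `truth` (`causal_site`, `causal_compound`,
#'   `genotype`), `config`.
#' @export
generate_emissions <- function(config = sim_config(), panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel)) panel <- generate_haplotype_panel(config)
  set.seed(config$seed + 2L)
  ids <- rownames(panel$truth$incidence)
  n <- length(ids)
  geno <- panel$truth$incidence[, config$causal_site]
  k <- length(config$compounds)
  contents <- matrix(rep(config$baseline, each = n), nrow = n,
                     dimnames = list(ids, config$compounds))
  contents <- contents + matrix(stats::rnorm(n * k, sd = config$noise_sd),
                                nrow = n)
  ci <- match(config$causal_compound, config$compounds)
  contents[, ci] <- config$baseline[ci] + config$effect_size * geno +
    stats::rnorm(n, sd = config$noise_sd)
  contents <- pmax(contents, 0)

  peaks <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(cultivar_id = ids[i], compound = config$compounds,
               peak_area = contents[i, ] * config$sample_weight *
                 config$is_peak_area / config$is_amount,
               is_name = "3-heptanone", is_amount_ug = config$is_amount,
               is_peak_area = config$is_peak_area,
               sample_weight_g = config$sample_weight,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  structure(list(peaks = peaks, emissions = contents,
                 truth = list(causal_site = config$causal_site,
                              causal_compound = config$causal_compound,
                              genotype = geno),
                 config = config), class = "sim_emissions")
}
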