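#' Map a cDNA onto a genomic locus
#'
#' Infers the exon/intron structure of a transcript on a single-gene genomic
#' sequence by exact k-mer anchoring, collinear chaining that maximizes cDNA
#' coverage, and junction refinement. When an exon/intron boundary placement
#' is ambiguous (the exon end and intron end share sequence, so the intron
#' can slide without changing the spliced product) the placement making the
#' intron start with GT and end with AG is preferred, then the 5'-most
#' placement. The concatenation of the returned exon sequences reproduces
#' the cDNA exactly (byte-identity is asserted whenever no mismatches were
#' tolerated).
#'
#' @param gdna,cdna Nucleotide strings or lists with `$id`/`$seq`.
#' @param k Anchor k-mer size (default 15).
#' @param max_mismatch Mismatches tolerated per exon during gap closure
#'   (default 2).
#' @param min_intron Minimum intron length (default 40 nt); smaller gaps in
#'   the genomic sequence are treated as unmappable.
#' @return List of class `gene_model`: `gdna_id`, `cdna_id`, `exons`
#'   (data frame `start`,`end`, 1-based inclusive genomic coordinates),
#'   `introns` (data frame `start`,`end`,`donor`,`acceptor`), `n_mismatch`.
#' @export
map_cdna <- function(gdna, cdna, k = 15, max_mismatch = 2, min_intron = 40) {
  gdna_id <- if (is.list(gdna) && !is.null(gdna$id)) gdna$id else "gdna"
  cdna_id <- if (is.list(cdna) && !is.null(cdna$id)) cdna$id else "cdna"
  g <- .clean_seq(gdna)
  q <- .clean_seq(cdna)
  ng <- nchar(g); nq <- nchar(q)
  if (nq < k) stop("cDNA '", cdna_id, "' is shorter than the anchor size k")
  gc <- strsplit(g, "", fixed = TRUE)[[1]]
  qc <- strsplit(q, "", fixed = TRUE)[[1]]

  # --- exact k-mer anchors -------------------------------------------------
  qk <- substring(q, 1:(nq - k + 1), k:nq)
  qmap <- split(seq_len(nq - k + 1), qk)
  gk <- substring(g, 1:(ng - k + 1), k:ng)
  gi <- which(gk %in% names(qmap))
  if (!length(gi)) stop("cDNA '", cdna_id, "' could not be anchored on '",
                        gdna_id, "'")
  anchors <- do.call(rbind, lapply(gi, function(gp) {
    cbind(q = qmap[[gk[gp]]], g = gp)
  }))

  # merge anchors on the same diagonal into maximal exact segments
  d <- anchors[, "g"] - anchors[, "q"]
  segs <- list()
  for (dd in unique(d)) {
    qs <- sort(unique(anchors[d == dd, "q"]))
    runs <- split(qs, cumsum(c(1L, as.integer(diff(qs) != 1L))))
    for (r in runs) {
      segs[[length(segs) + 1L]] <- c(qs = r[1], qe = r[length(r)] + k - 1L,
                                     gs = r[1] + dd, ge = r[length(r)] + k - 1L + dd)
    }
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, "qs"], segs[, "gs"]), , drop = FALSE]

  # --- collinear chain maximizing query coverage ---------------------------
  # adjacent exons may share up to k-1 bases of anchored query sequence at an
  # ambiguous junction; such overlaps are allowed and trimmed from the left
  # segment (the junction slide below restores the preferred placement)
  ns <- nrow(segs)
  cov <- segs[, "qe"] - segs[, "qs"] + 1L
  best <- as.numeric(cov)
  prev <- rep(NA_integer_, ns)
  for (jj in seq_len(ns)) {
    if (jj == 1L) next
    for (ii in seq_len(jj - 1L)) {
      ov <- max(0L, segs[ii, "qe"] - segs[jj, "qs"] + 1L)
      if (ov >= k) next
      qe_eff <- segs[ii, "qe"] - ov
      ge_eff <- segs[ii, "ge"] - ov
      if (qe_eff < segs[ii, "qs"]) next
      if (qe_eff < segs[jj, "qs"] && ge_eff < segs[jj, "gs"]) {
        qgap <- segs[jj, "qs"] - qe_eff - 1L
        ggap <- segs[jj, "gs"] - ge_eff - 1L
        if (ggap >= qgap) {
          s <- best[ii] - ov + cov[jj]
          if (s > best[jj]) { best[jj] <- s; prev[jj] <- ii }
        }
      }
    }
  }
  chain <- integer(0)
  node <- which.max(best)
  while (!is.na(node)) { chain <- c(node, chain); node <- prev[node] }
  ch <- segs[chain, , drop = FALSE]
  if (nrow(ch) > 1) for (i in seq_len(nrow(ch) - 1)) {
    ov <- max(0L, ch[i, "qe"] - ch[i + 1, "qs"] + 1L)
    if (ov > 0L) {
      ch[i, "qe"] <- ch[i, "qe"] - ov
      ch[i, "ge"] <- ch[i, "ge"] - ov
    }
  }

  # extend chain ends to cover the full cDNA (mismatches near the termini
  # have no k-mer anchor)
  ch[1, "gs"] <- ch[1, "gs"] - (ch[1, "qs"] - 1L)
  ch[1, "qs"] <- 1L
  last <- nrow(ch)
  ch[last, "ge"] <- ch[last, "ge"] + (nq - ch[last, "qe"])
  ch[last, "qe"] <- nq
  if (ch[1, "gs"] < 1L || ch[last, "ge"] > ng) {
    stop("cDNA '", cdna_id, "' extends beyond the genomic sequence")
  }

  # --- merge same-diagonal neighbours (mismatch regions inside one exon) ---
  blocks <- list(ch[1, ])
  if (nrow(ch) > 1) for (i in 2:nrow(ch)) {
    b <- blocks[[length(blocks)]]
    qgap <- ch[i, "qs"] - b["qe"] - 1L
    ggap <- ch[i, "gs"] - b["ge"] - 1L
    if (qgap == ggap && ggap < min_intron) {
      b["qe"] <- ch[i, "qe"]; b["ge"] <- ch[i, "ge"]
      blocks[[length(blocks)]] <- b
    } else {
      blocks[[length(blocks) + 1L]] <- ch[i, ]
    }
  }
  bl <- do.call(rbind, blocks)

  # --- junction refinement -------------------------------------------------
  nb <- nrow(bl)
  exon_g <- matrix(0L, nb, 2)
  exon_g[1, 1] <- bl[1, "gs"]
  introns <- NULL
  if (nb > 1) for (i in seq_len(nb - 1)) {
    qgap <- bl[i + 1, "qs"] - bl[i, "qe"] - 1L
    ggap <- bl[i + 1, "gs"] - bl[i, "ge"] - 1L
    ilen <- ggap - qgap
    if (ilen < min_intron) {
      stop("gap between anchored blocks of '", cdna_id, "' on '", gdna_id,
           "' is below min_intron; cDNA not mappable within tolerance")
    }
    # distribute the qgap unanchored bases: t to the left exon, rest right
    feas <- NULL
    for (t in qgap:0) {
      lq <- if (t > 0) qc[(bl[i, "qe"] + 1):(bl[i, "qe"] + t)] else character(0)
      lg <- if (t > 0) gc[(bl[i, "ge"] + 1):(bl[i, "ge"] + t)] else character(0)
      rt <- qgap - t
      rq <- if (rt > 0) qc[(bl[i + 1, "qs"] - rt):(bl[i + 1, "qs"] - 1)] else character(0)
      rg <- if (rt > 0) gc[(bl[i + 1, "gs"] - rt):(bl[i + 1, "gs"] - 1)] else character(0)
      if (all(lq == lg) && all(rq == rg)) { feas <- t; break }
    }
    if (is.null(feas)) {
      stop("junction ", i, " of '", cdna_id, "' cannot be closed exactly; ",
           "cDNA not mappable within tolerance")
    }
    istart <- bl[i, "ge"] + feas + 1L
    iend <- istart + ilen - 1L
    # equivalent placements: sliding preserves the spliced product when the
    # base entering the intron on one side equals the base leaving it on the
    # other side
    offs <- 0L
    o <- 0L
    while (istart + o - 1L >= 1L && gc[istart + o - 1L] == gc[iend + o]) {
      o <- o - 1L; offs <- c(offs, o)
      if (o < -200L) break
    }
    o <- 0L
    while (iend + o + 1L <= ng && gc[iend + o + 1L] == gc[istart + o]) {
      o <- o + 1L; offs <- c(offs, o)
      if (o > 200L) break
    }
    offs <- sort(offs)
    canon <- vapply(offs, function(o) {
      gc[istart + o] == "G" && gc[istart + o + 1L] == "T" &&
        gc[iend + o - 1L] == "A" && gc[iend + o] == "G"
    }, logical(1))
    pick <- if (any(canon)) offs[canon][1] else offs[1]
    istart <- istart + pick
    iend <- iend + pick
    exon_g[i, 2] <- istart - 1L
    exon_g[i + 1, 1] <- iend + 1L
    introns <- rbind(introns, c(start = unname(istart), end = unname(iend)))
  }
  exon_g[nb, 2] <- bl[nb, "ge"]

  exons <- data.frame(start = exon_g[, 1], end = exon_g[, 2])
  if (any(exons$end < exons$start)) {
    stop("degenerate exon while mapping '", cdna_id, "'")
  }
  spliced <- paste(vapply(seq_len(nb), function(i) {
    substr(g, exons$start[i], exons$end[i])
  }, character(1)), collapse = "")
  if (nchar(spliced) != nq) {
    stop("spliced exon chain length does not match cDNA '", cdna_id, "'")
  }
  n_mismatch <- sum(strsplit(spliced, "", fixed = TRUE)[[1]] != qc)
  if (n_mismatch > max_mismatch * nb) {
    stop("cDNA '", cdna_id, "' not mappable within the mismatch tolerance (",
         n_mismatch, " mismatches)")
  }
  if (n_mismatch == 0) stopifnot(identical(spliced, q))

  intron_df <- if (is.null(introns)) {
    data.frame(start = integer(0), end = integer(0),
               donor = character(0), acceptor = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(start = introns[, "start"], end = introns[, "end"],
               donor = substr(rep(g, nrow(introns)), introns[, "start"],
                              introns[, "start"] + 1L),
               acceptor = substr(rep(g, nrow(introns)), introns[, "end"] - 1L,
                                 introns[, "end"]),
               stringsAsFactors = FALSE)
  }
  structure(
    list(gdna_id = gdna_id, cdna_id = cdna_id, exons = exons,
         introns = intron_df, n_mismatch = n_mismatch),
    class = "gene_model"
  )
}

#' Validate GT-AG splice sites of a gene model
#'
#' Nearly all spliceosomal introns start with GT and end with AG; this
#' reports the donor/acceptor dinucleotides of every intron with a
#' conformance flag.
#'
#' @param model A `gene_model`.
#' @return Data frame with columns `intron_index`, `donor`, `acceptor`,
#'   `is_GT_AG`.
#' @export
validate_canonical_sites <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ii <- model$introns
  data.frame(intron_index = seq_len(nrow(ii)), donor = ii$donor,
             acceptor = ii$acceptor,
             is_GT_AG = ii$donor == "GT" & ii$acceptor == "AG",
             stringsAsFactors = FALSE)
}

#' Classify splicing differences between two isoform models
#'
#' Compares a query isoform against the canonical model on the same genomic
#' locus and classifies each structural difference: a moved donor is an
#' alternative 5' splice site, a moved acceptor an alternative 3' splice
#' site; a canonical intron retained in the query's exon space is intron
#' retention, and a canonical exon absent from the query is exon skipping.
#' `delta_nt` is the exonic sequence gained (+) or lost (-) by the query
#' relative to the canonical isoform.
#'
#' @param canonical,other `gene_model` objects on the same `gdna_id`.
#' @return Data frame with columns `cdna_id`, `kind`, `intron_index`,
#'   `delta_nt`; zero rows for identical structures.
#' @export
compare_isoforms <- function(canonical, other) {
  stopifnot(inherits(canonical, "gene_model"), inherits(other, "gene_model"))
  if (canonical$gdna_id != other$gdna_id) {
    stop("models are on different genomic sequences: ", canonical$gdna_id,
         " vs ", other$gdna_id)
  }
  ev <- list()
  add <- function(kind, idx, delta) {
    ev[[length(ev) + 1L]] <<- data.frame(cdna_id = other$cdna_id, kind = kind,
                                         intron_index = idx, delta_nt = delta,
                                         stringsAsFactors = FALSE)
  }
  ci <- canonical$introns
  oi <- other$introns
  if (nrow(ci) == nrow(oi)) {
    for (i in seq_len(nrow(ci))) {
      if (ci$start[i] != oi$start[i]) {
        add("alt_5prime", i, oi$start[i] - ci$start[i])
      }
      if (ci$end[i] != oi$end[i]) {
        add("alt_3prime", i, ci$end[i] - oi$end[i])
      }
    }
  } else {
    in_exon <- function(model, s, e) {
      any(model$exons$start <= s & model$exons$end >= e)
    }
    for (i in seq_len(nrow(ci))) {
      if (!any(oi$start == ci$start[i] | oi$end == ci$end[i])) {
        if (in_exon(other, ci$start[i], ci$end[i])) {
          add("intron_retention", i, ci$end[i] - ci$start[i] + 1L)
        }
      }
    }
    for (i in seq_len(nrow(canonical$exons))) {
      es <- canonical$exons$start[i]; ee <- canonical$exons$end[i]
      if (!any(other$exons$start <= ee & other$exons$end >= es)) {
        add("exon_skip", min(i, nrow(ci)), -(ee - es + 1L))
      }
    }
  }
  if (!length(ev)) {
    return(data.frame(cdna_id = character(0), kind = character(0),
                      intron_index = integer(0), delta_nt = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon features (1-based inclusive, forward strand) for one
#' or more transcript models on the same locus.
#'
#' @param models A `gene_model` or list of them.
#' @param path Output GFF3 path.
#' @return Invisibly, the path.
#' @export
write_gene_model_gff3 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  feats <- list()
  for (m in models) {
    span <- c(min(m$exons$start), max(m$exons$end))
    gid <- paste0("gene:", m$gdna_id)
    mid <- paste0("mRNA:", m$cdna_id)
    feats[[length(feats) + 1L]] <- data.frame(
      seq = m$gdna_id, type = c("gene", "mRNA", rep("exon", nrow(m$exons))),
      start = c(span[1], span[1], m$exons$start),
      end = c(span[2], span[2], m$exons$end),
      ID = c(gid, mid, paste0(mid, ":exon", seq_len(nrow(m$exons)))),
      Parent = c(NA, gid, rep(mid, nrow(m$exons))),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  df <- df[!duplicated(df$ID), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$seq,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+", type = df$type, ID = df$ID,
    Parent = ifelse(is.na(df$Parent), "", df$Parent))
  S4Vectors::mcols(gr)$source <- "scentvar"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
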