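#' Globally align two near-identical coding sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, tuned for
#' near-identical cDNA ORFs where isolated substitutions and one or two block
#' InDels are expected: match +2, mismatch -3, gap open 10, gap extend 0.5
#' (penalties positive). With these scores a contiguous 12- or 114-nt InDel
#' is always represented as a single gap run.
#'
#' @param ref,query Nucleotide strings, `orf` objects, or lists with `$seq`.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @return List of class `pairwise_alignment`: `aligned_ref`,
#'   `aligned_query` (equal-length gapped strings), `score`, `identity`
#'   (percent identical columns among aligned columns).
#' @export
align_pair <- function(ref, query, match = 2, mismatch = -3,
                       gap_open = 10, gap_extend = 0.5) {
  r <- .clean_seq(ref)
  q <- .clean_seq(query)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pwa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(q), subject = Biostrings::DNAString(r),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ar <- as.character(Biostrings::alignedSubject(pwa))
  aq <- as.character(Biostrings::alignedPattern(pwa))
  cols_r <- strsplit(ar, "", fixed = TRUE)[[1]]
  cols_q <- strsplit(aq, "", fixed = TRUE)[[1]]
  ident <- 100 * sum(cols_r == cols_q & cols_r != "-") / length(cols_r)
  structure(
    list(aligned_ref = ar, aligned_query = aq,
         score = Biostrings::score(pwa), identity = ident),
    class = "pairwise_alignment"
  )
}

# Shift one indel to its 5'-most equivalent placement (VCF-style).
# For a deletion at pos (first deleted ref base, allele = deleted sequence)
# a left shift by one is valid iff ref[pos + L - 1] == ref[pos - 1].
# For an insertion before ref position pos, a left shift is valid iff the
# last inserted base equals ref[pos - 1]; the allele is rotated.
# floor_pos is the smallest admissible pos: shifting never crosses another
# variant called on the same sequence (that would break reconstruction).
.left_normalize <- function(refseq, pos, kind, allele, floor_pos = 1L) {
  L <- nchar(allele)
  if (kind == "deletion") {
    while (pos > floor_pos &&
           substr(refseq, pos + L - 1, pos + L - 1) == substr(refseq, pos - 1, pos - 1)) {
      pos <- pos - 1
      allele <- substr(refseq, pos, pos + L - 1)
    }
  } else if (kind == "insertion") {
    while (pos > floor_pos &&
           substr(allele, L, L) == substr(refseq, pos - 1, pos - 1)) {
      allele <- paste0(substr(refseq, pos - 1, pos - 1), substr(allele, 1, L - 1))
      pos <- pos - 1
    }
  }
  list(pos = pos, allele = allele)
}

#' Call SNPs and InDels between a reference and a query ORF
#'
#' Walks a global alignment column by column: each mismatch column becomes a
#' SNP at its reference coordinate; each contiguous gap run becomes one
#' insertion (gap in reference row) or deletion (gap in query row),
#' left-normalized to its 5'-most equivalent position. Applying the returned
#' variants to the reference with [apply_variants()] reconstructs the query
#' exactly. Columns where either sequence carries the ambiguity code N are
#' excluded from the SNP catalogue and reported in the `n_excluded`
#' attribute.
#'
#' @param ref,query Nucleotide strings or `orf` objects.
#' @param alignment Optional precomputed [align_pair()] result.
#' @param ref_id Reference identifier recorded in the output.
#' @param ... Passed to [align_pair()].
#' @return Data frame of class `variant_table` with columns `ref_id`, `pos`
#'   (1-based on the reference), `kind` (`SNP`/`insertion`/`deletion`),
#'   `ref` (deleted/substituted reference bases; empty for insertions),
#'   `alt` (inserted/substituted query bases; empty for deletions), `effect`
#'   (`NA`; see [annotate_effects()]).
#' @export
call_variants <- function(ref, query, alignment = NULL, ref_id = "ref", ...) {
  r_seq <- .clean_seq(ref)
  if (is.list(ref) && !is.null(ref$id)) ref_id <- ref$id
  if (is.null(alignment)) alignment <- align_pair(r_seq, query, ...)
  rr <- strsplit(alignment$aligned_ref, "", fixed = TRUE)[[1]]
  qq <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  stopifnot(length(rr) == length(qq))
  refpos <- cumsum(rr != "-")

  n_excluded <- 0L

  # raw events in alignment-column order, each with its occupied reference
  # span; indels are left-normalized afterwards, never across another event
  raw <- list()
  snp <- which(rr != "-" & qq != "-" & rr != qq)
  for (i in snp) {
    if (rr[i] == "N" || qq[i] == "N") { n_excluded <- n_excluded + 1L; next }
    raw[[length(raw) + 1L]] <- list(pos = refpos[i], end = refpos[i],
                                    kind = "SNP", ref = rr[i], alt = qq[i])
  }
  state <- ifelse(rr == "-", "I", ifelse(qq == "-", "D", "M"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in seq_along(runs$values)) {
    st <- runs$values[j]
    if (st == "M") next
    i0 <- starts[j]; i1 <- ends[j]
    if (st == "I") {
      pos <- refpos[i0] + 1L  # inserted before this reference base
      raw[[length(raw) + 1L]] <- list(pos = pos, end = pos,
                                      kind = "insertion", ref = "",
                                      alt = paste(qq[i0:i1], collapse = ""))
    } else {
      pos <- refpos[i0]
      raw[[length(raw) + 1L]] <- list(pos = pos, end = pos + (i1 - i0),
                                      kind = "deletion",
                                      ref = paste(rr[i0:i1], collapse = ""),
                                      alt = "")
    }
  }

  vars <- list()
  if (length(raw)) {
    ord <- order(vapply(raw, `[[`, 0L, "pos"))
    raw <- raw[ord]
    raw_ends <- vapply(raw, `[[`, 0L, "end")
    for (j in seq_along(raw)) {
      ev <- raw[[j]]
      if (ev$kind != "SNP") {
        blockers <- raw_ends[seq_len(j - 1L)]
        floor_pos <- if (length(blockers)) max(1L, max(blockers) + 1L) else 1L
        allele <- if (ev$kind == "insertion") ev$alt else ev$ref
        nm <- .left_normalize(r_seq, ev$pos, ev$kind, allele, floor_pos)
        ev$pos <- nm$pos
        if (ev$kind == "insertion") ev$alt <- nm$allele else ev$ref <- nm$allele
      }
      vars[[length(vars) + 1L]] <- data.frame(
        ref_id = ref_id, pos = ev$pos, kind = ev$kind, ref = ev$ref,
        alt = ev$alt, effect = NA_character_, stringsAsFactors = FALSE)
    }
  }

  out <- if (length(vars)) do.call(rbind, vars) else
    data.frame(ref_id = character(0), pos = integer(0), kind = character(0),
               ref = character(0), alt = character(0), effect = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Apply a variant table to a reference sequence
#'
#' Reconstructs the query sequence from the reference and the variants
#' returned by [call_variants()] (the round-trip identity used throughout
#' the test-suite). Variants must not overlap.
#'
#' @param refseq Reference nucleotide string.
#' @param variants A `variant_table`.
#' @return Reconstructed sequence string.
#' @export
apply_variants <- function(refseq, variants) {
  refseq <- .clean_seq(refseq)
  if (nrow(variants) == 0) return(refseq)
  # apply right-to-left so earlier coordinates stay valid; at equal pos,
  # substitutions/deletions act on the reference base before an insertion
  # lands in front of it
  ord <- order(-variants$pos, variants$kind == "insertion")
  s <- refseq
  for (i in ord) {
    v <- variants[i, ]
    if (v$kind == "SNP") {
      stopifnot(substr(s, v$pos, v$pos) == v$ref)
      substr(s, v$pos, v$pos) <- v$alt
    } else if (v$kind == "deletion") {
      L <- nchar(v$ref)
      stopifnot(substr(s, v$pos, v$pos + L - 1) == v$ref)
      s <- paste0(substr(s, 1, v$pos - 1), substr(s, v$pos + L, nchar(s)))
    } else if (v$kind == "insertion") {
      s <- paste0(substr(s, 1, v$pos - 1), v$alt, substr(s, v$pos, nchar(s)))
    } else stop("unknown variant kind: ", v$kind)
  }
  s
}

#' Annotate the coding effect of one variant
#'
#' SNPs are classified by translating the reference codon and the mutated
#' codon under the standard genetic code (`synonymous` vs `nonsynonymous`);
#' InDels are `inframe_indel` when their length is divisible by 3 and
#' `frameshift` otherwise.
#'
#' @param ref_orf Reference ORF (an `orf` object or in-frame nucleotide
#'   string starting at codon 1).
#' @param variant One-row slice of a `variant_table` (or an equivalent list).
#' @return Effect label.
#' @export
annotate_effect <- function(ref_orf, variant) {
  seq <- .clean_seq(ref_orf)
  pos <- variant$pos
  if (is.na(pos) || pos < 1 || pos > nchar(seq) + (variant$kind == "insertion")) {
    stop("variant position ", pos, " lies outside the reference ORF")
  }
  if (variant$kind == "SNP") {
    ci <- (pos - 1) %/% 3
    codon <- substr(seq, ci * 3 + 1, ci * 3 + 3)
    mut <- codon
    substr(mut, pos - ci * 3, pos - ci * 3) <- variant$alt
    if (translate_cds(codon) == translate_cds(mut)) "synonymous" else "nonsynonymous"
  } else {
    L <- nchar(if (variant$kind == "insertion") variant$alt else variant$ref)
    if (L %% 3 == 0) "inframe_indel" else "frameshift"
  }
}

#' Annotate coding effects for a whole variant table
#'
#' @param ref_orf Reference ORF.
#' @param variants A `variant_table`.
#' @return The table with the `effect` column filled in.
#' @export
annotate_effects <- function(ref_orf, variants) {
  if (nrow(variants) == 0) return(variants)
  variants$effect <- vapply(seq_len(nrow(variants)), function(i) {
    annotate_effect(ref_orf, variants[i, ])
  }, character(1))
  variants
}

#' Assign a cDNA to an isoform group from its variant signature
#'
#' Against the designated group-1 reference, group-2 transcripts carry a
#' 12-bp insertion and group-3 transcripts a 114-bp deletion (both arising
#' from alternative splice-site use); a sequence showing both signatures is a
#' conflict and raises an error.
#'
#' @param variants A `variant_table` called against the group-1 reference.
#' @param ins_len,del_len Diagnostic InDel lengths (defaults 12 and 114).
#' @return List of class `isoform_group`: `label` (`"LTPS-1"`, `"LTPS-2"` or
#'   `"LTPS-3"`) and `evidence` (the diagnostic variant rows).
#' @export
assign_isoform_group <- function(variants, ins_len = 12, del_len = 114) {
  ins <- variants$kind == "insertion" & nchar(variants$alt) == ins_len
  del <- variants$kind == "deletion" & nchar(variants$ref) == del_len
  if (any(ins) && any(del)) {
    stop("conflicting isoform signature: both the ", ins_len,
         "-bp insertion and the ", del_len, "-bp deletion are present")
  }
  label <- if (any(ins)) "LTPS-2" else if (any(del)) "LTPS-3" else "LTPS-1"
  structure(list(label = label,
                 evidence = variants[ins | del, , drop = FALSE]),
            class = "isoform_group")
}
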