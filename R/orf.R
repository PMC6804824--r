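.clean_seq <- function(x) {
  if (is.list(x) && !is.null(x$seq)) x <- x$seq
  x <- toupper(as.character(x))
  if (length(x) != 1 || nchar(x) == 0) stop("sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", x)) stop("sequence contains characters outside {A,C,G,T,N}")
  x
}

#' Translate a coding sequence
#'
#' Standard genetic code; a single trailing stop codon is stripped.
#'
#' @param cds In-frame nucleotide string (length divisible by 3).
#' @return Amino-acid string (no stop symbol).
#' @export
translate_cds <- function(cds) {
  cds <- .clean_seq(cds)
  if (nchar(cds) %% 3 != 0) stop("coding sequence length must be divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Find the longest ATG-initiated open reading frame
#'
#' Scans all three forward frames for ATG-initiated ORFs that terminate in a
#' stop codon; returns the longest (ties broken by leftmost start). For a
#' valid ORF of L nucleotides the encoded protein has L/3 - 1 residues.
#'
#' @param record Nucleotide string, or a list with elements `id` and `seq`.
#' @param id Identifier used in error messages when `record` is a bare string.
#' @return List of class `orf`: `start`, `end` (1-based inclusive on the
#'   source), `seq` (the ORF, start codon through stop codon), `protein`.
#' @examples
#' find_orf("ATGAAATGA")  # 9-nt ORF, protein "MK"
#' @export
find_orf <- function(record, id = "sequence") {
  if (is.list(record) && !is.null(record$id)) id <- record$id
  seq <- .clean_seq(record)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- paste0(ch[starts], ch[starts + 1], ch[starts + 2])
    atg_idx <- which(codons == "ATG")
    stop_idx <- which(codons %in% stops)
    if (!length(atg_idx) || !length(stop_idx)) next
    for (a in atg_idx) {
      s <- stop_idx[stop_idx >= a]
      if (!length(s)) next
      s <- s[1]
      len <- (s - a + 1) * 3
      start <- starts[a]
      if (is.null(best) || len > best$len ||
          (len == best$len && start < best$start)) {
        best <- list(start = start, len = len)
      }
    }
  }
  if (is.null(best)) stop("no complete ATG-initiated ORF found in '", id, "'")
  orf_seq <- substr(seq, best$start, best$start + best$len - 1)
  structure(
    list(id = id, start = best$start, end = best$start + best$len - 1,
         seq = orf_seq, protein = translate_cds(orf_seq)),
    class = "orf"
  )
}
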