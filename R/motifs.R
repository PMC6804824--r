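#' Default terpene-synthase motif patterns
#'
#' Regular expressions over the amino-acid alphabet for the conserved
#' terpene-synthase motifs:
#' * `RRX8W` — the N-terminal arginine-rich tandem motif implicated in the
#'   isomerization-cyclization reaction; searched within the first 80
#'   residues (its position is N-terminal by definition).
#' * `RX8W` — the single-arginine variant (substrate-binding pocket); hits
#'   overlapping an `RRX8W` hit are suppressed so the tandem motif is not
#'   double-counted.
#' * `DDXXD` and `NSE/DTE` — the C-terminal aspartate-rich motifs forming
#'   the substrate (GPP)-divalent-metal binding site. The `NSE/DTE`
#'   expression is provisional: the motif family is loosely conserved and no
#'   canonical regular expression exists.
#'
#' @return Named character vector of regular expressions.
#' @export
default_motif_patterns <- function() {
  c("RRX8W"   = "RR.{8}W",
    "RX8W"    = "R.{8}W",
    "DDXXD"   = "DD..D",
    "NSE/DTE" = "[ND]D..[ST]...E")
}

#' Scan a protein for terpene-synthase motifs
#'
#' Reports all non-overlapping, leftmost-first matches of each configured
#' pattern. When an `RRX8W` hit is found after residue 1, the region upstream
#' of it is reported as `transit_region` (the putative plastid transit
#' peptide lies immediately N-terminal of the RRX8W motif).
#'
#' @param protein Amino-acid string.
#' @param patterns Named character vector of regular expressions; see
#'   [default_motif_patterns()].
#' @param rrx8w_window Last residue at which an `RRX8W` match may start
#'   (default 80).
#' @return Data frame with columns `motif`, `start`, `end` (1-based residue
#'   coordinates) and `matched` (the matched substring).
#' @export
scan_motifs <- function(protein, patterns = default_motif_patterns(),
                        rrx8w_window = 80) {
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) == 0) {
    stop("protein must be a single non-empty string")
  }
  if (is.null(names(patterns)) || any(names(patterns) == "")) {
    stop("motif patterns must be named")
  }
  find_hits <- function(name, pat) {
    m <- tryCatch(suppressWarnings(gregexpr(pat, protein, perl = TRUE)[[1]]),
                  error = function(e) stop("malformed motif pattern '", name,
                                           "': ", conditionMessage(e)))
    if (m[1] == -1) return(NULL)
    data.frame(motif = name, start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, Filter(Negate(is.null), Map(find_hits,
                                                     names(patterns),
                                                     unname(patterns))))
  if (is.null(hits)) hits <- data.frame(motif = character(0),
                                        start = integer(0), end = integer(0),
                                        stringsAsFactors = FALSE)
  # RRX8W is an N-terminal motif
  if ("RRX8W" %in% hits$motif) {
    hits <- hits[!(hits$motif == "RRX8W" & hits$start > rrx8w_window), ,
                 drop = FALSE]
  }
  rr <- hits[hits$motif == "RRX8W", , drop = FALSE]
  # RX8W hits inside/overlapping an RRX8W hit are the same physical motif
  if (nrow(rr) && any(hits$motif == "RX8W")) {
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      if (hits$motif[i] != "RX8W") return(TRUE)
      !any(hits$start[i] <= rr$end & hits$end[i] >= rr$start)
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(rr) && rr$start[1] > 1) {
    hits <- rbind(data.frame(motif = "transit_region", start = 1L,
                             end = rr$start[1] - 1L, stringsAsFactors = FALSE),
                  hits)
  }
  hits <- hits[order(hits$start, hits$motif), , drop = FALSE]
  hits$matched <- substr(rep(protein, nrow(hits)), hits$start, hits$end)
  rownames(hits) <- NULL
  hits
}
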