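.panel_matrix <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 2) stop("at least 2 sequences are required")
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("sequences must have equal length (filter group-defining InDels first)")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  attr(m, "valid") <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  m
}

#' Per-site nucleotide diversity (pi)
#'
#' The average number of nucleotide differences per site between two
#' sequences, averaged over all n(n-1)/2 unordered pairs. Sites carrying a
#' gap or ambiguity code are treated as missing: under the default
#' `"pairwise"` deletion policy each pair is compared over its mutually
#' non-missing sites; under `"complete"` deletion, columns with any missing
#' value are dropped globally before comparison.
#'
#' @param seqs Character vector of equal-length sequences (n >= 2).
#' @param policy Missing-data policy, `"pairwise"` (default) or
#'   `"complete"`.
#' @return pi (dimensionless, per site).
#' @export
nucleotide_diversity <- function(seqs, policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  m <- .panel_matrix(seqs)
  valid <- attr(m, "valid")
  if (policy == "complete") {
    keep <- colSums(!valid) == 0
    if (!any(keep)) stop("no comparable sites after complete deletion")
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) stop("a sequence pair shares no comparable sites")
      tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Haplotype count and haplotype diversity (Hd)
#'
#' Haplotypes are distinct sequences (exact string equality); Hd is the
#' unbiased probability that two randomly chosen haplotypes differ,
#' `n/(n-1) * (1 - sum(p_i^2))` with `p_i` the haplotype frequencies. A panel
#' of two distinct sequences gives Hd = 1 exactly.
#'
#' @param seqs Character vector of sequences (n >= 2).
#' @return List with `n_haplotypes` and `hd`.
#' @export
haplotype_diversity <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n < 2) stop("at least 2 sequences are required")
  p <- as.numeric(table(seqs)) / n
  list(n_haplotypes = length(p), hd = n / (n - 1) * (1 - sum(p^2)))
}

#' Count segregating sites
#'
#' Number of alignment columns with at least two distinct non-missing bases.
#'
#' @param seqs Character vector of equal-length sequences (n >= 2).
#' @return Integer count S.
#' @export
segregating_sites <- function(seqs) {
  m <- .panel_matrix(seqs)
  valid <- attr(m, "valid")
  sum(vapply(seq_len(ncol(m)), function(k) {
    length(unique(m[valid[, k], k])) >= 2
  }, logical(1)))
}

#' Within-group diversity summary
#'
#' Computes n, sites used, segregating sites, pi, haplotype count and Hd for
#' one haplotype panel. In summary printing, pi is conventionally reported to
#' 3 decimals and Hd to 2; this function returns full precision.
#'
#' @param seqs Character vector of equal-length sequences (n >= 2).
#' @param group Group label recorded in the output row.
#' @param policy Missing-data policy passed to [nucleotide_diversity()].
#' @return One-row data frame with columns `group`, `n`, `L`, `S`, `pi`,
#'   `n_haplotypes`, `hd`, `policy`.
#' @export
diversity_stats <- function(seqs, group = "panel",
                            policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  m <- .panel_matrix(seqs)
  valid <- attr(m, "valid")
  L <- if (policy == "complete") sum(colSums(!valid) == 0) else ncol(m)
  hd <- haplotype_diversity(seqs)
  data.frame(group = group, n = length(seqs), L = L,
             S = segregating_sites(seqs),
             pi = nucleotide_diversity(seqs, policy),
             n_haplotypes = hd$n_haplotypes, hd = hd$hd,
             policy = policy, stringsAsFactors = FALSE)
}
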