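#' Min-max normalize a series to [0, 1]
#'
#' Gray relational analysis preprocessing: `(x - min) / (max - min)`. This is
#' the scaling that makes binary 0/1 site-incidence vectors commensurate with
#' continuous emission series. Constant series carry no relational
#' information and are rejected (callers exclude them upstream).
#'
#' @param x Numeric vector, length >= 2.
#' @return Vector in [0, 1].
#' @export
normalize_series <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant series cannot be normalized")
  (x - rng[1]) / (rng[2] - rng[1])
}

.normalize_fun <- function(method) {
  switch(method,
         minmax = normalize_series,
         mean = function(x) {
           if (length(x) < 2) stop("series must have length >= 2")
           m <- mean(x)
           if (m == 0) stop("zero-mean series cannot be mean-normalized")
           x / m
         },
         stop("unknown normalization: ", method))
}

#' Gray relational degree of comparison series against a reference
#'
#' Deng's gray relational analysis. After normalizing the reference and each
#' comparison series, the absolute deviations `Delta_i(k)` are formed; with
#' global extrema `Dmin`/`Dmax` over all i and k, the gray relational
#' coefficient at each point is `(Dmin + rho * Dmax) / (Delta_i(k) + rho *
#' Dmax)` and the gray relational degree (GRD) of series i is the mean
#' coefficient over points. GRD lies in (0, 1], equals 1 exactly for a
#' comparison identical to the reference, and is non-decreasing in the
#' distinguishing coefficient `rho`.
#'
#' @param reference Numeric reference series.
#' @param comparisons Named list of numeric series (or a matrix with series
#'   in columns), each the same length as `reference`.
#' @param rho Distinguishing coefficient in (0, 1]; conventional default 0.5.
#' @param normalize `"minmax"` (default) or `"mean"`.
#' @return Named numeric vector of GRDs, one per comparison series.
#' @examples
#' grd(c(1, 2, 3), list(rev = c(3, 2, 1)))  # 5/9
#' @export
grd <- function(reference, comparisons, rho = 0.5,
                normalize = c("minmax", "mean")) {
  normalize <- match.arg(normalize)
  if (is.matrix(comparisons) || is.data.frame(comparisons)) {
    comparisons <- as.list(as.data.frame(comparisons))
  }
  if (!length(comparisons)) stop("at least one comparison series is required")
  n <- length(reference)
  if (n < 2) stop("series must have length >= 2")
  if (any(vapply(comparisons, length, integer(1)) != n)) {
    stop("all comparison series must have the same length as the reference")
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]")
  }
  nf <- .normalize_fun(normalize)
  ref <- nf(reference)
  delta <- vapply(comparisons, function(cmp) abs(ref - nf(cmp)), numeric(n))
  delta <- matrix(delta, nrow = n)
  dmin <- min(delta)
  dmax <- max(delta)
  if (dmax == 0) {
    # every comparison coincides with the reference after normalization
    return(setNames(rep(1, length(comparisons)), names(comparisons)))
  }
  xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  setNames(colMeans(xi), names(comparisons))
}

#' Gray relational association of polymorphic sites with emissions
#'
#' For each volatile compound (reference series: its emission across
#' cultivars) computes the GRD of every polymorphic-site incidence vector
#' (comparison series). Constant site columns carry no information and are
#' excluded with a message; cultivar ordering must agree between the two
#' matrices.
#'
#' @param sites Cultivar x site incidence matrix (0/1), cultivar row names.
#' @param emissions Cultivar x compound matrix of non-negative emissions
#'   (ug/g or relative percent), same rows as `sites`.
#' @param rho Distinguishing coefficient, see [grd()].
#' @param normalize Series normalization, see [grd()].
#' @return Object of class `gra_result`: `grd` (site x compound matrix),
#'   `rho`, `normalize`, `dropped_sites`.
#' @export
gra <- function(sites, emissions, rho = 0.5, normalize = c("minmax", "mean")) {
  normalize <- match.arg(normalize)
  sites <- as.matrix(sites)
  emissions <- as.matrix(emissions)
  if (nrow(sites) != nrow(emissions)) {
    stop("sites and emissions must cover the same cultivars")
  }
  if (!is.null(rownames(sites)) && !is.null(rownames(emissions)) &&
      !identical(rownames(sites), rownames(emissions))) {
    stop("cultivar ordering differs between sites and emissions")
  }
  if (any(emissions < 0)) stop("emissions must be non-negative")
  const <- apply(sites, 2, function(x) min(x) == max(x))
  if (any(const)) {
    message("excluding ", sum(const), " constant site column(s): ",
            paste(colnames(sites)[const], collapse = ", "))
  }
  sites <- sites[, !const, drop = FALSE]
  if (ncol(sites) == 0) stop("no polymorphic site columns remain")
  const_e <- apply(emissions, 2, function(x) min(x) == max(x))
  if (any(const_e)) {
    message("excluding ", sum(const_e), " constant compound column(s): ",
            paste(colnames(emissions)[const_e], collapse = ", "))
    emissions <- emissions[, !const_e, drop = FALSE]
  }
  if (ncol(emissions) == 0) stop("no variable compound columns remain")
  site_list <- as.list(as.data.frame(sites))
  g <- vapply(seq_len(ncol(emissions)), function(j) {
    grd(emissions[, j], site_list, rho = rho, normalize = normalize)
  }, numeric(ncol(sites)))
  g <- matrix(g, nrow = ncol(sites),
              dimnames = list(colnames(sites), colnames(emissions)))
  structure(list(grd = g, rho = rho, normalize = normalize,
                 dropped_sites = names(const)[const]),
            class = "gra_result")
}

#' Rank sites by gray relational degree for one compound
#'
#' @param result A `gra_result`.
#' @param compound Compound (column) name.
#' @return Data frame with columns `site`, `grd`, `rank`, ordered by GRD
#'   descending with ties broken by site label.
#' @export
rank_sites <- function(result, compound) {
  stopifnot(inherits(result, "gra_result"))
  if (!compound %in% colnames(result$grd)) {
    stop("unknown compound: ", compound)
  }
  g <- setNames(result$grd[, compound], rownames(result$grd))
  ord <- order(-g, names(g))
  data.frame(site = names(g)[ord], grd = unname(g[ord]),
             rank = seq_along(g), stringsAsFactors = FALSE)
}
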