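#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = 1e9 * read_count / (library_size * transcript_len_nt)`.
#'
#' @param read_count Non-negative read counts (vectorized).
#' @param transcript_len_nt Transcript lengths in nt, > 0.
#' @param library_size Mapped-read library sizes, > 0.
#' @return Numeric RPKM values.
#' @examples
#' rpkm(100, 500, 1e6)  # 200
#' @export
rpkm <- function(read_count, transcript_len_nt, library_size) {
  if (any(transcript_len_nt <= 0)) stop("transcript length must be > 0")
  if (any(library_size <= 0)) stop("library size must be > 0")
  1e9 * read_count / (library_size * transcript_len_nt)
}

#' Type ST-NAT mapping relationships
#'
#' Labels each pair of a cis catalog from the degrees of its endpoints in the
#' bipartite ST-NAT graph: `n:n` when the ST maps to two or more NATs and the
#' NAT maps to two or more STs; `1:n` when only the ST side is multiple;
#' `n:1` when only the NAT side is; otherwise `1:1`. Labels partition the
#' pair set and are invariant to input order.
#'
#' @param pairs A `CisPairs` (or `TransPairs`) table, or any table with
#'   `st_id` and `nat_id` columns.
#' @return A `DataFrame` with columns `st_id`, `nat_id`, `relation`.
#' @export
relationshipType <- function(pairs) {
  st <- as.character(pairs$st_id); nat <- as.character(pairs$nat_id)
  key <- !duplicated(paste0(st, "\r", nat))
  st <- st[key]; nat <- nat[key]
  st_deg <- table(st)[st]      # NATs per ST (rows are unique pairs)
  nat_deg <- table(nat)[nat]   # STs per NAT
  relation <- ifelse(st_deg >= 2L & nat_deg >= 2L, "n:n",
              ifelse(st_deg >= 2L, "1:n",
              ifelse(nat_deg >= 2L, "n:1", "1:1")))
  DataFrame(st_id = st, nat_id = nat, relation = unname(relation))
}

#' Stage-presence Venn partition over three stages
#'
#' A transcript is present in a stage when its abundance is at or above
#' `cutoff` (RPKM cutoff value of 2, inclusive). Every id present in at
#' least one stage falls in exactly one of the 7 exclusive Venn regions;
#' region counts always sum to the expressed total.
#'
#' @param expr A [StageExpression-class] with exactly 3 stages.
#' @param ids Transcript ids to partition (must be matrix rows).
#' @param cutoff Presence cutoff, inclusive (default 2).
#' @return A list with `counts` (named integer vector over the 7 regions,
#'   names like `"M"`, `"M&P"`, `"M&P&FB"` built from the stage labels),
#'   `total_expressed`, and `presence` (logical id-by-stage matrix).
#' @export
vennPartition <- function(expr, ids = rownames(exprValues(expr)), cutoff = 2.0) {
  stopifnot(methods::is(expr, "StageExpression"))
  v <- exprValues(expr)
  if (ncol(v) != 3L) stop("venn partition is defined for exactly 3 stages")
  if (!all(ids %in% rownames(v))) stop("unknown transcript id(s)")
  m <- v[ids, , drop = FALSE] >= cutoff
  st <- colnames(v)
  regions <- c(st[1], st[2], st[3],
               paste(st[1], st[2], sep = "&"), paste(st[1], st[3], sep = "&"),
               paste(st[2], st[3], sep = "&"), paste(st[1], st[2], st[3], sep = "&"))
  lab <- apply(m, 1L, function(p) paste(st[p], collapse = "&"))
  counts <- stats::setNames(integer(7L), regions)
  tab <- table(lab[lab != ""])
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, total_expressed = sum(lab != ""), presence = m)
}

#' Normalize a per-stage expression profile
#'
#' With `log = TRUE` values are first transformed as `log2(x + 1)`; the
#' profile is then divided by its mean (`mode = "mean"`, as used when
#' comparing profiles across technologies) or by its maximum
#' (`mode = "max"`, as used for relative stage profiles).
#'
#' @param values Non-negative per-stage expression, at least one > 0.
#' @param mode `"mean"` or `"max"`.
#' @param log Apply the log2(x+1) transform first (default `TRUE`).
#' @return Numeric vector of relative levels (mean exactly 1 for
#'   `mode = "mean"`, max exactly 1 for `mode = "max"`).
#' @export
normalizeProfile <- function(values, mode = c("mean", "max"), log = TRUE) {
  mode <- match.arg(mode)
  if (any(values < 0)) stop("expression values must be >= 0")
  if (all(values == 0)) stop("all-zero profile cannot be normalized")
  x <- if (log) log2(values + 1) else values
  denom <- if (mode == "mean") mean(x) else max(x)
  if (denom == 0) stop("degenerate profile: zero ", mode, " after transform")
  x / denom
}

#' t statistic of a Pearson correlation coefficient
#'
#' `t = r / sqrt((1 - r^2) / (N - 2))`, the test statistic of the null
#' `r = 0` with `N - 2` degrees of freedom; `+/-Inf` for a perfect
#' correlation.
#'
#' @param r Sample correlation in \[-1, 1\].
#' @param N Sample size, at least 3.
#' @return The t statistic.
#' @examples
#' correlationT(0.8, 5)  # 2.309
#' @export
correlationT <- function(r, N) {
  stopifnot(abs(r) <= 1, N >= 3)
  ifelse(abs(r) >= 1 - 1e-12, sign(r) * Inf, r / sqrt((1 - r^2) / (N - 2)))
}

#' Pearson correlation with a directional significance test
#'
#' Computes the sample Pearson correlation `r` of two profiles and its test
#' statistic `t = r / sqrt((1 - r^2) / (N - 2))` with `N - 2` degrees of
#' freedom under the null `r = 0`. The p-value is directional by default
#' (one-tailed in the direction of the observed `r`, so `r = 0` gives
#' `p = 0.5`); `alternative = "two.sided"` doubles it. A numerically perfect
#' correlation (`|r| = 1`) is reported with `t = +/-Inf` and `p = 0`.
#' Symmetric in its arguments.
#'
#' @param x,y Numeric profiles of equal length `N >= 3`, each with nonzero
#'   variance (an error otherwise, never a silent `NaN`).
#' @param alternative `"directional"` (default) or `"two.sided"`.
#' @return A one-row `DataFrame`: `r`, `N`, `t`, `p`.
#' @examples
#' pearsonWithSignificance(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
#' @export
pearsonWithSignificance <- function(x, y,
                                    alternative = c("directional", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("profiles must have equal length")
  N <- length(x)
  if (N < 3L) stop("need at least N = 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance profile: correlation undefined")
  r <- stats::cor(x, y)
  t <- correlationT(r, N)
  if (is.infinite(t)) {
    p <- 0
  } else {
    p <- stats::pt(abs(t), df = N - 2, lower.tail = FALSE)
    if (alternative == "two.sided") p <- 2 * p
  }
  DataFrame(r = r, N = N, t = t, p = p)
}

#' Correlate ST and NAT expression profiles over a pair catalog
#'
#' For every pair, correlates the (optionally log2(x+1)-transformed) stage
#' profiles of the ST and the NAT with [pearsonWithSignificance()]. Pairs
#' whose members are missing from the matrix or have a zero-variance profile
#' are reported with `NA` statistics rather than dropped.
#'
#' @param pairs Table with `st_id` and `nat_id` columns.
#' @param expr A [StageExpression-class].
#' @param log Log-transform profiles first (default `TRUE`).
#' @param alternative Passed to [pearsonWithSignificance()].
#' @return A `DataFrame`: `st_id`, `nat_id`, `r`, `N`, `t`, `p`.
#' @export
correlatePairs <- function(pairs, expr, log = TRUE,
                           alternative = c("directional", "two.sided")) {
  alternative <- match.arg(alternative)
  v <- exprValues(expr)
  if (log) v <- log2(v + 1)
  n <- nrow(pairs)
  r <- t <- p <- rep(NA_real_, n)
  N <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    si <- as.character(pairs$st_id[i]); ni <- as.character(pairs$nat_id[i])
    if (!si %in% rownames(v) || !ni %in% rownames(v)) next
    xs <- v[si, ]; ys <- v[ni, ]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    res <- pearsonWithSignificance(xs, ys, alternative = alternative)
    r[i] <- res$r; N[i] <- res$N; t[i] <- res$t; p[i] <- res$p
  }
  DataFrame(st_id = as.character(pairs$st_id),
            nat_id = as.character(pairs$nat_id),
            r = r, N = N, t = t, p = p)
}

#' Simulate profile pairs with a planted correlation
#'
#' Draws `n_pairs` standard bivariate normal profile pairs of length `N`
#' with population correlation `rho`; used to check that the correlation
#' estimator recovers a planted sign and magnitude.
#'
#' @param n_pairs Number of pairs.
#' @param rho Planted population correlation in \[-1, 1\].
#' @param N Points per profile (default 3 stages).
#' @return A list of two `n_pairs` x `N` matrices, `x` and `y`.
#' @export
simulateCorrelatedProfiles <- function(n_pairs, rho, N = 3L) {
  stopifnot(abs(rho) <= 1)
  x <- matrix(stats::rnorm(n_pairs * N), n_pairs, N)
  e <- matrix(stats::rnorm(n_pairs * N), n_pairs, N)
  y <- rho * x + sqrt(1 - rho^2) * e
  list(x = x, y = y)
}
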