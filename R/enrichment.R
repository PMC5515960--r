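#' Upper-tail hypergeometric probability, computed in log space
#'
#' The probability of observing `x_observed` or more STs annotated to a
#' functional category when `n_sts` STs are drawn without replacement from
#' `total_genes` genes of which `n_in_term` carry the category:
#' `P(X >= x) = sum_i C(n, i) C(m, N - i) / C(n + m, N)` for `i` from
#' `x` to `min(n, N)`, with `n = n_in_term`, `m = total_genes - n_in_term`,
#' `N = n_sts`. Terms are accumulated as `lchoose` sums with a log-sum-exp,
#' so tiny tails (p < 1e-300) stay finite. `inclusive = FALSE` gives the
#' strict tail `P(X > x)`.
#'
#' @param total_genes Number of genes in the genome (population).
#' @param n_in_term Genes annotated to the term (successes).
#' @param n_sts Number of STs tested (draws).
#' @param x_observed Observed STs annotated to the term (vectorized).
#' @param inclusive Include the observed count in the tail (default `TRUE`).
#' @return Probability in (0, 1].
#' @examples
#' hypergeomUpperTail(10, 4, 5, 3)  # 66/252
#' @export
hypergeomUpperTail <- function(total_genes, n_in_term, n_sts, x_observed,
                               inclusive = TRUE) {
  if (n_in_term > total_genes || n_sts > total_genes)
    stop("impossible counts: term size and draws must not exceed the population")
  if (any(x_observed > pmin(n_in_term, n_sts)) || any(x_observed < 0))
    stop("impossible counts: x_observed outside [0, min(n_in_term, n_sts)]")
  m <- total_genes - n_in_term
  one <- function(x) {
    if (!inclusive) x <- x + 1
    hi <- min(n_in_term, n_sts)
    if (x > hi) return(0)
    i <- x:hi
    lp <- lchoose(n_in_term, i) + lchoose(m, n_sts - i) - lchoose(total_genes, n_sts)
    mx <- max(lp)
    # clamp away float drift: the tail is a probability in (0, 1]
    max(min(exp(mx + log(sum(exp(lp - mx)))), 1), .Machine$double.xmin)
  }
  vapply(x_observed, one, numeric(1))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up q-values with monotonicity enforcement, input order preserved.
#' Always `q >= p` element-wise.
#'
#' @param pvalues Probabilities in (0, 1].
#' @return q-values in input order.
#' @export
bhFdr <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric functional-category enrichment of STs
#'
#' Tests every annotated category for over-representation among the STs that
#' have NATs, against a genome of `total_genes` genes. Unannotated STs
#' contribute to the number of draws `N` but to no category. FDR correction
#' runs over all tested categories; the `min_mapped` rule (at least 4 mapped
#' STs by default) is applied afterwards as a reporting filter.
#'
#' @param st_ids Character vector of ST gene ids (the draws; `N` defaults to
#'   its length — the number of all STs, not only the annotated ones).
#' @param annotation Either a `data.frame` with columns `gene_id`, `term_id`
#'   (optionally `term_name`) or a named list mapping term id to a character
#'   vector of gene ids.
#' @param total_genes Number of genes in the genome; must be at least the
#'   number of STs.
#' @param min_mapped Report filter: minimum STs mapped to a term (default 4).
#' @param n_sts Override for the number of draws `N` (e.g. to use only the
#'   annotated subset).
#' @return An `EnrichmentResults` table sorted by (q, p): `term`,
#'   `term_name`, `n_genome`, `m`, `N`, `x`, `p`, `q`.
#' @export
enrich <- function(st_ids, annotation, total_genes, min_mapped = 4,
                   n_sts = length(unique(st_ids))) {
  st_ids <- unique(as.character(st_ids))
  if (total_genes < length(st_ids))
    stop("total_genes must be at least the number of STs")
  if (is.data.frame(annotation) || methods::is(annotation, "DataFrame")) {
    term_genes <- split(as.character(annotation$gene_id),
                        as.character(annotation$term_id))
    term_names <- if ("term_name" %in% colnames(annotation))
      vapply(split(as.character(annotation$term_name),
                   as.character(annotation$term_id)), `[`, "", 1L)
    else NULL
  } else {
    term_genes <- annotation
    term_names <- NULL
  }
  term_genes <- lapply(term_genes, unique)
  terms <- names(term_genes)
  n_genome <- vapply(term_genes, length, 0L)
  x <- vapply(term_genes, function(g) sum(st_ids %in% g), 0L)
  p <- vapply(seq_along(terms), function(i)
    hypergeomUpperTail(total_genes, n_genome[i], n_sts, x[i]), numeric(1))
  q <- bhFdr(p)
  df <- DataFrame(term = terms,
                  term_name = if (is.null(term_names)) NA_character_
                              else unname(term_names[terms]),
                  n_genome = unname(n_genome), m = total_genes - unname(n_genome),
                  N = n_sts, x = unname(x), p = unname(p), q = unname(q))
  df <- df[df$x >= min_mapped, , drop = FALSE]
  df <- df[order(df$q, df$p), , drop = FALSE]
  rownames(df) <- NULL
  methods::new("EnrichmentResults", df)
}
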