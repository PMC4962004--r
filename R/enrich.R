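#' Term enrichment of a differentially expressed gene set
#'
#' For each term with at least one universe gene, the upper-tail
#' hypergeometric probability `P(X >= k)` of observing `k` DE genes in
#' the term, given `K` universe genes in the term, `n` DE genes and a
#' universe of size `N`; Benjamini-Hochberg adjustment across all tested
#' terms ([bh_adjust()], the same implementation as the DE stage); a term
#' is enriched when the adjusted p falls strictly below `p_cutoff`.
#'
#' When `weights` are supplied (see [length_bias_weights()]) and are not
#' all equal, the null is tilted by weighted sampling without
#' replacement and the p-value is estimated by Monte Carlo simulation
#' (`nsim` draws, add-one correction); equal weights use the exact
#' hypergeometric path.
#'
#' @param de_genes character vector of DE gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param term_map data.frame with columns `gene`, `term`.
#' @param p_cutoff adjusted-p cutoff (default 0.05).
#' @param weights optional per-universe-gene selection weights (named or
#'   in `universe` order).
#' @param nsim Monte Carlo draws for the weighted mode.
#' @return data.frame: `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `enriched`, ordered by `p`.
#' @export
enrich_terms <- function(de_genes, universe, term_map, p_cutoff = 0.05,
                         weights = NULL, nsim = 20000) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    abort("DE gene '%s' not in universe", setdiff(de_genes, universe)[1])
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  terms <- split(unique(term_map[c("gene", "term")])$gene,
                 unique(term_map[c("gene", "term")])$term)
  N <- length(universe); n <- length(de_genes)
  use_weights <- !is.null(weights)
  if (use_weights) {
    if (!is.null(names(weights))) weights <- weights[universe]
    if (length(weights) != N) abort("need one weight per universe gene")
    if (max(weights) - min(weights) < 1e-12) use_weights <- FALSE
  }
  sims <- NULL
  if (use_weights) {
    # presampled null DE sets shared across terms
    sims <- replicate(nsim, sample(universe, n, prob = weights), simplify = FALSE)
  }
  rows <- lapply(names(terms), function(t) {
    members <- terms[[t]]
    K <- length(members); k <- sum(de_genes %in% members)
    p <- if (!use_weights) {
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      exc <- sum(vapply(sims, function(s) sum(s %in% members) >= k,
                        logical(1)))
      (exc + 1) / (nsim + 1)
    }
    data.frame(term = t, k = k, K = K, n = n, N = N, p = min(1, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$enriched <- out$p_adj < p_cutoff
  out[order(out$p, out$term), , drop = FALSE]
}

#' Length-bias selection weights
#'
#' A monotone probability-weighting function obtained by isotonic
#' regression of DE status on gene length: long genes that are selected
#' more often receive proportionally larger weights, which can then tilt
#' the enrichment null ([enrich_terms()]'s weighted mode).  Weights are
#' non-negative, non-decreasing in length, invariant to rescaling all
#' lengths, and uniform when DE status carries no length trend -- in
#' which case the weighted null coincides exactly with the plain
#' hypergeometric.
#'
#' @param gene_lengths positive numeric vector.
#' @param de_flags logical vector, same length.
#' @return numeric weights (floored at 1e-6), one per gene, in input
#'   order.
#' @export
length_bias_weights <- function(gene_lengths, de_flags) {
  if (any(gene_lengths <= 0)) abort("gene lengths must be positive")
  if (length(gene_lengths) != length(de_flags))
    abort("lengths and flags differ in length")
  ord <- order(gene_lengths)
  fit <- isoreg(gene_lengths[ord], as.numeric(de_flags[ord]))
  w <- numeric(length(gene_lengths))
  w[ord] <- fit$yf
  pmax(w, 1e-6)
}
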