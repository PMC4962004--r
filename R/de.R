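#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: per-sample median of the ratios to the
#' row-wise geometric mean, computed over rows with no zero count.
#' All-zero rows are excluded.
#'
#' @param counts matrix, transcripts x samples.
#' @return named numeric vector of size factors (geometric mean 1 when
#'   computable; all 1 when no usable rows exist).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  use <- rowSums(counts == 0) == 0
  if (!any(use)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  lc <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(sweep(lc, 1, geo)), 2, median)
  setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion with mean-trend shrinkage
#'
#' Per transcript, the within-group method-of-moments estimate
#' `alpha = (Var - mu) / mu^2` is pooled across groups (floored at 0) and
#' shrunk toward a mean-trended common value, then floored at 0.  The
#' trend is a binned ratio-of-means fit: transcripts are binned by log
#' mean and each bin's common dispersion is `sum(Var - mu) / sum(mu^2)`
#' over the bin, interpolated between bin centres (ratio-of-means rather
#' than mean-of-ratios keeps the trend nearly unbiased at two samples per
#' group, where per-transcript estimates are individually useless).  The
#' shrinkage weight on the raw estimate is `df / (df + prior_df)` with
#' `df` the residual degrees of freedom, the empirical-Bayes-style
#' weighting of the established differential-expression packages: at two
#' samples per group the raw estimate gets weight 2/12, which keeps the
#' downstream exact test calibrated (equal weighting leaves too many
#' transcripts with halved dispersion and an anti-conservative null);
#' with many replicates the raw estimate dominates.
#'
#' @param counts matrix of (size-factor-normalised) counts.
#' @param groups factor/character vector of group labels, one per column.
#' @param prior_df prior degrees of freedom of the trend (default 10).
#' @return numeric vector of per-transcript dispersions.
#' @export
estimate_dispersion <- function(counts, groups, prior_df = 10) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2)) abort("each group needs at least 2 samples")
  per_group <- lapply(unique(groups), function(g) {
    m <- counts[, groups == g, drop = FALSE]
    list(mu = rowMeans(m), v = apply(m, 1, var), n = ncol(m))
  })
  num <- Reduce(`+`, lapply(per_group, function(p) (p$v - p$mu) * (p$n - 1)))
  den <- Reduce(`+`, lapply(per_group, function(p) p$mu^2 * (p$n - 1)))
  raw <- ifelse(den > 0, pmax(0, num / den), 0)
  mu_all <- rowMeans(counts)
  ok <- mu_all > 0
  trend <- rep(0, nrow(counts))
  if (sum(ok) >= 20) {
    bins <- cut(log(mu_all[ok]), breaks = 12)
    tr_bin <- tapply(seq_len(sum(ok)), bins, function(i)
      max(0, sum(num[ok][i]) / sum(den[ok][i])))
    mid <- tapply(log(mu_all[ok]), bins, mean)
    good <- !is.na(tr_bin)
    if (sum(good) >= 2) {
      trend[ok] <- stats::approx(mid[good], tr_bin[good],
                                 xout = log(mu_all[ok]), rule = 2,
                                 ties = mean)$y
    } else {
      trend[ok] <- max(0, sum(num[ok]) / sum(den[ok]))
    }
  } else if (any(ok)) {
    trend[ok] <- max(0, sum(num[ok]) / sum(den[ok]))
  }
  df_res <- sum(tab - 1L)
  w <- df_res / (df_res + prior_df)
  pmax(0, w * raw + (1 - w) * trend)
}

#' Exact conditional negative-binomial test for one transcript
#'
#' Size-factor-normalised counts are summed per group; under the
#' equal-mean null the two group sums are negative binomial and the test
#' conditions on their total, summing the probabilities of all outcomes
#' no more likely than the observed one (two-sided).  With dispersion 0
#' this reduces to the exact Poisson (binomial) conditional test.
#' All-zero transcripts give p = 1 by convention.
#'
#' @param counts_g1,counts_g2 integer count vectors for the two groups.
#' @param size_factors_g1,size_factors_g2 per-sample size factors
#'   (default 1).
#' @param dispersion negative-binomial dispersion (>= 0).
#' @return two-sided p-value in (0, 1].
#' @export
nb_test <- function(counts_g1, counts_g2, size_factors_g1 = NULL,
                    size_factors_g2 = NULL, dispersion = 0) {
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (is.null(size_factors_g1)) size_factors_g1 <- rep(1, length(counts_g1))
  if (is.null(size_factors_g2)) size_factors_g2 <- rep(1, length(counts_g2))
  norm1 <- counts_g1 / size_factors_g1
  norm2 <- counts_g2 / size_factors_g2
  y1 <- round(sum(norm1)); y2 <- round(sum(norm2))
  s <- y1 + y2
  if (s == 0) return(1)
  n1 <- length(counts_g1); n2 <- length(counts_g2)
  mu <- s / (n1 + n2)            # common per-sample mean under the null
  y <- 0:s
  if (dispersion > 0) {
    f <- dnbinom(y, size = n1 / dispersion, mu = n1 * mu) *
      dnbinom(s - y, size = n2 / dispersion, mu = n2 * mu)
  } else {
    f <- dpois(y, n1 * mu) * dpois(s - y, n2 * mu)
  }
  tot <- sum(f)
  if (tot <= 0) return(1)
  p <- sum(f[f <= f[y1 + 1L] * (1 + 1e-8)]) / tot
  min(1, max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped
#' at 1.  This wrapper is the single BH implementation shared by the
#' differential-expression and enrichment stages.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    abort("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Two-group negative-binomial differential expression
#'
#' Runs [estimate_dispersion()] and [nb_test()] for every transcript,
#' adjusts p-values with [bh_adjust()], and reports per-group mean
#' normalised counts, the log2 fold change (group2 over group1, computed
#' with a pseudocount of 1 fragment for display only), dispersion, p, q
#' and the call direction.
#'
#' @param counts matrix, transcripts x samples.
#' @param groups group label per column (exactly two groups).
#' @param sf optional size factors; computed by [size_factors()] when
#'   `NULL`.
#' @param q_threshold significance cutoff on q (strict `<`; default
#'   0.05).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `mean_g1`, `mean_g2`, `log2fc`, `dispersion`, `p`, `q`,
#'   `direction` in `up`/`down`/`ns`.
#' @export
run_de <- function(counts, groups, sf = NULL, q_threshold = 0.05) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) abort("exactly two groups required")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  disp <- estimate_dispersion(norm, groups)
  g1 <- groups == lv[1]; g2 <- groups == lv[2]
  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_test(counts[i, g1], counts[i, g2], sf[g1], sf[g2], disp[i]),
    numeric(1))
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  res <- data.frame(
    transcript_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_g1 = m1, mean_g2 = m2,
    log2fc = log2((m2 + 1) / (m1 + 1)),
    dispersion = disp, p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
  call_de(res, q_threshold)$results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differential expression at a q cutoff
#'
#' Adds/updates the `direction` column (`up` iff `q < q_threshold` and
#' `log2fc > 0`, `down` iff `q < q_threshold` and `log2fc < 0`, otherwise
#' `ns`; the cutoff is strict) and returns summary counts.
#'
#' @param results data.frame with at least `log2fc` and `q`.
#' @param q_threshold cutoff (default 0.05).
#' @return list with `results` (direction filled in) and `summary`
#'   (`up`, `down`, `total`).
#' @export
call_de <- function(results, q_threshold = 0.05) {
  sig <- results$q < q_threshold
  results$direction <- ifelse(!sig, "ns",
                              ifelse(results$log2fc > 0, "up", "down"))
  up <- sum(results$direction == "up")
  down <- sum(results$direction == "down")
  list(results = results,
       summary = c(up = up, down = down, total = up + down))
}
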