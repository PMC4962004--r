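#' Thyroid weight index
#'
#' Thyroid gland weight divided by body weight, in g/kg.
#'
#' @param thyroid_weight_g thyroid weight in grams.
#' @param body_weight_kg body weight in kilograms.
#' @return index in g/kg (vectorised).
#' @examples
#' round(thyroid_index(3.20, 29.33), 3)  # 0.109
#' @export
thyroid_index <- function(thyroid_weight_g, body_weight_kg) {
  if (any(thyroid_weight_g <= 0) || any(body_weight_kg <= 0))
    abort("weights must be positive")
  thyroid_weight_g / body_weight_kg
}

#' Two-sample Student's t-test from group summaries
#'
#' Pooled-df Student form computable from summary data alone:
#' `t = (m2 - m1) / sqrt(sem1^2 + sem2^2)` (via the identity
#' `s / sqrt(n) = SEM`), `df = n1 + n2 - 2`, two-sided p.  Antisymmetric
#' in group order: swapping groups flips the sign of t and leaves p
#' unchanged.
#'
#' @param mean1,sem1,n1 first group summary (mean, standard error of the
#'   mean, group size).
#' @param mean2,sem2,n2 second group summary.
#' @return list with `t`, `df`, `p`.
#' @examples
#' ttest_summary(29.33, 0.88, 3, 47.07, 1.93, 3)$p  # ~0.001
#' @export
ttest_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) abort("group sizes must be >= 2")
  if (sem1 < 0 || sem2 < 0) abort("SEMs must be non-negative")
  se <- sqrt(sem1^2 + sem2^2)
  df <- n1 + n2 - 2
  if (se == 0) return(list(t = 0, df = df, p = 1))
  t <- (mean2 - mean1) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Relative expression by the 2^(-DDCt) method
#'
#' `DDCt = (Ct_target - Ct_reference)_test - (Ct_target -
#' Ct_reference)_calibrator`; fold change `= 2^(-DDCt)`.
#'
#' @param ct_target_test,ct_ref_test Ct cycles in the test condition.
#' @param ct_target_cal,ct_ref_cal Ct cycles in the calibrator
#'   condition.
#' @return list with `ddct` and `fold`.
#' @examples
#' ddct(25, 20, 26, 20)$fold  # DDCt = -1 -> fold 2
#' @export
ddct <- function(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal) {
  if (!all(is.finite(c(ct_target_test, ct_ref_test, ct_target_cal,
                       ct_ref_cal))))
    abort("Ct values must be finite")
  d <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  list(ddct = d, fold = 2^(-d))
}

#' Group comparisons from a phenotype summary table
#'
#' Runs [ttest_summary()] for every trait of a summary table holding one
#' row per (trait, breed) with columns `trait`, `breed`, `mean`, `sem`,
#' `n` and exactly two breeds per trait.
#'
#' @param summary_df phenotype summary data.frame.
#' @return data.frame `trait`, `mean_1`, `mean_2`, `t`, `df`, `p`
#'   (breed order as first encountered in the table).
#' @export
phenotype_ttests <- function(summary_df) {
  out <- lapply(unique(summary_df$trait), function(tr) {
    s <- summary_df[summary_df$trait == tr, , drop = FALSE]
    if (nrow(s) != 2) abort("trait '%s' needs exactly two breed rows", tr)
    tt <- ttest_summary(s$mean[1], s$sem[1], s$n[1],
                        s$mean[2], s$sem[2], s$n[2])
    data.frame(trait = tr, mean_1 = s$mean[1], mean_2 = s$mean[2],
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene DDCt fold changes from a per-animal Ct table
#'
#' Averages Ct values per (gene, breed), computes the fold change of the
#' test breed against the calibrator breed by [ddct()], and attaches a
#' per-animal two-sample t-test on the per-animal DCt values.
#'
#' @param ct data.frame with columns `gene`, `breed`, `animal`,
#'   `ct_target`, `ct_reference`.
#' @param calibrator breed acting as calibrator (default the first
#'   breed in the table).
#' @return data.frame `gene`, `ddct`, `fold`, `p`.
#' @export
qpcr_fold_changes <- function(ct, calibrator = NULL) {
  breeds <- unique(ct$breed)
  if (length(breeds) != 2) abort("Ct table needs exactly two breeds")
  if (is.null(calibrator)) calibrator <- breeds[1]
  test <- setdiff(breeds, calibrator)
  out <- lapply(unique(ct$gene), function(g) {
    s <- ct[ct$gene == g, , drop = FALSE]
    dct <- s$ct_target - s$ct_reference
    d_test <- dct[s$breed == test]; d_cal <- dct[s$breed == calibrator]
    r <- ddct(mean(d_test), 0, mean(d_cal), 0)
    p <- tryCatch(stats::t.test(d_test, d_cal, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    data.frame(gene = g, ddct = r$ddct, fold = r$fold, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
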