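#' Pool transcript models from all samples and assemblers
#'
#' Models are deduplicated by structure key: exact intron-chain match on
#' the same chromosome and strand for multi-exon transcripts (terminal
#' exon ends may differ), exact exon interval for single-exon
#' transcripts.  Each distinct structure yields one support record whose
#' sample and assembler sets are the unions over occurrences; the
#' representative model is the occurrence with maximal coverage (ties
#' broken by lexicographically smallest transcript id).
#'
#' @param models transcript table (see [transcript_model()]); rows from
#'   any number of (sample, assembler) sets sharing one coordinate
#'   system.
#' @return a support-record `data.frame`: one row per structure with
#'   `key`, `chrom`, `strand`, `exons` (representative exon chain),
#'   `n_exons`, `length`, `coverage` (max over occurrences),
#'   `transcript_id`/`gene_id` of the representative, `samples` and
#'   `assemblers` (list columns of character vectors) and `n_occurrences`.
#' @examples
#' a <- transcript_model("t1", "g", "chr1", "+", cbind(c(0, 300), c(100, 400)),
#'                       sample_id = "S1", assembler = "A1", coverage = 5)
#' b <- transcript_model("t2", "g", "chr1", "+", cbind(c(10, 300), c(100, 420)),
#'                       sample_id = "S2", assembler = "A1", coverage = 9)
#' pool_models(rbind(a, b))  # one record, samples {S1,S2}
#' @export
pool_models <- function(models) {
  if (is.null(models) || nrow(models) == 0L)
    return(empty_support_records())
  keys <- structure_keys(models)
  groups <- split(seq_len(nrow(models)), keys)
  recs <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    m <- models[idx, , drop = FALSE]
    ord <- order(-m$coverage, m$transcript_id)
    rep_i <- ord[1L]
    df <- data.frame(key = k, chrom = m$chrom[rep_i], strand = m$strand[rep_i],
                     n_exons = nrow(m$exons[[rep_i]]),
                     length = tx_length(m$exons[[rep_i]]),
                     coverage = max(m$coverage),
                     transcript_id = m$transcript_id[rep_i],
                     gene_id = m$gene_id[rep_i],
                     n_occurrences = nrow(m), stringsAsFactors = FALSE)
    df$exons <- list(m$exons[[rep_i]])
    df$samples <- list(sort(unique(m$sample_id)))
    df$assemblers <- list(sort(unique(m$assembler)))
    df
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

empty_support_records <- function() {
  df <- data.frame(key = character(0), chrom = character(0),
                   strand = character(0), n_exons = integer(0),
                   length = integer(0), coverage = numeric(0),
                   transcript_id = character(0), gene_id = character(0),
                   n_occurrences = integer(0), stringsAsFactors = FALSE)
  df$exons <- list(); df$samples <- list(); df$assemblers <- list()
  df
}

#' Apply the reliability rule to pooled support records
#'
#' A structure is retained if it was found in at least two samples or in
#' both assemblers; everything else is dropped with reason `unreliable`.
#'
#' @param records support records from [pool_models()].
#' @param min_samples,n_assemblers rule parameters (defaults 2 and 2).
#' @return list with `retained` and `dropped` record tables and
#'   `drop_counts` (named integer vector).
#' @export
apply_reliability_rule <- function(records, min_samples = 2L,
                                   n_assemblers = 2L) {
  if (nrow(records) == 0L)
    return(list(retained = records, dropped = records,
                drop_counts = c(unreliable = 0L)))
  n_samp <- vapply(records$samples, length, integer(1))
  n_asm <- vapply(records$assemblers, length, integer(1))
  keep <- n_samp >= min_samples | n_asm >= n_assemblers
  list(retained = records[keep, , drop = FALSE],
       dropped = records[!keep, , drop = FALSE],
       drop_counts = c(unreliable = sum(!keep)))
}
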