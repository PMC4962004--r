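#' FPKM: fragments per kilobase of exon per million mapped fragments
#'
#' `FPKM[t, s] = counts[t, s] * 1e9 / (length[t] * lib_size[s])`.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths per-transcript exonic length in bases (named or in row
#'   order).
#' @param lib_sizes per-sample mapped fragments (named or in column
#'   order).
#' @return numeric matrix of FPKM values with the dimnames of `counts`.
#' @examples
#' compute_fpkm(matrix(500), lengths = 2000, lib_sizes = 1e7)  # 25
#' @export
compute_fpkm <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (!is.null(names(lib_sizes)) && !is.null(colnames(counts)))
    lib_sizes <- lib_sizes[colnames(counts)]
  if (length(lengths) != nrow(counts) || length(lib_sizes) != ncol(counts))
    abort("dimension mismatch between counts, lengths and lib_sizes")
  if (any(lengths <= 0)) abort("transcript lengths must be positive")
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  sweep(sweep(counts * 1e9, 1, lengths, "/"), 2, lib_sizes, "/")
}

#' Expression sets by breed
#'
#' A transcript is expressed in a breed if its FPKM exceeds
#' `expressed_threshold` in at least one sample of that breed.  The
#' expressed set splits additively into the shared set (both breeds) and
#' the two breed-specific sets.  The high-expression set contains
#' transcripts whose mean FPKM exceeds `high_threshold` in either breed.
#'
#' @param fpkm FPKM matrix, transcripts x samples.
#' @param breed_map named character vector mapping each sample (column)
#'   to a breed.
#' @param expressed_threshold FPKM strictly above this counts as
#'   expressed (default 0).
#' @param high_threshold mean-FPKM cutoff for the high-expression set
#'   (default 1000).
#' @return list with `expressed`, `shared`, per-breed specific sets (one
#'   per breed, named `specific_<breed>`), `high`, and a logical
#'   `membership` data.frame.
#' @export
expression_sets <- function(fpkm, breed_map, expressed_threshold = 0,
                            high_threshold = 1000) {
  fpkm <- as.matrix(fpkm)
  if (!all(colnames(fpkm) %in% names(breed_map)))
    abort("sample '%s' missing from breed_map",
          setdiff(colnames(fpkm), names(breed_map))[1])
  breeds <- unique(unname(breed_map[colnames(fpkm)]))
  expr_in <- vapply(breeds, function(b) {
    cols <- colnames(fpkm)[breed_map[colnames(fpkm)] == b]
    apply(fpkm[, cols, drop = FALSE] > expressed_threshold, 1, any)
  }, logical(nrow(fpkm)))
  mean_in <- vapply(breeds, function(b) {
    cols <- colnames(fpkm)[breed_map[colnames(fpkm)] == b]
    rowMeans(fpkm[, cols, drop = FALSE])
  }, numeric(nrow(fpkm)))
  ids <- rownames(fpkm)
  n_breeds_expr <- rowSums(expr_in)
  out <- list(expressed = ids[n_breeds_expr > 0],
              shared = ids[n_breeds_expr == length(breeds)])
  for (b in breeds)
    out[[paste0("specific_", b)]] <-
      ids[expr_in[, b] & n_breeds_expr == 1]
  out$high <- ids[apply(mean_in > high_threshold, 1, any)]
  memb <- data.frame(transcript_id = ids, expr_in, check.names = FALSE,
                     stringsAsFactors = FALSE)
  out$membership <- memb
  out
}

#' Per-breed expression share of each transcript
#'
#' The share of a transcript is its mean FPKM within a breed divided by
#' the sum of all transcripts' mean FPKM in that breed; shares sum to 1
#' per breed.
#'
#' @inheritParams expression_sets
#' @return data.frame with `transcript_id` and one share column per
#'   breed.
#' @export
expression_share <- function(fpkm, breed_map) {
  fpkm <- as.matrix(fpkm)
  breeds <- unique(unname(breed_map[colnames(fpkm)]))
  out <- data.frame(transcript_id = rownames(fpkm), stringsAsFactors = FALSE)
  for (b in breeds) {
    cols <- colnames(fpkm)[breed_map[colnames(fpkm)] == b]
    m <- rowMeans(fpkm[, cols, drop = FALSE])
    tot <- sum(m)
    if (tot <= 0) abort("breed '%s' has zero total FPKM", b)
    out[[paste0("share_", b)]] <- m / tot
  }
  out
}
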