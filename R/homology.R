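# Fixed local-alignment scoring scheme and Karlin-Altschul calibration
# constants shipped as named configuration (a stand-in calibration for
# this scheme, not re-derived).
ALIGN_SCHEME <- list(match = 1, mismatch = -2, gap_open = 5, gap_extend = 2,
                     K = 0.711, lambda = 1.37)

#' Optimal local alignment score
#'
#' Smith-Waterman local alignment under the fixed DNA scheme: match +1,
#' mismatch -2, a gap of length k costs `gap_open + k * gap_extend`
#' (5 + 2k).  Symmetric in its arguments; empty sequences score 0.
#'
#' @param query,subject DNA sequences (character scalars).
#' @return non-negative integer score.
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")  # 8
#' @export
local_align <- function(query, subject) {
  if (nchar(query) == 0 || nchar(subject) == 0) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALIGN_SCHEME$match, mismatch = ALIGN_SCHEME$mismatch,
    baseOnly = TRUE)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = ALIGN_SCHEME$gap_open,
    gapExtension = ALIGN_SCHEME$gap_extend, scoreOnly = TRUE)
  max(0, sc)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the shipped constants
#' (`K = 0.711`, `lambda = 1.37` for this scoring scheme's calibration);
#' monotone decreasing in the score.
#'
#' @param score alignment score.
#' @param m query length, `n` total database length (bases).
#' @param n see `m`.
#' @return positive E-value.
#' @export
karlin_evalue <- function(score, m, n) {
  ALIGN_SCHEME$K * m * n * exp(-ALIGN_SCHEME$lambda * score)
}

#' Classify candidate lncRNAs by homology to two reference sets
#'
#' Each candidate is aligned to every entry of each database; the flag
#' for a database is set when the best hit's E-value falls below the
#' threshold.  Percentages are reported to one decimal place.
#'
#' @param candidates named character vector (or `DNAStringSet`) of
#'   candidate sequences.
#' @param db_a,db_b named character vectors of reference sequences
#'   (e.g. human-like and mouse-like lncRNA sets).
#' @param e_threshold E-value cutoff (default 1e-6, strict `<`).
#' @return list with `flags` (data.frame: id, `a_similar`, `b_similar`,
#'   `both`), `hits` (best hit per candidate per database) and
#'   `percentages` (`a`, `b`, `both`, 1 d.p.).
#' @export
classify_homology <- function(candidates, db_a, db_b, e_threshold = 1e-6) {
  as_chr <- function(x) if (methods::is(x, "DNAStringSet"))
    setNames(as.character(x), names(x)) else x
  candidates <- as_chr(candidates); db_a <- as_chr(db_a); db_b <- as_chr(db_b)
  if (length(db_a) == 0 || length(db_b) == 0)
    abort("homology databases must be non-empty")
  best_hit <- function(q, db) {
    scores <- vapply(db, function(s) local_align(q, s), numeric(1))
    i <- which.max(scores)
    e <- karlin_evalue(scores[i], nchar(q), sum(nchar(db)))
    list(subject = names(db)[i], score = scores[i], evalue = e)
  }
  ids <- names(candidates) %||% as.character(seq_along(candidates))
  hits <- list(); fa <- logical(length(candidates)); fb <- fa
  for (i in seq_along(candidates)) {
    ha <- best_hit(candidates[[i]], db_a)
    hb <- best_hit(candidates[[i]], db_b)
    fa[i] <- ha$evalue < e_threshold
    fb[i] <- hb$evalue < e_threshold
    hits[[length(hits) + 1L]] <- data.frame(
      query = ids[i], db = c("A", "B"),
      subject = c(ha$subject, hb$subject),
      score = c(ha$score, hb$score), evalue = c(ha$evalue, hb$evalue),
      stringsAsFactors = FALSE)
  }
  flags <- data.frame(id = ids, a_similar = fa, b_similar = fb,
                      both = fa & fb, stringsAsFactors = FALSE)
  list(flags = flags, hits = do.call(rbind, hits),
       percentages = similarity_percentages(
         c(a = sum(fa), b = sum(fb), both = sum(fa & fb)),
         length(candidates)))
}

#' Percentages of a candidate total, one decimal place
#'
#' @param counts named numeric vector of numerators.
#' @param total denominator (candidate count).
#' @return named numeric vector of percentages rounded to one decimal.
#' @examples
#' similarity_percentages(c(human = 473, mouse = 237, both = 198), 1018)
#' @export
similarity_percentages <- function(counts, total) {
  if (total <= 0) abort("total must be positive")
  round(100 * counts / total, 1)
}
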