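# Independent brute-force oracles used to freeze expected values.  These
# deliberately re-derive results with naive algorithms that share no code
# with the package implementations.

# --- shared fixtures (built once per test run) -------------------------
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_dataset(simulation_config(seed = 1))
  .fixture_env$sim
}

default_discovery <- function() {
  if (is.null(.fixture_env$disc)) {
    sim <- default_sim()
    rec <- pool_models(sim$models)
    .fixture_env$records <- rec
    .fixture_env$disc <- run_discovery(rec, sim$annotation, sim$genome)
  }
  .fixture_env$disc
}

default_records <- function() {
  default_discovery()
  .fixture_env$records
}

# map structure keys back to planted truth ids via the models' gene ids
truth_ids_of <- function(keys) {
  rec <- default_records()
  sub("^G\\.", "", setNames(rec$gene_id, rec$key)[keys])
}

# --- naive six-frame ORF scan (character loop) -------------------------
bf_longest_orf_sixframe <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  best <- 0L
  for (s in c(seq, rc)) {
    n <- nchar(s)
    for (frame in 0:2) {
      i <- frame + 1L
      while (i + 2L <= n) {
        if (substr(s, i, i + 2L) == "ATG") {
          j <- i; len <- 0L; found <- FALSE
          while (j + 2L <= n) {
            cod <- substr(s, j, j + 2L)
            if (cod %in% c("TAA", "TAG", "TGA")) { found <- TRUE; break }
            len <- len + 1L
            j <- j + 3L
          }
          if (found && len > best) best <- len
        }
        i <- i + 3L
      }
    }
  }
  best
}

# sense-strand-only variant: frames of the given string, complete ORFs
bf_longest_orf_sixframe_sense <- function(seq) {
  n <- nchar(seq); best <- 0L
  for (frame in 0:2) {
    i <- frame + 1L
    while (i + 2L <= n) {
      if (substr(seq, i, i + 2L) == "ATG") {
        j <- i; len <- 0L; found <- FALSE
        while (j + 2L <= n) {
          cod <- substr(seq, j, j + 2L)
          if (cod %in% c("TAA", "TAG", "TGA")) { found <- TRUE; break }
          len <- len + 1L
          j <- j + 3L
        }
        if (found && len > best) best <- len
      }
      i <- i + 3L
    }
  }
  best
}

# --- BH step-up by direct evaluation of its definition ------------------
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (rank in seq_len(m)) {
    cand <- vapply(rank:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[rank]] <- min(1, min(cand))
  }
  q
}

# --- Smith-Waterman with affine gaps (independent Gotoh DP) -------------
# gap of length k costs open + k * ext, matching the package scheme
bf_local_align <- function(q, s, match = 1, mismatch = -2, open = 5, ext = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# --- all-pairs cis scan -------------------------------------------------
bf_cis_pairs <- function(lnc, mrna, window) {
  out <- character(0)
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(mrna))) {
    if (lnc$chrom[i] != mrna$chrom[j]) next
    gap <- max(0, max(lnc$start[i], mrna$start[j]) -
                 min(lnc$end[i], mrna$end[j]))
    if (gap <= window)
      out <- c(out, paste(lnc$gene_id[i], mrna$gene_id[j], gap, sep = "|"))
  }
  sort(out)
}

# --- exact two-sided conditional binomial test (Poisson null) -----------
bf_binom_conditional <- function(y1, s, prob) {
  f <- dbinom(0:s, s, prob)
  sum(f[f <= f[y1 + 1] * (1 + 1e-8)])
}

# random transcript-model row helper
rand_tx <- function(id, chrom = "chr1", strand = "+", exons,
                    sample_id = "S1", assembler = "A1", coverage = 10) {
  transcript_model(id, paste0("G.", id), chrom, strand, exons,
                   sample_id = sample_id, assembler = assembler,
                   coverage = coverage)
}
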