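#' Configuration for the synthetic dataset generator
#'
#' The defaults emulate the study design the pipeline is built for: two
#' breeds with two RNA-seq samples each, transcript models emitted
#' independently by two assemblers per sample, a reference annotation
#' carrying mRNAs plus five noncoding biotypes, planted novel mRNAs and
#' lncRNAs, structured noise (low-coverage, single-exon, short,
#' assembler-private, annotation-overlapping), negative-binomial counts
#' with planted breed effects, and cis lncRNA-mRNA pairs planted at 10 kb
#' (inside the 100 kb analysis window) and 150 kb (outside it).
#'
#' @param seed master seed; every artifact derives its own substream from
#'   it so outputs are byte-identical across runs.
#' @param n_chromosomes,chrom_length genome shape (bases).
#' @param n_known_mrna,n_novel_mrna,n_lncrna,n_noise planted transcript
#'   counts per class.
#' @param n_samples_per_breed RNA-seq samples per breed (default 2).
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param de_fraction fraction of each class planted as differentially
#'   expressed (in addition, when positive, the cis-planted loci are
#'   always differentially expressed so the cis stage has signal).
#' @param de_log2fc absolute planted log2 fold change (breed2 vs breed1).
#' @param window_planting two distances (bases) for planted cis pairs:
#'   one inside and one outside the analysis window.
#' @return an object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_known_mrna = 10, n_lncrna = 5,
#'                          n_novel_mrna = 3, n_noise = 5)
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 3,
                              chrom_length = 1200000,
                              n_known_mrna = 120,
                              n_novel_mrna = 40,
                              n_lncrna = 60,
                              n_noise = 40,
                              n_samples_per_breed = 2,
                              nb_dispersion = 0.1,
                              de_fraction = 0.2,
                              de_log2fc = 2,
                              window_planting = c(10000, 150000)) {
  counts <- c(n_known_mrna, n_novel_mrna, n_lncrna, n_noise)
  if (any(counts < 0)) abort("planted counts must be >= 0")
  if (n_samples_per_breed < 1) abort("need at least one sample per breed")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (de_fraction < 0 || de_fraction > 1) abort("de_fraction must be in [0,1]")
  if (length(window_planting) != 2) abort("window_planting needs 2 distances")
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_known_mrna = n_known_mrna,
                 n_novel_mrna = n_novel_mrna, n_lncrna = n_lncrna,
                 n_noise = n_noise, n_samples_per_breed = n_samples_per_breed,
                 nb_dispersion = nb_dispersion, de_fraction = de_fraction,
                 de_log2fc = de_log2fc, window_planting = window_planting),
            class = "simulation_config")
}

sim_samples <- function(config) {
  n <- config$n_samples_per_breed
  samples <- paste0("S", seq_len(2 * n))
  breeds <- rep(c("breed1", "breed2"), each = n)
  setNames(breeds, samples)
}

NOISE_CLASSES <- c("low_coverage", "single_exon", "too_short",
                   "private_singleton", "anno_overlap")
BIOTYPES_NONCODING <- c("pseudogene", "pre_miRNA", "tRNA", "rRNA", "snoRNA")

# random DNA string of length n under the current RNG
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# Random sequence patched so that no frame on either strand contains an
# ATG-initiated stop-free run of >= max_codons codons (open-ended runs
# included).  Patching overwrites a codon inside the offending run with a
# stop; the patched codon index varies with the iteration because two
# runs on overlapping frames can otherwise erase each other's stops in a
# cycle.  Deterministic: no RNG after the initial draw.
make_noncoding <- function(len, max_codons = 35) {
  s <- random_dna(len)
  for (iter in 1:500) {
    runs <- long_orf_runs(s, max_codons)
    if (length(runs) == 0) return(s)
    for (ri in seq_along(runs)) {
      run <- runs[[ri]]
      # codon index within the run (< 35), varied per iteration and run
      j <- 4L + (iter * 7L + run$offset + ri * 3L) %% 25L
      pos <- run$offset + 3L * j       # 0-based, in scanned-strand coords
      if (run$strand == "+") {
        substr(s, pos + 1L, pos + 3L) <- "TAA"
      } else {
        fwd <- len - pos - 3L          # map revcomp offset to forward
        substr(s, fwd + 1L, fwd + 3L) <- "TTA"  # revcomp("TAA")
      }
    }
  }
  abort("failed to patch noncoding sequence of length %d", len)
}

# All ATG-initiated stop-free runs of >= min_codons codons (open-ended
# runs included) over the six frames; offsets are 0-based in the
# scanned strand's coordinates.
long_orf_runs <- function(seq, min_codons) {
  scan_one <- function(s, strand_lab) {
    n <- nchar(s); out <- list()
    for (frame in 0:2) {
      if (frame + 3L > n) next
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      stop_after <- c(which(cods %in% STOP_CODONS), length(cods) + 1L)
      for (i in which(cods == "ATG")) {
        nxt <- stop_after[stop_after > i][1L]
        if (nxt - i >= min_codons)
          out[[length(out) + 1L]] <- list(codons = nxt - i,
                                          strand = strand_lab,
                                          offset = starts[i] - 1L)
      }
    }
    out
  }
  c(scan_one(seq, "+"), scan_one(revcomp(seq), "-"))
}

# Designed coding transcript: UTR5 + ATG + body codons + stop + UTR3,
# with one library motif embedded in-frame.
make_coding <- function(orf_codons, utr5, utr3, motif) {
  ct <- coding_codon_table()
  body <- sample(names(ct), orf_codons - 1L, replace = TRUE, prob = ct)
  body[20:29] <- substring(motif, seq(1, 28, 3), seq(3, 30, 3))
  paste0(random_dna(utr5), "ATG", paste(body, collapse = ""), "TAA",
         random_dna(utr3))
}

# exon lengths >= min_len summing to total (multinomial composition)
split_exons <- function(total, k, min_len = 50) {
  if (k == 1L) return(total)
  if (total < k * min_len) abort("transcript too short to split into %d exons", k)
  as.vector(stats::rmultinom(1, total - k * min_len, rep(1, k))) + min_len
}

# absolute exon matrix from a locus start, exon lengths and intron lengths
layout_exons <- function(start, exon_lens, intron_lens) {
  k <- length(exon_lens)
  starts <- integer(k); ends <- integer(k)
  cur <- start
  for (i in seq_len(k)) {
    starts[i] <- cur
    ends[i] <- cur + exon_lens[i]
    cur <- ends[i] + if (i < k) intron_lens[i] else 0L
  }
  cbind(start = starts, end = ends)
}

#' Generate the synthetic reference: genome, annotation and truth
#'
#' Places all loci non-overlapping on both strands, writes designed
#' transcript sequences into the genome (coding ORFs of at least 200
#' codons for mRNA classes; noncoding sequences with no ORF reaching 35
#' codons in any of the six frames for lncRNAs), and records the ground
#' truth for every transcript that will be emitted, including planted
#' differential-expression effects and cis pairs.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character vector), `annotation`
#'   (transcript table with `biotype`), `truth` (one row per planted
#'   transcript model) and `cis_truth` (all true DE lncRNA / DE mRNA gene
#'   pairs on one chromosome with their gap distances).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 1L))  # artifact key 1: reference
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  motifs <- toy_domain_motifs()

  # --- design all loci -------------------------------------------------
  specs <- list()   # each: id, gene, class, noise_class, biotype, k, tx_len,
                    #       seq, forced chrom/start or NULL, de info
  add <- function(x) specs[[length(specs) + 1L]] <<- x

  n_cis_units <- if (config$de_fraction > 0)
    min(3L, config$n_lncrna, config$n_known_mrna) else 0L
  cis_defs <- list(list(gap = config$window_planting[1], lnc_dir = +1, m_dir = +1),
                   list(gap = config$window_planting[1], lnc_dir = -1, m_dir = +1),
                   list(gap = config$window_planting[2], lnc_dir = +1, m_dir = +1))

  mk_mrna <- function(id, gene, class, motif_i) {
    orf <- sample(200:300, 1)
    utr5 <- sample(30:60, 1); utr3 <- sample(30:60, 1)
    list(id = id, gene = gene, class = class, noise_class = NA,
         biotype = if (class == "known_mRNA") "mRNA" else NA,
         k = sample(3:6, 1), tx_len = utr5 + 3L * (orf + 1L) + utr3,
         seq = make_coding(orf, utr5, utr3, motifs[[motif_i]]),
         coding = TRUE)
  }
  mk_lnc <- function(id, gene) {
    len <- sample(300:1200, 1)
    list(id = id, gene = gene, class = "lncRNA", noise_class = NA,
         biotype = NA, k = sample(2:4, 1), tx_len = len,
         seq = make_noncoding(len), coding = FALSE)
  }

  cis_ids <- list()
  for (u in seq_len(n_cis_units)) {
    lid <- sprintf("LNC%04d", u); mid <- sprintf("KM%04d", u)
    lnc <- mk_lnc(lid, paste0("G.", lid))
    mr <- mk_mrna(mid, paste0("G.", mid), "known_mRNA", (u - 1L) %% 5L + 1L)
    lnc$cis_unit <- u; mr$cis_unit <- u
    add(lnc); add(mr)
    cis_ids[[u]] <- c(lnc = lid, mrna = mid)
  }
  for (i in seq_len(config$n_known_mrna - n_cis_units)) {
    id <- sprintf("KM%04d", n_cis_units + i)
    add(mk_mrna(id, paste0("G.", id), "known_mRNA", (i - 1L) %% 5L + 1L))
  }
  for (i in seq_len(config$n_novel_mrna)) {
    id <- sprintf("NM%04d", i)
    add(mk_mrna(id, paste0("G.", id), "novel_mRNA", (i - 1L) %% 5L + 1L))
  }
  for (i in seq_len(config$n_lncrna - n_cis_units)) {
    id <- sprintf("LNC%04d", n_cis_units + i)
    add(mk_lnc(id, paste0("G.", id)))
  }
  # annotated noncoding biotype loci (two of each), annotation-only
  bio_specs <- list()
  bio_lens <- c(pseudogene = 800L, pre_miRNA = 80L, tRNA = 75L,
                rRNA = 1500L, snoRNA = 120L)
  for (b in BIOTYPES_NONCODING) for (j in 1:2) {
    id <- sprintf("BIO.%s.%d", b, j)
    bio_specs[[id]] <- list(id = id, gene = paste0("G.", id), class = "biotype",
                            biotype = b, k = 1L, tx_len = bio_lens[[b]],
                            seq = NULL, coding = FALSE)
  }
  noise_specs <- list()
  for (i in seq_len(config$n_noise)) {
    cls <- NOISE_CLASSES[(i - 1L) %% 5L + 1L]
    id <- sprintf("NS%04d", i)
    len <- switch(cls,
                  low_coverage = sample(300:600, 1),
                  single_exon = sample(300:800, 1),
                  too_short = sample(120:179, 1),  # stays <200 after end jitter
                  private_singleton = sample(300:600, 1),
                  anno_overlap = NA)
    k <- switch(cls, low_coverage = sample(2:3, 1), single_exon = 1L,
                too_short = 2L, private_singleton = sample(2:3, 1),
                anno_overlap = 2L)
    noise_specs[[id]] <- list(id = id, gene = paste0("G.", id), class = "noise",
                              noise_class = cls, biotype = NA, k = k,
                              tx_len = len, seq = NULL, coding = FALSE)
  }

  # --- placement -------------------------------------------------------
  # chr1 carries the cis units, separated by large guards; everything
  # else fills the chromosomes sequentially with 0.5-3 kb gaps.
  placements <- list()  # id -> list(chrom, strand, exons)
  capacity_error <- function() abort(
    "chrom_length %d too small to place all loci", config$chrom_length)

  place_spec <- function(sp, chrom, start) {
    strand <- sample(c("+", "-"), 1)
    introns <- if (sp$k > 1L) sample(100:800, sp$k - 1L, replace = TRUE)
               else integer(0)
    exon_lens <- split_exons(sp$tx_len, sp$k)
    exons <- layout_exons(start, exon_lens, introns)
    if (max(exons[, 2]) > config$chrom_length) return(NULL)
    list(chrom = chrom, strand = strand, exons = exons)
  }

  cursor <- setNames(rep(0L, length(chroms)), chroms)
  # cis units first, on chr1
  for (u in seq_len(n_cis_units)) {
    gap <- cis_defs[[u]]$gap
    start <- cursor[["chr1"]] + 5000L
    lid <- cis_ids[[u]][["lnc"]]; mid <- cis_ids[[u]][["mrna"]]
    sp_l <- specs[[which(vapply(specs, `[[`, "", "id") == lid)]]
    sp_m <- specs[[which(vapply(specs, `[[`, "", "id") == mid)]]
    pl <- place_spec(sp_l, "chr1", start)
    if (is.null(pl)) capacity_error()
    m_start <- max(pl$exons[, 2]) + gap
    pm <- place_spec(sp_m, "chr1", m_start)
    if (is.null(pm)) capacity_error()
    placements[[lid]] <- pl; placements[[mid]] <- pm
    cursor[["chr1"]] <- max(pm$exons[, 2]) + 150000L  # guard beyond window
  }
  # everything else
  rest <- c(Filter(function(s) is.null(s$cis_unit), specs), bio_specs,
            Filter(function(s) !identical(s$noise_class, "anno_overlap"),
                   noise_specs))
  # remaining loci fill chromosomes in order, starting after the cis
  # guard on chr1 (so nothing can pair with a planted cis unit)
  chrom_i <- if (config$n_chromosomes > 1L && n_cis_units > 0L) 2L else 1L
  spill_to_chr1 <- chrom_i == 2L
  for (sp in rest) {
    placed <- FALSE
    while (!placed) {
      if (chrom_i > length(chroms)) {
        if (spill_to_chr1) {           # use chr1's leftover space last
          chrom_i <- 1L; spill_to_chr1 <- FALSE; next
        }
        capacity_error()
      }
      ch <- chroms[chrom_i]
      start <- cursor[[ch]] + sample(500:3000, 1)
      pl <- place_spec(sp, ch, start)
      if (is.null(pl)) { chrom_i <- chrom_i + 1L; next }
      placements[[sp$id]] <- pl
      cursor[[ch]] <- max(pl$exons[, 2])
      placed <- TRUE
    }
  }
  # annotation-overlap noise rides on top of the biotype loci
  overlap_noise <- Filter(function(s) identical(s$noise_class, "anno_overlap"),
                          noise_specs)
  bio_ids <- names(bio_specs)
  for (i in seq_along(overlap_noise)) {
    sp <- overlap_noise[[i]]
    host <- placements[[bio_ids[(i - 1L) %% length(bio_ids) + 1L]]]
    b0 <- host$exons[1, 1]; blen <- host$exons[1, 2] - b0
    e1 <- min(blen, 120L)
    exons <- rbind(c(b0, b0 + e1),
                   c(b0 + e1 + 150L, b0 + e1 + 300L))
    placements[[sp$id]] <- list(chrom = host$chrom, strand = host$strand,
                                exons = exons)
    noise_specs[[sp$id]]$host <- bio_ids[(i - 1L) %% length(bio_ids) + 1L]
  }

  # --- genome ----------------------------------------------------------
  gchars <- setNames(lapply(chroms, function(ch)
    sample(DNA_BASES, config$chrom_length, replace = TRUE)), chroms)
  for (sp in specs) {           # write designed sequences (mRNA/lncRNA)
    pl <- placements[[sp$id]]
    s <- if (pl$strand == "-") revcomp(sp$seq) else sp$seq
    schars <- strsplit(s, "")[[1]]
    offs <- cumsum(c(0L, pl$exons[, 2] - pl$exons[, 1]))
    for (e in seq_len(nrow(pl$exons))) {
      gchars[[pl$chrom]][(pl$exons[e, 1] + 1L):pl$exons[e, 2]] <-
        schars[(offs[e] + 1L):offs[e + 1L]]
    }
  }
  genome <- vapply(gchars, paste, character(1), collapse = "")

  # --- truth table -----------------------------------------------------
  all_model_specs <- c(specs, noise_specs)
  truth <- do.call(rbind, lapply(all_model_specs, function(sp) {
    pl <- placements[[sp$id]]
    df <- data.frame(transcript_id = sp$id, gene_id = sp$gene,
                     label = if (sp$class == "lncRNA") "lncRNA" else sp$class,
                     noise_class = if (is.null(sp$noise_class)) NA_character_
                                   else as.character(sp$noise_class),
                     chrom = pl$chrom, strand = pl$strand,
                     length = tx_length(pl$exons), n_exons = nrow(pl$exons),
                     coding = isTRUE(sp$coding), stringsAsFactors = FALSE)
    df$exons <- list(pl$exons)
    df$seq <- if (is.null(sp$seq)) NA_character_ else sp$seq
    df
  }))
  rownames(truth) <- NULL

  # planted differential expression
  truth$de_flag <- FALSE
  truth$true_log2fc <- 0
  truth$base_mean <- 0
  expr_rows <- truth$label %in% c("known_mRNA", "novel_mRNA", "lncRNA")
  truth$base_mean[expr_rows] <- 2 ^ runif(sum(expr_rows), 3, 9)
  for (u in seq_len(n_cis_units)) {
    d <- cis_defs[[u]]
    il <- match(cis_ids[[u]][["lnc"]], truth$transcript_id)
    im <- match(cis_ids[[u]][["mrna"]], truth$transcript_id)
    truth$de_flag[c(il, im)] <- TRUE
    truth$true_log2fc[il] <- d$lnc_dir * config$de_log2fc
    truth$true_log2fc[im] <- d$m_dir * config$de_log2fc
  }
  if (config$de_fraction > 0) {
    cis_tx <- unlist(cis_ids)
    for (lab in c("known_mRNA", "novel_mRNA", "lncRNA")) {
      pool <- which(truth$label == lab & !truth$de_flag &
                      !(truth$transcript_id %in% cis_tx))
      n_de <- floor(config$de_fraction * length(pool))
      if (n_de > 0) {
        pick <- sample(pool, n_de)
        truth$de_flag[pick] <- TRUE
        truth$true_log2fc[pick] <-
          rep_len(c(1, -1), n_de) * config$de_log2fc
      }
    }
  }

  # annotation: known mRNAs + noncoding biotype loci
  anno_specs <- c(Filter(function(s) s$class == "known_mRNA", specs),
                  bio_specs)
  annotation <- do.call(rbind, lapply(anno_specs, function(sp) {
    pl <- placements[[sp$id]]
    transcript_model(paste0("ANN.", sp$id), sp$gene, pl$chrom, pl$strand,
                     pl$exons, biotype = sp$biotype)
  }))
  rownames(annotation) <- NULL

  # true cis pairs: DE lncRNA gene x DE mRNA gene, gene-body gap
  cis_truth <- cis_pair_scan(truth, max_gap = 2L * max(config$window_planting))

  list(config = config, genome = genome, annotation = annotation,
       truth = truth, cis_truth = cis_truth)
}

# Brute-force all-pairs scan of true DE lncRNA vs DE mRNA gene bodies.
cis_pair_scan <- function(truth, max_gap) {
  lnc <- truth[truth$label == "lncRNA" & truth$de_flag, , drop = FALSE]
  mr <- truth[truth$label %in% c("known_mRNA", "novel_mRNA") & truth$de_flag, ,
              drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(mr))) {
    if (lnc$chrom[i] != mr$chrom[j]) next
    a <- range(lnc$exons[[i]]); b <- range(mr$exons[[j]])
    gap <- max(0L, max(a[1], b[1]) - min(a[2], b[2]))
    if (gap > max_gap) next
    out[[length(out) + 1L]] <- data.frame(
      lnc_gene = lnc$gene_id[i], mrna_gene = mr$gene_id[j], distance = gap,
      lnc_log2fc = lnc$true_log2fc[i], mrna_log2fc = mr$true_log2fc[j],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(lnc_gene = character(0), mrna_gene = character(0),
                      distance = numeric(0), lnc_log2fc = numeric(0),
                      mrna_log2fc = numeric(0)))
  do.call(rbind, out)
}

#' Emit per-sample, per-assembler transcript models
#'
#' Every planted (non-noise) transcript is given a support pattern that
#' satisfies the reliability rule (at least two samples, or both
#' assemblers); noise transcripts get the support and coverage their
#' class dictates (e.g. assembler-private singletons appear in exactly
#' one sample and one assembler).  Terminal exon ends of multi-exon
#' occurrences are jittered so pooling by intron chain is exercised.
#'
#' @param config a [simulation_config()].
#' @param ref output of [generate_reference()].
#' @return transcript table of all emitted models (`sample_id`,
#'   `assembler`, `coverage` filled in).
#' @export
emit_transcript_models <- function(config, ref) {
  set.seed(substream_seed(config$seed, 2L))  # artifact key 2: models
  truth <- ref$truth
  samples <- names(sim_samples(config))
  assemblers <- c("A1", "A2")
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    cls <- truth$noise_class[i]
    if (identical(cls, "private_singleton")) {
      occ <- expand.grid(sample_id = sample(samples, 1),
                         assembler = sample(assemblers, 1),
                         stringsAsFactors = FALSE)
    } else {
      u <- runif(1)
      occ <- if (u < 0.7) {
        expand.grid(sample_id = samples, assembler = assemblers,
                    stringsAsFactors = FALSE)
      } else if (u < 0.85) {
        expand.grid(sample_id = sample(samples, 2),
                    assembler = sample(assemblers, 1),
                    stringsAsFactors = FALSE)
      } else {
        expand.grid(sample_id = sample(samples, 1), assembler = assemblers,
                    stringsAsFactors = FALSE)
      }
    }
    base_cov <- if (identical(cls, "low_coverage")) NA else runif(1, 4, 60)
    exons0 <- truth$exons[[i]]
    for (o in seq_len(nrow(occ))) {
      cov <- if (identical(cls, "low_coverage")) runif(1, 0.5, 2.9)
             else base_cov * runif(1, 0.8, 1.2)
      exons <- exons0
      if (nrow(exons) > 1L) {  # jitter terminal ends, intron chain intact
        exons[1, 1] <- max(0L, exons[1, 1] + sample(-10:10, 1))
        exons[nrow(exons), 2] <- exons[nrow(exons), 2] + sample(-10:10, 1)
        if (exons[1, 2] - exons[1, 1] < 5L) exons[1, 1] <- exons0[1, 1]
      }
      rows[[length(rows) + 1L]] <- transcript_model(
        sprintf("%s.%s.%s", occ$sample_id[o], occ$assembler[o],
                truth$transcript_id[i]),
        truth$gene_id[i], truth$chrom[i], truth$strand[i], exons,
        sample_id = occ$sample_id[o], assembler = occ$assembler[o],
        coverage = round(cov, 3))
    }
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  models
}

#' Simulate negative-binomial fragment counts
#'
#' Counts for every non-noise planted transcript across all samples:
#' `NB(mean, dispersion)` with breed means differing by the planted log2
#' fold change for true-DE transcripts and equal otherwise.  At
#' `nb_dispersion = 0` draws are Poisson.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [generate_reference()].
#' @return list with `counts` (matrix, transcripts x samples), `lengths`
#'   (exonic lengths), `lib_sizes` (per-sample mapped fragments; the
#'   simulated totals inflated by the fraction of reads mapping outside
#'   planted loci) and `breed_map`.
#' @export
simulate_counts <- function(config, truth) {
  set.seed(substream_seed(config$seed, 3L))  # artifact key 3: counts
  breed_map <- sim_samples(config)
  keep <- truth$label %in% c("known_mRNA", "novel_mRNA", "lncRNA")
  tt <- truth[keep, , drop = FALSE]
  n <- nrow(tt)
  counts <- matrix(0L, nrow = n, ncol = length(breed_map),
                   dimnames = list(tt$transcript_id, names(breed_map)))
  for (s in seq_along(breed_map)) {
    mu <- tt$base_mean
    if (breed_map[s] == "breed2") mu <- mu * 2 ^ tt$true_log2fc
    counts[, s] <- if (config$nb_dispersion > 0)
      rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    else rpois(n, mu)
  }
  lib_sizes <- round(colSums(counts) * 1.35) + 1000
  list(counts = counts, lengths = setNames(tt$length, tt$transcript_id),
       lib_sizes = lib_sizes, breed_map = breed_map)
}

#' Simulate phenotype and qPCR tables
#'
#' Per-animal phenotypes (three animals per breed) for body weight,
#' thyroid gland weight and the derived thyroid index, summarised as mean
#' and SEM per breed, plus a per-animal qPCR Ct table for up to three
#' differentially expressed transcripts quantified against a reference
#' gene, with target Ct values consistent with the planted fold changes
#' under the 2^(-DDCt) model (breed1 is the calibrator).
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [generate_reference()].
#' @return list with `animals`, `summary` (trait, breed, mean, sem, n)
#'   and `ct` (gene, breed, animal, ct_target, ct_reference).
#' @export
simulate_phenotypes_qpcr <- function(config, truth) {
  set.seed(substream_seed(config$seed, 4L))  # artifact key 4: phenotypes
  n_animals <- 3L
  pars <- list(body_weight_kg = list(mean = c(29.33, 47.07), sd = c(1.52, 3.34)),
               thyroid_weight_g = list(mean = c(3.20, 4.93), sd = c(0.10, 0.66)))
  breeds <- c("breed1", "breed2")
  animals <- expand.grid(breed = breeds, animal = seq_len(n_animals),
                         stringsAsFactors = FALSE)
  animals <- animals[order(animals$breed, animals$animal), ]
  for (tr in names(pars)) {
    b <- match(animals$breed, breeds)
    animals[[tr]] <- pmax(0.01, rnorm(nrow(animals), pars[[tr]]$mean[b],
                                      pars[[tr]]$sd[b]))
  }
  animals$thyroid_index <- thyroid_index(animals$thyroid_weight_g,
                                         animals$body_weight_kg)
  traits <- c(names(pars), "thyroid_index")
  summ <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(breeds, function(b) {
      v <- animals[[tr]][animals$breed == b]
      data.frame(trait = tr, breed = b, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))

  expr_tx <- truth[truth$label != "noise", , drop = FALSE]
  genes <- head(expr_tx$transcript_id[order(!expr_tx$de_flag)], 3)
  fold <- setNames(2 ^ expr_tx$true_log2fc[match(genes, expr_tx$transcript_id)],
                   genes)
  ct <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(breeds, function(b) {
      tgt_mean <- if (b == "breed1") 25 else 25 - log2(fold[[g]])
      data.frame(gene = g, breed = b, animal = seq_len(n_animals),
                 ct_target = rnorm(n_animals, tgt_mean, 0.15),
                 ct_reference = rnorm(n_animals, 20, 0.1),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(ct)) ct <- data.frame(gene = character(0), breed = character(0),
                                    animal = integer(0), ct_target = numeric(0),
                                    ct_reference = numeric(0))
  list(animals = animals, summary = summ, ct = ct,
       planted_fold = if (length(genes)) fold else setNames(numeric(0), NULL))
}

# Homology reference databases derived from the planted lncRNAs: a
# "human-like" and a "mouse-like" set whose membership fractions mirror
# published overlap proportions (46.5% / 23.3%, 19.4% shared), entries
# mutated at 1% so alignment is non-trivial, plus random decoys.
simulate_homology_dbs <- function(config, truth) {
  set.seed(substream_seed(config$seed, 5L))  # artifact key 5: homology dbs
  lnc <- truth[truth$label == "lncRNA", , drop = FALSE]
  n <- nrow(lnc)
  n_both <- round(0.194 * n); n_h <- round(0.465 * n) - n_both
  n_m <- round(0.233 * n) - n_both
  ids <- lnc$transcript_id
  grp <- rep("none", n)
  if (n > 0) {
    idx <- sample.int(n)
    grp[idx[seq_len(n_both)]] <- "both"
    if (n_h > 0) grp[idx[n_both + seq_len(n_h)]] <- "human"
    if (n_m > 0) grp[idx[n_both + n_h + seq_len(n_m)]] <- "mouse"
  }
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < 0.01)
    ch[hit] <- sample(DNA_BASES, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  db_h <- list(); db_m <- list()
  for (i in seq_len(n)) {
    if (grp[i] %in% c("human", "both"))
      db_h[[paste0("HS.", ids[i])]] <- mutate(lnc$seq[i])
    if (grp[i] %in% c("mouse", "both"))
      db_m[[paste0("MM.", ids[i])]] <- mutate(lnc$seq[i])
  }
  for (j in 1:5) {
    db_h[[sprintf("HS.DECOY%02d", j)]] <- make_noncoding(500)
    db_m[[sprintf("MM.DECOY%02d", j)]] <- make_noncoding(500)
  }
  list(human = unlist(db_h), mouse = unlist(db_m),
       membership = setNames(grp, ids))
}

# Gene-term map over the known-mRNA universe with one term planted to be
# enriched among the true-DE genes.
simulate_term_map <- function(config, truth) {
  set.seed(substream_seed(config$seed, 6L))  # artifact key 6: term map
  km <- truth[truth$label == "known_mRNA", , drop = FALSE]
  genes <- km$gene_id
  if (length(genes) < 10)
    return(data.frame(gene = character(0), term = character(0)))
  de_genes <- km$gene_id[km$de_flag]
  rows <- list()
  planted <- unique(c(head(de_genes, 10),
                      sample(genes, max(0, 10 - min(10, length(de_genes))))))
  for (g in planted)
    rows[[length(rows) + 1L]] <- data.frame(gene = g, term = "TERM.planted",
                                            stringsAsFactors = FALSE)
  for (t in 1:14) {
    members <- sample(genes, min(length(genes), sample(8:30, 1)))
    for (g in members)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, term = sprintf("TERM%03d", t), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic dataset
#'
#' Runs [generate_reference()], [emit_transcript_models()],
#' [simulate_counts()] and [simulate_phenotypes_qpcr()], plus synthetic
#' homology databases and a gene-term map, each on its own seed
#' substream.  Optionally writes everything to disk as plain-text files
#' (FASTA, GTF, TSV).
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory; created if missing.
#' @return list with all artifacts and the recorded ground truth.
#' @examples
#' sim <- simulate_dataset(simulation_config(seed = 1, n_known_mrna = 8,
#'   n_novel_mrna = 3, n_lncrna = 6, n_noise = 5))
#' table(sim$truth$label)
#' @export
simulate_dataset <- function(config = simulation_config(), outdir = NULL) {
  ref <- generate_reference(config)
  models <- emit_transcript_models(config, ref)
  expr <- simulate_counts(config, ref$truth)
  pheno <- simulate_phenotypes_qpcr(config, ref$truth)
  dbs <- simulate_homology_dbs(config, ref$truth)
  term_map <- simulate_term_map(config, ref$truth)
  sim <- list(config = config, genome = ref$genome,
              annotation = ref$annotation, truth = ref$truth,
              cis_truth = ref$cis_truth, models = models, expr = expr,
              phenotypes = pheno, db_human = dbs$human, db_mouse = dbs$mouse,
              homology_membership = dbs$membership, term_map = term_map)
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' Write a simulated dataset to plain-text files
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              p("genome.fa"), width = 60)
  write_gtf(sim$annotation, p("annotation.gtf"))
  by_set <- split(seq_len(nrow(sim$models)),
                  paste(sim$models$sample_id, sim$models$assembler, sep = "_"))
  for (nm in names(by_set))
    write_gtf(sim$models[by_set[[nm]], ], p(sprintf("models_%s.gtf", nm)))
  wt <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(data.frame(transcript_id = rownames(sim$expr$counts), sim$expr$counts,
                check.names = FALSE), "counts.tsv")
  wt(data.frame(sample = names(sim$expr$lib_sizes),
                breed = unname(sim$expr$breed_map),
                lib_size = unname(sim$expr$lib_sizes)), "library_sizes.tsv")
  tr <- sim$truth
  tr$exons <- vapply(tr$exons, function(e)
    paste(e[, 1], e[, 2], sep = "-", collapse = ";"), character(1))
  tr$seq <- NULL
  wt(tr, "truth.tsv")
  wt(sim$phenotypes$animals, "phenotypes.tsv")
  wt(sim$phenotypes$summary, "phenotype_summary.tsv")
  wt(sim$phenotypes$ct, "qpcr_ct.tsv")
  wt(sim$term_map, "term_map.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$db_human),
                              p("lncdb_human.fa"), width = 60)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$db_mouse),
                              p("lncdb_mouse.fa"), width = 60)
  invisible(outdir)
}
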