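small_cfg <- function(seed = 3, ...) {
  simulation_config(seed = seed, n_chromosomes = 2, chrom_length = 600000,
                    n_known_mrna = 12, n_novel_mrna = 5, n_lncrna = 8,
                    n_noise = 10, ...)
}

test_that("identical seeds give byte-identical outputs, distinct seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_dataset(small_cfg(seed = 3), outdir = d1)
  simulate_dataset(small_cfg(seed = 3), outdir = d2)
  simulate_dataset(small_cfg(seed = 4), outdir = d3)
  md5 <- function(d) unname(tools::md5sum(sort(list.files(d, full.names = TRUE))))
  expect_identical(md5(d1), md5(d2))
  expect_false(identical(md5(d1), md5(d3)))
})

test_that("truth bookkeeping partitions the emitted transcripts", {
  sim <- default_sim()
  cfg <- sim$config
  tab <- table(sim$truth$label)
  expect_equal(as.integer(tab[c("known_mRNA", "novel_mRNA", "lncRNA",
                                "noise")]),
               c(cfg$n_known_mrna, cfg$n_novel_mrna, cfg$n_lncrna,
                 cfg$n_noise))
  expect_identical(nrow(sim$truth), length(unique(sim$truth$transcript_id)))
  # every emitted model maps to exactly one truth record
  model_truth <- unique(sub("^G\\.", "", sim$models$gene_id))
  expect_setequal(model_truth, sim$truth$transcript_id)
})

test_that("planted lncRNAs have no ORF reaching 100 codons in any frame", {
  sim <- default_sim()
  lnc <- sim$truth[sim$truth$label == "lncRNA", ]
  longest <- vapply(lnc$seq, bf_longest_orf_sixframe, integer(1),
                    USE.NAMES = FALSE)
  expect_true(all(longest < 100))
  # and the genome carries exactly the designed sequences
  i <- which.max(lnc$length)
  expect_identical(
    extract_tx_seq(sim$genome, lnc$chrom[i], lnc$strand[i], lnc$exons[[i]]),
    lnc$seq[i])
})

test_that("planted mRNAs carry an ORF of at least 200 codons", {
  sim <- default_sim()
  mr <- sim$truth[sim$truth$coding, ]
  pick <- seq(1, nrow(mr), length.out = 10)
  longest <- vapply(mr$seq[pick], bf_longest_orf_sixframe, integer(1),
                    USE.NAMES = FALSE)
  expect_true(all(longest >= 200))
})

test_that("support patterns respect the planted design", {
  sim <- default_sim()
  occ <- split(paste(sim$models$sample_id, sim$models$assembler),
               sub("^G\\.", "", sim$models$gene_id))
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    o <- occ[[truth$transcript_id[i]]]
    n_samp <- length(unique(sub(" .*", "", o)))
    n_asm <- length(unique(sub(".* ", "", o)))
    if (identical(truth$noise_class[i], "private_singleton")) {
      expect_identical(c(n_samp, n_asm), c(1L, 1L))
    } else {
      expect_true(n_samp >= 2 || n_asm == 2)  # reliability by construction
    }
  }
  # low-coverage noise is below 3 in every occurrence
  low <- truth$transcript_id[truth$noise_class %in% "low_coverage"]
  expect_true(all(sim$models$coverage[
    sub("^G\\.", "", sim$models$gene_id) %in% low] < 3))
})

test_that("edge configurations behave as documented", {
  cfg <- simulation_config(seed = 5, n_chromosomes = 1, chrom_length = 400000,
                           n_known_mrna = 0, n_novel_mrna = 3, n_lncrna = 4,
                           n_noise = 5)
  ref <- generate_reference(cfg)
  expect_false("mRNA" %in% ref$annotation$biotype)        # no mRNA records
  expect_true(all(c("pseudogene", "pre_miRNA", "tRNA", "rRNA", "snoRNA")
                  %in% ref$annotation$biotype))
  # noise-free config discards nothing for structural reasons
  cfg0 <- simulation_config(seed = 6, n_chromosomes = 1,
                            chrom_length = 1000000, n_known_mrna = 10,
                            n_novel_mrna = 3, n_lncrna = 4, n_noise = 0)
  sim0 <- simulate_dataset(cfg0)
  disc <- run_discovery(pool_models(sim0$models), sim0$annotation,
                        sim0$genome)
  expect_identical(sum(disc$classification$label == "discarded"), 0L)
  # capacity failure is an explicit error
  expect_error(generate_reference(
    simulation_config(seed = 1, n_chromosomes = 1, chrom_length = 20000,
                      n_known_mrna = 40, n_novel_mrna = 10, n_lncrna = 10,
                      n_noise = 10)), "too small")
})

test_that("de_fraction = 0 plants no fold changes", {
  ref <- generate_reference(small_cfg(seed = 7, de_fraction = 0))
  expect_true(all(ref$truth$true_log2fc == 0))
  expect_false(any(ref$truth$de_flag))
})

test_that("simulated counts match the configured NB moments", {
  # many samples of a few transcripts: 10,000 draws per transcript
  cfg <- simulation_config(seed = 8, n_chromosomes = 1,
                           chrom_length = 200000, n_known_mrna = 4,
                           n_novel_mrna = 0, n_lncrna = 2, n_noise = 0,
                           n_samples_per_breed = 5000, de_fraction = 0,
                           nb_dispersion = 0.1)
  ref <- generate_reference(cfg)
  expr <- simulate_counts(cfg, ref$truth)
  for (i in seq_len(nrow(expr$counts))) {
    x <- expr$counts[i, ]
    mu <- ref$truth$base_mean[match(rownames(expr$counts)[i],
                                    ref$truth$transcript_id)]
    expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
    # block-wise MoM dispersion estimate vs configured value
    blocks <- split(x, rep(1:10, length.out = length(x)))
    a_hat <- vapply(blocks, function(b) (var(b) - mean(b)) / mean(b)^2,
                    numeric(1))
    expect_lt(abs(mean(a_hat) - 0.1), 3 * sd(a_hat) / sqrt(10))
  }
  # Poisson limit: variance/mean ratio near 1 when dispersion is 0
  cfg0 <- simulation_config(seed = 9, n_chromosomes = 1,
                            chrom_length = 200000, n_known_mrna = 4,
                            n_novel_mrna = 0, n_lncrna = 0, n_noise = 0,
                            n_samples_per_breed = 5000, de_fraction = 0,
                            nb_dispersion = 0)
  ref0 <- generate_reference(cfg0)
  expr0 <- simulate_counts(cfg0, ref0$truth)
  for (i in seq_len(nrow(expr0$counts))) {
    x <- expr0$counts[i, ]
    ratio <- var(x) / mean(x)
    expect_lt(abs(ratio - 1), 3 * sqrt(2 / length(x)))  # var of s2/mean ~ 2/n
  }
})

test_that("phenotype and Ct tables mirror the study layout", {
  sim <- default_sim()
  s <- sim$phenotypes$summary
  expect_identical(sort(unique(s$breed)), c("breed1", "breed2"))
  expect_true(all(s$n == 3))
  expect_true(all(s$sem > 0))
  # Ct values encode the planted fold changes: mean DDCt ~ -log2(fold)
  fc <- qpcr_fold_changes(sim$phenotypes$ct, calibrator = "breed1")
  planted <- sim$phenotypes$planted_fold[fc$gene]
  expect_true(all(abs(fc$ddct - (-log2(planted))) < 0.5))
  # a planted fold of 1 gives DDCt near 0
  cfgnull <- small_cfg(seed = 11, de_fraction = 0)
  refn <- generate_reference(cfgnull)
  phn <- simulate_phenotypes_qpcr(cfgnull, refn$truth)
  fcn <- qpcr_fold_changes(phn$ct, calibrator = "breed1")
  expect_true(all(abs(fcn$ddct) < 0.5))
  expect_true(all(phn$planted_fold == 1))
})
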