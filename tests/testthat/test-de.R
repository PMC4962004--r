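test_that("dispersion estimation recovers method-of-moments identities", {
  # within-group variance equal to the mean -> Poisson, dispersion 0
  cnt <- rbind(t1 = c(10, 10, 10, 10))
  expect_equal(estimate_dispersion(cnt, c("a", "a", "b", "b"))[[1]], 0)
  expect_error(estimate_dispersion(cnt, c("a", "a", "a", "b")), "2 samples")
  # Monte-Carlo recovery: NB(mu = 100, alpha = 0.1), 50 per group
  set.seed(21)
  m <- 400
  x <- matrix(rnbinom(m * 100, mu = 100, size = 10), nrow = m)
  groups <- rep(c("a", "b"), each = 50)
  a_hat <- estimate_dispersion(x, groups)
  se <- sd(a_hat) / sqrt(m)
  expect_lt(abs(mean(a_hat) - 0.1), 3 * se)
})

test_that("the exact NB test behaves at its anchor points", {
  # identical groups -> p = 1 by symmetry
  expect_identical(nb_test(c(5, 5), c(5, 5), dispersion = 0.1), 1)
  expect_identical(nb_test(c(0, 0), c(0, 0), dispersion = 0.1), 1)
  # dispersion 0 reduces to the exact binomial conditional test
  set.seed(3)
  for (i in 1:25) {
    y1 <- rpois(2, 40); y2 <- rpois(2, 60)
    mine <- nb_test(y1, y2, dispersion = 0)
    s <- sum(y1) + sum(y2)
    expect_equal(mine, bf_binom_conditional(sum(y1), s, 0.5),
                 tolerance = 1e-10)
  }
  # label exchange preserves p
  set.seed(4)
  for (i in 1:10) {
    a <- rnbinom(2, mu = 80, size = 10); b <- rnbinom(2, mu = 200, size = 10)
    expect_equal(nb_test(a, b, dispersion = 0.1),
                 nb_test(b, a, dispersion = 0.1))
  }
  # monotonicity: a larger mean difference never increases p
  base <- c(50, 50)
  p_seq <- vapply(c(60, 100, 200, 400), function(m2)
    nb_test(base, c(m2, m2), dispersion = 0.05), numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
  expect_error(nb_test(c(1, 2), c(3, 4), dispersion = -1), ">= 0")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  # worked example: p = (.01,.02,.03,.04) -> all q = 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.2), 0.2)              # single p
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))  # all ones
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DE calls use a strict q threshold and report additive summaries", {
  res <- data.frame(transcript_id = c("a", "b", "c"),
                    log2fc = c(2, -2, 1), q = c(0.01, 0.049, 0.05))
  out <- call_de(res)
  expect_identical(out$results$direction, c("up", "down", "ns"))  # q = 0.05 is ns
  expect_identical(unname(out$summary),
                   c(1L, 1L, 2L))
  expect_identical(out$summary[["total"]],
                   out$summary[["up"]] + out$summary[["down"]])
})

test_that("swapping group labels negates log2FC and preserves p", {
  set.seed(6)
  cnt <- matrix(rnbinom(40, mu = 100, size = 10), 10, 4,
                dimnames = list(paste0("t", 1:10), paste0("S", 1:4)))
  g <- c("a", "a", "b", "b")
  r1 <- run_de(cnt, g)
  r2 <- run_de(cnt[, c(3, 4, 1, 2)], g)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-9)
})

test_that("planted differential expression is recovered on synthetic counts", {
  sim <- default_sim()
  de <- run_de(sim$expr$counts, sim$expr$breed_map)
  truth <- sim$truth
  tde <- setNames(truth$de_flag, truth$transcript_id)[de$transcript_id]
  called <- de$direction != "ns"
  recall <- sum(called & tde) / sum(tde)
  fdr <- if (sum(called) > 0) sum(called & !tde) / sum(called) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.10)
  # called directions match the planted sign of the fold change
  tl <- setNames(truth$true_log2fc, truth$transcript_id)[de$transcript_id]
  hit <- called & tde
  expect_identical(unname(ifelse(de$direction[hit] == "up", 1, -1)),
                   unname(sign(tl[hit])))
})

test_that("the exact test agrees with an independent implementation", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  n <- 200; disp <- 0.15
  mu <- 2^runif(n, 4, 9)
  fc <- ifelse(runif(n) < 0.2, 4, 1)
  cnt <- cbind(rnbinom(n, mu = mu, size = 1 / disp),
               rnbinom(n, mu = mu, size = 1 / disp),
               rnbinom(n, mu = mu * fc, size = 1 / disp),
               rnbinom(n, mu = mu * fc, size = 1 / disp))
  p_mine <- vapply(seq_len(n), function(i)
    nb_test(cnt[i, 1:2], cnt[i, 3:4], dispersion = disp), numeric(1))
  d <- edgeR::DGEList(counts = cnt, group = c(1, 1, 2, 2),
                      lib.size = rep(1e6, 4))
  # big.count forces edgeR's exact path (it approximates above 900 counts)
  p_ref <- edgeR::exactTest(d, dispersion = disp,
                            big.count = 1e9)$table$PValue
  expect_equal(p_mine, p_ref, tolerance = 1e-8)
})
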