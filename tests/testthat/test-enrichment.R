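test_that("ks_enrichment flags a fully separated dataset", {
  set.seed(1)
  bg <- rnorm(2000)
  ds <- max(bg) + 1 + runif(20)
  expect_lt(ks_enrichment(ds, c(bg, ds)), 1e-6)
  expect_error(ks_enrichment(numeric(0), bg), "nonempty")
})

test_that("ks_enrichment p-values are roughly uniform under the null", {
  set.seed(2)
  ps <- replicate(200, {
    bg <- rnorm(400)
    ds <- bg[sample.int(400, 25)]
    ks_enrichment(ds, bg)
  })
  expect_gt(median(ps), 0.35)
  expect_lte(median(ps), 1)
  # n = 1 datasets still give a valid probability
  expect_true(ks_enrichment(0.2, rnorm(50)) > 0 &&
                ks_enrichment(0.2, rnorm(50)) <= 1)
})

test_that("exact 2x3 Fisher matches stats::fisher.test (dual route)", {
  set.seed(3)
  for (i in 1:25) {
    d <- c(sample(0:6, 2, replace = TRUE), sample(0:12, 1))
    bg <- d + c(sample(0:15, 2, replace = TRUE), sample(5:40, 1))
    if (sum(d) == 0) next
    mine <- fisher_enrichment(d, bg, override = FALSE)
    ref <- stats::fisher.test(rbind(d, bg - d))$p.value
    expect_equal(mine, min(ref, 1), tolerance = 1e-7)
  }
})

test_that("a 2x3 table with an empty column reduces to the classical 2x2", {
  # dataset (3, 0, 7) vs background (5, 0, 95): column 2 empty
  d <- c(3, 0, 7); bg <- c(5, 0, 95)
  p23 <- fisher_enrichment(d, bg, override = FALSE)
  # hand hypergeometric: P(X >= observed extremes) over 2x2 with margins
  ref <- stats::fisher.test(matrix(c(3, 2, 7, 88), 2))$p.value
  expect_equal(p23, ref, tolerance = 1e-9)
  # and the collapse_2x2 mode agrees here since sig_neg is empty
  expect_equal(fisher_enrichment(d, bg, mode = "collapse_2x2",
                                 override = FALSE), ref, tolerance = 1e-9)
})

test_that("enumeration and Monte-Carlo Fisher agree within MC error", {
  d <- c(10, 0, 0); bg <- c(12, 10, 978)
  p_enum <- fisher_enrichment(d, bg, override = FALSE)
  p_mc <- fisher_enrichment(d, bg, mode = "monte_carlo", override = FALSE,
                            mc_draws = 1e5L, seed = 4L)
  se <- sqrt(p_enum * (1 - p_enum) / 1e5) + 1 / 1e5
  expect_lt(abs(p_mc - p_enum), 3 * se + 1e-6)
})

test_that("excess non-significant proportion forces fisher_p = 1", {
  # dataset has 100% non-significant vs 90% in background
  expect_identical(fisher_enrichment(c(0, 0, 10), c(50, 50, 910)), 1)
  # no deviation from background proportions: near 1 even without override
  expect_gt(fisher_enrichment(c(1, 1, 8), c(10, 10, 80), override = FALSE),
            0.5)
  expect_error(fisher_enrichment(c(5, 0, 0), c(4, 1, 1)), "inconsistent")
})

test_that("rank_datasets orders, adjusts, and summarizes direction", {
  sig <- signature_set(paste0("g", 1:10), paste0("g", 11:30))
  comp <- toy_compendium(n_datasets = 6L, n_genes = 60L, n_samples = 10L,
                         sig = sig, effect_size = 2.5,
                         affected_fraction = 0.5, perturbed = 1L,
                         seed = 21L)
  scored <- score_compendium(comp, sig)
  enr <- rank_datasets(scored)
  expect_s3_class(enr, "dataset_enrichment")
  expect_equal(nrow(enr), 6L)
  expect_true(!is.unsorted(enr$ks_q))
  expect_true(all(enr$ks_q <= 1 & enr$fisher_q <= 1))
  expect_equal(enr$n_sig_pos + enr$n_sig_neg + enr$n_ns,
               enr$n_samples_scored)
  # BH never lowers the smallest p below itself * m / 1 ordering sanity:
  expect_true(all(enr$ks_q >= enr$ks_p - 1e-12))
  # the planted dataset leads and is 'mixed': renormalization pushes
  # affected samples positive and unaffected samples negative symmetrically
  expect_identical(enr$dataset_id[1], "synth001")

  # no sample significant anywhere: all fisher_p = 1, K-S still defined
  null_scored <- score_compendium(toy_compendium(n_datasets = 3L),
                                  signature_set(paste0("g", 1:4),
                                                paste0("g", 5:10)))
  enr0 <- rank_datasets(null_scored)
  expect_true(all(enr0$fisher_p == 1))
  expect_true(all(enr0$ks_p > 0))
})

test_that("datasets with no defined scores are skipped with a message", {
  comp <- toy_compendium(n_datasets = 2L, n_genes = 20L)
  sig <- signature_set(paste0("g", 1:3), paste0("g", 4:8))
  scored <- score_compendium(comp, sig)
  # blank out one dataset's coverage by marking scores undefined
  scored$defined[scored$dataset_id == "synth002"] <- FALSE
  expect_message(enr <- rank_datasets(scored), "synth002")
  expect_equal(nrow(enr), 1L)
})

test_that("Fisher beats K-S on strong effects; K-S on weak diffuse ones", {
  sig <- signature_set(paste0("g", 1:10), paste0("g", 11:30))
  strong_wins <- 0L; weak_wins <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    # strong: large shift, most samples of a small dataset affected
    comp_s <- toy_compendium(n_datasets = 5L, n_genes = 60L,
                             n_samples = 10L, sig = sig, effect_size = 4,
                             affected_fraction = 0.8, perturbed = 1L,
                             seed = 1000L + r)
    ps <- enrichment_for(score_compendium(comp_s, sig), "synth001")
    strong_wins <- strong_wins + (ps[["fisher_p"]] < ps[["ks_p"]])
    # weak: small shift, minority of a large dataset affected — per-sample
    # SA stays below the q cutoff (Fisher blind) but the distribution moves
    comp_w <- simulate_compendium(synthetic_spec(
      n_genes = 60L, dataset_sizes = c(60L, rep(15L, 4L)), sig = sig,
      effect_size = 0.4, affected_fraction = 0.3, perturbed_datasets = 1L,
      seed = 2000L + r))
    pw <- enrichment_for(score_compendium(comp_w, sig), "synth001")
    weak_wins <- weak_wins + (pw[["ks_p"]] < pw[["fisher_p"]])
  }
  expect_gt(strong_wins, n_rep / 2)
  expect_gt(weak_wins, n_rep / 2)
})
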