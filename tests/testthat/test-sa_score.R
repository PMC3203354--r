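test_that("compute_w spans [0, n_up*n_down] and matches hand cases", {
  expect_equal(compute_w(c(3, 4), 2, 2), 4)   # maximal separation
  expect_equal(compute_w(1, 1, 1), 0)         # minimal
  expect_error(compute_w(numeric(0), 0, 3), "at least one")
})

test_that("W equals the brute-force concordant-pair count", {
  set.seed(10)
  for (i in 1:30) {
    nu <- sample(1:6, 1); nd <- sample(1:6, 1)
    vals <- sample(1:8, nu + nd, replace = TRUE)  # ties likely
    r <- rank(vals)
    w <- compute_w(r[seq_len(nu)], nu, nd)
    expect_equal(w, pair_count_w(vals[seq_len(nu)], vals[-seq_len(nu)]))
    expect_gte(w, 0)
    expect_lte(w, nu * nd)
  }
})

test_that("sa_from_w uses the printed null moments", {
  # n_up = 34, n_down = 77: mu = 1309, so SA(mu) = 0
  expect_equal(sa_from_w(1309, 34, 77), 0)
  expect_equal(sa_from_w(34 * 77, 34, 77),
               (34 * 77 - 1309) / sqrt(34 * 77 * 112 / 12))
  # smallest case: mu = 0.5, sigma = 0.5
  expect_equal(sa_from_w(1, 1, 1), 1)
  # antisymmetry under swapping up/down: W' = n_up*n_down - W
  for (w in c(0, 3, 7.5)) {
    expect_equal(sa_from_w(3 * 4 - w, 4, 3), -sa_from_w(w, 3, 4))
  }
})

test_that("exhaustive SA null has mean 0 and variance 1", {
  for (nn in list(c(2, 2), c(3, 4), c(4, 6), c(5, 5), c(2, 8))) {
    sa <- enumerate_sa_null(nn[1], nn[2])
    expect_lt(abs(mean(sa)), 1e-12)
    # population variance over the equally likely outcomes
    expect_lt(abs(mean(sa^2) - 1), 1e-12)
  }
})

test_that("sa_pvalue is the two-sided t tail", {
  expect_equal(sa_pvalue(0, 5, 5), 1)
  for (sa in c(-2.3, 0.4, 1.7)) {
    expect_equal(sa_pvalue(sa, 10, 7), sa_pvalue(-sa, 10, 7))
  }
  # quadrature oracle: integrate the t(38) density above sa = 2
  tail_num <- integrate(function(x) dt(x, df = 38), 2, Inf,
                        rel.tol = 1e-10)$value
  expect_equal(sa_pvalue(2, 20, 20), 2 * tail_num, tolerance = 1e-8)
  expect_error(sa_pvalue(1, 1, 1), "degrees of freedom")
})

test_that("score_sample handles concordance, coverage, and rank invariance", {
  sig <- toy_signature(3L, 3L)
  x <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  ds <- znormalize(expression_dataset(x, "d1"))

  # force perfect concordance in sample s1: up z-scores above down z-scores
  ds2 <- ds
  ds2$values[sig$up, 1] <- c(2, 3, 4)
  ds2$values[sig$down, 1] <- c(-2, -3, -4)
  sc <- score_sample(ds2, "s1", sig)
  expect_equal(sc$w, 9)
  expect_equal(sc$sa, sa_from_w(9, 3, 3))  # maximum attainable

  # signature absent from the platform: flagged, not an exception
  far <- signature_set(c("x1", "x2"), c("x3", "x4"))
  sc2 <- score_sample(ds, "s1", far)
  expect_false(sc2$defined)
  expect_true(is.na(sc2$sa))

  expect_error(score_sample(ds, "nope", sig), "no such sample")

  # invariance under strictly increasing transforms of a sample's values
  for (i in 1:20) {
    dsr <- toy_dataset(n_genes = 12L, n_samples = 4L, seed = 100L + i,
                       normalized = TRUE)
    sigr <- signature_set(paste0("g", 1:4), paste0("g", 5:9))
    s_id <- sample(colnames(dsr$values), 1L)
    base <- score_sample(dsr, s_id, sigr)
    dst <- dsr
    dst$values[, s_id] <- dst$values[, s_id]^3 + dst$values[, s_id]
    expect_equal(score_sample(dst, s_id, sigr)$sa, base$sa)
  }
})

test_that("SA scores are antisymmetric and gauge invariant", {
  comp <- toy_compendium(n_datasets = 3L, n_genes = 30L, n_samples = 6L)
  sig <- signature_set(paste0("g", 1:5), paste0("g", 6:12))
  fw <- score_compendium(comp, sig)
  rev_sig <- signature_set(sig$down, sig$up)
  bw <- score_compendium(comp, rev_sig)
  expect_equal(bw$sa, -fw$sa)

  # adding a sample-specific constant to every gene leaves SA unchanged
  ds <- comp$datasets[[1]]
  ds$values <- sweep(ds$values, 2L, rnorm(ncol(ds$values), 0, 5), `+`)
  shifted <- sapply(colnames(ds$values), function(s)
    score_sample(ds, s, sig)$sa)
  orig <- sapply(colnames(comp$datasets[[1]]$values), function(s)
    score_sample(comp$datasets[[1]], s, sig)$sa)
  expect_equal(shifted, orig)
})

test_that("label shuffling centers SA at zero", {
  ds <- toy_dataset(n_genes = 40L, n_samples = 3L, seed = 77L,
                    normalized = TRUE)
  set.seed(99)
  sas <- replicate(1000, {
    genes <- sample(rownames(ds$values), 12L)
    sig <- signature_set(genes[1:5], genes[6:12])
    score_sample(ds, "s1", sig)$sa
  })
  se <- sd(sas) / sqrt(length(sas))
  expect_lt(abs(mean(sas)), 3 * se)
})

test_that("categorize_scores applies compendium-wide BH", {
  mk <- function(p, sa) data.frame(
    sample_id = paste0("s", seq_along(p)), dataset_id = "d",
    n_up_used = 5L, n_down_used = 5L, w = NA_real_, sa = sa, p = p,
    q = NA_real_, category = "not_significant",
    defined = !is.na(p), stringsAsFactors = FALSE)

  out <- categorize_scores(mk(c(0.001, 0.02, 0.9), c(3, -2, 0.1)))
  expect_equal(out$q, c(0.003, 0.03, 0.9))
  expect_identical(out$category,
                   c("sig_positive", "sig_negative", "not_significant"))

  out2 <- categorize_scores(mk(rep(1, 4), rep(0.5, 4)))
  expect_true(all(out2$q == 1))
  expect_true(all(out2$category == "not_significant"))

  out3 <- categorize_scores(mk(c(1e-8, 1e-9), c(1, 2)), q_threshold = 0)
  expect_true(all(out3$category == "not_significant"))

  # undefined rows are excluded from BH (m counts defined scores only)
  out4 <- categorize_scores(mk(c(0.01, NA, 0.04), c(1, NA, 2)))
  expect_equal(out4$q[out4$defined], c(0.02, 0.04))
  expect_true(is.na(out4$q[2]))
})

test_that("score tables round-trip through write_scores", {
  comp <- toy_compendium(n_datasets = 2L)
  sig <- signature_set(paste0("g", 1:4), paste0("g", 5:10))
  scored <- score_compendium(comp, sig)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_scores(scored, p)
  back <- read.delim(p)
  expect_equal(nrow(back), nrow(scored))
  expect_named(back, c("sample_id", "dataset_id", "n_up_used", "n_down_used",
                       "W", "SA", "p", "q", "category", "defined"))
  expect_equal(back$SA, scored$sa, tolerance = 1e-9)
})
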