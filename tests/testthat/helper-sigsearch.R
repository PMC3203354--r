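# shared in-code fixtures: tiny signatures, datasets, and compendia

toy_signature <- function(k_up = 3L, k_down = 3L, prefix = "g") {
  signature_set(paste0(prefix, seq_len(k_up)),
                paste0(prefix, k_up + seq_len(k_down)),
                name = "toy")
}

# deterministic dataset: n_genes x n_samples of rnorm under a local seed
toy_dataset <- function(n_genes = 10L, n_samples = 5L, seed = 42L,
                        dataset_id = "ds1", normalized = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  ds <- expression_dataset(x, dataset_id, "plat1")
  if (normalized) znormalize(ds) else ds
}

# small synthetic compendium with one optional planted dataset
toy_compendium <- function(n_datasets = 4L, n_genes = 30L, n_samples = 8L,
                           sig = NULL, effect_size = 0,
                           affected_fraction = 0, perturbed = integer(0),
                           seed = 7L) {
  simulate_compendium(synthetic_spec(
    n_genes = n_genes, dataset_sizes = rep(n_samples, n_datasets),
    sig = sig, effect_size = effect_size,
    affected_fraction = affected_fraction,
    perturbed_datasets = perturbed, seed = seed))
}

# brute-force rank-sum oracle: W as the count of (up, down) pairs with
# up-value > down-value, ties counted 1/2
pair_count_w <- function(up_vals, down_vals) {
  s <- 0
  for (u in up_vals) for (d in down_vals) {
    s <- s + if (u > d) 1 else if (u == d) 0.5 else 0
  }
  s
}

# exhaustive null of the SA score: all C(n_up + n_down, n_up) tie-free rank
# assignments, equally likely
enumerate_sa_null <- function(n_up, n_down) {
  n <- n_up + n_down
  combs <- utils::combn(n, n_up)
  apply(combs, 2L, function(r_up) {
    sa_from_w(compute_w(r_up, n_up, n_down), n_up, n_down)
  })
}
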