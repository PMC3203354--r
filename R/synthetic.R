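#' Specification for a synthetic compendium
#'
#' Describes a compendium of standard-normal datasets sharing one gene
#' namespace, with optional planted coordinate effects: in each perturbed
#' dataset, a chosen fraction of samples has \code{effect_size} added to the
#' signature's up genes and subtracted from its down genes before the
#' per-gene z-normalization. The effect size is therefore nominal, in
#' pre-normalization standard-deviation units: normalization rescales it by
#' the induced within-gene variance, so the realized z-shift depends on
#' \code{affected_fraction} (and normalization centers each gene, pushing
#' unaffected samples the opposite way).
#'
#' @param n_genes genes per dataset (all datasets share genes g1..g n_genes).
#' @param dataset_sizes integer vector of per-dataset sample counts.
#' @param sig a \code{\link{signature_set}} whose genes must lie in the
#'   namespace, or NULL when no effect is planted.
#' @param effect_size nominal additive shift, in pre-normalization SD units.
#' @param affected_fraction fraction of samples perturbed per perturbed
#'   dataset, in [0, 1] (round-half-away-from-zero of fraction * n_samples).
#' @param perturbed_datasets integer indices into \code{dataset_sizes}.
#' @param seed master integer seed; each dataset gets its own stream derived
#'   from it by dataset index, so generation is reproducible and
#'   order-independent.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_genes, dataset_sizes, sig = NULL,
                           effect_size = 0, affected_fraction = 0,
                           perturbed_datasets = integer(0), seed = 1L) {
  stopifnot(n_genes >= 1L, all(dataset_sizes >= 2L),
            affected_fraction >= 0, affected_fraction <= 1,
            is.finite(effect_size),
            all(perturbed_datasets >= 1L),
            all(perturbed_datasets <= length(dataset_sizes)))
  genes <- paste0("g", seq_len(n_genes))
  if (!is.null(sig)) {
    outside <- setdiff(c(sig$up, sig$down), genes)
    if (length(outside))
      stop("signature gene(s) outside generated namespace: ",
           paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 dataset_sizes = as.integer(dataset_sizes),
                 sig = sig, effect_size = effect_size,
                 affected_fraction = affected_fraction,
                 perturbed_datasets = as.integer(perturbed_datasets),
                 seed = as.integer(seed), genes = genes),
            class = "synthetic_spec")
}

# per-dataset stream seed, derived from master seed and dataset index;
# kept below 2^31 (R integers are 32-bit)
derive_seed <- function(master, idx) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(idx)) %% 2147483647)
}

#' Simulate a normalized compendium
#'
#' Each dataset is drawn i.i.d. standard normal (genes x samples), planted
#' effects are added where specified, and every gene row is z-normalized
#' across the dataset's samples. Identical (spec, seed) gives a
#' bit-identical compendium.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{\link{compendium}}; each perturbed dataset records which
#'   samples were affected in its \code{affected} component.
#' @export
simulate_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  datasets <- lapply(seq_along(spec$dataset_sizes), function(i) {
    restore <- local_seed(derive_seed(spec$seed, i))
    on.exit(restore(), add = TRUE)
    n_s <- spec$dataset_sizes[i]
    x <- matrix(stats::rnorm(spec$n_genes * n_s), nrow = spec$n_genes,
                dimnames = list(spec$genes,
                                sprintf("d%d_s%d", i, seq_len(n_s))))
    affected <- character(0)
    if (i %in% spec$perturbed_datasets && !is.null(spec$sig) &&
        spec$effect_size != 0 && spec$affected_fraction > 0) {
      k <- as.integer(round_half_up(spec$affected_fraction * n_s))
      k <- min(max(k, 0L), n_s)
      if (k > 0L) {
        cols <- sort(sample.int(n_s, k))
        x[spec$sig$up, cols] <- x[spec$sig$up, cols] + spec$effect_size
        x[spec$sig$down, cols] <- x[spec$sig$down, cols] - spec$effect_size
        affected <- colnames(x)[cols]
      }
    }
    ds <- znormalize(expression_dataset(x, sprintf("synth%03d", i),
                                        platform_id = "synthetic"))
    ds$affected <- affected
    ds
  })
  compendium(datasets)
}

#' Shuffle each gene's values independently across samples
#'
#' The specificity protocol: permuting every gene row independently preserves
#' each row's value multiset (hence its marginal distribution) but destroys
#' any coordinate structure across genes, so planted enrichment must vanish.
#' Deterministic per seed.
#'
#' @param ds an \code{\link{expression_dataset}}.
#' @param seed integer seed.
#' @return the dataset with rows independently permuted.
#' @export
shuffle_genes <- function(ds, seed) {
  stopifnot(inherits(ds, "expression_dataset"))
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  n_s <- ncol(ds$values)
  if (n_s > 1L) {
    for (i in seq_len(nrow(ds$values))) {
      ds$values[i, ] <- ds$values[i, sample.int(n_s)]
    }
  }
  ds
}

#' Draw a random sample subset of a dataset
#'
#' Uniform without-replacement draw of \code{n} columns. By default the
#' subset is re-z-normalized within itself, matching how a smaller series
#' would have been normalized had it been deposited at that size; set
#' \code{renormalize = FALSE} to keep the full-set z-scores for sensitivity
#' analysis. Dataset and platform identity are preserved.
#'
#' @param ds an \code{\link{expression_dataset}}.
#' @param n subset size, 2 <= n <= n_samples.
#' @param seed integer seed.
#' @param renormalize recompute z-scores within the subset (default TRUE).
#' @return an \code{\link{expression_dataset}} with \code{n} samples.
#' @export
subset_samples <- function(ds, n, seed, renormalize = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  n_s <- ncol(ds$values)
  if (n < 2L || n > n_s)
    stop(sprintf("[%s] subset size %d out of range [2, %d]",
                 ds$dataset_id, n, n_s), call. = FALSE)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  cols <- sort(sample.int(n_s, n))
  ds$values <- ds$values[, cols, drop = FALSE]
  if (renormalize) ds <- znormalize(ds)
  ds
}
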