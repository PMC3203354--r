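#' ROC curve and AUC from per-sample scores
#'
#' Standard ROC over score thresholds with tied scores grouped (each unique
#' score contributes one operating point), and area under the curve by the
#' trapezoid rule. With ties handled this way the AUC equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, counting ties as 1/2, and is invariant under strictly
#' increasing score transforms.
#'
#' @param scores numeric vector (higher = more positive call).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return list with \code{curve} (data.frame fpr, tpr, threshold, descending
#'   threshold) and \code{auc}.
#' @export
roc_from_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build a ROC", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores: keep the last index of each tie block
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tpr <- cumsum(l)[keep] / n_pos
  fpr <- cumsum(!l)[keep] / n_neg
  curve <- data.frame(threshold = c(Inf, s[keep]), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1L) +
                                  utils::tail(curve$tpr, -1L)) / 2)
  list(curve = curve, auc = auc)
}

# K-S and Fisher enrichment p-values for one dataset within a categorized
# score table; the workhorse shared by rank_datasets-style sweeps.
enrichment_for <- function(scored, dataset_id, fisher_mode = "exact_2x3",
                           seed = 1L) {
  def <- scored[scored$defined, , drop = FALSE]
  cats <- c("sig_positive", "sig_negative", "not_significant")
  bg_counts <- as.numeric(table(factor(def$category, levels = cats)))
  di <- def[def$dataset_id == dataset_id, , drop = FALSE]
  if (nrow(di) == 0L)
    stop("no defined scores for dataset ", dataset_id, call. = FALSE)
  counts <- as.numeric(table(factor(di$category, levels = cats)))
  c(ks_p = ks_enrichment(di$sa, def$sa),
    fisher_p = fisher_enrichment(counts, bg_counts, mode = fisher_mode,
                                 seed = seed))
}

#' Power / Type-I sweep over sample size, signature size, or composition
#'
#' Reproduces the permutation sweep protocols: a base synthetic compendium is
#' generated once from \code{base_spec} (the first perturbed dataset, or the
#' first dataset when nothing is planted, is the dataset under test); then
#' for each grid setting and replicate the varied ingredient is redrawn —
#' a random sample subset of the test dataset (axis \code{sample_size},
#' re-z-normalized within the subset), or a random signature subset at fixed
#' composition (\code{signature_size}) or at fixed total size
#' (\code{composition}) — the full score + categorize + enrichment path is
#' run against the compendium background, and the fraction of replicates
#' with p below each threshold is tabulated for both tests.
#'
#' @param axis \code{"sample_size"}, \code{"signature_size"}, or
#'   \code{"composition"}.
#' @param grid sample counts, signature sizes, or up-fractions respectively;
#'   validated for feasibility before any computation.
#' @param base_spec a \code{\link{synthetic_spec}}.
#' @param sig the full \code{\link{signature_set}} to subsample (also the
#'   scoring signature on the sample-size axis).
#' @param replicates replicates per setting (default 200).
#' @param seed master seed; the sweep is bit-reproducible given it.
#' @param thresholds p-value thresholds to tabulate (default 0.05, 0.01,
#'   0.001).
#' @param n_total fixed signature size, required for the composition axis.
#' @param q_threshold,min_per_set,fisher_mode scoring/enrichment parameters.
#' @return data.frame of class \code{"sweep_result"}, long format: axis,
#'   setting, test, threshold, sensitivity, replicates, seed.
#' @export
power_sweep <- function(axis = c("sample_size", "signature_size",
                                 "composition"),
                        grid, base_spec, sig, replicates = 200L, seed = 1L,
                        thresholds = c(0.05, 0.01, 0.001), n_total = NULL,
                        q_threshold = 0.1, min_per_set = 2L,
                        fisher_mode = "exact_2x3") {
  axis <- match.arg(axis)
  stopifnot(length(grid) >= 1L, replicates >= 1L)
  comp <- simulate_compendium(base_spec)
  test_idx <- if (length(base_spec$perturbed_datasets))
    base_spec$perturbed_datasets[1L] else 1L
  test_id <- comp$manifest$dataset_id[test_idx]
  test_ds <- comp$datasets[[test_id]]
  up_frac <- n_up(sig) / (n_up(sig) + n_down(sig))

  # feasibility before any computation
  if (axis == "sample_size") {
    if (any(grid < 2L) || any(grid > ncol(test_ds$values)))
      stop(sprintf("sample sizes must lie in [2, %d]", ncol(test_ds$values)),
           call. = FALSE)
  } else if (axis == "signature_size") {
    for (g in grid) {
      k_up <- round_half_up(g * up_frac)
      if (k_up < 1L || g - k_up < 1L || k_up > n_up(sig) ||
          g - k_up > n_down(sig))
        stop("infeasible signature size: ", g, call. = FALSE)
    }
  } else {
    if (is.null(n_total))
      stop("composition axis requires n_total", call. = FALSE)
    for (g in grid) {
      k_up <- round_half_up(n_total * g)
      if (k_up < 1L || n_total - k_up < 1L || k_up > n_up(sig) ||
          n_total - k_up > n_down(sig))
        stop("infeasible up_fraction: ", g, call. = FALSE)
    }
  }

  # background fixed on the sample-size axis: signature does not change
  if (axis == "sample_size") {
    bg_rows <- do.call(rbind, lapply(
      comp$datasets[setdiff(names(comp$datasets), test_id)],
      score_dataset, sig = sig, min_per_set = min_per_set))
  }

  rows <- list()
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    hits <- matrix(0L, nrow = length(thresholds), ncol = 2L,
                   dimnames = list(NULL, c("ks", "fisher")))
    for (r in seq_len(replicates)) {
      rseed <- derive_seed(seed, gi * 100003L + r)
      if (axis == "sample_size") {
        sub <- subset_samples(test_ds, g, seed = rseed)
        scored <- categorize_scores(rbind(bg_rows,
                                          score_dataset(sub, sig,
                                                        min_per_set)),
                                    q_threshold = q_threshold)
      } else {
        sig_r <- if (axis == "signature_size")
          subsample_signature(sig, g, up_frac, seed = rseed)
        else
          subsample_signature(sig, n_total, g, seed = rseed)
        scored <- score_compendium(comp, sig_r, min_per_set = min_per_set,
                                   q_threshold = q_threshold)
      }
      ps <- enrichment_for(scored, test_id, fisher_mode = fisher_mode,
                           seed = rseed)
      hits[, "ks"] <- hits[, "ks"] + (ps[["ks_p"]] < thresholds)
      hits[, "fisher"] <- hits[, "fisher"] + (ps[["fisher_p"]] < thresholds)
    }
    for (test in c("fisher", "ks")) {
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, setting = g, test = test, threshold = thresholds,
        sensitivity = hits[, test] / replicates,
        replicates = replicates, seed = seed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Write a sweep result table
#'
#' Tab-delimited long format: axis, setting, test, threshold, sensitivity,
#' replicates, seed.
#'
#' @param sweep a \code{sweep_result} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
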