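#' Kolmogorov-Smirnov enrichment test for one dataset
#'
#' Two-sample, two-sided K-S test of a dataset's SA scores against the pooled
#' SA scores of all defined samples in the compendium. The background includes
#' the tested dataset's own samples (the pooled distribution has no stated
#' exclusion), which biases slightly toward the null; ties between the dataset
#' and its own copies in the background make the p-value asymptotic.
#'
#' @param dataset_scores numeric vector of the dataset's SA scores (nonempty).
#' @param background_scores pooled SA scores of all defined samples.
#' @return two-sided K-S p-value in (0, 1].
#' @export
ks_enrichment <- function(dataset_scores, background_scores) {
  if (length(dataset_scores) < 1L || length(background_scores) < 1L)
    stop("K-S test needs nonempty score vectors", call. = FALSE)
  p <- suppressWarnings(
    stats::ks.test(dataset_scores, background_scores,
                   alternative = "two.sided")$p.value)
  max(min(p, 1), .Machine$double.xmin)
}

# Exact p for a 2 x k table with fixed margins by enumeration over the first
# row (Freeman-Halton probability ordering): p = sum of the multivariate
# hypergeometric probabilities of all tables no more probable than the
# observed one. The first row is the (small) dataset, so the enumeration is
# O(n^(k-1)) in the dataset size n, not the background size.
freeman_halton_exact <- function(first_row, col_totals) {
  n <- sum(first_row)
  N <- sum(col_totals)
  logp_obs <- sum(lchoose(col_totals, first_row)) - lchoose(N, n)
  k <- length(col_totals)
  grids <- lapply(col_totals[-k], function(cj) 0:min(n, cj))
  tab <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  last <- n - rowSums(tab)
  ok <- last >= 0 & last <= col_totals[k]
  tab <- cbind(tab[ok, , drop = FALSE], last[ok])
  logp <- rep(-lchoose(N, n), nrow(tab))
  for (j in seq_len(k)) logp <- logp + lchoose(col_totals[j], tab[, j])
  sum(exp(logp[logp <= logp_obs + 1e-7]))
}

# Monte-Carlo version for tables too large to enumerate: draws B tables with
# the observed margins (stats::r2dtable) and estimates the tail fraction.
freeman_halton_mc <- function(first_row, second_row, B = 1e5L, seed = 1L) {
  col_totals <- first_row + second_row
  n <- sum(first_row)
  N <- sum(col_totals)
  logp_obs <- sum(lchoose(col_totals, first_row)) - lchoose(N, n)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  draws <- stats::r2dtable(B, c(n, sum(second_row)), col_totals)
  logp <- vapply(draws, function(tb) {
    sum(lchoose(col_totals, tb[1L, ])) - lchoose(N, n)
  }, numeric(1L))
  (1 + sum(logp <= logp_obs + 1e-7)) / (B + 1)
}

#' Fisher exact enrichment test on categorized SA scores
#'
#' Tests whether a dataset's categorical SA distribution (sig_positive,
#' sig_negative, not_significant) differs from the compendium background by an
#' exact test on the 2 x 3 table (dataset vs rest-of-compendium rows). The
#' exact 2 x 3 (Freeman-Halton) p is computed by full enumeration of tables
#' with the observed margins when that enumeration is at most \code{max_enum}
#' tables, otherwise by Monte-Carlo with at least 1e5 draws at a fixed seed.
#' A dataset enriched only in non-significant samples is uninteresting by
#' construction, so after the test the override applies: if the dataset's
#' proportion of not_significant samples exceeds the background's, p is set
#' to exactly 1.
#'
#' @param dataset_counts integer 3-vector (sig_positive, sig_negative,
#'   not_significant) for the dataset.
#' @param background_counts 3-vector for all defined samples in the
#'   compendium (componentwise >= dataset_counts).
#' @param mode \code{"exact_2x3"} (Freeman-Halton; Monte-Carlo fallback above
#'   \code{max_enum}), \code{"collapse_2x2"} (significant-vs-not 2 x 2 exact
#'   test), or \code{"monte_carlo"} (force the Monte-Carlo path).
#' @param override apply the excess-non-significant p := 1 rule (default
#'   TRUE).
#' @param max_enum enumeration cap in number of tables (default 1e7).
#' @param mc_draws,seed Monte-Carlo draw count and seed.
#' @return p-value in (0, 1].
#' @export
fisher_enrichment <- function(dataset_counts, background_counts,
                              mode = c("exact_2x3", "collapse_2x2",
                                       "monte_carlo"),
                              override = TRUE, max_enum = 1e7,
                              mc_draws = 1e5L, seed = 1L) {
  mode <- match.arg(mode)
  d <- as.numeric(dataset_counts)
  bg <- as.numeric(background_counts)
  stopifnot(length(d) == 3L, length(bg) == 3L)
  if (any(d < 0) || any(bg < d))
    stop("inconsistent margins: dataset counts must be 0 <= d <= background",
         call. = FALSE)
  rest <- bg - d
  n <- sum(d); N <- sum(bg)
  if (n == 0L) stop("dataset has no categorized samples", call. = FALSE)
  if (mode == "collapse_2x2") {
    d2 <- c(d[1L] + d[2L], d[3L])
    bg2 <- c(bg[1L] + bg[2L], bg[3L])
    p <- freeman_halton_exact(d2, bg2)
  } else {
    n_tables <- (n + 1) * (n + 2) / 2
    if (mode == "monte_carlo" || n_tables > max_enum) {
      p <- freeman_halton_mc(d, rest, B = as.integer(mc_draws), seed = seed)
    } else {
      p <- freeman_halton_exact(d, bg)
    }
  }
  p <- max(min(p, 1), .Machine$double.xmin)
  if (override && d[3L] / n > bg[3L] / N) p <- 1
  p
}

#' Rank datasets by enrichment of signature-associated samples
#'
#' For each dataset with at least one defined SA score, computes the K-S
#' p-value of its SA distribution against the pooled background and the
#' Fisher exact p-value of its category counts against the compendium-wide
#' counts, then Benjamini-Hochberg-adjusts each p-value vector across
#' datasets. Datasets whose every score is undefined are omitted and listed
#' in a message to standard error. Output is sorted ascending by
#' \code{ks_q}, then \code{fisher_q}, then \code{dataset_id}.
#'
#' @param scores a categorized \code{sample_scores} data.frame (from
#'   \code{\link{score_compendium}} or \code{\link{categorize_scores}}).
#' @param q_threshold FDR cutoff used for the categories; recorded on the
#'   result.
#' @param fisher_mode passed to \code{\link{fisher_enrichment}}.
#' @param seed seed for any Monte-Carlo Fisher fallback.
#' @return data.frame of class \code{"dataset_enrichment"} with columns
#'   dataset_id, n_samples_scored, n_sig_pos, n_sig_neg, n_ns, ks_p, ks_q,
#'   fisher_p, fisher_q, direction.
#' @export
rank_datasets <- function(scores, q_threshold = 0.1,
                          fisher_mode = c("exact_2x3", "collapse_2x2",
                                          "monte_carlo"),
                          seed = 1L) {
  fisher_mode <- match.arg(fisher_mode)
  def <- scores[scores$defined, , drop = FALSE]
  skipped <- setdiff(unique(scores$dataset_id), unique(def$dataset_id))
  if (length(skipped))
    message("skipped dataset(s) with no defined scores: ",
            paste(skipped, collapse = ", "))
  if (nrow(def) == 0L) stop("no defined SA scores in compendium", call. = FALSE)
  cats <- c("sig_positive", "sig_negative", "not_significant")
  bg_counts <- as.numeric(table(factor(def$category, levels = cats)))
  background <- def$sa
  ids <- unique(def$dataset_id)
  rows <- lapply(ids, function(id) {
    di <- def[def$dataset_id == id, , drop = FALSE]
    counts <- as.numeric(table(factor(di$category, levels = cats)))
    data.frame(dataset_id = id,
               n_samples_scored = nrow(di),
               n_sig_pos = counts[1L], n_sig_neg = counts[2L],
               n_ns = counts[3L],
               ks_p = ks_enrichment(di$sa, background),
               fisher_p = fisher_enrichment(counts, bg_counts,
                                            mode = fisher_mode, seed = seed),
               direction = if (counts[1L] > counts[2L]) "positive"
                           else if (counts[2L] > counts[1L]) "negative"
                           else "mixed",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$ks_q <- stats::p.adjust(res$ks_p, method = "BH")
  res$fisher_q <- stats::p.adjust(res$fisher_p, method = "BH")
  res <- res[order(res$ks_q, res$fisher_q, res$dataset_id), ,
             drop = FALSE]
  res <- res[, c("dataset_id", "n_samples_scored", "n_sig_pos", "n_sig_neg",
                 "n_ns", "ks_p", "ks_q", "fisher_p", "fisher_q", "direction")]
  rownames(res) <- NULL
  class(res) <- c("dataset_enrichment", "data.frame")
  attr(res, "q_threshold") <- q_threshold
  attr(res, "background_counts") <- bg_counts
  res
}

#' Write a per-dataset enrichment table
#'
#' Tab-delimited, sorted ascending by ks_q (then fisher_q, then dataset_id):
#' dataset_id, n_samples_scored, n_sig_pos, n_sig_neg, n_ns, ks_p, ks_q,
#' fisher_p, fisher_q, direction.
#'
#' @param enrichment a \code{dataset_enrichment} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
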