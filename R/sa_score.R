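#' Wilcoxon rank-sum W statistic from up-gene ranks
#'
#' Given the midranks of the pooled up and down signature-gene values within
#' one sample, W = sum(ranks of up genes) - n_up(n_up+1)/2. W ranges from 0
#' (every down gene outranks every up gene) to n_up*n_down (perfect
#' concordance with the signature), and equals the number of (up, down) pairs
#' in which the up gene has the larger value, counting ties as 1/2.
#'
#' @param ranks_up numeric vector of the up genes' midranks in the pooled set.
#' @param n_up,n_down effective set sizes (both >= 1).
#' @return the W statistic, a scalar in [0, n_up*n_down].
#' @export
compute_w <- function(ranks_up, n_up, n_down) {
  if (n_up < 1L || n_down < 1L)
    stop("W undefined: need at least one up and one down gene", call. = FALSE)
  if (length(ranks_up) != n_up)
    stop("ranks_up must have length n_up", call. = FALSE)
  sum(ranks_up) - n_up * (n_up + 1) / 2
}

#' Signature association (SA) score from W
#'
#' Standardizes W against the mean and standard deviation of its null
#' distribution: mu = n_up*n_down/2 and
#' sigma = sqrt(n_up*n_down*(n_up+n_down+1)/12), giving SA = (W - mu)/sigma.
#' Positive SA: the sample's up genes outrank its down genes (coordinate
#' expression in the signature's direction); negative SA: the reverse.
#' Antisymmetric under swapping the up and down sets. No tie correction is
#' applied to sigma and no continuity correction to SA: the untied closed
#' forms above are the contract, and ties are rare in continuous z-scores.
#'
#' @param w the W statistic.
#' @param n_up,n_down effective set sizes.
#' @return the dimensionless SA score.
#' @export
sa_from_w <- function(w, n_up, n_down) {
  stopifnot(n_up >= 1L, n_down >= 1L)
  mu <- n_up * n_down / 2
  sigma <- sqrt(n_up * n_down * (n_up + n_down + 1) / 12)
  (w - mu) / sigma
}

#' Two-sided p-value for an SA score
#'
#' The SA score's null distribution is approximated by a t distribution with
#' n_up + n_down - 2 degrees of freedom; the p-value is the two-sided tail
#' probability of |sa|.
#'
#' @param sa SA score (vectorized).
#' @param n_up,n_down effective set sizes with n_up + n_down >= 3.
#' @return two-sided p-value in (0, 1].
#' @export
sa_pvalue <- function(sa, n_up, n_down) {
  df <- n_up + n_down - 2
  if (df < 1) stop("degrees of freedom below 1", call. = FALSE)
  2 * stats::pt(-abs(sa), df = df)
}

# Score every sample of one normalized dataset; returns a data.frame row set.
# Undefined scores (effective set below min_per_set) get NA statistics and
# defined = FALSE, never an exception: platform coverage legitimately varies.
score_dataset <- function(ds, sig, min_per_set = 2L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!ds$normalized)
    stop(sprintf("[%s] dataset must be z-normalized before scoring",
                 ds$dataset_id), call. = FALSE)
  genes <- rownames(ds$values)
  eff_up <- intersect(sig$up, genes)
  eff_dn <- intersect(sig$down, genes)
  nu <- length(eff_up); nd <- length(eff_dn)
  samples <- colnames(ds$values)
  base <- data.frame(sample_id = samples, dataset_id = ds$dataset_id,
                     n_up_used = nu, n_down_used = nd,
                     w = NA_real_, sa = NA_real_, p = NA_real_, q = NA_real_,
                     category = "not_significant", defined = FALSE,
                     stringsAsFactors = FALSE)
  if (nu < min_per_set || nd < min_per_set) return(base)
  vals <- ds$values[c(eff_up, eff_dn), , drop = FALSE]
  ranks <- apply(vals, 2L, rank)            # midranks, per sample
  w <- colSums(ranks[seq_len(nu), , drop = FALSE]) - nu * (nu + 1) / 2
  base$w <- as.numeric(w)
  base$sa <- sa_from_w(base$w, nu, nd)
  base$p <- sa_pvalue(base$sa, nu, nd)
  base$defined <- TRUE
  base
}

#' Score one sample of a dataset against a signature
#'
#' Intersects the signature's up and down sets with the dataset's genes,
#' midranks the pooled effective-set z-scores for the sample, and returns the
#' W statistic, SA score, and t-based p-value. If either effective set is
#' smaller than \code{min_per_set} the score is flagged undefined
#' (\code{defined = FALSE}, NA statistics) and is excluded downstream.
#'
#' @param ds a z-normalized \code{\link{expression_dataset}}.
#' @param sample_id one of the dataset's sample identifiers.
#' @param sig a \code{\link{signature_set}}.
#' @param min_per_set minimum effective genes per direction (default 2; below
#'   this the t approximation with n_up+n_down-2 df is meaningless).
#' @return one-row data.frame with columns sample_id, dataset_id, n_up_used,
#'   n_down_used, w, sa, p, q, category, defined.
#' @export
score_sample <- function(ds, sample_id, sig, min_per_set = 2L) {
  if (!sample_id %in% colnames(ds$values))
    stop(sprintf("[%s] no such sample: %s", ds$dataset_id, sample_id),
         call. = FALSE)
  out <- score_dataset(ds, sig, min_per_set = min_per_set)
  out[out$sample_id == sample_id, , drop = FALSE]
}

#' Score every sample in a compendium
#'
#' Applies SA scoring to each dataset and pools the per-sample rows, then
#' fills in q-values and significance categories with
#' \code{\link{categorize_scores}}.
#'
#' @param comp a \code{\link{compendium}}.
#' @param sig a \code{\link{signature_set}}.
#' @param min_per_set see \code{\link{score_sample}}.
#' @param q_threshold FDR cutoff defining per-sample significance (default
#'   0.1).
#' @return data.frame of class \code{"sample_scores"}, one row per sample.
#' @export
score_compendium <- function(comp, sig, min_per_set = 2L, q_threshold = 0.1) {
  stopifnot(inherits(comp, "compendium"))
  rows <- do.call(rbind, lapply(comp$datasets, score_dataset, sig = sig,
                                min_per_set = min_per_set))
  rownames(rows) <- NULL
  categorize_scores(rows, q_threshold = q_threshold)
}

#' Assign q-values and significance categories to sample scores
#'
#' Benjamini-Hochberg correction is applied to the p-values of all defined
#' scores pooled across the whole compendium (every sample of every dataset:
#' each dataset is ultimately compared against all samples in all datasets,
#' so the per-sample multiplicity is compendium-wide). A sample is
#' \code{sig_positive} if q <= threshold and SA > 0, \code{sig_negative} if
#' q <= threshold and SA < 0, otherwise \code{not_significant}.
#'
#' @param scores data.frame of sample scores (from \code{score_dataset} /
#'   \code{\link{score_compendium}}).
#' @param q_threshold FDR cutoff (default 0.1).
#' @return the scores with \code{q} and \code{category} filled, class
#'   \code{"sample_scores"}.
#' @export
categorize_scores <- function(scores, q_threshold = 0.1) {
  def <- scores$defined
  scores$q <- NA_real_
  if (any(def)) scores$q[def] <- stats::p.adjust(scores$p[def], method = "BH")
  scores$category <- "not_significant"
  sig <- def & !is.na(scores$q) & scores$q <= q_threshold
  scores$category[sig & scores$sa > 0] <- "sig_positive"
  scores$category[sig & scores$sa < 0] <- "sig_negative"
  class(scores) <- c("sample_scores", "data.frame")
  attr(scores, "q_threshold") <- q_threshold
  scores
}

#' Write a per-sample score table
#'
#' Tab-delimited, one row per sample: sample_id, dataset_id, n_up_used,
#' n_down_used, W, SA, p, q, category, defined. Undefined scores are emitted
#' with NA statistics and defined = FALSE.
#'
#' @param scores a \code{sample_scores} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores[, c("sample_id", "dataset_id", "n_up_used", "n_down_used",
                    "w", "sa", "p", "q", "category", "defined")]
  names(out)[5:6] <- c("W", "SA")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
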