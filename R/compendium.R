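#' Construct an expression dataset
#'
#' One dataset (a GEO-series-like unit) holds a genes x samples matrix of
#' expression values for a single platform. Before normalization values are on
#' an arbitrary expression scale; after \code{\link{znormalize}} each gene row
#' is a dimensionless relative-expression z-score across that dataset's
#' samples. Rows containing missing values are dropped with a warning: the
#' intended upstream (RMA-style) summarization produces complete matrices, and
#' imputing would invent data.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene identifiers) and colnames (sample identifiers).
#' @param dataset_id dataset label, e.g. a series accession.
#' @param platform_id platform label; normalization blocks never span
#'   platforms.
#' @param normalized logical; TRUE if rows are already z-scores.
#' @return an object of class \code{"expression_dataset"}.
#' @export
expression_dataset <- function(values, dataset_id, platform_id = "platform0",
                               normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in dataset ", dataset_id, call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in dataset ", dataset_id, call. = FALSE)
  bad <- rowSums(!is.finite(values)) > 0L
  if (any(bad)) {
    warning(sprintf("[%s] dropping %d gene row(s) with missing values",
                    dataset_id, sum(bad)), call. = FALSE)
    values <- values[!bad, , drop = FALSE]
  }
  structure(list(dataset_id = as.character(dataset_id)[1L],
                 platform_id = as.character(platform_id)[1L],
                 values = values,
                 normalized = isTRUE(normalized)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s' (%s): %d genes x %d samples%s\n",
              x$dataset_id, x$platform_id, nrow(x$values), ncol(x$values),
              if (x$normalized) ", z-normalized" else ""))
  invisible(x)
}

#' Within-dataset per-gene z-score normalization
#'
#' Each gene row is centered and scaled to mean 0, standard deviation 1
#' (sample sd, divisor n-1) across the dataset's samples, converting absolute
#' expression into relative expression within the dataset. Zero-variance rows
#' map to all-zero rows: a gene constant within a dataset carries mid-rank
#' information only, which an all-zero row represents honestly. Idempotent up
#' to floating point, and invariant to positive affine transforms of each row.
#'
#' @param ds an \code{\link{expression_dataset}} with at least 2 samples.
#' @return the dataset with normalized values and \code{normalized = TRUE}.
#' @export
znormalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  x <- ds$values
  if (ncol(x) < 2L)
    stop(sprintf("[%s] z-score undefined for a single-sample dataset",
                 ds$dataset_id), call. = FALSE)
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  z <- xc / sdv
  z[sdv == 0, ] <- 0
  ds$values <- z
  ds$normalized <- TRUE
  ds
}

#' Assemble a normalized compendium from datasets
#'
#' A compendium is a named collection of per-dataset z-normalized matrices
#' sharing a gene namespace (the union of dataset gene sets; genes absent from
#' a dataset's platform are simply absent there, never imputed). Datasets not
#' yet normalized are passed through \code{\link{znormalize}}.
#'
#' @param datasets list of \code{\link{expression_dataset}} objects.
#' @return an object of class \code{"compendium"} with components
#'   \code{datasets} (named list) and \code{manifest} (data.frame of
#'   dataset_id, platform_id, n_genes, n_samples).
#' @export
compendium <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  ids <- vapply(datasets, function(d) d$dataset_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate dataset_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  datasets <- lapply(datasets, function(d) if (d$normalized) d else znormalize(d))
  names(datasets) <- ids
  manifest <- data.frame(
    dataset_id = ids,
    platform_id = vapply(datasets, function(d) d$platform_id, character(1L)),
    n_genes = vapply(datasets, function(d) nrow(d$values), integer(1L)),
    n_samples = vapply(datasets, function(d) ncol(d$values), integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(datasets = datasets, manifest = manifest),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d datasets, %d samples, %d genes in union namespace\n",
              length(x$datasets), sum(x$manifest$n_samples),
              length(unique(unlist(lapply(x$datasets,
                                          function(d) rownames(d$values)))))))
  invisible(x)
}

#' Write a compendium to a manifest plus matrix files
#'
#' Matrices are tab-delimited with a \code{gene_id} first column and a header
#' row of sample identifiers. The manifest is tab-delimited with columns
#' \code{dataset_id}, \code{platform_id}, \code{path},
#' \code{already_normalized}.
#'
#' @param comp a \code{\link{compendium}}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_compendium <- function(comp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(comp$datasets, function(d) {
    fn <- paste0(d$dataset_id, ".tsv")
    df <- data.frame(gene_id = rownames(d$values), d$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(dataset_id = d$dataset_id, platform_id = d$platform_id,
               path = fn, already_normalized = d$normalized,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Load a compendium from a manifest
#'
#' Reads the manifest written by \code{\link{write_compendium}} (or assembled
#' by hand): tab-delimited columns \code{dataset_id}, \code{platform_id},
#' \code{path} (relative to the manifest or absolute), and
#' \code{already_normalized}. Datasets flagged as not yet normalized are
#' z-normalized on load. Progress and skipped rows are logged to standard
#' error with the dataset_id as context.
#'
#' @param manifest_path path to the manifest file.
#' @return a \code{\link{compendium}}.
#' @export
load_compendium <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "platform_id", "path", "already_normalized")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$dataset_id))
    stop("duplicate dataset_id in manifest: ",
         man$dataset_id[duplicated(man$dataset_id)][1L], call. = FALSE)
  base <- dirname(manifest_path)
  datasets <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop(sprintf("[%s] matrix file not readable: %s",
                   man$dataset_id[i], man$path[i]), call. = FALSE)
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1L, drop = FALSE])
    rownames(vals) <- as.character(df[[1L]])
    expression_dataset(vals, man$dataset_id[i], man$platform_id[i],
                       normalized = isTRUE(as.logical(man$already_normalized[i])))
  })
  message(sprintf("loaded %d dataset(s) from %s", length(datasets),
                  manifest_path))
  compendium(datasets)
}
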