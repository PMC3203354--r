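#' Construct a query signature
#'
#' A signature is a named pair of disjoint gene-identifier sets: genes
#' coordinately induced (\code{up}) and repressed (\code{down}) under some
#' reference perturbation. Identifiers are opaque text (typically Entrez Gene
#' IDs); no translation is attempted. Surrounding whitespace is stripped and
#' case is preserved.
#'
#' @param up character vector of up-regulated gene identifiers.
#' @param down character vector of down-regulated gene identifiers.
#' @param name text label for the signature.
#' @return An object of class \code{"signature_set"} with components
#'   \code{name}, \code{up}, \code{down}.
#' @examples
#' sig <- signature_set(c("g1", "g2"), c("g3"), name = "toy")
#' n_up(sig); n_down(sig)
#' @export
signature_set <- function(up, down, name = "signature") {
  up <- unique(trimws(as.character(up)))
  down <- unique(trimws(as.character(down)))
  up <- up[nzchar(up)]
  down <- down[nzchar(down)]
  both <- intersect(up, down)
  if (length(both) > 0L) {
    stop("gene(s) listed in both up and down sets: ",
         paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(up) < 1L || length(down) < 1L) {
    stop("signature must have at least one up and one down gene", call. = FALSE)
  }
  structure(list(name = as.character(name)[1L], up = up, down = down),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Signature set sizes
#' @param sig a \code{signature_set}.
#' @return integer count of up (resp. down) genes.
#' @export
n_up <- function(sig) length(sig$up)

#' @rdname n_up
#' @export
n_down <- function(sig) length(sig$down)

#' Read a query signature from a file
#'
#' Two plain-text layouts are supported. \code{two_column}: tab-delimited rows
#' of \code{gene_id<TAB>direction} with direction \code{up} or \code{down}
#' (case-insensitive); an optional header row \code{gene\\tdirection} is
#' detected and skipped. \code{gmt_pair}: a standard GMT file containing two
#' records whose names end in \code{_UP} and \code{_DOWN} (first field name,
#' second description, remaining fields the member genes).
#'
#' Duplicate (gene, direction) rows collapse to a single entry; a gene listed
#' in both directions is a validation error naming the gene.
#'
#' @param path path to the signature file.
#' @param format \code{"two_column"} or \code{"gmt_pair"}.
#' @param name signature label; defaults to the file name (two_column) or the
#'   shared GMT record prefix (gmt_pair).
#' @return a \code{\link{signature_set}}.
#' @export
read_signature <- function(path, format = c("two_column", "gmt_pair"),
                           name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("signature file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "two_column") {
    if (length(lines) && grepl("^\\s*gene\\s*\t\\s*direction\\s*$",
                               lines[1L], ignore.case = TRUE)) {
      lines <- lines[-1L]
    }
    up <- character(0); down <- character(0)
    for (i in seq_along(lines)) {
      fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
      if (length(fields) < 2L) {
        stop(sprintf("line %d: expected 'gene\\tdirection', got '%s'",
                     i, lines[[i]]), call. = FALSE)
      }
      dir <- tolower(fields[2L])
      if (dir == "up") up <- c(up, fields[1L])
      else if (dir == "down") down <- c(down, fields[1L])
      else stop(sprintf("line %d: unknown direction token '%s'", i, fields[2L]),
                call. = FALSE)
    }
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
    return(signature_set(up, down, name = name))
  }
  # gmt_pair
  recs <- lapply(lines, function(l) trimws(strsplit(l, "\t", fixed = TRUE)[[1L]]))
  rec_names <- vapply(recs, `[`, character(1L), 1L)
  i_up <- grep("_UP$", rec_names)
  i_dn <- grep("_DOWN$", rec_names)
  if (length(i_up) != 1L || length(i_dn) != 1L) {
    stop("gmt_pair file must contain exactly one *_UP and one *_DOWN record",
         call. = FALSE)
  }
  up <- recs[[i_up]][-(1:2)]
  down <- recs[[i_dn]][-(1:2)]
  if (is.null(name)) name <- sub("_UP$", "", rec_names[i_up])
  signature_set(up, down, name = name)
}

#' Write a signature to a file
#'
#' Inverse of \code{\link{read_signature}}: the parse/write/parse round trip
#' is the identity on the up and down gene sets for both formats.
#'
#' @param sig a \code{signature_set}.
#' @param path output path.
#' @param format \code{"two_column"} or \code{"gmt_pair"}.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(sig, path, format = c("two_column", "gmt_pair")) {
  format <- match.arg(format)
  if (format == "two_column") {
    lines <- c("gene\tdirection",
               paste0(sig$up, "\tup"),
               paste0(sig$down, "\tdown"))
  } else {
    lines <- c(paste(c(paste0(sig$name, "_UP"), "na", sig$up), collapse = "\t"),
               paste(c(paste0(sig$name, "_DOWN"), "na", sig$down), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# round half away from zero; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Subsample a signature at a given size and up/down composition
#'
#' Draws \code{round(n_total * up_fraction)} up genes (round half away from
#' zero) and the remaining \code{n_total - } that many down genes, each
#' uniformly without replacement. Used by the power sweeps that vary signature
#' size at fixed composition, or composition at fixed size.
#'
#' @param sig a \code{signature_set}.
#' @param n_total total number of genes requested.
#' @param up_fraction proportion of up genes, in (0, 1).
#' @param seed integer seed; identical inputs give identical output.
#' @return a \code{signature_set} with the requested composition.
#' @export
subsample_signature <- function(sig, n_total, up_fraction, seed) {
  stopifnot(n_total >= 2L, up_fraction > 0, up_fraction < 1)
  k_up <- as.integer(round_half_up(n_total * up_fraction))
  k_down <- as.integer(n_total) - k_up
  if (k_up < 1L || k_down < 1L) {
    stop(sprintf("infeasible composition: n_total=%d, up_fraction=%.4g gives %d up / %d down",
                 n_total, up_fraction, k_up, k_down), call. = FALSE)
  }
  if (k_up > n_up(sig) || k_down > n_down(sig)) {
    stop(sprintf("requested %d up / %d down but signature has %d up / %d down",
                 k_up, k_down, n_up(sig), n_down(sig)), call. = FALSE)
  }
  withr_seed <- local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  up <- if (k_up == n_up(sig)) sig$up else sample(sig$up, k_up)
  down <- if (k_down == n_down(sig)) sig$down else sample(sig$down, k_down)
  signature_set(up, down, name = sprintf("%s_sub%d", sig$name, n_total))
}

# Set the RNG seed, returning a restorer for the previous RNG state.
# All package randomness funnels through this so user sessions are untouched.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
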