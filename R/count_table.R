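#' Microbial read-count table
#'
#' Container for a taxa-by-samples matrix of non-negative integer read counts
#' together with per-taxon annotation (display name and domain, fungal or
#' archaeal). This is the shape that per-sample metagenomic classifier
#' reports (e.g. PathoScope-style output) take once aggregated into a single
#' matrix.
#'
#' @param counts integer matrix, taxa in rows, samples in columns. Row names
#'   are taxon ids and column names sample ids; both must be unique.
#' @param taxa data frame with columns `id`, `name`, `domain`
#'   (`"fungal"`/`"archaeal"`), one row per row of `counts` in the same
#'   order. If `NULL`, minimal annotation is derived from the row names and
#'   every taxon is labelled fungal.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix), `taxa` (annotation data frame) and `samples`
#'   (character vector of sample ids).
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("T", 1:3), c("s1", "s2")))
#' ct <- count_table(m)
#' dim(ct)
#' @export
count_table <- function(counts, taxa = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("taxon%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%04d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (is.null(taxa)) {
    taxa <- data.frame(
      id = rownames(counts), name = rownames(counts),
      domain = "fungal", stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(taxa), all(c("id", "name", "domain") %in% names(taxa)))
  if (nrow(taxa) != nrow(counts) ||
      (nrow(counts) > 0 &&
       !identical(as.character(taxa$id), rownames(counts)))) {
    stop("taxa annotation must match count matrix rows (same ids, same order)")
  }
  if (!all(taxa$domain %in% c("fungal", "archaeal"))) {
    stop("taxon domain must be 'fungal' or 'archaeal'")
  }
  structure(
    list(counts = counts, taxa = taxa, samples = colnames(counts)),
    class = "count_table"
  )
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @export
print.count_table <- function(x, ...) {
  nd <- table(factor(x$taxa$domain, levels = c("fungal", "archaeal")))
  cat(sprintf(
    "count_table: %d taxa (%d fungal, %d archaeal) x %d samples\n",
    nrow(x$counts), nd[["fungal"]], nd[["archaeal"]], ncol(x$counts)
  ))
  cat(sprintf("total reads: %.0f\n", sum(as.numeric(x$counts))))
  invisible(x)
}

#' Subset a count table by taxa and/or samples
#'
#' @param x a [count_table].
#' @param taxa,samples character vectors of ids (or logical/integer indices)
#'   to keep; `NULL` keeps everything.
#' @return A `count_table` restricted to the requested rows/columns.
#' @export
subset_count_table <- function(x, taxa = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_table"))
  ti <- if (is.null(taxa)) seq_len(nrow(x$counts)) else taxa
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else samples
  m <- x$counts[ti, si, drop = FALSE]
  ann <- x$taxa[match(rownames(m), x$taxa$id), , drop = FALSE]
  rownames(ann) <- NULL
  count_table(m, ann)
}
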