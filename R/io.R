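#' @importFrom utils read.delim write.table
NULL

# strict TSV split used by the readers: readLines + split keeps full control
# over ragged-row and malformed-cell reporting.
read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    c(
      paste(names(df), collapse = "\t"),
      do.call(paste, c(lapply(df, function(x) {
        x <- as.character(x)
        x[is.na(x)] <- "NA"
        x
      }), sep = "\t"))
    ),
    con, sep = "\n", useBytes = TRUE
  )
  invisible(path)
}

#' Read a taxon-by-sample read-count TSV
#'
#' The canonical count layout: a header row of `taxon_id`, `taxon_name`,
#' `domain` followed by sample ids; one row per taxon with integer counts.
#' This is the natural aggregation of per-sample metagenomic classifier
#' reports into one matrix.
#'
#' @param path path to a tab-separated file.
#' @return A [count_table].
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  rows <- read_tsv_lines(path)
  header <- rows[[1L]]
  if (length(header) < 4L ||
      !identical(header[1:3], c("taxon_id", "taxon_name", "domain"))) {
    stop("count table must start with columns taxon_id, taxon_name, domain")
  }
  body <- rows[-1L]
  ncol_exp <- length(header)
  bad <- which(vapply(body, length, 1L) != ncol_exp)
  if (length(bad)) stop("ragged row(s) in count table: line ", bad[1L] + 1L)
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate taxon id: ", ids[duplicated(ids)][1L])
  nms <- vapply(body, `[[`, "", 2L)
  dom <- vapply(body, `[[`, "", 3L)
  samp <- header[-(1:3)]
  cells <- unlist(lapply(body, `[`, -(1:3)), use.names = FALSE)
  if (!all(grepl("^[0-9]+$", cells))) {
    bad_cell <- cells[!grepl("^[0-9]+$", cells)][1L]
    stop("non-integer or negative count cell: '", bad_cell, "'")
  }
  m <- matrix(as.integer(cells), nrow = length(body), byrow = TRUE,
              dimnames = list(ids, samp))
  count_table(m, data.frame(id = ids, name = nms, domain = dom,
                            stringsAsFactors = FALSE))
}

#' Write a count table to TSV
#'
#' @param x a [count_table].
#' @param path output path (UTF-8, LF, tab-separated).
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(
    taxon_id = x$taxa$id, taxon_name = x$taxa$name, domain = x$taxa$domain,
    x$counts, check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

sample_metadata_columns <- c(
  "sample_id", "patient_id", "tissue", "subtype", "gender",
  "seq_date", "seq_plate", "braf_v600e",
  "vital_status", "perineural_invasion", "pathologic_stage",
  "t_stage", "n_stage", "m_stage"
)

#' Clinical variables carried in the sample metadata
#' @return Character vector of the six clinical column names.
#' @export
clinical_variables <- function() {
  c("vital_status", "perineural_invasion", "pathologic_stage",
    "t_stage", "n_stage", "m_stage")
}

validate_enum <- function(x, levels, column, hard = FALSE) {
  x[x == "NA" | x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    if (hard) {
      stop(sprintf("invalid %s value '%s' (allowed: %s)",
                   column, x[bad][1L], paste(levels, collapse = ", ")))
    }
    warning(sprintf("%d unknown %s level(s) (e.g. '%s') set to NA",
                    sum(bad), column, x[bad][1L]), call. = FALSE)
    x[bad] <- NA_character_
  }
  x
}

#' Read per-sample metadata
#'
#' Reads the tab-separated sample annotation table: tissue class, histologic
#' subtype, gender, sequencing date and plate, BRAF V600E status, and the six
#' clinical variables. Enum columns are validated; unknown levels become `NA`
#' with a warning, except `tissue`, which must be `tumor` or `normal`.
#' Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path path to a TSV file with (at least) the columns
#'   `sample_id, patient_id, tissue, subtype, gender, seq_date, seq_plate,
#'   braf_v600e, vital_status, perineural_invasion, pathologic_stage,
#'   t_stage, n_stage, m_stage`.
#' @return A data frame, one row per sample, `seq_date` as `Date`.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  missing <- setdiff(sample_metadata_columns, names(df))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df$tissue <- validate_enum(df$tissue, c("tumor", "normal"), "tissue",
                             hard = TRUE)
  if (anyNA(df$tissue)) stop("tissue may not be NA")
  df$subtype <- validate_enum(df$subtype, c("CPTC", "FVPTC", "TCPTC"), "subtype")
  if (any(!is.na(df$subtype) & df$tissue == "normal")) {
    stop("subtype must be NA for normal samples")
  }
  df$gender <- validate_enum(df$gender, c("male", "female"), "gender")
  df$braf_v600e <- validate_enum(df$braf_v600e, c("positive", "negative"),
                                 "braf_v600e")
  ok_date <- grepl("^\\d{4}-\\d{2}-\\d{2}$", df$seq_date)
  if (!all(ok_date)) {
    stop("seq_date must be ISO-8601 YYYY-MM-DD; offending value: '",
         df$seq_date[!ok_date][1L], "'")
  }
  df$seq_date <- as.Date(df$seq_date)
  for (v in clinical_variables()) {
    df[[v]][df[[v]] %in% c("NA", "")] <- NA_character_
  }
  df
}

#' Write sample metadata to TSV
#' @param meta data frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  missing <- setdiff(sample_metadata_columns, names(meta))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- meta[, sample_metadata_columns]
  out$seq_date <- format(as.Date(out$seq_date), "%Y-%m-%d")
  write_tsv(out, path)
}

#' Read/write GCT v1.2 expression matrices
#'
#' GCT is the tab-separated expression format used by gene-set enrichment
#' tools: a `#1.2` version line, a dimensions line, then a header
#' (`Name`, `Description`, sample ids) and one row per gene.
#'
#' @param path file path.
#' @return `read_gct()` returns a list with `values` (numeric matrix,
#'   genes x samples, gene symbols upper-cased as row names) and
#'   `description` (character vector).
#' @export
read_gct <- function(path) {
  rows <- read_tsv_lines(path)
  if (!identical(rows[[1L]][1L], "#1.2")) stop("not a GCT 1.2 file (missing #1.2)")
  dims <- suppressWarnings(as.integer(rows[[2L]][1:2]))
  if (anyNA(dims)) stop("malformed GCT dimensions line")
  header <- rows[[3L]]
  samples <- header[-(1:2)]
  body <- rows[-(1:3)]
  if (length(body) != dims[1L] || length(samples) != dims[2L]) {
    stop("GCT dimensions line disagrees with table body")
  }
  genes <- toupper(vapply(body, `[[`, "", 1L))
  if (anyDuplicated(genes)) stop("duplicate gene symbol in GCT")
  vals <- matrix(
    as.numeric(unlist(lapply(body, `[`, -(1:2)), use.names = FALSE)),
    nrow = dims[1L], byrow = TRUE, dimnames = list(genes, samples)
  )
  list(values = vals, description = vapply(body, `[[`, "", 2L))
}

#' @rdname read_gct
#' @param values numeric matrix, genes x samples, dimnames required.
#' @param description optional per-gene description column.
#' @export
write_gct <- function(values, path, description = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (is.null(description)) description <- rep("na", nrow(values))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "#1.2",
    paste(nrow(values), ncol(values), sep = "\t"),
    paste(c("Name", "Description", colnames(values)), collapse = "\t"),
    vapply(seq_len(nrow(values)), function(i) {
      paste(c(rownames(values)[i], description[i],
              format(values[i, ], trim = TRUE, digits = 15)), collapse = "\t")
    }, "")
  ), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read/write continuous CLS phenotype files
#'
#' The continuous ("numeric") CLS dialect: a `#numeric` line, a `#<name>`
#' line, and one line of numeric phenotype values, one per sample.
#'
#' @param path file path.
#' @return `read_cls_continuous()` returns a named list of one numeric
#'   vector per phenotype (usually one).
#' @export
read_cls_continuous <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!identical(lines[1L], "#numeric")) stop("not a continuous CLS file")
  out <- list()
  i <- 2L
  while (i < length(lines)) {
    nm <- sub("^#", "", lines[i])
    vals <- as.numeric(strsplit(trimws(lines[i + 1L]), "[\t ]+")[[1L]])
    if (anyNA(vals)) stop("non-numeric token on CLS data line")
    out[[nm]] <- vals
    i <- i + 2L
  }
  out
}

#' @rdname read_cls_continuous
#' @param values numeric phenotype vector.
#' @param name phenotype name written on the `#`-prefixed label line.
#' @export
write_cls_continuous <- function(values, path, name = "phenotype") {
  stopifnot(is.numeric(values), length(values) >= 1L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "#numeric",
    paste0("#", name),
    paste(format(values, trim = TRUE, digits = 15), collapse = "\t")
  ), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read/write GMT gene-set collections
#'
#' One set per line: name, description, then member gene symbols. Symbols
#' are upper-cased; duplicate genes within a set are dropped with a warning;
#' an empty set is a format error.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  rows <- read_tsv_lines(path)
  sets <- list()
  for (r in rows) {
    if (length(r) < 3L) stop("GMT line with no genes: '", r[1L], "'")
    genes <- toupper(r[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line with no genes: '", r[1L], "'")
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", r[1L], "' dropped", call. = FALSE)
      genes <- unique(genes)
    }
    if (r[1L] %in% names(sets)) stop("duplicate gene-set name: ", r[1L])
    sets[[r[1L]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene symbols.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(lengths(sets) > 0L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", toupper(sets[[nm]])), collapse = "\t")
  }, ""), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Generic writer used for all stage outputs (contaminant reports, DA
#' tables, partitions, clinical and enrichment results): UTF-8, LF line
#' endings, tab delimiter, `NA` as literal token.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_result_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  write_tsv(as.data.frame(df), path)
}
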