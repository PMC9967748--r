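#' Associate taxa with clinical variables
#'
#' For each (taxon, clinical variable) pair, runs a Kruskal-Wallis test of
#' CLR abundance across the variable's levels on tumor samples only,
#' Bonferroni-adjusting over all pairs actually tested. Samples with `NA`
#' for a variable are dropped for that variable; a variable with fewer than
#' two non-empty levels among tumors is skipped with a warning. Pathologic
#' stage sub-levels ("Stage IVA" etc.) are collapsed to their roman-numeral
#' majors by default.
#'
#' @param abund CLR [abundance_table] (taxa x samples).
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param taxa taxon ids to test; the pipeline default is the taxa
#'   significant in at least one cohort comparison.
#' @param variables clinical variables to test (default all six:
#'   vital status, perineural invasion, pathologic stage, T/N/M stage).
#' @param p_threshold significance threshold on the adjusted p-value.
#' @param collapse_stage collapse stage sub-levels (IVA -> IV).
#' @return A `clinical_assoc` data frame: `taxon`, `variable`, `levels`,
#'   `H`, `p_raw`, `p_adj`, `top_level` (level with the highest median
#'   abundance), `significant`.
#' @export
associate_clinical <- function(abund, meta, taxa,
                               variables = clinical_variables(),
                               p_threshold = 0.05, collapse_stage = TRUE) {
  idx <- match(colnames(abund), meta$sample_id)
  if (anyNA(idx)) stop("abundance samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  tumors <- meta$tissue == "tumor"
  meta <- meta[tumors, , drop = FALSE]
  abund <- abund[, tumors, drop = FALSE]
  unknown <- setdiff(taxa, rownames(abund))
  if (length(unknown)) stop("unknown taxon id: ", unknown[1L])
  rows <- list()
  for (v in variables) {
    if (!v %in% names(meta)) stop("unknown clinical variable: ", v)
    lev <- as.character(meta[[v]])
    if (collapse_stage && grepl("stage", v)) {
      lev <- sub("^Stage\\s+", "", lev)
      lev <- sub("^(IV|III|II|I)[A-C]$", "\\1", lev)
      lev <- sub("^(T[1-4]|N[01]|M[01])[a-c]$", "\\1", lev)
    }
    keep <- !is.na(lev)
    if (length(unique(lev[keep])) < 2L) {
      warning("clinical variable '", v, "' has fewer than 2 levels among ",
              "tumors; skipped", call. = FALSE)
      next
    }
    for (tx in taxa) {
      vals <- abund[tx, keep]
      kw <- kruskal_wallis(vals, lev[keep])
      med <- tapply(vals, lev[keep], stats::median)
      rows[[paste(tx, v)]] <- data.frame(
        taxon = tx, variable = v,
        levels = paste(sort(unique(lev[keep])), collapse = "|"),
        H = kw$H, p_raw = kw$p,
        top_level = names(med)[which.max(med)],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    out <- data.frame(taxon = character(0), variable = character(0),
                      levels = character(0), H = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      top_level = character(0), significant = logical(0))
    class(out) <- c("clinical_assoc", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bonferroni_adjust(pmax(out$p_raw, .Machine$double.xmin))
  out$significant <- out$p_adj < p_threshold
  out <- out[, c("taxon", "variable", "levels", "H", "p_raw", "p_adj",
                 "top_level", "significant")]
  class(out) <- c("clinical_assoc", "data.frame")
  out
}

#' Boxplots of abundance by clinical-variable level
#'
#' One PNG per (taxon, variable) pair, tumors only -- the human-review
#' surface for significant clinical associations.
#'
#' @inheritParams associate_clinical
#' @param pairs data frame with columns `taxon` and `variable` (e.g. the
#'   significant rows of a `clinical_assoc` table).
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
render_clinical_boxplots <- function(abund, meta, pairs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- match(colnames(abund), meta$sample_id)
  meta <- meta[idx, , drop = FALSE]
  tumors <- meta$tissue == "tumor"
  paths <- character(0)
  for (i in seq_len(nrow(pairs))) {
    tx <- pairs$taxon[i]; v <- pairs$variable[i]
    lev <- as.character(meta[[v]][tumors])
    keep <- !is.na(lev)
    f <- file.path(out_dir, paste0(tx, "_", v, ".png"))
    grDevices::png(f, width = 640, height = 480)
    graphics::boxplot(split(abund[tx, tumors][keep], lev[keep]),
                      ylab = "CLR abundance", xlab = v,
                      main = paste(tx, "by", v), las = 2)
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
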