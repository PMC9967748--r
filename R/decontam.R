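#' @name decontam
#' @title Contamination correction by three batch-effect detectors
#'
#' @description
#' Reagent and batch contaminants in tissue RNA-seq-derived microbial
#' profiles leave three recognizable signatures, each operationalized here
#' as a deterministic detector:
#'
#' * **total-abundance slope** ([slope_contaminant_scan()]): a genuine taxon
#'   scales with the sample's total microbial read yield, a contaminant does
#'   not. The per-taxon OLS slope of abundance against total abundance is
#'   computed; a slope of zero within a margin of +/- 0.1 (boundary
#'   inclusive) flags the taxon.
#' * **sequencing plate** ([plate_contaminant_scan()]): a taxon whose reads
#'   are disproportionately concentrated on two or fewer plates.
#' * **sequencing date** ([date_contaminant_scan()]): a taxon whose reads
#'   form one abundance cluster on a single sequencing date.
#'
#' The plate/date criteria are concentration-share statistics: the fraction
#' of the taxon's total reads contributed by its top plates (or single top
#' date), flagged when the share reaches a threshold *and* the implicated
#' batch holds fewer than half of all samples (a batch that covers most of
#' the study cannot be called a batch artifact). Flags are combined by
#' union and flagged taxa removed before differential abundance analysis.
NULL

match_meta <- function(counts, meta) {
  m <- if (inherits(counts, "count_table")) counts$counts else counts
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from metadata: ",
         paste(colnames(m)[is.na(idx)][1:3], collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}

count_matrix <- function(x) if (inherits(x, "count_table")) x$counts else as.matrix(x)

#' Slope detector: abundance vs. total microbial abundance
#'
#' Regresses each taxon's abundance on the sample's total microbial
#' abundance and flags taxa whose fitted slope is zero within `margin`
#' (inclusive). On the default `"log"` scale the response is
#' `log(count + pseudocount)` and the regressor `log(total reads)`, so a
#' well-behaved taxon (counts proportional to depth) sits near slope 1
#' while a depth-independent contaminant sits near slope 0. `scale = "raw"`
#' regresses raw counts on raw totals instead.
#'
#' Taxa observed (count > 0) in fewer than `max(3, ceiling(min_prevalence *
#' n_samples))` samples are skipped: their slope is `NA` and they are never
#' flagged by this detector.
#'
#' @param counts a [count_table] or numeric matrix (taxa x samples).
#' @param margin half-width of the zero-slope band; boundary inclusive.
#' @param min_prevalence minimum fraction of samples in which a taxon must
#'   be observed for a line to be fitted (floor of 3 samples).
#' @param scale regression scale, `"log"` (default) or `"raw"`.
#' @param pseudocount added before logs on the `"log"` scale.
#' @return Data frame with `taxon`, `slope_stat`, `slope_flag`.
#' @export
slope_contaminant_scan <- function(counts, margin = 0.1, min_prevalence = 0.1,
                                   scale = c("log", "raw"), pseudocount = 1) {
  scale <- match.arg(scale)
  m <- count_matrix(counts)
  n <- ncol(m)
  totals <- colSums(m)
  x <- if (scale == "log") log(totals + pseudocount) else totals
  if (stats::var(x) == 0) stop("degenerate design: zero variance in sample totals")
  y <- if (scale == "log") log(m + pseudocount) else m
  required <- max(3L, ceiling(min_prevalence * n))
  prevalent <- rowSums(m > 0) >= required
  xc <- x - mean(x)
  # closed-form OLS slope per taxon: cov(x, y) / var(x)
  slope <- as.vector(y %*% xc) / sum(xc^2)
  slope[!prevalent] <- NA_real_
  if (any(!prevalent)) {
    message(sum(!prevalent), " taxa below prevalence guard (", required,
            " samples); slope detector skipped them")
  }
  data.frame(
    taxon = rownames(m),
    slope_stat = slope,
    slope_flag = !is.na(slope) & abs(slope) <= margin,
    stringsAsFactors = FALSE
  )
}

concentration_scan <- function(m, batch, top_k, share_threshold) {
  batch <- as.character(batch)
  batch_sizes <- table(batch)
  n <- ncol(m)
  # per-taxon read totals within each batch
  agg <- t(rowsum(t(m), group = batch))  # taxa x batches
  total <- rowSums(agg)
  share <- rep(NA_real_, nrow(m))
  guard_ok <- rep(FALSE, nrow(m))
  pos <- total > 0
  for (i in which(pos)) {
    ord <- order(agg[i, ], decreasing = TRUE)[seq_len(min(top_k, ncol(agg)))]
    share[i] <- sum(agg[i, ord]) / total[i]
    guard_ok[i] <- sum(batch_sizes[colnames(agg)[ord]]) < 0.5 * n
  }
  list(share = share, flag = !is.na(share) & share >= share_threshold & guard_ok)
}

#' Plate detector: concentration on two or fewer sequencing plates
#'
#' Flags taxa whose reads are disproportionately contributed by their
#' `max_plates` highest-abundance plates: the top-plate share must reach
#' `share_threshold` and those plates must hold fewer than 50% of all
#' samples. With fewer than 3 distinct plates the detector abstains (all
#' flags `FALSE`, shares `NA`).
#'
#' @inheritParams slope_contaminant_scan
#' @param meta sample metadata with `sample_id` and `seq_plate`.
#' @param share_threshold minimum top-plate read share to flag.
#' @param max_plates number of top plates pooled into the share.
#' @return Data frame with `taxon`, `plate_top2_share`, `plate_flag`.
#' @export
plate_contaminant_scan <- function(counts, meta, share_threshold = 0.9,
                                   max_plates = 2) {
  m <- count_matrix(counts)
  meta <- match_meta(m, meta)
  if (length(unique(meta$seq_plate)) < 3L) {
    warning("fewer than 3 distinct plates: plate detector abstains",
            call. = FALSE)
    return(data.frame(taxon = rownames(m), plate_top2_share = NA_real_,
                      plate_flag = FALSE, stringsAsFactors = FALSE))
  }
  sc <- concentration_scan(m, meta$seq_plate, max_plates, share_threshold)
  data.frame(taxon = rownames(m), plate_top2_share = sc$share,
             plate_flag = sc$flag, stringsAsFactors = FALSE)
}

#' Date detector: one abundance cluster on a single sequencing date
#'
#' Flags taxa whose single highest-abundance sequencing date contributes at
#' least `share_threshold` of the taxon's reads, provided that date holds
#' fewer than 50% of all samples.
#'
#' @inheritParams plate_contaminant_scan
#' @return Data frame with `taxon`, `date_modal_share`, `date_flag`.
#' @export
date_contaminant_scan <- function(counts, meta, share_threshold = 0.9) {
  m <- count_matrix(counts)
  meta <- match_meta(m, meta)
  sc <- concentration_scan(m, as.character(meta$seq_date), 1L, share_threshold)
  data.frame(taxon = rownames(m), date_modal_share = sc$share,
             date_flag = sc$flag, stringsAsFactors = FALSE)
}

#' Run all three contaminant detectors
#'
#' @inheritParams plate_contaminant_scan
#' @param slope_margin,slope_scale,min_prevalence passed to
#'   [slope_contaminant_scan()].
#' @param plate_share,max_plates passed to [plate_contaminant_scan()].
#' @param date_share passed to [date_contaminant_scan()].
#' @return A `contaminant_report` data frame: per-taxon statistics and flags
#'   from each detector plus the union `flagged` column that drives removal.
#' @export
detect_contaminants <- function(counts, meta,
                                slope_margin = 0.1, min_prevalence = 0.1,
                                slope_scale = c("log", "raw"),
                                plate_share = 0.9, max_plates = 2,
                                date_share = 0.9) {
  stopifnot(inherits(counts, "count_table"))
  s <- slope_contaminant_scan(counts, margin = slope_margin,
                              min_prevalence = min_prevalence,
                              scale = match.arg(slope_scale))
  p <- plate_contaminant_scan(counts, meta, share_threshold = plate_share,
                              max_plates = max_plates)
  d <- date_contaminant_scan(counts, meta, share_threshold = date_share)
  rep_ <- data.frame(
    taxon = counts$taxa$id, domain = counts$taxa$domain,
    slope_stat = s$slope_stat, slope_flag = s$slope_flag,
    plate_top2_share = p$plate_top2_share, plate_flag = p$plate_flag,
    date_modal_share = d$date_modal_share, date_flag = d$date_flag,
    stringsAsFactors = FALSE
  )
  rep_$flagged <- rep_$slope_flag | rep_$plate_flag | rep_$date_flag
  class(rep_) <- c("contaminant_report", "data.frame")
  rep_
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat(sprintf(
    "contaminant_report: %d taxa; flagged %d (slope %d, plate %d, date %d)\n",
    nrow(x), sum(x$flagged), sum(x$slope_flag), sum(x$plate_flag),
    sum(x$date_flag)
  ))
  invisible(x)
}

#' Remove flagged contaminants from a count table
#'
#' Union semantics: a taxon flagged by any detector is removed.
#'
#' @param counts a [count_table].
#' @param report a `contaminant_report` covering every taxon in `counts`.
#' @return List with `counts` (filtered [count_table]) and `removed`
#'   (character vector of removed taxon ids).
#' @export
remove_contaminants <- function(counts, report) {
  stopifnot(inherits(counts, "count_table"))
  if (!all(counts$taxa$id %in% report$taxon)) {
    stop("contaminant report does not cover every taxon")
  }
  flagged <- report$taxon[report$flagged]
  keep <- setdiff(counts$taxa$id, flagged)
  if (!length(keep)) {
    warning("all taxa flagged as contaminants: filtered table is empty",
            call. = FALSE)
  }
  list(
    counts = subset_count_table(counts, taxa = keep),
    removed = intersect(counts$taxa$id, flagged)
  )
}

#' Diagnostic plots for human review of contaminant calls
#'
#' For each requested taxon writes three PNGs mirroring the plots a reviewer
#' would inspect: abundance vs. sequencing date (scatter), abundance by
#' plate (boxplot), and abundance vs. total microbial abundance with the
#' fitted line. Flagged taxa are drawn in red with a "flagged" annotation.
#'
#' @inheritParams plate_contaminant_scan
#' @param report a `contaminant_report`.
#' @param taxa character vector of taxon ids to plot.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths of the files written (3 per taxon).
#' @export
render_diagnostics <- function(counts, meta, report, taxa, out_dir) {
  m <- count_matrix(counts)
  meta <- match_meta(m, meta)
  unknown <- setdiff(taxa, rownames(m))
  if (length(unknown)) stop("unknown taxon id: ", unknown[1L])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  totals <- colSums(m)
  paths <- character(0)
  for (tx in taxa) {
    y <- log(m[tx, ] + 1)
    fl <- report$flagged[match(tx, report$taxon)]
    col <- if (isTRUE(fl)) "red" else "black"
    ann <- if (isTRUE(fl)) " [flagged]" else ""
    f1 <- file.path(out_dir, paste0(tx, "_date.png"))
    grDevices::png(f1, width = 640, height = 480)
    plot(meta$seq_date, y, col = col, pch = 19, xlab = "sequencing date",
         ylab = "log(count + 1)", main = paste0(tx, ": date", ann))
    grDevices::dev.off()
    f2 <- file.path(out_dir, paste0(tx, "_plate.png"))
    grDevices::png(f2, width = 640, height = 480)
    graphics::boxplot(split(y, meta$seq_plate), border = col,
                      xlab = "sequencing plate", ylab = "log(count + 1)",
                      main = paste0(tx, ": plate", ann), las = 2)
    grDevices::dev.off()
    f3 <- file.path(out_dir, paste0(tx, "_total.png"))
    grDevices::png(f3, width = 640, height = 480)
    plot(log(totals + 1), y, col = col, pch = 19,
         xlab = "log(total reads + 1)", ylab = "log(count + 1)",
         main = paste0(tx, ": total abundance", ann))
    graphics::abline(stats::lm(y ~ log(totals + 1)), col = "grey40")
    grDevices::dev.off()
    paths <- c(paths, f1, f2, f3)
  }
  invisible(paths)
}
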