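#' Direction-concordant Venn partition of significant taxa
#'
#' Given differential-abundance tables for k cohort comparisons over the
#' same taxa, assigns every taxon that is significant in at least one
#' comparison to exactly one Venn region: the subset S of cohorts in which
#' it is significant, provided its direction of dysregulation is the same
#' in all of them (strict Venn semantics). Taxa significant in several
#' cohorts with conflicting directions are quarantined in `discordant`
#' rather than forced into a region.
#'
#' @param tables named list of `da_table` objects (from
#'   [run_cohort_comparison()]) with identical taxa universes.
#' @return An `overlap_partition`: list with `cohort_names`, `regions` (one
#'   entry per non-empty cohort subset, keyed `"A&B"`, each a data frame of
#'   `taxon`, `domain`, `direction`) and `discordant` (data frame of
#'   `taxon`, `domain`, `directions`).
#' @export
partition_by_direction <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)))
  cohorts <- names(tables)
  taxa <- tables[[1L]]$taxon
  for (tb in tables) {
    if (!identical(sort(tb$taxon), sort(taxa))) {
      stop("taxa universes differ across DA tables")
    }
  }
  k <- length(cohorts)
  sig <- sapply(tables, function(tb) tb$significant[match(taxa, tb$taxon)])
  dir_ <- sapply(tables, function(tb) tb$direction[match(taxa, tb$taxon)])
  sig <- matrix(sig, nrow = length(taxa), dimnames = list(taxa, cohorts))
  dir_ <- matrix(dir_, nrow = length(taxa), dimnames = list(taxa, cohorts))
  domain <- tables[[1L]]$domain[match(taxa, tables[[1L]]$taxon)]

  subset_keys <- unlist(lapply(seq_len(k), function(size) {
    apply(utils::combn(cohorts, size), 2L, paste, collapse = "&")
  }))
  regions <- stats::setNames(lapply(subset_keys, function(...) {
    data.frame(taxon = character(0), domain = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }), subset_keys)
  discordant <- data.frame(taxon = character(0), domain = character(0),
                           directions = character(0), stringsAsFactors = FALSE)

  for (i in seq_along(taxa)) {
    s <- cohorts[sig[i, ]]
    if (!length(s)) next
    dirs <- dir_[i, s]
    row <- data.frame(taxon = taxa[i], domain = domain[i],
                      stringsAsFactors = FALSE)
    if (length(unique(dirs)) == 1L) {
      key <- paste(s, collapse = "&")
      row$direction <- dirs[[1L]]
      regions[[key]] <- rbind(regions[[key]], row)
    } else {
      row$directions <- paste(s, dirs, sep = "=", collapse = ";")
      discordant <- rbind(discordant, row)
    }
  }
  structure(list(cohort_names = cohorts, regions = regions,
                 discordant = discordant),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("overlap_partition over {%s}\n",
              paste(x$cohort_names, collapse = ", ")))
  for (key in names(x$regions)) {
    n <- nrow(x$regions[[key]])
    if (n) cat(sprintf("  %-30s %d taxa\n", key, n))
  }
  cat(sprintf("  discordant: %d taxa\n", nrow(x$discordant)))
  invisible(x)
}

#' Summarize a Venn partition as counts per region, direction and domain
#'
#' The count-per-region summary underlying statements like "N fungal
#' species were over-abundant in all three subtypes".
#'
#' @param partition an `overlap_partition`.
#' @return Data frame with `region`, `direction`, `domain`, `n` (only
#'   non-zero rows, plus one `discordant` row per domain when present);
#'   counts sum to the total number of concordant significant taxa plus
#'   discordant taxa.
#' @export
summarize_partition <- function(partition) {
  stopifnot(inherits(partition, "overlap_partition"))
  rows <- list()
  for (key in names(partition$regions)) {
    reg <- partition$regions[[key]]
    if (!nrow(reg)) next
    agg <- stats::aggregate(list(n = reg$taxon),
                            by = list(direction = reg$direction,
                                      domain = reg$domain), FUN = length)
    agg$region <- key
    rows[[key]] <- agg
  }
  if (nrow(partition$discordant)) {
    agg <- stats::aggregate(list(n = partition$discordant$taxon),
                            by = list(domain = partition$discordant$domain),
                            FUN = length)
    agg$direction <- "mixed"
    agg$region <- "discordant"
    rows[["discordant"]] <- agg
  }
  if (!length(rows)) {
    return(data.frame(region = character(0), direction = character(0),
                      domain = character(0), n = integer(0)))
  }
  out <- do.call(rbind, lapply(rows, function(d) {
    d[, c("region", "direction", "domain", "n")]
  }))
  rownames(out) <- NULL
  out
}

#' Flatten a partition to one row per taxon
#'
#' @param partition an `overlap_partition`.
#' @return Data frame with `taxon`, `domain`, `region`, `direction`
#'   (discordant taxa get region `"discordant"` and their per-cohort
#'   direction string).
#' @export
partition_table <- function(partition) {
  stopifnot(inherits(partition, "overlap_partition"))
  rows <- lapply(names(partition$regions), function(key) {
    reg <- partition$regions[[key]]
    if (!nrow(reg)) return(NULL)
    data.frame(taxon = reg$taxon, domain = reg$domain, region = key,
               direction = reg$direction, stringsAsFactors = FALSE)
  })
  if (nrow(partition$discordant)) {
    rows <- c(rows, list(data.frame(
      taxon = partition$discordant$taxon,
      domain = partition$discordant$domain,
      region = "discordant", direction = partition$discordant$directions,
      stringsAsFactors = FALSE
    )))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(taxon = character(0), domain = character(0),
                      region = character(0), direction = character(0))
  }
  rownames(out) <- NULL
  out
}
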