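#' Kruskal-Wallis rank test
#'
#' The k-group rank location test used throughout the pipeline, computed on
#' mid-ranks with the standard tie correction:
#' \deqn{H = \frac{12}{N(N+1)} \sum_g \frac{R_g^2}{n_g} - 3(N+1)}
#' divided by \eqn{1 - \sum (t^3 - t) / (N^3 - N)} over tie groups of size
#' \eqn{t}; the p-value comes from the chi-square distribution with
#' \eqn{k - 1} degrees of freedom. With two groups this is equivalent to the
#' Wilcoxon rank-sum test.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; at least two
#'   distinct groups each with one observation, total N >= 3.
#' @return List with `H` and `p`. All-tied data yield `H = 0`, `p = 1`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  n <- length(values)
  k <- length(unique(groups))
  if (k < 2L) stop("kruskal_wallis needs at least 2 groups")
  if (n < 3L) stop("kruskal_wallis needs N >= 3")
  r <- rank(values)
  rg <- rowsum(r, groups)
  ng <- as.vector(table(groups)[rownames(rg)])
  h <- 12 / (n * (n + 1)) * sum(rg^2 / ng) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) return(list(H = 0, p = 1))  # all observations identical
  h <- h / tie_corr
  list(H = h, p = stats::pchisq(h, df = k - 1, lower.tail = FALSE))
}

#' Log2 fold change of group mean relative abundances
#'
#' Counts are converted to within-sample relative abundances; the fold
#' change is `log2((mean_a + pseudo) / (mean_b + pseudo))` of the group
#' means. Positive values mean over-abundance in group A.
#'
#' @param counts a [count_table] or numeric matrix.
#' @param samples_a,samples_b character vectors of sample ids (non-empty,
#'   disjoint).
#' @param pseudo small fraction added to both means to keep the ratio
#'   finite when a group mean is zero.
#' @return Named numeric vector of per-taxon log2 fold changes.
#' @export
log_fold_change <- function(counts, samples_a, samples_b, pseudo = 1e-6) {
  m <- count_matrix(counts)
  stopifnot(length(samples_a) > 0, length(samples_b) > 0)
  if (length(intersect(samples_a, samples_b))) stop("groups must be disjoint")
  rel <- sweep(m, 2L, pmax(colSums(m), 1), "/")
  ma <- rowMeans(rel[, samples_a, drop = FALSE])
  mb <- rowMeans(rel[, samples_b, drop = FALSE])
  log2((ma + pseudo) / (mb + pseudo))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m = length(p)`; delegates to
#' [stats::p.adjust()]. Input p-values must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Define a cohort comparison
#'
#' A cohort pair is a pair of sample-selection predicates over the sample
#' metadata, each a named list of `field = allowed values` conjunctions,
#' e.g. `list(tissue = "tumor", subtype = "CPTC")`. Gender-matched normals
#' are expressed the same way (`list(tissue = "normal", gender = "male")`).
#'
#' @param name cohort comparison name.
#' @param group_a,group_b predicates (named lists); group A is the focal
#'   cohort, so positive log fold changes mean over-abundance in A.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(name, group_a, group_b) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(group_a), is.list(group_b),
            !is.null(names(group_a)), !is.null(names(group_b)))
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "cohort_spec")
}

resolve_predicate <- function(meta, predicate) {
  keep <- rep(TRUE, nrow(meta))
  for (field in names(predicate)) {
    if (!field %in% names(meta)) stop("unknown metadata field: ", field)
    keep <- keep & !is.na(meta[[field]]) &
      as.character(meta[[field]]) %in% as.character(predicate[[field]])
  }
  meta$sample_id[keep]
}

#' The study's default cohort comparisons
#'
#' Six tumor-versus-normal style comparisons (all tumors, the three
#' histologic subtypes, and the two genders against gender-matched normals)
#' plus the tumor-only BRAF V600E positive-versus-negative comparison.
#'
#' @return Named list of [cohort_spec] objects.
#' @export
default_cohorts <- function() {
  specs <- list(
    cohort_spec("tumor_vs_normal",
                list(tissue = "tumor"), list(tissue = "normal")),
    cohort_spec("CPTC_vs_normal",
                list(tissue = "tumor", subtype = "CPTC"), list(tissue = "normal")),
    cohort_spec("FVPTC_vs_normal",
                list(tissue = "tumor", subtype = "FVPTC"), list(tissue = "normal")),
    cohort_spec("TCPTC_vs_normal",
                list(tissue = "tumor", subtype = "TCPTC"), list(tissue = "normal")),
    cohort_spec("male_vs_male_normal",
                list(tissue = "tumor", gender = "male"),
                list(tissue = "normal", gender = "male")),
    cohort_spec("female_vs_female_normal",
                list(tissue = "tumor", gender = "female"),
                list(tissue = "normal", gender = "female")),
    cohort_spec("braf_pos_vs_braf_neg",
                list(tissue = "tumor", braf_v600e = "positive"),
                list(tissue = "tumor", braf_v600e = "negative"))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Differential abundance for one cohort comparison
#'
#' Per retained taxon: Kruskal-Wallis test of CLR abundance between the two
#' groups, Bonferroni adjustment across all taxa in this comparison, log2
#' fold change of mean relative abundances, and the significance call
#' `p < p_threshold` (adjusted by default) and `|logFC| > lfc_threshold`.
#'
#' @param counts contaminant-filtered [count_table] (used for fold changes).
#' @param abund matching CLR [abundance_table] (used for the rank test); if
#'   `NULL` it is computed from `counts`.
#' @param meta sample metadata.
#' @param spec a [cohort_spec].
#' @param p_threshold significance threshold on the p-value (default 0.05).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param adjust apply the threshold to Bonferroni-adjusted p-values
#'   (default) or to raw p-values.
#' @return A `da_table` data frame: `taxon`, `domain`, `H`, `p_raw`,
#'   `p_adj`, `logFC`, `direction` (`over_in_a`/`over_in_b`), `significant`.
#' @export
run_cohort_comparison <- function(counts, abund = NULL, meta, spec,
                                  p_threshold = 0.05, lfc_threshold = 1,
                                  adjust = TRUE) {
  stopifnot(inherits(counts, "count_table"), inherits(spec, "cohort_spec"))
  if (is.null(abund)) abund <- clr_transform(counts)
  meta <- match_meta(counts, meta)
  a <- resolve_predicate(meta, spec$group_a)
  b <- resolve_predicate(meta, spec$group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("cohort '", spec$name, "': group resolves to fewer than 2 samples (",
         "a: ", length(a), ", b: ", length(b), ")")
  }
  if (length(intersect(a, b))) {
    stop("cohort '", spec$name, "': groups overlap; predicates must be disjoint")
  }
  groups <- rep(c("a", "b"), c(length(a), length(b)))
  cols <- c(a, b)
  kw <- apply(abund[, cols, drop = FALSE], 1L, function(v) {
    unlist(kruskal_wallis(v, groups))
  })
  lfc <- log_fold_change(counts, a, b)
  p_adj <- bonferroni_adjust(pmax(kw["p", ], .Machine$double.xmin))
  p_used <- if (adjust) p_adj else kw["p", ]
  out <- data.frame(
    taxon = counts$taxa$id, domain = counts$taxa$domain,
    H = kw["H", ], p_raw = kw["p", ], p_adj = p_adj,
    logFC = as.vector(lfc),
    direction = ifelse(lfc > 0, "over_in_a", "over_in_b"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$significant <- p_used < p_threshold & abs(out$logFC) > lfc_threshold
  attr(out, "cohort") <- spec$name
  attr(out, "n_a") <- length(a)
  attr(out, "n_b") <- length(b)
  class(out) <- c("da_table", "data.frame")
  out
}

#' @export
print.da_table <- function(x, ...) {
  cat(sprintf(
    "da_table '%s': %d taxa, %d significant (%d over in A, %d over in B)\n",
    attr(x, "cohort") %||% "?", nrow(x), sum(x$significant),
    sum(x$significant & x$direction == "over_in_a"),
    sum(x$significant & x$direction == "over_in_b")
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
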