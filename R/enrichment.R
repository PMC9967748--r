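#' Rank genes by correlation with a continuous phenotype
#'
#' The continuous-phenotype ranking step of gene-set enrichment: every
#' gene's expression is correlated with the phenotype vector (here, a
#' microbe's abundance across samples) and genes are ordered by descending
#' correlation. Ties are broken by gene symbol so the ordering is
#' deterministic. Zero-variance genes get metric 0 with a note.
#'
#' @param expr numeric matrix, genes x samples (e.g. `read_gct()$values`).
#' @param phenotype numeric vector, one value per column of `expr`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `ranked_list` data frame with `gene` and `metric`, ordered by
#'   non-increasing metric.
#' @export
rank_genes_by_phenotype <- function(expr, phenotype,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), ncol(expr) == length(phenotype), ncol(expr) >= 3L)
  if (stats::sd(phenotype) == 0) stop("zero-variance phenotype")
  metric <- gene_phenotype_correlation(standardize_rows(expr, method),
                                       phenotype, method)
  ord <- order(-metric, rownames(expr))
  out <- data.frame(gene = rownames(expr)[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# rows standardized to mean 0, unit variance (ranks first for spearman);
# zero-variance rows become all-zero so their correlation is 0.
standardize_rows <- function(expr, method) {
  if (method == "spearman") expr <- t(apply(expr, 1L, rank))
  mu <- rowMeans(expr)
  ctr <- expr - mu
  s <- sqrt(rowSums(ctr^2))
  zero <- s == 0
  if (any(zero)) {
    message(sum(zero), " zero-variance gene(s): correlation set to 0")
    s[zero] <- 1
  }
  z <- ctr / s
  z[zero, ] <- 0
  z
}

gene_phenotype_correlation <- function(z_expr, phenotype, method) {
  if (method == "spearman") phenotype <- rank(phenotype)
  p <- phenotype - mean(phenotype)
  p <- p / sqrt(sum(p^2))
  as.vector(z_expr %*% p)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating a running sum: at a gene in the
#' set ("hit") the sum increases by `|metric|^weight / sum(|metric|^weight
#' over hits)`, at a miss it decreases by `1 / (N - N_hits)`. The
#' enrichment score is the signed maximum deviation of the running sum from
#' zero; it always lies in [-1, 1]. `weight = 0` gives the classic
#' (unweighted) Kolmogorov-Smirnov statistic; `weight = 1` is the standard
#' weighted scheme.
#'
#' @param ranked a `ranked_list` from [rank_genes_by_phenotype()] (or any
#'   data frame with `gene` and `metric`, ordered).
#' @param gene_set character vector of gene symbols; must intersect the
#'   ranked list and must not cover it entirely.
#' @param weight exponent on `|metric|` in the hit increments.
#' @return List with `ES` and `running` (the length-N running-sum profile).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- ranked$gene
  hits <- genes %in% toupper(gene_set)
  es_from_hits(hits, ranked$metric, weight)
}

# core running-sum computation shared by the observed and permutation paths
es_from_hits <- function(hits, metric, weight, profile = TRUE) {
  n <- length(hits)
  nh <- sum(hits)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")
  w <- abs(metric[hits])^weight
  sw <- sum(w)
  inc <- numeric(n)
  if (sw == 0) {
    inc[hits] <- 1 / nh  # all hit metrics zero: fall back to equal weights
  } else {
    inc[hits] <- w / sw
  }
  inc[!hits] <- -1 / (n - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  if (profile) list(ES = es, running = running) else es
}

#' Phenotype-permutation significance for gene-set enrichment
#'
#' Computes the observed enrichment score of every gene set against the
#' ranking induced by `phenotype`, then recomputes ranking and scores under
#' `n_perm` random permutations of the phenotype. Per set:
#' * `p_perm`: one-sided tail fraction among same-signed null scores, with
#'   +1 smoothing (so p > 0 always);
#' * `NES`: observed ES divided by the mean magnitude of same-signed null
#'   scores for that set;
#' * `fdr_q`: the NES-based FDR -- the proportion of (pooled, normalized)
#'   null scores at least as extreme, divided by the proportion of observed
#'   scores at least as extreme, capped at 1;
#' * `pass_filter`: `p_perm < p_threshold` and `fdr_q < fdr_threshold`
#'   (defaults 0.05 and 0.25).
#'
#' @inheritParams rank_genes_by_phenotype
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm number of phenotype permutations (>= 100).
#' @param weight hit-weight exponent, see [enrichment_score()].
#' @param seed integer seed making the permutation null reproducible.
#' @param p_threshold,fdr_threshold the significance filter.
#' @return An `enrichment_result` data frame: `gene_set`, `size`, `ES`,
#'   `NES`, `p_perm`, `fdr_q`, `pass_filter`; attributes `n_perm`, `seed`.
#' @export
permutation_significance <- function(expr, phenotype, gene_sets,
                                     n_perm = 1000, weight = 1,
                                     method = c("pearson", "spearman"),
                                     seed = NULL, p_threshold = 0.05,
                                     fdr_threshold = 0.25) {
  method <- match.arg(method)
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(expr)
  z <- standardize_rows(expr, method)
  members <- lapply(gene_sets, function(gs) {
    hit <- genes %in% toupper(gs)
    if (!any(hit)) stop("gene set does not intersect the expression matrix")
    if (all(hit)) stop("gene set covers the whole expression matrix")
    hit
  })
  score_all <- function(ph) {
    metric <- gene_phenotype_correlation(z, ph, method)
    ord <- order(-metric, genes)
    ms <- metric[ord]
    vapply(members, function(hit) es_from_hits(hit[ord], ms, weight,
                                               profile = FALSE), 0)
  }
  obs <- score_all(phenotype)
  null_es <- matrix(NA_real_, nrow = n_perm, ncol = length(gene_sets),
                    dimnames = list(NULL, names(gene_sets)))
  for (b in seq_len(n_perm)) {
    null_es[b, ] <- score_all(sample(phenotype))
  }
  res <- normalize_and_test(obs, null_es, p_threshold, fdr_threshold)
  res <- cbind(
    data.frame(gene_set = names(gene_sets),
               size = vapply(members, sum, 0L), stringsAsFactors = FALSE),
    res
  )
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("enrichment_result", "data.frame")
  res
}

normalize_and_test <- function(obs, null_es, p_threshold, fdr_threshold) {
  s <- length(obs)
  p <- nes <- fdr <- rep(NA_real_, s)
  pos_mean <- neg_mean <- rep(NA_real_, s)
  for (j in seq_len(s)) {
    nj <- null_es[, j]
    pos_mean[j] <- mean(nj[nj > 0])
    neg_mean[j] <- mean(abs(nj[nj < 0]))
    if (obs[j] >= 0) {
      p[j] <- (1 + sum(nj >= obs[j])) / (1 + sum(nj >= 0))
      nes[j] <- obs[j] / pos_mean[j]
    } else {
      p[j] <- (1 + sum(nj <= obs[j])) / (1 + sum(nj <= 0))
      nes[j] <- -abs(obs[j]) / neg_mean[j]
    }
  }
  # pooled null NES: every null score normalized by its own set's
  # same-signed null mean, as in the standard NES-based FDR
  null_nes <- sapply(seq_len(s), function(j) {
    nj <- null_es[, j]
    ifelse(nj >= 0, nj / pos_mean[j], -abs(nj) / neg_mean[j])
  })
  for (j in seq_len(s)) {
    if (is.na(nes[j])) next
    if (nes[j] >= 0) {
      pool <- null_nes[null_nes >= 0]
      num <- if (length(pool)) mean(pool >= nes[j]) else 0
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[j])
    } else {
      pool <- null_nes[null_nes < 0]
      num <- if (length(pool)) mean(pool <= nes[j]) else 0
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[j])
    }
    fdr[j] <- min(1, num / den)
  }
  data.frame(ES = obs, NES = nes, p_perm = p, fdr_q = fdr,
             pass_filter = !is.na(p) & !is.na(fdr) &
               p < p_threshold & fdr < fdr_threshold)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d gene sets, %d pass p<0.05 & FDR<0.25 (n_perm=%d)\n",
              nrow(x), sum(x$pass_filter), attr(x, "n_perm") %||% NA))
  invisible(x)
}

#' The six oncogenic-signature set names shipped as a stub collection
#'
#' Name-only stubs of the oncogenic-pathway signature sets used in the
#' enrichment stage (PI3K/AKT, RAS, BRAF-mutant kinase signaling, p53, RET,
#' oncogenic MAPK). Members must be supplied by the user from MSigDB; the
#' curated gene lists are not redistributed here.
#'
#' @return Character vector of six signature names.
#' @export
signature_set_names <- function() {
  c("PID_PI3KCI_AKT_PATHWAY",
    "BIOCARTA_RAS_PATHWAY",
    "REACTOME_SIGNALING_BY_MODERATE_KINASE_ACTIVITY_BRAF_MUTANTS",
    "KEGG_P53_SIGNALING_PATHWAY",
    "REACTOME_RET_SIGNALING",
    "REACTOME_ONCOGENIC_MAPK_SIGNALING")
}
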