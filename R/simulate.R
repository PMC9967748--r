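#' Configuration for the synthetic study generator
#'
#' Collects every knob of the synthetic dataset in one validated list. The
#' defaults emulate the structure of a thyroid-carcinoma RNA-seq microbiome
#' study: 453 tumors and 54 adjacent normals; tumor subtypes in proportions
#' 385 (classical) : 102 (follicular-variant) : 36 (tall-cell); genders in
#' proportion 140 male : 366 female; taxon counts scaled to 500 fungal and
#' 50 archaeal species (roughly 20x below the ~9800/~480 species a
#' full-scale extraction yields) so the whole pipeline runs in seconds.
#' Counts are overdispersed (negative-binomial) with per-sample depths drawn
#' log-normally; three contaminant archetypes and cohort-specific abundance
#' effects are planted and recorded in a [truth manifest][write_truth()].
#'
#' @param n_tumor,n_normal sample counts.
#' @param subtype_weights,gender_weights sampling weights for tumor subtype
#'   and patient gender.
#' @param n_taxa_fungal,n_taxa_archaeal taxon counts per domain.
#' @param n_dates,n_plates number of distinct sequencing dates and plates.
#' @param contaminants named integer vector: planted contaminants per
#'   archetype (`slope`, `plate`, `date`).
#' @param da_effects data frame (`cohort`, `n`, `lfc`, `direction`): taxa
#'   whose mean abundance is multiplied by `2^lfc` (direction `"up"`) or
#'   `2^-lfc` (`"down"`) in the named cohort's samples. Cohorts: `tumor`,
#'   `CPTC`, `FVPTC`, `TCPTC`, `male`, `female`, `braf_positive`,
#'   `braf_negative`.
#' @param clinical_effects data frame (`variable`, `level`, `n`, `lfc`):
#'   taxa shifted by `2^lfc` in tumor samples whose clinical variable
#'   matches `level` (a regex alternation like `"III|IV"` is allowed).
#' @param depth_meanlog,depth_sdlog log-normal per-sample total-depth
#'   parameters (defaults: median 1e5 microbial reads, sdlog 1 -- microbial
#'   read yield from host RNA-seq varies over orders of magnitude).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param base_logprop_range log10 range of per-taxon baseline proportions.
#' @param braf_positive_fraction fraction of tumors carrying BRAF V600E.
#' @param expression list: `n_genes`, `set_size` (planted gene-set size),
#'   `target_cor` (gene-microbe correlation of planted genes),
#'   `n_null_sets`, `null_set_size`.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tumor = 453, n_normal = 54,
                              subtype_weights = c(CPTC = 385, FVPTC = 102, TCPTC = 36),
                              gender_weights = c(male = 140, female = 366),
                              n_taxa_fungal = 500, n_taxa_archaeal = 50,
                              n_dates = 12, n_plates = 10,
                              contaminants = c(slope = 50, plate = 25, date = 25),
                              da_effects = data.frame(
                                cohort = c("tumor", "tumor", "braf_negative"),
                                n = c(15, 15, 5),
                                lfc = c(2, 2, 2),
                                direction = c("up", "down", "up"),
                                stringsAsFactors = FALSE),
                              clinical_effects = data.frame(
                                variable = "pathologic_stage", level = "III|IV",
                                n = 5, lfc = 2, stringsAsFactors = FALSE),
                              depth_meanlog = log(1e5), depth_sdlog = 1,
                              dispersion = 0.2,
                              base_logprop_range = c(-4.5, -3),
                              braf_positive_fraction = 0.6,
                              expression = list(n_genes = 1000, set_size = 20,
                                                target_cor = 0.8,
                                                n_null_sets = 5,
                                                null_set_size = 20),
                              seed = 7) {
  cfg <- list(
    n_tumor = n_tumor, n_normal = n_normal,
    subtype_weights = subtype_weights, gender_weights = gender_weights,
    n_taxa_fungal = n_taxa_fungal, n_taxa_archaeal = n_taxa_archaeal,
    n_dates = n_dates, n_plates = n_plates, contaminants = contaminants,
    da_effects = da_effects, clinical_effects = clinical_effects,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    dispersion = dispersion, base_logprop_range = base_logprop_range,
    braf_positive_fraction = braf_positive_fraction,
    expression = expression, seed = seed
  )
  n_taxa <- n_taxa_fungal + n_taxa_archaeal
  n_planted <- sum(contaminants) + sum(da_effects$n) +
    sum(clinical_effects$n)
  if (n_planted > n_taxa) {
    stop("planted contaminants and effects (", n_planted,
         ") exceed taxon count (", n_taxa, ")")
  }
  stopifnot(all(contaminants >= 0), n_tumor > 0, n_normal >= 0,
            dispersion > 0, all(c("slope", "plate", "date") %in% names(contaminants)))
  class(cfg) <- "simulation_config"
  cfg
}

cohort_members <- function(meta, cohort) {
  tum <- meta$tissue == "tumor"
  switch(cohort,
    tumor = tum,
    CPTC = tum & !is.na(meta$subtype) & meta$subtype == "CPTC",
    FVPTC = tum & !is.na(meta$subtype) & meta$subtype == "FVPTC",
    TCPTC = tum & !is.na(meta$subtype) & meta$subtype == "TCPTC",
    male = tum & !is.na(meta$gender) & meta$gender == "male",
    female = tum & !is.na(meta$gender) & meta$gender == "female",
    braf_positive = tum & !is.na(meta$braf_v600e) & meta$braf_v600e == "positive",
    braf_negative = tum & !is.na(meta$braf_v600e) & meta$braf_v600e == "negative",
    stop("unknown simulated cohort: ", cohort)
  )
}

#' Simulate a full synthetic study with planted ground truth
#'
#' Generates a read-count table, sample metadata (including sequencing
#' dates, plates, BRAF status, and clinical variables), a gene-expression
#' matrix tied to a designated microbe, GSEA-style gene sets, and a truth
#' manifest recording exactly what was planted. Baseline counts are
#' negative-binomial with mean `depth_s * proportion_t`; slope-archetype
#' contaminants are depth-independent; plate/date archetypes are
#' concentrated on two plates / one date; differential-abundance taxa have
#' their group mean multiplied by `2^lfc` in the configured cohort; planted
#' expression genes share a latent factor with the target microbe's CLR
#' abundance.
#'
#' @param config a [simulation_config()].
#' @param out_dir if non-`NULL`, the canonical files (`counts.tsv`,
#'   `metadata.tsv`, `expression.gct`, `phenotype.cls`, `gene_sets.gmt`,
#'   `truth.json`) are written there.
#' @return List with `counts` ([count_table]), `meta` (data frame), `expr`
#'   (genes x samples matrix), `gene_sets` (named list), `truth`
#'   (`truth_manifest`), and `files` (paths written, or `NULL`).
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_tumor + config$n_normal
  meta <- simulate_metadata(config)
  nt <- config$n_taxa_fungal + config$n_taxa_archaeal
  taxa <- data.frame(
    id = c(sprintf("F%04d", seq_len(config$n_taxa_fungal)),
           sprintf("A%04d", seq_len(config$n_taxa_archaeal))),
    name = c(sprintf("Fungus sp. %04d", seq_len(config$n_taxa_fungal)),
             sprintf("Archaeon sp. %04d", seq_len(config$n_taxa_archaeal))),
    domain = rep(c("fungal", "archaeal"),
                 c(config$n_taxa_fungal, config$n_taxa_archaeal)),
    stringsAsFactors = FALSE
  )

  # disjoint planted index sets, drawn over all taxa
  pool <- sample(nt)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx_slope <- take(config$contaminants[["slope"]])
  idx_plate <- take(config$contaminants[["plate"]])
  idx_date <- take(config$contaminants[["date"]])
  archetype <- rep("none", nt)
  archetype[idx_slope] <- "slope"
  archetype[idx_plate] <- "plate"
  archetype[idx_date] <- "date"

  da_rows <- list()
  for (i in seq_len(nrow(config$da_effects))) {
    e <- config$da_effects[i, ]
    if (e$n == 0) next
    da_rows[[i]] <- data.frame(
      taxon = taxa$id[take(e$n)], cohort = e$cohort,
      lfc = if (e$direction == "up") e$lfc else -e$lfc,
      stringsAsFactors = FALSE
    )
  }
  da_truth <- if (length(da_rows)) do.call(rbind, da_rows) else
    data.frame(taxon = character(0), cohort = character(0), lfc = numeric(0))

  clin_rows <- list()
  for (i in seq_len(nrow(config$clinical_effects))) {
    e <- config$clinical_effects[i, ]
    if (e$n == 0) next
    clin_rows[[i]] <- data.frame(
      taxon = taxa$id[take(e$n)], variable = e$variable, level = e$level,
      lfc = e$lfc, stringsAsFactors = FALSE
    )
  }
  clin_truth <- if (length(clin_rows)) do.call(rbind, clin_rows) else
    data.frame(taxon = character(0), variable = character(0),
               level = character(0), lfc = numeric(0))
  # clinical associations are assessed among dysregulated taxa, so every
  # clinical-effect taxon also carries a tumor-vs-normal effect
  if (nrow(clin_truth)) {
    da_truth <- rbind(da_truth, data.frame(
      taxon = clin_truth$taxon, cohort = "tumor",
      lfc = clin_truth$lfc, stringsAsFactors = FALSE
    ))
  }

  depth <- stats::rlnorm(n, config$depth_meanlog, config$depth_sdlog)
  mean_depth <- exp(config$depth_meanlog + config$depth_sdlog^2 / 2)
  prop <- 10^stats::runif(nt, config$base_logprop_range[1L],
                          config$base_logprop_range[2L])
  mu <- outer(prop, depth)  # taxa x samples

  # slope archetype: mean independent of sample depth
  mu[idx_slope, ] <- prop[idx_slope] * mean_depth
  # plate archetype: confined to two plates, depth-independent
  plates <- unique(meta$seq_plate)
  for (i in idx_plate) {
    on <- meta$seq_plate %in% sample(plates, min(2L, length(plates)))
    mu[i, ] <- ifelse(on, prop[i] * mean_depth * 5, 0)
  }
  # date archetype: confined to one date
  dates <- unique(meta$seq_date)
  for (i in idx_date) {
    on <- meta$seq_date == sample(dates, 1L)
    mu[i, ] <- ifelse(on, prop[i] * mean_depth * 5, 0)
  }
  # cohort abundance effects
  for (i in seq_len(nrow(da_truth))) {
    on <- cohort_members(meta, da_truth$cohort[i])
    ti <- match(da_truth$taxon[i], taxa$id)
    mu[ti, on] <- mu[ti, on] * 2^da_truth$lfc[i]
  }
  # clinical effects (tumors only)
  for (i in seq_len(nrow(clin_truth))) {
    v <- as.character(meta[[clin_truth$variable[i]]])
    on <- meta$tissue == "tumor" & !is.na(v) &
      grepl(paste0("^(", clin_truth$level[i], ")$"), v)
    ti <- match(clin_truth$taxon[i], taxa$id)
    mu[ti, on] <- mu[ti, on] * 2^clin_truth$lfc[i]
  }

  counts <- matrix(
    stats::rnbinom(nt * n, mu = as.vector(mu), size = 1 / config$dispersion),
    nrow = nt, dimnames = list(taxa$id, meta$sample_id)
  )
  ct <- count_table(counts, taxa)

  # expression block tied to the first planted DA taxon (or first clean one)
  target <- if (nrow(da_truth)) da_truth$taxon[1L] else
    taxa$id[archetype == "none"][1L]
  ex <- simulate_expression(ct, target, config$expression)

  truth <- structure(list(
    taxa = data.frame(taxon = taxa$id, domain = taxa$domain,
                      archetype = archetype, stringsAsFactors = FALSE),
    da = da_truth,
    clinical = clin_truth,
    expression = list(target_taxon = target,
                      planted_set = "PLANTED_SET",
                      planted_genes = ex$planted_genes,
                      target_cor = config$expression$target_cor),
    seed = config$seed
  ), class = "truth_manifest")

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      counts = file.path(out_dir, "counts.tsv"),
      metadata = file.path(out_dir, "metadata.tsv"),
      expression = file.path(out_dir, "expression.gct"),
      phenotype = file.path(out_dir, "phenotype.cls"),
      gene_sets = file.path(out_dir, "gene_sets.gmt"),
      truth = file.path(out_dir, "truth.json")
    )
    write_count_table(ct, files[["counts"]])
    write_sample_metadata(meta, files[["metadata"]])
    write_gct(ex$expr, files[["expression"]])
    write_cls_continuous(clr_transform(ct)[target, ], files[["phenotype"]],
                         name = target)
    write_gmt(ex$gene_sets, files[["gene_sets"]])
    write_truth(truth, files[["truth"]])
  }
  list(counts = ct, meta = meta, expr = ex$expr, gene_sets = ex$gene_sets,
       truth = truth, files = files)
}

simulate_metadata <- function(config) {
  n_t <- config$n_tumor
  n_n <- config$n_normal
  n <- n_t + n_n
  tissue <- rep(c("tumor", "normal"), c(n_t, n_n))
  patient <- c(sprintf("P%04d", seq_len(n_t)), sprintf("P%04d", seq_len(n_n)))
  gender_t <- sample(names(config$gender_weights), n_t, replace = TRUE,
                     prob = config$gender_weights)
  gender <- c(gender_t, gender_t[seq_len(n_n)])  # normals share patient gender
  subtype <- c(sample(names(config$subtype_weights), n_t, replace = TRUE,
                      prob = config$subtype_weights), rep(NA_character_, n_n))
  braf <- c(ifelse(stats::runif(n_t) < config$braf_positive_fraction,
                   "positive", "negative"), rep(NA_character_, n_n))
  dates <- format(seq.Date(as.Date("2011-01-15"), by = "month",
                           length.out = config$n_dates), "%Y-%m-%d")
  plates <- sprintf("plate%02d", seq_len(config$n_plates))
  clin <- function(levels, prob) {
    c(sample(levels, n_t, replace = TRUE, prob = prob), rep(NA_character_, n_n))
  }
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    patient_id = patient, tissue = tissue, subtype = subtype, gender = gender,
    seq_date = as.Date(sample(dates, n, replace = TRUE)),
    seq_plate = sample(plates, n, replace = TRUE),
    braf_v600e = braf,
    vital_status = clin(c("alive", "dead"), c(0.9, 0.1)),
    perineural_invasion = clin(c("no", "yes"), c(0.85, 0.15)),
    pathologic_stage = clin(c("I", "II", "III", "IV"), c(0.55, 0.17, 0.18, 0.10)),
    t_stage = clin(c("T1", "T2", "T3", "T4"), c(0.3, 0.35, 0.25, 0.1)),
    n_stage = clin(c("N0", "N1"), c(0.5, 0.5)),
    m_stage = clin(c("M0", "M1"), c(0.95, 0.05)),
    stringsAsFactors = FALSE
  )
}

simulate_expression <- function(ct, target, excfg) {
  z <- clr_transform(ct)[target, ]
  z <- (z - mean(z)) / stats::sd(z)
  genes <- sprintf("G%04d", seq_len(excfg$n_genes))
  expr <- matrix(stats::rnorm(excfg$n_genes * length(z)),
                 nrow = excfg$n_genes,
                 dimnames = list(genes, names(z) %||% colnames(ct$counts)))
  colnames(expr) <- colnames(ct$counts)
  planted <- sample(genes, excfg$set_size)
  rho <- excfg$target_cor
  for (g in planted) {
    expr[g, ] <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
  }
  others <- setdiff(genes, planted)
  gene_sets <- c(
    list(PLANTED_SET = planted),
    stats::setNames(
      lapply(seq_len(excfg$n_null_sets), function(i) {
        sample(others, excfg$null_set_size)
      }),
      sprintf("NULL_SET_%02d", seq_len(excfg$n_null_sets))
    )
  )
  list(expr = expr, planted_genes = planted, gene_sets = gene_sets)
}

#' Write / read the ground-truth manifest
#'
#' @param truth a `truth_manifest` from [simulate_dataset()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_manifest"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("taxa", "da", "clinical")) raw[[f]] <- as.data.frame(raw[[f]])
  structure(raw, class = "truth_manifest")
}

#' Score pipeline outputs against the planted truth
#'
#' Exact set comparison of each stage's calls with the manifest: per
#' detector, sensitivity on its own archetype and false-positive rate on
#' unplanted taxa; for differential abundance, per-cohort sensitivity on
#' planted taxa (counted as detected only when the direction matches the
#' planted sign) and FPR on taxa with no planted effect of any kind; for
#' the clinical stage, sensitivity/FPR over (taxon, variable) pairs; for
#' enrichment, whether the planted gene set passes the filter and the pass
#' rate among null sets.
#'
#' @param truth a `truth_manifest`.
#' @param report optional `contaminant_report`.
#' @param da_tables optional named list of `da_table`s; names must match
#'   the simulated cohort labels (e.g. `tumor` for tumor-vs-normal).
#' @param clinical optional `clinical_assoc` table.
#' @param enrichment optional `enrichment_result` table.
#' @return A `truth_scorecard`: nested list of metrics per stage.
#' @export
score_against_truth <- function(truth, report = NULL, da_tables = NULL,
                                clinical = NULL, enrichment = NULL) {
  stopifnot(inherits(truth, "truth_manifest"))
  out <- list()
  if (!is.null(report)) {
    if (!all(report$taxon %in% truth$taxa$taxon)) {
      stop("contaminant report contains taxa unknown to the manifest")
    }
    arch <- truth$taxa$archetype[match(report$taxon, truth$taxa$taxon)]
    det <- function(flag, a) {
      list(sensitivity = mean(flag[arch == a]),
           fpr = mean(flag[arch == "none"]))
    }
    out$decontam <- list(
      slope = det(report$slope_flag, "slope"),
      plate = det(report$plate_flag, "plate"),
      date = det(report$date_flag, "date"),
      union = list(sensitivity = mean(report$flagged[arch != "none"]),
                   fpr = mean(report$flagged[arch == "none"]))
    )
  }
  if (!is.null(da_tables)) {
    planted_any <- unique(c(truth$da$taxon, truth$clinical$taxon,
                            truth$taxa$taxon[truth$taxa$archetype != "none"]))
    out$da <- lapply(stats::setNames(nm = names(da_tables)), function(co) {
      tb <- da_tables[[co]]
      pl <- truth$da[truth$da$cohort == co, , drop = FALSE]
      hit <- function(taxon, lfc) {
        i <- match(taxon, tb$taxon)
        !is.na(i) && tb$significant[i] &&
          ((lfc > 0) == (tb$direction[i] == "over_in_a"))
      }
      sens <- if (nrow(pl)) {
        mean(mapply(hit, pl$taxon, pl$lfc))
      } else NA_real_
      nulls <- setdiff(tb$taxon, planted_any)
      list(sensitivity = sens,
           fpr = mean(tb$significant[tb$taxon %in% nulls]),
           n_significant = sum(tb$significant))
    })
  }
  if (!is.null(clinical)) {
    key <- paste(clinical$taxon, clinical$variable)
    pkey <- paste(truth$clinical$taxon, truth$clinical$variable)
    out$clinical <- list(
      sensitivity = if (length(pkey)) {
        mean(pkey %in% key[clinical$significant])
      } else NA_real_,
      fpr = mean(clinical$significant[!key %in% pkey])
    )
  }
  if (!is.null(enrichment)) {
    pl <- truth$expression$planted_set
    out$enrichment <- list(
      planted_detected = as.integer(
        isTRUE(enrichment$pass_filter[match(pl, enrichment$gene_set)])),
      null_pass_rate = mean(enrichment$pass_filter[enrichment$gene_set != pl])
    )
  }
  structure(out, class = "truth_scorecard")
}

#' @export
print.truth_scorecard <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @importFrom utils str
NULL
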