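#' Default pipeline configuration
#'
#' One nested list drives every stage; [read_pipeline_config()] merges a
#' YAML file over these defaults. Blocks: `decontam` (detector thresholds),
#' `da` (p/logFC thresholds, whether the p threshold applies to
#' Bonferroni-adjusted p-values), `clinical` (variables, stage-collapsing),
#' `enrichment` (permutations, weight, ranking metric), and `simulate`
#' (passed to [simulation_config()]).
#'
#' @param seed integer seed used for the simulate and enrichment stages.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 7) {
  list(
    seed = seed,
    decontam = list(slope_margin = 0.1, min_prevalence = 0.1,
                    slope_scale = "log", plate_share = 0.9, max_plates = 2,
                    date_share = 0.9),
    da = list(p_threshold = 0.05, lfc_threshold = 1, adjust = TRUE),
    clinical = list(variables = clinical_variables(), collapse_stage = TRUE,
                    p_threshold = 0.05),
    enrichment = list(n_perm = 1000, weight = 1, metric = "pearson",
                      p_threshold = 0.05, fdr_threshold = 0.25),
    simulate = list()
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are a configuration error; known blocks are
#' merged key-by-key over [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), c(names(base[[k]]),
                                         names(formals(simulation_config))))
      if (length(bad)) stop("unknown key(s) in '", k, "': ",
                            paste(bad, collapse = ", "))
      base[[k]][names(user[[k]])] <- user[[k]]
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

stage_metadata <- function(out_dir, stage, seed, params) {
  meta <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("mycoarch")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, parameters = params
  )
  jsonlite::write_json(meta, file.path(out_dir, paste0(stage, "_run.json")),
                       auto_unbox = TRUE, null = "null")
}

#' Run the whole pipeline on synthetic data
#'
#' One-shot end-to-end mode chaining simulate -> contaminant detection and
#' removal -> differential abundance over the default cohorts -> Venn
#' partitioning (subtype trio and gender pair) -> clinical association ->
#' gene-set enrichment for the designated target microbe, then scoring
#' everything against the planted truth. Each stage writes its result TSV
#' and a JSON run-metadata record under `out_dir`; no stage mutates its
#' inputs. Stages depend strictly on their upstream stage: differential
#' abundance refuses to run on an unfiltered table.
#'
#' @param config nested configuration (see [default_pipeline_config()]).
#' @param out_dir output directory; `NULL` skips all file output.
#' @param stages character vector of stages to run, in pipeline order; a
#'   downstream stage without its upstream dependency is an error naming
#'   the missing stage.
#' @return Invisibly, a list with every stage's in-memory result:
#'   `data` (simulated inputs), `report`, `filtered`, `abund`,
#'   `da_tables`, `partitions`, `clinical`, `enrichment`, `scorecard`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         stages = c("simulate", "decontam", "da", "overlap",
                                    "clinical", "gsea")) {
  order_ <- c("simulate", "decontam", "da", "overlap", "clinical", "gsea")
  stages <- match.arg(stages, order_, several.ok = TRUE)
  upstream <- c(decontam = "simulate", da = "decontam", overlap = "da",
                clinical = "da", gsea = "da")
  for (s in stages) {
    if (s %in% names(upstream) && !upstream[[s]] %in% stages) {
      stop("stage '", s, "' requires upstream stage '", upstream[[s]],
           "' (not in the requested stages)")
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_result_table(df, file.path(out_dir, name))
  }
  res <- list()

  simcfg <- do.call(simulation_config,
                    c(config$simulate,
                      if (!"seed" %in% names(config$simulate))
                        list(seed = config$seed)))
  res$data <- simulate_dataset(simcfg, out_dir = out_dir)
  if (!is.null(out_dir)) stage_metadata(out_dir, "simulate", simcfg$seed,
                                        config$simulate)
  if (!"decontam" %in% stages) return(invisible(res))

  dc <- config$decontam
  res$report <- detect_contaminants(
    res$data$counts, res$data$meta,
    slope_margin = dc$slope_margin, min_prevalence = dc$min_prevalence,
    slope_scale = dc$slope_scale, plate_share = dc$plate_share,
    max_plates = dc$max_plates, date_share = dc$date_share
  )
  filt <- remove_contaminants(res$data$counts, res$report)
  res$filtered <- filt$counts
  res$removed <- filt$removed
  emit(res$report, "contaminant_report.tsv")
  if (!is.null(out_dir)) stage_metadata(out_dir, "decontam", config$seed, dc)
  if (!"da" %in% stages) return(invisible(res))

  res$abund <- clr_transform(res$filtered)
  cohorts <- default_cohorts()
  res$da_tables <- list()
  for (nm in names(cohorts)) {
    tb <- tryCatch(
      run_cohort_comparison(res$filtered, res$abund, res$data$meta,
                            cohorts[[nm]],
                            p_threshold = config$da$p_threshold,
                            lfc_threshold = config$da$lfc_threshold,
                            adjust = config$da$adjust),
      error = function(e) {
        warning("cohort '", nm, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(tb)) next
    res$da_tables[[nm]] <- tb
    emit(tb, paste0("da_", nm, ".tsv"))
  }
  if (!is.null(out_dir)) stage_metadata(out_dir, "da", config$seed, config$da)

  if ("overlap" %in% stages) {
    res$partitions <- list()
    trio <- intersect(c("CPTC_vs_normal", "FVPTC_vs_normal",
                        "TCPTC_vs_normal"), names(res$da_tables))
    duo <- intersect(c("male_vs_male_normal", "female_vs_female_normal"),
                     names(res$da_tables))
    if (length(trio)) {
      res$partitions$subtype <- partition_by_direction(res$da_tables[trio])
      emit(partition_table(res$partitions$subtype), "overlap_subtype.tsv")
      emit(summarize_partition(res$partitions$subtype),
           "overlap_subtype_summary.tsv")
    }
    if (length(duo)) {
      res$partitions$gender <- partition_by_direction(res$da_tables[duo])
      emit(partition_table(res$partitions$gender), "overlap_gender.tsv")
      emit(summarize_partition(res$partitions$gender),
           "overlap_gender_summary.tsv")
    }
    if (!is.null(out_dir)) stage_metadata(out_dir, "overlap", config$seed,
                                          list())
  }

  if ("clinical" %in% stages) {
    sig_taxa <- unique(unlist(lapply(res$da_tables, function(tb) {
      tb$taxon[tb$significant]
    })))
    if (length(sig_taxa)) {
      res$clinical <- associate_clinical(
        res$abund, res$data$meta, sig_taxa,
        variables = config$clinical$variables,
        p_threshold = config$clinical$p_threshold,
        collapse_stage = config$clinical$collapse_stage
      )
      emit(res$clinical, "clinical_assoc.tsv")
    }
    if (!is.null(out_dir)) stage_metadata(out_dir, "clinical", config$seed,
                                          config$clinical)
  }

  if ("gsea" %in% stages) {
    target <- res$data$truth$expression$target_taxon
    if (target %in% rownames(res$abund)) {
      phen <- res$abund[target, colnames(res$data$expr)]
      res$enrichment <- permutation_significance(
        res$data$expr, phen, res$data$gene_sets,
        n_perm = config$enrichment$n_perm,
        weight = config$enrichment$weight,
        method = config$enrichment$metric,
        seed = config$seed,
        p_threshold = config$enrichment$p_threshold,
        fdr_threshold = config$enrichment$fdr_threshold
      )
      res$enrichment <- cbind(microbe = target, res$enrichment)
      emit(res$enrichment, "enrichment.tsv")
    }
    if (!is.null(out_dir)) stage_metadata(out_dir, "gsea", config$seed,
                                          config$enrichment)
  }

  # score whatever was produced against the planted truth
  da_for_scoring <- res$da_tables
  names(da_for_scoring) <- sub("_vs_.*$", "", names(da_for_scoring))
  names(da_for_scoring)[names(da_for_scoring) == "braf_pos"] <- "braf_positive"
  if ("braf_positive" %in% names(da_for_scoring)) {
    # same comparison seen from the negative cohort's side
    flip <- da_for_scoring[["braf_positive"]]
    flip$logFC <- -flip$logFC
    flip$direction <- ifelse(flip$direction == "over_in_a",
                             "over_in_b", "over_in_a")
    da_for_scoring[["braf_negative"]] <- flip
  }
  res$scorecard <- score_against_truth(
    res$data$truth, report = res$report, da_tables = da_for_scoring,
    clinical = res$clinical, enrichment = res$enrichment
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(res$scorecard),
                         file.path(out_dir, "scorecard.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}
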