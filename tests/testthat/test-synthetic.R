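test_that("the generator is byte-identical across runs with the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(quick_config(seed = 7), out_dir = d1)
  simulate_dataset(quick_config(seed = 7), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed produces different data
  d3 <- withr::local_tempdir()
  simulate_dataset(quick_config(seed = 8), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})

test_that("per-sample totals follow the configured log-normal depth", {
  cfg <- simulation_config(
    n_tumor = 150, n_normal = 50, n_taxa_fungal = 180, n_taxa_archaeal = 20,
    contaminants = c(slope = 0, plate = 0, date = 0),
    da_effects = data.frame(cohort = character(0), n = integer(0),
                            lfc = numeric(0), direction = character(0)),
    clinical_effects = data.frame(variable = character(0), level = character(0),
                                  n = integer(0), lfc = numeric(0)),
    expression = list(n_genes = 12, set_size = 3, target_cor = 0.8,
                      n_null_sets = 1, null_set_size = 3),
    seed = 61
  )
  sim <- simulate_dataset(cfg)
  lt <- log(colSums(sim$counts$counts))
  # spread driven by depth_sdlog = 1; loose band
  expect_gt(sd(lt), 0.7)
  expect_lt(sd(lt), 1.3)
  ks <- suppressWarnings(stats::ks.test(lt, "pnorm", mean(lt), sd(lt)))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted DA taxa carry their configured fold change", {
  lfc_err <- c()
  for (seed in 1:10) {
    cfg <- simulation_config(
      n_tumor = 100, n_normal = 50, n_taxa_fungal = 90, n_taxa_archaeal = 10,
      contaminants = c(slope = 0, plate = 0, date = 0),
      da_effects = data.frame(cohort = "tumor", n = 5, lfc = 2,
                              direction = "up", stringsAsFactors = FALSE),
      clinical_effects = data.frame(variable = character(0),
                                    level = character(0), n = integer(0),
                                    lfc = numeric(0)),
      expression = list(n_genes = 12, set_size = 3, target_cor = 0.8,
                        n_null_sets = 1, null_set_size = 3),
      seed = 600 + seed
    )
    sim <- simulate_dataset(cfg)
    tum <- sim$meta$sample_id[sim$meta$tissue == "tumor"]
    nrm <- sim$meta$sample_id[sim$meta$tissue == "normal"]
    obs <- log_fold_change(sim$counts, tum, nrm)[sim$truth$da$taxon]
    lfc_err <- c(lfc_err, obs - sim$truth$da$lfc)
  }
  expect_lt(abs(mean(lfc_err)), 0.3)
})

test_that("planted slope contaminants refit near slope zero", {
  hits <- 0L
  total <- 0L
  for (seed in 1:5) {
    cfg <- simulation_config(
      n_tumor = 150, n_normal = 50, n_taxa_fungal = 180, n_taxa_archaeal = 20,
      contaminants = c(slope = 20, plate = 0, date = 0),
      da_effects = data.frame(cohort = character(0), n = integer(0),
                              lfc = numeric(0), direction = character(0)),
      clinical_effects = data.frame(variable = character(0),
                                    level = character(0), n = integer(0),
                                    lfc = numeric(0)),
      expression = list(n_genes = 12, set_size = 3, target_cor = 0.8,
                        n_null_sets = 1, null_set_size = 3),
      seed = 700 + seed
    )
    sim <- simulate_dataset(cfg)
    planted <- sim$truth$taxa$taxon[sim$truth$taxa$archetype == "slope"]
    res <- suppressMessages(slope_contaminant_scan(sim$counts))
    sl <- res$slope_stat[match(planted, res$taxon)]
    hits <- hits + sum(abs(sl) <= 0.1, na.rm = TRUE)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)
})

test_that("truth manifest round-trips through JSON", {
  sim <- simulate_dataset(quick_config(seed = 7))
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$taxa, sim$truth$taxa, ignore_attr = TRUE)
  expect_equal(back$da, sim$truth$da, ignore_attr = TRUE)
  expect_identical(back$expression$target_taxon,
                   sim$truth$expression$target_taxon)
})

test_that("scoring matches a hand-counted toy confusion matrix", {
  truth <- structure(list(
    taxa = data.frame(
      taxon = paste0("t", 1:10), domain = "fungal",
      archetype = c("slope", "slope", "plate", "date", rep("none", 6)),
      stringsAsFactors = FALSE
    ),
    da = data.frame(taxon = "t5", cohort = "tumor", lfc = 2,
                    stringsAsFactors = FALSE),
    clinical = data.frame(taxon = character(0), variable = character(0),
                          level = character(0), lfc = numeric(0)),
    expression = list(target_taxon = "t5", planted_set = "S",
                      planted_genes = "G1", target_cor = 0.8),
    seed = 1
  ), class = "truth_manifest")

  report <- data.frame(
    taxon = paste0("t", 1:10),
    slope_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 4)),
    plate_flag = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    date_flag = rep(FALSE, 10)
  )
  report$flagged <- report$slope_flag | report$plate_flag | report$date_flag

  da <- structure(data.frame(
    taxon = paste0("t", 1:10), domain = "fungal", H = 1, p_raw = 0.5,
    p_adj = 0.5, logFC = c(rep(0, 4), 2, rep(0, 5)),
    direction = c(rep("over_in_b", 4), "over_in_a", rep("over_in_b", 5)),
    significant = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE
  ), class = c("da_table", "data.frame"))

  sc <- score_against_truth(truth, report = report,
                            da_tables = list(tumor = da))
  # slope: 1 of 2 planted flagged; FPR: 1 of 6 unplanted flagged
  expect_equal(sc$decontam$slope$sensitivity, 0.5)
  expect_equal(sc$decontam$slope$fpr, 1 / 6)
  expect_equal(sc$decontam$plate$sensitivity, 1)
  expect_equal(sc$decontam$date$sensitivity, 0)
  expect_equal(sc$decontam$union$sensitivity, 0.5)
  expect_equal(sc$da$tumor$sensitivity, 1)
  # nulls are t6..t10 (t1..t4 are contaminants, t5 planted); none significant
  expect_equal(sc$da$tumor$fpr, 0)

  # perfect / zero recovery edge cases
  perfect <- report
  perfect$slope_flag <- truth$taxa$archetype == "slope"
  perfect$plate_flag <- truth$taxa$archetype == "plate"
  perfect$date_flag <- truth$taxa$archetype == "date"
  perfect$flagged <- perfect$slope_flag | perfect$plate_flag | perfect$date_flag
  sc2 <- score_against_truth(truth, report = perfect)
  expect_equal(sc2$decontam$slope$sensitivity, 1)
  expect_equal(sc2$decontam$union$fpr, 0)

  nothing <- report
  nothing$slope_flag <- nothing$plate_flag <- nothing$date_flag <-
    nothing$flagged <- FALSE
  sc3 <- score_against_truth(truth, report = nothing)
  expect_equal(sc3$decontam$slope$sensitivity, 0)

  bad <- report
  bad$taxon[1] <- "mystery"
  expect_error(score_against_truth(truth, report = bad), "unknown")
})
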