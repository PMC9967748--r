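# a matrix whose column totals are controlled exactly via a filler taxon
constructed_counts <- function() {
  totals <- c(100L, 200L, 300L, 400L)
  t1 <- as.integer(0.1 * totals)   # slope exactly 0.1 on the raw scale
  t2 <- as.integer(0.5 * totals)   # slope exactly 0.5
  t3 <- rep(7L, 4)                 # constant: slope 0
  filler <- totals - t1 - t2 - t3
  m <- rbind(t1 = t1, t2 = t2, t3 = t3, filler = filler)
  colnames(m) <- paste0("s", 1:4)
  m
}

test_that("raw-scale slope detector flags the zero-slope band inclusively", {
  m <- constructed_counts()
  res <- slope_contaminant_scan(m, margin = 0.1, scale = "raw")
  expect_equal(res$slope_stat[res$taxon == "t1"], 0.1, tolerance = 1e-12)
  expect_true(res$slope_flag[res$taxon == "t1"])   # boundary inclusive
  expect_equal(res$slope_stat[res$taxon == "t2"], 0.5, tolerance = 1e-12)
  expect_false(res$slope_flag[res$taxon == "t2"])
  expect_equal(res$slope_stat[res$taxon == "t3"], 0)
  expect_true(res$slope_flag[res$taxon == "t3"])
})

test_that("log-scale slope detector separates depth-proportional from constant taxa", {
  set.seed(11)
  n <- 120
  depth <- rlnorm(n, log(5e4), 1)
  m <- rbind(proportional = rpois(n, depth * 2e-3), constant = rpois(n, 60),
             bulk = rpois(n, depth * 0.05))
  colnames(m) <- paste0("s", 1:n)
  res <- slope_contaminant_scan(m, margin = 0.1, scale = "log")
  expect_false(res$slope_flag[res$taxon == "proportional"])
  expect_true(res$slope_flag[res$taxon == "constant"])
  expect_false(res$slope_flag[res$taxon == "bulk"])
})

test_that("slope detector skips sparse taxa and rejects degenerate totals", {
  m <- constructed_counts()
  m <- rbind(m, sparse = c(0L, 0L, 1L, 0L))
  res <- suppressMessages(slope_contaminant_scan(m, scale = "raw"))
  expect_true(is.na(res$slope_stat[res$taxon == "sparse"]))
  expect_false(res$slope_flag[res$taxon == "sparse"])

  flat <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(slope_contaminant_scan(flat), "degenerate")
})

test_that("plate detector flags concentration on few small plates only", {
  n <- 20
  meta <- make_meta(paste0("s", 1:n), n_plates = 10, n_dates = 4)
  m <- matrix(0L, 3, n, dimnames = list(c("conc", "unif", "zero"),
                                        meta$sample_id))
  m["conc", meta$seq_plate == "plate01"] <- 50L
  m["unif", ] <- 10L
  res <- plate_contaminant_scan(m, meta)
  expect_equal(res$plate_top2_share[res$taxon == "conc"], 1.0)
  expect_true(res$plate_flag[res$taxon == "conc"])
  # uniform across 10 plates: top-2 share = 2/10
  expect_equal(res$plate_top2_share[res$taxon == "unif"], 0.2)
  expect_false(res$plate_flag[res$taxon == "unif"])
  expect_true(is.na(res$plate_top2_share[res$taxon == "zero"]))
  expect_false(res$plate_flag[res$taxon == "zero"])
})

test_that("plate detector abstains with fewer than 3 plates", {
  meta <- make_meta(paste0("s", 1:4), n_plates = 2)
  m <- matrix(5L, 2, 4, dimnames = list(c("a", "b"), meta$sample_id))
  expect_warning(res <- plate_contaminant_scan(m, meta), "abstains")
  expect_true(all(!res$plate_flag))
  expect_true(all(is.na(res$plate_top2_share)))
})

test_that("date detector flags one-date clusters and honours the 50% guard", {
  n <- 40
  meta <- make_meta(paste0("s", 1:n), n_dates = 10)
  one_date <- meta$seq_date == meta$seq_date[1]
  m <- matrix(0L, 2, n, dimnames = list(c("clustered", "unif"),
                                        meta$sample_id))
  m["clustered", one_date] <- 30L
  m["unif", ] <- 10L
  res <- date_contaminant_scan(m, meta)
  expect_equal(res$date_modal_share[res$taxon == "clustered"], 1.0)
  expect_true(res$date_flag[res$taxon == "clustered"])
  expect_false(res$date_flag[res$taxon == "unif"])

  # every sample on one date: the implicated batch holds 100% of samples
  meta1 <- meta
  meta1$seq_date <- as.Date("2011-01-15")
  res1 <- date_contaminant_scan(m, meta1)
  expect_equal(res1$date_modal_share[res1$taxon == "clustered"], 1.0)
  expect_false(any(res1$date_flag))
})

test_that("removal implements the union of detector flags", {
  sim <- simulate_dataset(quick_config(seed = 13))
  report <- suppressMessages(detect_contaminants(sim$counts, sim$meta))
  expect_identical(report$flagged,
                   report$slope_flag | report$plate_flag | report$date_flag)
  filt <- remove_contaminants(sim$counts, report)
  expected_removed <- sort(unique(c(report$taxon[report$slope_flag],
                                    report$taxon[report$plate_flag],
                                    report$taxon[report$date_flag])))
  expect_identical(sort(filt$removed), expected_removed)
  expect_identical(sort(c(filt$counts$taxa$id, filt$removed)),
                   sort(sim$counts$taxa$id))

  # no flags: identity
  none <- report
  none$slope_flag <- none$plate_flag <- none$date_flag <- none$flagged <- FALSE
  id <- remove_contaminants(sim$counts, none)
  expect_identical(id$counts$counts, sim$counts$counts)

  # all flagged: empty table with a hard warning
  all_ <- report
  all_$flagged <- TRUE
  expect_warning(empty <- remove_contaminants(sim$counts, all_), "empty")
  expect_equal(nrow(empty$counts$counts), 0)
})

test_that("detectors are equivariant under sample permutation", {
  sim <- simulate_dataset(quick_config(seed = 17))
  report <- suppressMessages(detect_contaminants(sim$counts, sim$meta))
  set.seed(99)
  perm <- sample(ncol(sim$counts$counts))
  shuffled <- subset_count_table(sim$counts, samples = perm)
  report2 <- suppressMessages(detect_contaminants(shuffled, sim$meta))
  expect_identical(report$flagged, report2$flagged)
  expect_equal(report$slope_stat, report2$slope_stat)
  expect_equal(report$plate_top2_share, report2$plate_top2_share)
})

test_that("diagnostic plots are written, three per taxon, unknown taxon errors", {
  sim <- simulate_dataset(quick_config(seed = 7))
  report <- suppressMessages(detect_contaminants(sim$counts, sim$meta))
  dir <- withr::local_tempdir()
  taxa <- sim$counts$taxa$id[1:2]
  paths <- render_diagnostics(sim$counts, sim$meta, report, taxa, dir)
  expect_length(paths, 6L)
  expect_true(all(file.exists(paths)))
  expect_error(
    render_diagnostics(sim$counts, sim$meta, report, "NOT_A_TAXON", dir),
    "unknown taxon"
  )
})
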