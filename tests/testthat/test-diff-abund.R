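test_that("Kruskal-Wallis reproduces the hand-worked two-group case", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(res$H, 27 / 7, tolerance = 1e-12)
  expect_equal(res$H, 3.857, tolerance = 1e-3)
  expect_equal(res$p, 0.0495, tolerance = 1e-3)
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test including ties", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    g <- sample(letters[1:k], 6 + rpois(1, 10), replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(letters[1:k], 12, replace = TRUE)
    v <- sample(1:6, length(g), replace = TRUE)  # many ties
    if (length(unique(v)) == 1) next
    ours <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H matches the independent rank-formula oracle on all small datasets", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    n_a <- sample(1:(n - 1), 1)
    v <- sample(1:5, n, replace = TRUE)
    g <- rep(c("a", "b"), c(n_a, n - n_a))
    if (length(unique(v)) == 1) {
      expect_equal(kruskal_wallis(v, g)$H, 0)
      next
    }
    expect_equal(kruskal_wallis(v, g)$H, kw_oracle_H(v, g), tolerance = 1e-10)
  }
})

test_that("permutation p from the implementation's H matches exhaustive enumeration", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    n_a <- sample(2:(n - 2), 1)
    v <- round(rnorm(n), 2)
    g <- rep(c("a", "b"), c(n_a, n - n_a))
    h_obs <- kruskal_wallis(v, g)$H
    # permutation p computed twice: from the implementation's H over all
    # splits, and fully inside the oracle
    splits <- utils::combn(n, n_a)
    impl_perm_p <- mean(apply(splits, 2, function(ia) {
      gg <- rep("b", n); gg[ia] <- "a"
      kruskal_wallis(v, gg)$H
    }) >= h_obs - 1e-10)
    expect_equal(impl_perm_p, kw_perm_p_oracle(v, n_a, h_obs))
  }
})

test_that("degenerate inputs behave as specified", {
  expect_equal(kruskal_wallis(c(1, 2, 1, 2), c("a", "a", "b", "b"))$H, 0)
  expect_equal(kruskal_wallis(c(5, 5, 5, 5), c("a", "a", "b", "b")),
               list(H = 0, p = 1))
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "2 groups")
  expect_identical(
    kruskal_wallis(c(3, 1, 2, 6, 5, 4), rep(c("a", "b"), each = 3)),
    kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  )
})

test_that("log fold change follows direct arithmetic and is antisymmetric", {
  # relative abundances 4e-3 in group a, 1e-3 in group b
  m <- matrix(0L, 2, 4,
              dimnames = list(c("t", "rest"), c("a1", "a2", "b1", "b2")))
  m["t", ] <- c(4L, 4L, 1L, 1L)
  m["rest", ] <- c(996L, 996L, 999L, 999L)
  lfc <- log_fold_change(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(lfc["t"]), 2, tolerance = 1e-3)
  rev_ <- log_fold_change(m, c("b1", "b2"), c("a1", "a2"))
  expect_equal(unname(lfc), -unname(rev_))

  same <- log_fold_change(m, c("a1", "b1"), c("a2", "b2"))
  expect_true(abs(same["t"]) < 0.01)
  expect_error(log_fold_change(m, c("a1", "a2"), c("a2", "b1")), "disjoint")
})

test_that("Bonferroni adjustment multiplies, caps, and preserves order", {
  expect_equal(bonferroni_adjust(0.03), 0.03)
  expect_equal(bonferroni_adjust(c(0.01, 0.4)), c(0.02, 0.8))
  expect_equal(bonferroni_adjust(c(0.9, 0.2, 0.01, 0.04, 0.5))[1], 1)
  expect_error(bonferroni_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bonferroni_adjust(1.2), "\\(0, 1\\]")

  set.seed(24)
  p <- runif(30)
  adj <- bonferroni_adjust(p)
  expect_equal(adj, pmin(1, length(p) * p))           # definition by hand
  expect_true(all(diff(adj[order(p)]) >= 0))          # monotone (ties at cap)
  expect_true(all(adj >= p))
})

test_that("cohort comparison detects a planted effect and validates groups", {
  cfg <- simulation_config(
    n_tumor = 100, n_normal = 50, n_taxa_fungal = 90, n_taxa_archaeal = 10,
    contaminants = c(slope = 0, plate = 0, date = 0),
    da_effects = data.frame(cohort = "tumor", n = 1, lfc = 2,
                            direction = "up", stringsAsFactors = FALSE),
    clinical_effects = data.frame(variable = character(0), level = character(0),
                                  n = integer(0), lfc = numeric(0)),
    expression = list(n_genes = 12, set_size = 3, target_cor = 0.8,
                      n_null_sets = 1, null_set_size = 3),
    seed = 101
  )
  sim <- simulate_dataset(cfg)
  spec <- cohort_spec("tumor_vs_normal", list(tissue = "tumor"),
                      list(tissue = "normal"))
  tb <- run_cohort_comparison(sim$counts, meta = sim$meta, spec = spec)
  planted <- sim$truth$da$taxon[1]
  row <- tb[tb$taxon == planted, ]
  expect_true(row$significant)
  expect_identical(row$direction, "over_in_a")
  expect_gt(row$logFC, 1)
  expect_true(all(tb$p_adj >= tb$p_raw))
  expect_identical(tb$direction == "over_in_a", tb$logFC > 0)

  # misconfigured groups
  same <- cohort_spec("bad", list(tissue = "tumor"), list(tissue = "tumor"))
  expect_error(run_cohort_comparison(sim$counts, meta = sim$meta, spec = same),
               "overlap")

  # relabelling the groups flips direction but not the call
  rev_spec <- cohort_spec("normal_vs_tumor", list(tissue = "normal"),
                          list(tissue = "tumor"))
  tb_rev <- run_cohort_comparison(sim$counts, meta = sim$meta, spec = rev_spec)
  expect_equal(tb_rev$p_raw, tb$p_raw, tolerance = 1e-12)
  expect_equal(tb_rev$logFC, -tb$logFC, tolerance = 1e-9)
  expect_identical(tb_rev$significant, tb$significant)
})

test_that("empty predicate resolution names the cohort", {
  sim <- simulate_dataset(quick_config(seed = 7))
  spec <- cohort_spec("ghost", list(tissue = "tumor", subtype = "NOSUCH"),
                      list(tissue = "normal"))
  expect_error(run_cohort_comparison(sim$counts, meta = sim$meta, spec = spec),
               "ghost")
})
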