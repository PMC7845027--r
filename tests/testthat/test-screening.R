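test_that("compute_cv matches the defining formula and its invariances", {
  expect_equal(compute_cv(c(100, 100, 100)), 0)
  expect_equal(compute_cv(c(50, 100, 150)), 0.5)
  set.seed(5)
  v <- rlnorm(20, 4, 0.5)
  expect_equal(compute_cv(v * 10), compute_cv(v))
  expect_error(compute_cv(100), ">= 2 values")
  expect_error(compute_cv(c(0, 0)), "mean is zero")
})

make_two_experiment_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m, rep(c("E1", "E2"), each = ncol(m) / 2))
}

test_that("MEAN screening averages per-experiment statistics inclusively", {
  # gene 'edge': per-experiment CVs 0.1 and 0.3 (mean 0.2), mean FPKM 200
  e1 <- 200 + c(-1, 1) * 200 * 0.1 / sqrt(2)
  e2 <- 200 + c(-1, 1) * 200 * 0.3 / sqrt(2)
  m <- make_two_experiment_matrix(list(edge = c(e1, e2),
                                       rare = c(99.9, 99.9, 99.9, 99.9)))
  rep <- screen_mean(m, fpkm_min = 100, cv_max = 0.2)
  pg <- rep$per_gene
  expect_equal(pg$cv[pg$gene_id == "edge"], 0.2, tolerance = 1e-12)
  expect_true("edge" %in% rep$pass)     # boundary inclusive
  expect_false("rare" %in% rep$pass)    # 99.9 < 100
})

test_that("SIMULTANEOUS screening intersects per-experiment pass sets", {
  cv_vals <- function(mu, cv) mu + c(-1, 1) * mu * cv / sqrt(2)
  m <- make_two_experiment_matrix(list(
    all_pass = c(cv_vals(150, 0.15), cv_vals(150, 0.15)),  # boundary CV
    one_fail = c(cv_vals(150, 0.05), cv_vals(150, 0.4))))
  rep <- screen_simultaneous(m, fpkm_min = 100, cv_max = 0.15)
  expect_equal(rep$pass, "all_pass")
  expect_true("one_fail" %in% rep$pass_sets$E1)
  expect_false("one_fail" %in% rep$pass_sets$E2)
  for (s in rep$pass_sets) expect_true(all(rep$pass %in% s))
})

test_that("screening recovers planted stable genes on synthetic data", {
  sim <- simulate_fpkm(synthetic_spec(n_genes = 300,
                                      samples_per_experiment = 10,
                                      seed = 42))
  stable <- sim$truth$gene_id[sim$truth$class == "stable"]
  sr <- screen_simultaneous(sim$matrix)
  expect_setequal(sr$pass, stable)
  # the housekeeping-like tier passes the lenient mean-averaged screen
  mr <- screen_mean(sim$matrix)
  expect_true(all(stable %in% mr$pass))
})

test_that("expression ratios average to one within every experiment", {
  m <- make_two_experiment_matrix(list(g1 = c(50, 150, 80, 120),
                                       g2 = c(7, 7, 7, 7)))
  r1 <- expression_ratio_profile(m, "g1")
  expect_equal(unname(r1[1:2]), c(0.5, 1.5))
  expect_equal(unname(expression_ratio_profile(m, "g2")),
               rep(1, 4))
  set.seed(6)
  for (i in 1:25) {
    em <- random_expression_matrix(4, 8, 2)
    for (g in rownames(em$values)) {
      r <- expression_ratio_profile(em, g)
      for (e in unique(em$experiment))
        expect_equal(mean(r[em$experiment == e]), 1, tolerance = 1e-12)
    }
  }
})

test_that("cv rank lists sort by CV with lexicographic tie-break", {
  m <- make_two_experiment_matrix(list(
    b_gene = c(100, 101, 100, 101),        # low CV
    a_gene = c(100, 150, 100, 150),        # higher CV
    c_gene = c(200, 202, 200, 202)))       # exact CV tie with b_gene
  rl <- cv_rank_lists(m, c("a_gene", "b_gene", "c_gene"))
  for (l in rl$lists) expect_equal(l, c("b_gene", "c_gene", "a_gene"))
  # independent oracle: recompute CVs and sort
  for (e in c("E1", "E2")) {
    idx <- m$experiment == e
    cvs <- apply(m$values[, idx], 1, compute_cv)
    expect_equal(rl$lists[[e]], names(cvs)[order(cvs, names(cvs))])
  }
  expect_error(cv_rank_lists(m, c("a_gene", "zz")), "missing from matrix")
})

test_that("ct abundance QC uses strict bounds at 15 and 30 cycles", {
  m <- matrix(c(9.51, 27, 30, 15, 31),
              5, 3, dimnames = list(c("rRNA", "ok", "edge30", "edge15",
                                      "high"), NULL))
  colnames(m) <- paste0("s", 1:3)
  qc <- ct_qc(m)
  expect_true(qc$flagged[qc$gene_id == "rRNA"])
  expect_false(qc$flagged[qc$gene_id == "ok"])
  expect_false(qc$flagged[qc$gene_id == "edge30"])
  expect_false(qc$flagged[qc$gene_id == "edge15"])
  expect_true(qc$flagged[qc$gene_id == "high"])
})

test_that("screening is invariant under sample reordering", {
  set.seed(7)
  em <- random_expression_matrix(6, 8, 2)
  perm <- sample(ncol(em$values))
  em2 <- expression_matrix(em$values[, perm], em$experiment[perm])
  a <- screen_simultaneous(em, fpkm_min = 50, cv_max = 0.8)
  b <- screen_simultaneous(em2, fpkm_min = 50, cv_max = 0.8)
  expect_equal(a$pass, b$pass)
})
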