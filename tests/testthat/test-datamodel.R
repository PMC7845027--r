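test_that("expression matrix validation rejects malformed inputs", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_matrix(m, c(s1 = "E1", s2 = "E2")),
               ">= 2 samples")
  m4 <- cbind(m, m); colnames(m4) <- paste0("s", 1:4)
  em <- expression_matrix(m4, c(s1 = "E1", s2 = "E1", s3 = "E2", s4 = "E2"))
  expect_s3_class(em, "expression_matrix")
  m4neg <- m4; m4neg[1, 1] <- -5
  expect_error(expression_matrix(m4neg, rep(c("E1", "E2"), each = 2)),
               "negative expression")
  rownames(m4) <- c("g1", "g1")
  expect_error(expression_matrix(m4, rep(c("E1", "E2"), each = 2)),
               "duplicate gene ids")
})

test_that("expression matrix reader enforces the sample sheet", {
  dir <- withr::local_tempdir()
  sheet_path <- file.path(dir, "sheet.csv")
  writeLines(c("sample_id,experiment,cultivar,stage,group,replicate",
               "s1,E1,Ruegen,SG,A,1", "s2,E1,Ruegen,BG,A,1",
               "s3,E2,Ruegen,SG,A,1", "s4,E2,Ruegen,BG,A,1"),
             sheet_path)
  sheet <- read_sample_sheet(sheet_path)
  expect_true(is.ordered(sheet$stage))

  mat_path <- file.path(dir, "expr.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t10\t20\t30\t40", "g2\t1\t2\t3\t4"), mat_path)
  em <- read_expression_matrix(mat_path, sheet)
  expect_equal(em$values["g1", "s3"], 30)

  writeLines(c("gene_id\ts1\ts2\ts3\tsX",
               "g1\t10\t20\t30\t40", "g2\t1\t2\t3\t4"), mat_path)
  expect_error(read_expression_matrix(mat_path, sheet),
               "without experiment assignment")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t10\t20\t30\t-5", "g2\t1\t2\t3\t4"), mat_path)
  expect_error(read_expression_matrix(mat_path, sheet),
               "negative expression")
})

test_that("write/read round trip reproduces expression values bit-exactly", {
  dir <- withr::local_tempdir()
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:6),
                      experiment = rep(c("E1", "E2"), each = 3),
                      stringsAsFactors = FALSE)
  set.seed(1)
  for (i in 1:100) {
    em <- random_expression_matrix(4, 6, 2)
    path <- file.path(dir, "m.tsv")
    write_expression_matrix(em, path)
    back <- read_expression_matrix(path, sheet)
    expect_identical(back$values, em$values)
  }
})

test_that("ct table validation enforces replicate and range invariants", {
  rec <- toy_ct_records()
  ct <- ct_table(rec)
  expect_equal(ct$replicates, 4)
  expect_equal(unname(ct$efficiency["gA"]), 2.0)

  ragged <- rec[-1, ]
  expect_error(ct_table(ragged), "ragged replicates")
  bad <- rec; bad$ct[1] <- 50
  expect_error(ct_table(bad), "outside \\(0, 45\\)")
  expect_error(ct_table(rec, efficiency = c(gA = 1.2)),
               "efficiency outside")
})

test_that("efficiency percentages convert as E = 1 + pct/100", {
  dir <- withr::local_tempdir()
  rec <- toy_ct_records(genes = "RPT6A")
  write.csv(rec, file.path(dir, "ct.csv"), row.names = FALSE)
  writeLines(c("gene_id,efficiency_percent", "RPT6A,100.2"),
             file.path(dir, "eff.csv"))
  ct <- read_ct_table(file.path(dir, "ct.csv"), file.path(dir, "eff.csv"))
  expect_equal(unname(ct$efficiency["RPT6A"]), 2.002)
})

test_that("ct table round trip is lossless", {
  dir <- withr::local_tempdir()
  set.seed(2)
  rec <- toy_ct_records(ct = 0)  # placeholder, then randomize
  rec$ct <- runif(nrow(rec), 18, 32)
  ct <- ct_table(rec, efficiency = c(gA = 1.95, gB = 2.1))
  write_ct_table(ct, file.path(dir, "ct.csv"), file.path(dir, "eff.csv"))
  back <- read_ct_table(file.path(dir, "ct.csv"), file.path(dir, "eff.csv"))
  o <- order(rec$gene_id, rec$sample_id, rec$replicate)
  ob <- order(back$records$gene_id, back$records$sample_id,
              back$records$replicate)
  expect_identical(back$records$ct[ob], rec$ct[o])
  expect_equal(back$efficiency, ct$efficiency)
})

test_that("replicate collapse matches direct recomputation", {
  rec <- toy_ct_records(genes = "g", samples = "s", reps = 4)
  rec$ct <- c(19, 20, 21, 24)
  ct <- ct_table(rec)
  expect_equal(collapse_replicates(ct, "mean")["g", "s"], 21)
  expect_equal(collapse_replicates(ct, "median")["g", "s"], 20.5)
  # skewed replicate sets: mean and median differ as the direct formulas say
  set.seed(3)
  for (i in 1:20) {
    vals <- rlnorm(4, 3, 0.3)
    rec$ct <- vals
    ct <- ct_table(rec)
    expect_equal(collapse_replicates(ct, "mean")["g", "s"], mean(vals))
    expect_equal(collapse_replicates(ct, "median")["g", "s"], median(vals))
  }
})

test_that("ct_to_quantities follows Q = E^(Ctmin - Ct)", {
  m <- matrix(c(20, 21, 22), 1, 3, dimnames = list("g", c("a", "b", "c")))
  q <- ct_to_quantities(m, c(g = 2))
  expect_equal(as.numeric(q), c(1, 0.5, 0.25))
  # independent power-function oracle at non-ideal efficiency
  m2 <- matrix(c(20, 23.32), 1, 2, dimnames = list("g", c("a", "b")))
  q2 <- ct_to_quantities(m2, c(g = 2.002))
  expect_equal(q2["g", "b"], exp(-3.32 * log(2.002)), tolerance = 1e-12)
  expect_equal(unname(apply(q2, 1, max)), 1)
})

test_that("quantities are monotone in Ct and shift-invariant per gene", {
  set.seed(4)
  m <- random_ct_matrix(3, 8)
  q <- ct_to_quantities(m)
  for (g in rownames(m)) {
    expect_equal(order(m[g, ]), order(-q[g, ]))
  }
  q_shift <- ct_to_quantities(m + 3)  # add a constant to every gene
  expect_equal(unclass(q_shift), unclass(q), tolerance = 1e-12,
               ignore_attr = TRUE)
})
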