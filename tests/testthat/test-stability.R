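test_that("delta-Ct score equals geNorm M on Q = 2^(-Ct)", {
  set.seed(14)
  for (i in 1:10) {
    m <- random_ct_matrix(6, 12)
    q <- ct_to_quantities(m)   # E defaults to 2
    expect_equal(max(abs(deltact_score(m) - genorm_m(q))), 0,
                 tolerance = 1e-9)
  }
})

test_that("delta-Ct score is shift-invariant and zero between duplicates", {
  set.seed(15)
  m <- random_ct_matrix(4, 8)
  m2 <- rbind(m, dup = m["g01", ])
  expect_equal(sd(m2["dup", ] - m2["g01", ]), 0)
  shifted <- m; shifted["g02", ] <- shifted["g02", ] + 5
  expect_equal(deltact_score(shifted), deltact_score(m), tolerance = 1e-12)
})

test_that("bestkeeper statistics match direct formula recomputation", {
  m <- rbind(gA = c(20, 21, 22), gB = c(24, 25, 29))
  colnames(m) <- paste0("s", 1:3)
  bk <- bestkeeper(m)
  expect_equal(bk$mean_ct, c(21, 26))
  expect_equal(bk$sd_ct, c(sd(c(20, 21, 22)), sd(c(24, 25, 29))))
  expect_equal(bk$cv_pct, 100 * bk$sd_ct / bk$mean_ct)
  expect_equal(bk$geo_mean_ct,
               c(exp(mean(log(c(20, 21, 22)))),
                 exp(mean(log(c(24, 25, 29))))))
  index <- attr(bk, "index")
  expect_equal(index, exp(colMeans(log(m))))
  expect_equal(bk$r[1], cor(m["gA", ], index))
  expect_true(bk$inconsistent[2])   # SD > 1 cycle
  expect_false(bk$inconsistent[1])
})

test_that("bestkeeper flags an undefined r for constant genes", {
  m <- rbind(const = c(20, 20, 20), var = c(24, 25, 26))
  colnames(m) <- paste0("s", 1:3)
  bk <- bestkeeper(m)
  expect_true(bk$r_undefined[bk$gene_id == "const"])
  expect_true(is.na(bk$r[bk$gene_id == "const"]))
  # a gene tracking the index exactly has r = 1
  m2 <- rbind(a = c(20, 21, 22), b = c(20, 21, 22))
  colnames(m2) <- paste0("s", 1:3)
  expect_equal(bestkeeper(m2)$r, c(1, 1))
})

test_that("bestkeeper mad option uses deviation about the geometric mean", {
  set.seed(16)
  m <- random_ct_matrix(3, 6)
  bk <- bestkeeper(m, dispersion = "mad")
  g <- rownames(m)[1]
  gm <- exp(mean(log(m[g, ])))
  expect_equal(bk$sd_ct[bk$gene_id == g], mean(abs(m[g, ] - gm)))
})

test_that("normfinder vanishes on exact additive data", {
  k <- 5; n <- 10
  y <- outer(seq_len(k), rnorm(n), "+")   # y_ij = a_j + b_i, zero noise
  q <- 2 ^ y
  rownames(q) <- sprintf("g%02d", 1:k); colnames(q) <- sprintf("s%02d", 1:n)
  nf <- normfinder(quantity_matrix(q, provenance = "from-FPKM"))
  expect_equal(unname(nf$stability), rep(0, k))
  # grouped model also vanishes
  nfg <- normfinder(quantity_matrix(q, provenance = "from-FPKM"),
                    groups = rep(c("A", "B"), each = n / 2))
  expect_equal(unname(nfg$stability), rep(0, k))
})

test_that("grouped normfinder intergroup deviations sum to zero per group", {
  set.seed(17)
  m <- random_ct_matrix(5, 12)
  q <- ct_to_quantities(m)
  nf <- normfinder(q, groups = rep(c("A", "B"), 6))
  expect_true(all(abs(colSums(nf$decomposition$d)) < 1e-10))
  expect_true(all(nf$decomposition$sigma2 >= 0))
})

test_that("normfinder separates genes with distinct noise levels", {
  set.seed(18)
  hits <- 0
  for (i in 1:20) {
    sim <- simulate_ct(ct_sim_spec(n_genes = 4, n_samples = 16,
                                   noise_sd = c(0.1, 0.1, 1, 1),
                                   seed = 100 + i))
    q <- ct_to_quantities(collapse_replicates(sim$ct))
    st <- normfinder(q)$stability
    if (max(st[c("gene01", "gene02")]) < min(st[c("gene03", "gene04")]))
      hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("ct descriptives agree with an independent order-statistics oracle", {
  m <- matrix(c(15, 16, 17, 18), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  d <- ct_descriptives(m)
  expect_equal(d$median_ct, 16.5)
  expect_equal(d$range_ct, 3)
  single <- matrix(20, 1, 1, dimnames = list("g", "s1"))
  ds <- ct_descriptives(single)
  expect_equal(ds$min_ct, ds$max_ct)
  expect_equal(ds$median_ct, 20)
  set.seed(19)
  m2 <- random_ct_matrix(4, 9)
  d2 <- ct_descriptives(m2)
  for (i in 1:4) {
    v <- m2[i, ]
    expect_equal(d2$q25[i], unname(quantile(v, 0.25)))
    expect_equal(d2$q75[i], unname(quantile(v, 0.75)))
    expect_true(d2$min_ct[i] <= d2$q25[i] && d2$q25[i] <= d2$median_ct[i] &&
                  d2$median_ct[i] <= d2$q75[i] && d2$q75[i] <= d2$max_ct[i])
  }
})

test_that("stability panel ranks are score-consistent permutations", {
  sim <- simulate_ct(ct_sim_spec(n_genes = 6,
                                 noise_sd = c(0.05, 0.1, 0.3, 0.5, 0.8, 1),
                                 seed = 20))
  m <- collapse_replicates(sim$ct)
  st <- stability_panel(m)
  for (cols in list(c("genorm_m", "genorm_rank"),
                    c("normfinder_stability", "normfinder_rank"),
                    c("bestkeeper_sd", "bestkeeper_rank"),
                    c("deltact_score", "deltact_rank"))) {
    expect_setequal(st[[cols[2]]], seq_len(nrow(st)))
    ord <- order(st[[cols[2]]])
    expect_true(all(diff(st[[cols[1]]][ord]) >= 0))
  }
  units <- attr(st, "units")
  expect_equal(unname(units["bestkeeper_sd"]), "cycles")
  expect_equal(unname(units["normfinder_stability"]), "log2")
})

test_that("stability scores are invariant under sample permutation", {
  set.seed(21)
  m <- random_ct_matrix(5, 10)
  perm <- sample(ncol(m))
  a <- stability_panel(m)
  b <- stability_panel(m[, perm])
  for (col in c("genorm_m", "normfinder_stability", "bestkeeper_sd",
                "deltact_score"))
    expect_equal(b[[col]], a[[col]], tolerance = 1e-12)
})

test_that("ranked lists reproduce a reference sort with deterministic ties", {
  sim <- simulate_ct(ct_sim_spec(n_genes = 5, seed = 22))
  st <- stability_panel(collapse_replicates(sim$ct))
  rl <- build_ranked_lists(st)
  expect_named(rl$lists, c("genorm", "normfinder", "bestkeeper", "deltact"))
  expect_equal(rl$lists$genorm, st$gene_id[order(st$genorm_m, st$gene_id)])
  expect_equal(rl$lists$deltact,
               st$gene_id[order(st$deltact_score, st$gene_id)])
  # a tie resolves lexicographically
  st2 <- st
  st2$deltact_score <- rep(1, nrow(st2))
  rl2 <- build_ranked_lists(st2)
  expect_equal(rl2$lists$deltact, sort(st2$gene_id))
})
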