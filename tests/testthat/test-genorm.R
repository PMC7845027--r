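test_that("pairwise variation is zero for proportional genes and symmetric", {
  set.seed(8)
  m <- random_ct_matrix(4, 10)
  q <- ct_to_quantities(m)
  qq <- unclass(q)
  qq["g02", ] <- 2 * qq["g01", ]          # constant ratio
  qq <- quantity_matrix(qq / apply(qq, 1, max), provenance = "from-Ct")
  expect_equal(pairwise_variation(qq, "g01", "g02"), 0)
  for (i in 1:5) {
    pair <- sample(rownames(qq), 2)
    expect_equal(pairwise_variation(qq, pair[1], pair[2]),
                 pairwise_variation(qq, pair[2], pair[1]))
  }
  # algebraic identity: V on Q = 2^(-Ct) equals SD of Ct differences
  expect_equal(pairwise_variation(q, "g01", "g03"),
               sd(m["g03", ] - m["g01", ]))
})

test_that("genorm M matches its definition", {
  set.seed(9)
  m <- random_ct_matrix(5, 8)
  q <- ct_to_quantities(m)
  # two genes: both M equal V_12
  m2 <- genorm_m(q, c("g01", "g02"))
  v12 <- pairwise_variation(q, "g01", "g02")
  expect_equal(unname(m2), c(v12, v12))
  # direct recomputation oracle on the full panel
  mm <- genorm_m(q)
  for (g in rownames(q)) {
    others <- setdiff(rownames(q), g)
    expect_equal(mm[[g]],
                 mean(sapply(others, function(o)
                   sd(log2(q[g, ] / q[o, ])))))
  }
  # a duplicated gene (zero pairwise term) scores below the others' average
  qq <- rbind(unclass(q), dup = unclass(q)["g01", ])
  qq <- quantity_matrix(qq, provenance = "from-Ct")
  md <- genorm_m(qq)
  expect_lt(md[["dup"]], mean(md[setdiff(names(md), c("dup", "g01"))]))
  # pairwise-proportional panel: all M zero
  base <- matrix(rep(c(1, 0.5, 0.25, 0.125), each = 3), 3, 4, byrow = FALSE)
  prop <- quantity_matrix(rbind(a = c(1, .5, .25, .125),
                                b = c(1, .5, .25, .125) ,
                                c = c(1, .5, .25, .125)),
                          provenance = "from-Ct")
  colnames(prop) <- paste0("s", 1:4)
  expect_equal(unname(genorm_m(prop)), c(0, 0, 0))
})

test_that("iterative ranking removes the least stable gene first", {
  q <- quantity_matrix(
    rbind(a = c(1, 0.5, 0.25, 0.5),
          b = c(1, 0.5, 0.25, 0.5),        # proportional to a
          c = c(1, 0.9, 0.1, 0.7)),
    provenance = "from-Ct")
  colnames(q) <- paste0("s", 1:4)
  gr <- genorm_rank(q)
  expect_equal(gr$exclusion_order, "c")
  expect_equal(gr$ranking$gene_id, c("a", "b", "c"))
  expect_true(all(gr$ranking$tied[1:2]))
})

test_that("iterative ranking equals a brute-force reimplementation", {
  naive_rank <- function(q) {
    genes <- rownames(q)
    removed <- character(0)
    while (length(genes) > 2) {
      lq <- log2(q[genes, , drop = FALSE])
      mv <- sapply(genes, function(g)
        mean(sapply(setdiff(genes, g), function(o) sd(lq[g, ] - lq[o, ]))))
      worst <- names(mv)[order(-mv, names(mv))][1]
      removed <- c(removed, worst)
      genes <- setdiff(genes, worst)
    }
    c(sort(genes), rev(removed))
  }
  set.seed(10)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    q <- ct_to_quantities(random_ct_matrix(k, 8))
    expect_equal(genorm_rank(q)$ranking$gene_id, naive_rank(q))
  }
})

test_that("ranking is monotone in planted noise tiers", {
  sim <- simulate_ct(ct_sim_spec(n_genes = 5, sample_effect_sd = 0,
                                 noise_sd = c(0.05, 0.1, 0.4, 0.8, 1.6),
                                 seed = 12))
  q <- ct_to_quantities(collapse_replicates(sim$ct))
  rk <- genorm_rank(q)$ranking$gene_id
  expect_equal(rk[3:5], c("gene03", "gene04", "gene05"))
  expect_setequal(rk[1:2], c("gene01", "gene02"))
})

test_that("M and V are invariant to per-gene constant scaling", {
  set.seed(13)
  m <- random_ct_matrix(4, 8)
  q <- unclass(ct_to_quantities(m))
  q_scaled <- q * c(2, 0.5, 7, 1)
  expect_equal(unname(genorm_m(quantity_matrix(q_scaled,
                                               provenance = "from-FPKM"))),
               unname(genorm_m(quantity_matrix(q,
                                               provenance = "from-FPKM"))),
               tolerance = 1e-12)
})

test_that("pairwise-variation series finds the planted optimal number", {
  sim <- simulate_ct(ct_sim_spec(n_genes = 6,
                                 noise_sd = c(0.02, 0.03, 0.6, 0.7, 0.8, 0.9),
                                 seed = 5))
  q <- ct_to_quantities(collapse_replicates(sim$ct))
  gr <- genorm_rank(q)
  pv <- pv_series(q, gr)
  expect_equal(pv$optimal_n, 2)
  expect_true(all(pv$series$v >= 0))
  expect_equal(pv$series$n, 2:5)
})

test_that("V_n is zero when the next gene matches the running factor", {
  # three proportional genes: adding the third cannot change NF
  q <- quantity_matrix(rbind(a = c(1, .5, .25, .5),
                             b = c(1, .5, .25, .5),
                             c = c(1, .5, .25, .5)),
                       provenance = "from-Ct")
  colnames(q) <- paste0("s", 1:4)
  pv <- pv_series(q, c("a", "b", "c"), threshold = 0.15)
  expect_equal(pv$series$v, 0)
  expect_equal(pv$optimal_n, 2)
})
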