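#' Pairwise delta-Ct stability score
#'
#' For each candidate j, the mean over all partner genes k of the standard
#' deviation (over samples) of the per-sample Ct difference Ct_j - Ct_k.
#' A stable gene keeps a constant offset to every partner. In cycles.
#' With all efficiencies equal to 2 this equals the geNorm M value computed
#' on quantities Q = 2^(-Ct), since log2(Q_j/Q_k) = Ct_k - Ct_j.
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix.
#' @param candidates Gene ids (>= 2); default all.
#' @return Named numeric vector of scores (cycles).
#' @export
deltact_score <- function(ct_matrix, candidates = rownames(ct_matrix)) {
  k <- length(candidates)
  if (k < 2) stop("need >= 2 candidates")
  if (ncol(ct_matrix) < 3) stop("need >= 3 samples")
  x <- ct_matrix[candidates, , drop = FALSE]
  v <- matrix(0, k, k, dimnames = list(candidates, candidates))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      v[a, b] <- v[b, a] <- stats::sd(x[a, ] - x[b, ])
    }
  }
  rowSums(v) / (k - 1)
}

#' BestKeeper descriptive statistics and index correlations
#'
#' Per candidate: arithmetic and geometric mean Ct, min, max, the
#' dispersion statistic, and CV% = 100 * SD / mean. The BestKeeper index is
#' the per-sample geometric mean of Ct over all candidates; each gene's
#' Pearson correlation r with the index (with its two-sided p-value) says
#' how well the gene tracks the panel consensus. Genes with SD > 1 cycle
#' are flagged inconsistent; a zero-variance gene has an undefined r, which
#' is reported as `NA` with a flag rather than an error.
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix.
#' @param candidates Gene ids (>= 2); default all.
#' @param dispersion `"sd"` (default; sample SD about the arithmetic mean)
#'   or `"mad"` (mean absolute deviation about the geometric mean, the
#'   original spreadsheet's convention).
#' @return A data.frame of class `bestkeeper_result` with one row per
#'   candidate and the index in attribute `"index"`.
#' @export
bestkeeper <- function(ct_matrix, candidates = rownames(ct_matrix),
                       dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  if (length(candidates) < 2) stop("need >= 2 candidates")
  if (ncol(ct_matrix) < 3) stop("need >= 3 samples")
  x <- ct_matrix[candidates, , drop = FALSE]
  if (any(x <= 0)) stop("Ct must be positive for geometric statistics")
  index <- exp(colMeans(log(x)))
  rows <- lapply(candidates, function(g) {
    v <- x[g, ]
    gm <- exp(mean(log(v)))
    sdv <- stats::sd(v)
    disp <- if (dispersion == "sd") sdv else mean(abs(v - gm))
    if (sdv == 0) {
      r <- NA_real_; p <- NA_real_; undef <- TRUE
    } else {
      ht <- stats::cor.test(v, index)
      r <- unname(ht$estimate); p <- ht$p.value; undef <- FALSE
    }
    data.frame(gene_id = g, mean_ct = mean(v), geo_mean_ct = gm,
               min_ct = min(v), max_ct = max(v), sd_ct = disp,
               cv_pct = 100 * disp / mean(v), r = r, p_value = p,
               r_undefined = undef, inconsistent = disp > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "index") <- index
  attr(out, "dispersion") <- dispersion
  class(out) <- c("bestkeeper_result", "data.frame")
  out
}

# Ungrouped NormFinder variance estimate on sample-centered log expression.
# t_j is the raw per-gene variance of the residuals r_ij = y_ij - mean_i;
# under the additive model E[t_j] = sigma2_j (1 - 2/k) + (1/k^2) sum sigma2_l,
# which the closed-form correction inverts. Negative estimates clip to 0.
nf_sigma2_ungrouped <- function(r) {
  k <- nrow(r)
  t_j <- apply(r, 1, stats::var)
  total <- sum(t_j)
  pmax((t_j - total / (k * (k - 1))) * k / (k - 2), 0)
}

#' NormFinder model-based stability
#'
#' Works on y = log2(Q). Each sample is centered across genes, removing the
#' common abundance component. Ungrouped: the per-gene residual variance is
#' bias-corrected in closed form (the naive variance of centered residuals
#' mixes every gene's noise) and the stability is sigma-hat, in log2 units.
#' Grouped: per group, z is the group mean of the centered residuals and
#' d = z minus the gene's across-group mean is the intergroup deviation
#' (summing to zero over genes within each group); d is shrunk towards 0 by
#' the empirical-Bayes factor gamma^2 / (gamma^2 + sigma2/n_g), where
#' gamma^2 is the across-(gene, group) variance of d minus the mean
#' sampling variance (clipped at 0); the stability of gene j is the mean
#' over groups of |d-tilde| + sqrt(sigma2_jg / n_g), combining systematic
#' between-group deviation with within-group noise.
#'
#' @param q A [quantity_matrix()] (or strictly positive matrix); y =
#'   log2(q). For Ct input, convert with [ct_to_quantities()] first.
#' @param candidates Gene ids (>= 3); default all.
#' @param groups Optional factor/character vector of group labels, one per
#'   sample (>= 2 samples per group); `NULL` for the ungrouped model.
#' @return A `normfinder_result`: list with `stability` (named vector,
#'   log2 units), and `decomposition` (per-group z, d, d_shrunk, sigma2,
#'   n_g, gamma2 when grouped; sigma2 when ungrouped).
#' @export
normfinder <- function(q, candidates = rownames(q), groups = NULL) {
  k <- length(candidates)
  if (k < 3) stop("need >= 3 candidates")
  y <- log2(q[candidates, , drop = FALSE])
  if (ncol(y) < 3) stop("need >= 3 samples")
  r <- sweep(y, 2, colMeans(y))
  if (is.null(groups)) {
    sigma2 <- nf_sigma2_ungrouped(r)
    res <- list(stability = sqrt(sigma2),
                decomposition = list(sigma2 = sigma2, k = k,
                                     n = ncol(y)))
  } else {
    groups <- as.character(groups)
    if (length(groups) != ncol(y))
      stop("`groups` must have one label per sample")
    glev <- sort(unique(groups))
    n_g <- table(groups)[glev]
    if (any(n_g < 2)) stop("every group needs >= 2 samples")
    z <- sapply(glev, function(g)
      rowMeans(r[, groups == g, drop = FALSE]))           # k x G
    sigma2 <- sapply(glev, function(g) {
      sub <- r[, groups == g, drop = FALSE]
      nf_sigma2_ungrouped(sub)
    })                                                    # k x G
    d <- z - rowMeans(z)
    samp_var <- sweep(sigma2, 2, as.numeric(n_g), "/")
    gamma2 <- max(stats::var(as.vector(d)) - mean(samp_var), 0)
    shrink <- gamma2 / (gamma2 + samp_var)
    shrink[!is.finite(shrink)] <- 0                       # gamma2 = samp_var = 0
    d_shrunk <- d * shrink
    stability <- rowMeans(abs(d_shrunk) + sqrt(samp_var))
    names(stability) <- candidates
    res <- list(stability = stability,
                decomposition = list(z = z, d = d, d_shrunk = d_shrunk,
                                     sigma2 = sigma2, n_g = as.numeric(n_g),
                                     gamma2 = gamma2, k = k,
                                     groups = glev))
  }
  class(res) <- "normfinder_result"
  res
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("<normfinder_result> stability (log2 units):\n")
  print(sort(x$stability), ...)
  invisible(x)
}

#' Pooled Ct descriptive statistics per gene
#'
#' Order statistics of the collapsed Ct values across the sample panel:
#' the box-whisker summary used to judge abundance range and raw Ct
#' variation before any model-based analysis. Quartiles use linear
#' interpolation (R type 7).
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix.
#' @return data.frame with median, quartiles, min, max, range and mean per
#'   gene (all in cycles).
#' @export
ct_descriptives <- function(ct_matrix) {
  rows <- lapply(rownames(ct_matrix), function(g) {
    v <- ct_matrix[g, ]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(gene_id = g, mean_ct = mean(v), median_ct = qs[2],
               q25 = qs[1], q75 = qs[3], min_ct = min(v), max_ct = max(v),
               range_ct = max(v) - min(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the four-method stability panel
#'
#' Computes geNorm M (on quantities Q = E^(Ct_min - Ct)), NormFinder
#' stability, BestKeeper dispersion/CV%/index correlation, and the pairwise
#' delta-Ct score for one candidate panel, with a per-method rank column
#' (1 = most stable, ascending score, ties broken lexicographically by
#' gene id). Units: BestKeeper SD and delta-Ct scores are in cycles;
#' geNorm M and NormFinder stability are in log2 expression units.
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix.
#' @param candidates Gene ids (>= 3); default all.
#' @param efficiency Named per-gene amplification factors (default: the
#'   matrix's `"efficiency"` attribute, else 2.0).
#' @param groups Optional per-sample group labels for grouped NormFinder.
#' @param bestkeeper_dispersion Passed to [bestkeeper()].
#' @return A data.frame of class `stability_table` with score and rank
#'   columns per method; attribute `"units"` records the per-method units.
#' @export
stability_panel <- function(ct_matrix, candidates = rownames(ct_matrix),
                            efficiency = NULL, groups = NULL,
                            bestkeeper_dispersion = c("sd", "mad")) {
  if (length(candidates) < 3) stop("need >= 3 candidates")
  q <- ct_to_quantities(ct_matrix[candidates, , drop = FALSE], efficiency)
  m <- genorm_m(q, candidates)
  nf <- normfinder(q, candidates, groups = groups)
  bk <- bestkeeper(ct_matrix, candidates,
                   dispersion = bestkeeper_dispersion)
  dct <- deltact_score(ct_matrix, candidates)
  tab <- data.frame(
    gene_id = candidates,
    genorm_m = as.numeric(m[candidates]),
    normfinder_stability = as.numeric(nf$stability[candidates]),
    bestkeeper_sd = bk$sd_ct[match(candidates, bk$gene_id)],
    bestkeeper_cv = bk$cv_pct[match(candidates, bk$gene_id)],
    bestkeeper_r = bk$r[match(candidates, bk$gene_id)],
    deltact_score = as.numeric(dct[candidates]),
    stringsAsFactors = FALSE)
  rank_of <- function(score) {
    ord <- order(score, tab$gene_id)
    rk <- integer(length(score)); rk[ord] <- seq_along(score); rk
  }
  tab$genorm_rank <- rank_of(tab$genorm_m)
  tab$normfinder_rank <- rank_of(tab$normfinder_stability)
  tab$bestkeeper_rank <- rank_of(tab$bestkeeper_sd)
  tab$deltact_rank <- rank_of(tab$deltact_score)
  attr(tab, "units") <- c(genorm_m = "log2", normfinder_stability = "log2",
                          bestkeeper_sd = "cycles",
                          bestkeeper_cv = "percent_of_mean_ct",
                          deltact_score = "cycles")
  attr(tab, "normfinder") <- nf
  attr(tab, "bestkeeper") <- bk
  class(tab) <- c("stability_table", "data.frame")
  tab
}

#' Build the four ranked lists from a stability table
#'
#' One total order per method — ascending geNorm M, ascending NormFinder
#' stability, ascending BestKeeper dispersion (or CV% when configured),
#' ascending delta-Ct score — with lexicographic tie-breaks; the input form
#' for rank aggregation.
#'
#' @param stability A `stability_table` from [stability_panel()].
#' @param bestkeeper_key `"sd"` (default) or `"cv"`.
#' @return A [ranked_list_set()] with lists named `genorm`, `normfinder`,
#'   `bestkeeper`, `deltact`.
#' @export
build_ranked_lists <- function(stability, bestkeeper_key = c("sd", "cv")) {
  bestkeeper_key <- match.arg(bestkeeper_key)
  need <- c("genorm_m", "normfinder_stability", "bestkeeper_sd",
            "bestkeeper_cv", "deltact_score")
  if (!all(need %in% names(stability)) || anyNA(stability[need]))
    stop("incomplete stability table")
  key <- list(genorm = stability$genorm_m,
              normfinder = stability$normfinder_stability,
              bestkeeper = if (bestkeeper_key == "sd")
                stability$bestkeeper_sd else stability$bestkeeper_cv,
              deltact = stability$deltact_score)
  lists <- lapply(key, function(s)
    stability$gene_id[order(s, stability$gene_id)])
  ranked_list_set(lists)
}
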