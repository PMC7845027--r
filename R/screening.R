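#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean. Dimensionless; the screening statistic for expression stability.
#'
#' @param values Numeric vector of at least two finite values.
#' @return The CV as a single number.
#' @examples
#' compute_cv(c(50, 100, 150))  # 0.5
#' @export
compute_cv <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  if (any(!is.finite(values))) stop("non-finite values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(values) / m
}

# Per-(gene, experiment) mean FPKM and CV, as a long data.frame.
per_experiment_stats <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  expts <- sort(unique(em$experiment))
  out <- lapply(expts, function(e) {
    sub <- em$values[, em$experiment == e, drop = FALSE]
    if (ncol(sub) < 2) stop("experiment with < 2 samples: ", e)
    mu <- rowMeans(sub)
    if (any(mu == 0))
      cv <- ifelse(mu == 0, Inf, apply(sub, 1, stats::sd) / mu)
    else
      cv <- apply(sub, 1, stats::sd) / mu
    data.frame(gene_id = rownames(sub), experiment = e, mean_fpkm = mu,
               cv = cv, row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

new_screening_report <- function(mode, thresholds, per_gene, per_experiment,
                                 pass_sets, pass) {
  structure(list(mode = mode, thresholds = thresholds,
                 per_gene = per_gene, per_experiment = per_experiment,
                 pass_sets = pass_sets, pass = pass),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> mode %s: %d genes pass (fpkm >= %g, cv <= %g)\n",
              x$mode, length(x$pass), x$thresholds["fpkm_min"],
              x$thresholds["cv_max"]))
  invisible(x)
}

#' Screen genes on averaged per-experiment statistics
#'
#' Housekeeping-style screen: per gene, the mean FPKM and the CV are
#' computed within each experiment and then averaged across experiments;
#' a gene passes when the mean-of-means is at least `fpkm_min` and the
#' mean-of-CVs is at most `cv_max` (both boundaries inclusive).
#'
#' @param em An [expression_matrix()].
#' @param fpkm_min Abundance threshold on the averaged mean FPKM
#'   (default 100).
#' @param cv_max Stability threshold on the averaged CV (default 0.2).
#' @param pooled If `TRUE`, compute one mean and CV over all samples pooled
#'   instead of averaging per-experiment statistics.
#' @return A `screening_report` with `per_gene` (averaged statistics and
#'   pass flag), `per_experiment` (the long statistics table) and `pass`
#'   (the surviving gene ids).
#' @export
screen_mean <- function(em, fpkm_min = 100, cv_max = 0.2, pooled = FALSE) {
  pe <- per_experiment_stats(em)
  if (pooled) {
    mu <- rowMeans(em$values)
    cv <- ifelse(mu == 0, Inf, apply(em$values, 1, stats::sd) / mu)
    per_gene <- data.frame(gene_id = rownames(em$values), mean_fpkm = mu,
                           cv = cv, row.names = NULL,
                           stringsAsFactors = FALSE)
  } else {
    mu <- tapply(pe$mean_fpkm, pe$gene_id, mean)
    cv <- tapply(pe$cv, pe$gene_id, mean)
    genes <- rownames(em$values)
    per_gene <- data.frame(gene_id = genes,
                           mean_fpkm = as.vector(mu[genes]),
                           cv = as.vector(cv[genes]),
                           stringsAsFactors = FALSE)
  }
  per_gene$pass <- per_gene$mean_fpkm >= fpkm_min & per_gene$cv <= cv_max
  new_screening_report("MEAN",
                       c(fpkm_min = fpkm_min, cv_max = cv_max),
                       per_gene, pe, pass_sets = NULL,
                       pass = per_gene$gene_id[per_gene$pass])
}

#' Screen genes with thresholds applied in every experiment
#'
#' Stringent screen: a gene passes only when, in every experiment
#' simultaneously, its within-experiment CV is at most `cv_max` and its
#' within-experiment mean FPKM is at least `fpkm_min` (inclusive
#' boundaries). The per-experiment pass sets are the Venn-diagram strata;
#' the intersection is the candidate reference-gene set.
#'
#' @inheritParams screen_mean
#' @param cv_max Stability threshold per experiment (default 0.15).
#' @param per_sample_fpkm If `TRUE`, require every individual sample (not
#'   the per-experiment mean) to reach `fpkm_min`.
#' @return A `screening_report`; `pass_sets` holds one gene set per
#'   experiment, `pass` their intersection, and `per_gene` the
#'   gene x experiment pass flags.
#' @export
screen_simultaneous <- function(em, fpkm_min = 100, cv_max = 0.15,
                                per_sample_fpkm = FALSE) {
  pe <- per_experiment_stats(em)
  if (per_sample_fpkm) {
    expts <- sort(unique(em$experiment))
    minv <- sapply(expts, function(e)
      apply(em$values[, em$experiment == e, drop = FALSE], 1, min))
    pe$abundance_ok <-
      minv[cbind(pe$gene_id, pe$experiment)] >= fpkm_min
  } else {
    pe$abundance_ok <- pe$mean_fpkm >= fpkm_min
  }
  pe$pass <- pe$abundance_ok & pe$cv <= cv_max
  expts <- sort(unique(pe$experiment))
  pass_sets <- lapply(expts, function(e)
    pe$gene_id[pe$experiment == e & pe$pass])
  names(pass_sets) <- expts
  pass <- Reduce(intersect, pass_sets)
  new_screening_report("SIMULTANEOUS",
                       c(fpkm_min = fpkm_min, cv_max = cv_max),
                       per_gene = pe, per_experiment = pe,
                       pass_sets = pass_sets,
                       pass = pass[order(pass)])
}

#' Expression-ratio profile of one gene
#'
#' Each sample's expression divided by the gene's mean expression within
#' that sample's experiment; by construction the ratios average to 1 within
#' every experiment, which puts genes of different abundance on a common
#' stability scale.
#'
#' @param em An [expression_matrix()].
#' @param gene A gene id present in `em`.
#' @return Named numeric vector of per-sample ratios.
#' @export
expression_ratio_profile <- function(em, gene) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!gene %in% rownames(em$values)) stop("gene not in matrix: ", gene)
  v <- em$values[gene, ]
  out <- v
  for (e in unique(em$experiment)) {
    idx <- em$experiment == e
    m <- mean(v[idx])
    if (m == 0) stop("zero-mean experiment for gene ", gene, ": ", e)
    out[idx] <- v[idx] / m
  }
  out
}

#' Per-experiment CV rank lists over a candidate set
#'
#' Within each experiment, candidates are sorted by ascending CV (ties
#' broken lexicographically by gene id). The resulting lists are the input
#' to rank aggregation.
#'
#' @param em An [expression_matrix()].
#' @param candidates Character vector of gene ids (>= 2).
#' @return A [ranked_list_set()] with one list per experiment.
#' @export
cv_rank_lists <- function(em, candidates) {
  if (length(candidates) < 2) stop("need >= 2 candidates")
  missing <- setdiff(candidates, rownames(em$values))
  if (length(missing))
    stop("candidate missing from matrix: ", paste(missing, collapse = ", "))
  pe <- per_experiment_stats(
    expression_matrix(em$values[candidates, , drop = FALSE],
                      em$experiment))
  expts <- sort(unique(pe$experiment))
  lists <- lapply(expts, function(e) {
    sub <- pe[pe$experiment == e, ]
    sub$gene_id[order(sub$cv, sub$gene_id)]
  })
  names(lists) <- expts
  ranked_list_set(lists)
}

#' Flag genes with inappropriate qPCR abundance
#'
#' A candidate whose mean Ct over the panel is above 30 (too scarce) or
#' below 15 (too abundant, e.g. rRNA) is flagged as having inappropriate
#' abundance for a reference gene; both comparisons are strict, so a mean
#' Ct of exactly 30 or 15 is acceptable. Flagged genes are excluded from
#' default downstream candidate sets but remain reported.
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix.
#' @param high Upper bound (default 30 cycles).
#' @param low Lower bound (default 15 cycles).
#' @return data.frame with `gene_id`, `mean_ct`, `flagged`, `reason`.
#' @export
ct_qc <- function(ct_matrix, high = 30, low = 15) {
  mu <- rowMeans(ct_matrix)
  flagged <- mu > high | mu < low
  data.frame(gene_id = rownames(ct_matrix), mean_ct = mu,
             flagged = flagged,
             reason = ifelse(!flagged, "",
                             ifelse(mu > high, sprintf("mean Ct > %g", high),
                                    sprintf("mean Ct < %g", low))),
             row.names = NULL, stringsAsFactors = FALSE)
}
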