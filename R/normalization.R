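#' Relative expression by the delta-delta-Cq method
#'
#' Efficiency-aware relative quantification: each gene's quantity is
#' Q_g = E_g^(-Ct_g) (up to a per-gene constant that cancels), the
#' normalization factor NF is the per-sample geometric mean of the
#' reference genes' quantities, and the reported fold is
#' (Q_target / NF) scaled so the calibrator sample equals 1. With all
#' efficiencies equal to 2 and a single reference this is the textbook
#' 2^(-delta-delta-Ct).
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix.
#' @param target Target gene id.
#' @param refs Character vector of reference gene ids (nonempty).
#' @param calibrator Calibrator sample id; default the sample where the
#'   target's Ct is highest (lowest expression), ties broken by sample id.
#' @param efficiency Named per-gene amplification factors (default: the
#'   matrix's `"efficiency"` attribute, else 2.0).
#' @return A `normalization_result`: list with `relative` (named
#'   per-sample fold, calibrator = 1), `nf_log2` (log2 normalization
#'   factor per sample, up to a constant), `target`, `refs`, `calibrator`.
#' @examples
#' ct <- rbind(ref = rep(20, 3), chs = c(25, 23, 24))
#' colnames(ct) <- paste0("s", 1:3)
#' relative_expression(ct, "chs", "ref", calibrator = "s1")$relative
#' @export
relative_expression <- function(ct_matrix, target, refs, calibrator = NULL,
                                efficiency = NULL) {
  if (length(refs) < 1) stop("need >= 1 reference gene")
  genes <- rownames(ct_matrix)
  missing <- setdiff(c(target, refs), genes)
  if (length(missing)) stop("gene not in Ct matrix: ",
                            paste(missing, collapse = ", "))
  eff <- efficiency %||% attr(ct_matrix, "efficiency") %||%
    stats::setNames(rep(2.0, length(genes)), genes)
  eff <- eff[genes]
  if (any(is.na(eff))) stop("efficiency missing for some genes")
  if (any(!is.finite(ct_matrix))) stop("missing Ct")
  # log2 Q_g = -Ct_g * log2(E_g), per-gene constants cancel in the ratio
  lq <- -ct_matrix * log2(eff)
  nf_log2 <- colMeans(lq[refs, , drop = FALSE])
  rel_log2 <- lq[target, ] - nf_log2
  calibrator <- calibrator %||%
    colnames(ct_matrix)[order(-ct_matrix[target, ],
                              colnames(ct_matrix))][1]
  if (!calibrator %in% colnames(ct_matrix))
    stop("calibrator sample not present: ", calibrator)
  rel <- 2 ^ (rel_log2 - rel_log2[[calibrator]])
  structure(list(relative = rel, nf_log2 = nf_log2, target = target,
                 refs = refs, calibrator = calibrator),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> %s vs {%s}, calibrator %s\n",
              x$target, paste(x$refs, collapse = ", "), x$calibrator))
  print(round(x$relative, 4), ...)
  invisible(x)
}

#' Concordance of normalization schemes
#'
#' For each scheme (a set of reference genes), compute the target's
#' relative-expression profile, then the Pearson correlation R between
#' every pair of profiles (on linear folds by default). The column of the
#' designated reference scheme — conventionally the recommended
#' reference-gene pair — is the headline comparison: schemes whose R
#' against it is high normalize the target equivalently.
#'
#' @param ct_matrix Collapsed genes x samples Ct matrix (>= 3 samples).
#' @param target Target gene id.
#' @param schemes Named list of reference-gene sets.
#' @param reference_scheme Name of the scheme used as the standard
#'   (default: the first).
#' @param efficiency Named per-gene amplification factors.
#' @param calibrator Calibrator sample shared by all schemes (default: the
#'   target-Ct-maximum rule of [relative_expression()]).
#' @param log2_folds If `TRUE`, correlate log2 folds instead of linear.
#' @return A `concordance_matrix`: symmetric matrix of Pearson R with
#'   attributes `reference_scheme`, `vs_reference` (the headline column)
#'   and `profiles`.
#' @export
compare_normalizations <- function(ct_matrix, target, schemes,
                                   reference_scheme = names(schemes)[1],
                                   efficiency = NULL, calibrator = NULL,
                                   log2_folds = FALSE) {
  if (length(schemes) < 2) stop("need >= 2 schemes")
  if (is.null(names(schemes)) || anyDuplicated(names(schemes)))
    stop("schemes must be uniquely named")
  if (!reference_scheme %in% names(schemes))
    stop("unknown reference scheme: ", reference_scheme)
  if (ncol(ct_matrix) < 3) stop("need >= 3 samples")
  profiles <- sapply(schemes, function(refs)
    relative_expression(ct_matrix, target, refs, calibrator = calibrator,
                        efficiency = efficiency)$relative)
  if (log2_folds) profiles <- log2(profiles)
  ns <- length(schemes)
  R <- matrix(NA_real_, ns, ns, dimnames = list(names(schemes),
                                                names(schemes)))
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      if (i == j) { R[i, j] <- 1; next }
      if (stats::sd(profiles[, i]) == 0 || stats::sd(profiles[, j]) == 0) {
        R[i, j] <- R[j, i] <- NA_real_  # zero-variance profile: undefined
      } else {
        R[i, j] <- R[j, i] <- stats::cor(profiles[, i], profiles[, j])
      }
    }
  }
  structure(R, reference_scheme = reference_scheme,
            vs_reference = R[, reference_scheme],
            profiles = profiles, class = c("concordance_matrix", "matrix"))
}
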