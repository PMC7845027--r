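#' Pairwise variation between two genes
#'
#' The geNorm building block: the sample standard deviation (n - 1
#' denominator), over samples, of the log2 expression ratio of two genes.
#' Two genes whose ratio is constant across samples — ideal co-stable
#' references — have V = 0. Symmetric in its arguments, and invariant to
#' multiplying either gene by a positive constant (equivalently, shifting
#' all its Ct values).
#'
#' @param q A [quantity_matrix()] (or strictly positive matrix).
#' @param j,k Gene ids or row indices.
#' @return V_jk in log2 units.
#' @export
pairwise_variation <- function(q, j, k) {
  if (ncol(q) < 3) stop("need >= 3 samples")
  stats::sd(log2(q[j, ] / q[k, ]))
}

#' geNorm expression-stability measure M
#'
#' M_j is the mean of gene j's pairwise variations against every other
#' candidate. Low M means the gene's log-ratio to the other candidates is
#' nearly constant, i.e. it varies the way the panel consensus varies.
#'
#' @param q A [quantity_matrix()].
#' @param candidates Gene ids (>= 2); default all genes in `q`.
#' @return Named numeric vector of M values (log2 units).
#' @export
genorm_m <- function(q, candidates = rownames(q)) {
  k <- length(candidates)
  if (k < 2) stop("need >= 2 candidates")
  if (ncol(q) < 3) stop("need >= 3 samples")
  lq <- log2(q[candidates, , drop = FALSE])
  v <- matrix(0, k, k, dimnames = list(candidates, candidates))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      v[a, b] <- v[b, a] <- stats::sd(lq[a, ] - lq[b, ])
    }
  }
  rowSums(v) / (k - 1)
}

#' geNorm iterative stability ranking
#'
#' Starting from the full candidate panel, repeatedly recompute M and drop
#' the least stable gene (highest M; ties broken lexicographically by gene
#' id) until two genes remain. The ranking is the reverse of the removal
#' order; the final two genes cannot be separated by geNorm (each one's M
#' is its pairwise variation to the other, which is symmetric) and are
#' reported tied at ranks 1-2 in lexicographic order.
#'
#' @param q A [quantity_matrix()].
#' @param candidates Gene ids (>= 3); default all genes in `q`.
#' @return A `genorm_result`: list with `ranking` (data.frame gene_id,
#'   rank, m, tied), `exclusion_order`, and `m_steps` (per-step M tables).
#' @export
genorm_rank <- function(q, candidates = rownames(q)) {
  if (length(candidates) < 3) stop("need >= 3 candidates")
  remaining <- candidates
  excluded <- character(0)
  excluded_m <- numeric(0)
  m_steps <- list()
  step <- 1L
  while (length(remaining) > 2) {
    m <- genorm_m(q, remaining)
    m_steps[[step]] <- data.frame(step = step, gene_id = names(m), m = m,
                                  row.names = NULL,
                                  stringsAsFactors = FALSE)
    worst <- names(m)[order(-m, names(m))][1]
    excluded <- c(excluded, worst)
    excluded_m <- c(excluded_m, m[[worst]])
    remaining <- setdiff(remaining, worst)
    step <- step + 1L
  }
  m_final <- genorm_m(q, remaining)
  m_steps[[step]] <- data.frame(step = step, gene_id = names(m_final),
                                m = m_final, row.names = NULL,
                                stringsAsFactors = FALSE)
  final_pair <- sort(remaining)
  ranking <- data.frame(
    gene_id = c(final_pair, rev(excluded)),
    rank = seq_len(length(candidates)),
    m = c(m_final[final_pair], rev(excluded_m)),
    tied = c(TRUE, TRUE, rep(FALSE, length(excluded))),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 exclusion_order = excluded,
                 m_steps = do.call(rbind, m_steps)),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result> ranking:\n")
  print(x$ranking, ...)
  invisible(x)
}

#' Pairwise-variation series and the optimal number of reference genes
#'
#' For n = 2 ... k-1, the normalization factor NF_n is the per-sample
#' geometric mean of the n best-ranked genes' quantities, and
#' V_n is the standard deviation over samples of log2(NF_n / NF_{n+1}).
#' Small V_n means adding the (n+1)-th gene barely changes the
#' normalization factor, so n genes suffice: the optimal number is the
#' smallest n with V_n strictly below the threshold (conventionally 0.15),
#' or k when no V_n clears it.
#'
#' @param q A [quantity_matrix()].
#' @param ranking Character vector of gene ids, best first (e.g. the
#'   `ranking$gene_id` of [genorm_rank()]), or a `genorm_result`.
#' @param threshold Cutoff on V_n (default 0.15, strict inequality).
#' @return A `pv_series` object: list with `series` (data.frame n, v),
#'   `threshold`, `optimal_n`, and `nf_log2` (log2 normalization factors,
#'   one row per n).
#' @export
pv_series <- function(q, ranking, threshold = 0.15) {
  if (inherits(ranking, "genorm_result")) ranking <- ranking$ranking$gene_id
  k <- length(ranking)
  if (k < 3) stop("need >= 3 ranked genes")
  lq <- log2(q[ranking, , drop = FALSE])
  # log2 NF_n = mean of the top-n genes' log2 quantities, per sample
  nf_log2 <- apply(lq, 2, cumsum) / seq_len(k)   # k x samples
  ns <- 2:(k - 1)
  v <- vapply(ns, function(n) stats::sd(nf_log2[n, ] - nf_log2[n + 1, ]),
              numeric(1))
  ok <- ns[v < threshold]
  optimal_n <- if (length(ok)) min(ok) else k
  structure(list(series = data.frame(n = ns, v = v),
                 threshold = threshold, optimal_n = optimal_n,
                 nf_log2 = nf_log2),
            class = "pv_series")
}

#' @export
print.pv_series <- function(x, ...) {
  cat(sprintf("<pv_series> optimal n = %d (threshold %g)\n",
              x$optimal_n, x$threshold))
  print(x$series, ...)
  invisible(x)
}
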