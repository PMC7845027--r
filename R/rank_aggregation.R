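#' Bundle ranked lists for aggregation
#'
#' @param lists List of character vectors, each a total order (permutation)
#'   of the same item universe.
#' @param weights Nonnegative per-list weights (default all 1).
#' @return A `ranked_list_set`.
#' @export
ranked_list_set <- function(lists, weights = rep(1, length(lists))) {
  if (length(lists) < 1) stop("need >= 1 list")
  universe <- sort(lists[[1]])
  for (l in lists) {
    if (!identical(sort(l), universe) || anyDuplicated(l))
      stop("every list must be a permutation of the same universe")
  }
  if (length(weights) != length(lists) || any(weights < 0))
    stop("weights must be nonnegative, one per list")
  structure(list(lists = lists, weights = weights, universe = universe),
            class = "ranked_list_set")
}

#' @export
print.ranked_list_set <- function(x, ...) {
  cat(sprintf("<ranked_list_set> %d lists over %d items\n",
              length(x$lists), length(x$universe)))
  invisible(x)
}

#' Spearman footrule distance between two rankings
#'
#' Sum over items of the absolute difference of their positions.
#'
#' @param a,b Character vectors, permutations of the same universe.
#' @return Nonnegative integer distance.
#' @examples
#' footrule_distance(c("a","b","c","d"), c("d","c","b","a"))  # 8
#' @export
footrule_distance <- function(a, b) {
  if (!identical(sort(a), sort(b)) || anyDuplicated(a))
    stop("item universe mismatch")
  sum(abs(seq_along(a) - match(a, b)))
}

#' Kendall tau distance between two rankings
#'
#' Number of item pairs ordered differently by the two rankings.
#'
#' @inheritParams footrule_distance
#' @return Nonnegative integer distance.
#' @examples
#' kendall_distance(c("a","b","c","d"), c("d","c","b","a"))  # 6
#' @export
kendall_distance <- function(a, b) {
  if (!identical(sort(a), sort(b)) || anyDuplicated(a))
    stop("item universe mismatch")
  pos_b <- match(a, b)
  k <- length(a)
  disc <- 0L
  for (i in seq_len(k - 1)) {
    disc <- disc + sum(pos_b[(i + 1):k] < pos_b[i])
  }
  disc
}

# item x list matrix of 0-based positions, rows ordered by universe
lists_position_matrix <- function(ls) {
  sapply(ls$lists, function(l) match(ls$universe, l) - 1L)
}

rls_phi <- function(ls, perm, distance) {
  d <- if (distance == "footrule") footrule_distance else kendall_distance
  sum(ls$weights * vapply(ls$lists, function(l) as.numeric(d(perm, l)),
                          numeric(1)))
}

new_consensus <- function(ranking, phi, distance, algorithm, seed = NA,
                          iterations = NA, converged = NA) {
  structure(list(ranking = ranking, phi = phi, distance = distance,
                 algorithm = algorithm, seed = seed,
                 iterations = iterations, converged = converged),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("<consensus_ranking> %s/%s, phi = %g\n  %s\n",
              x$algorithm, x$distance, x$phi,
              paste(x$ranking, collapse = " > ")))
  invisible(x)
}

#' Exact consensus ranking by exhaustive enumeration
#'
#' Enumerates all k! candidate permutations and returns the global
#' minimizer of the weighted total distance to the input lists; ties
#' resolve to the lexicographically smallest permutation (in universe
#' order). Intended as the exact oracle for small panels.
#'
#' @param lists A [ranked_list_set()] with universe size k <= 8.
#' @param distance `"footrule"` or `"kendall"`.
#' @return A `consensus_ranking`.
#' @export
aggregate_brute <- function(lists, distance = c("footrule", "kendall")) {
  distance <- match.arg(distance)
  stopifnot(inherits(lists, "ranked_list_set"))
  k <- length(lists$universe)
  if (k > 8) stop("brute force limited to k <= 8 items")
  res <- brute_force_consensus(lists_position_matrix(lists),
                               as.numeric(lists$weights),
                               if (distance == "footrule") 0L else 1L)
  new_consensus(lists$universe[res$perm + 1L], res$phi, distance, "brute")
}

#' Consensus ranking by cross-entropy Monte-Carlo optimization
#'
#' Minimizes the weighted total distance of one permutation to all input
#' lists with the cross-entropy method: a k x k item-position probability
#' matrix starts uniform; each iteration samples `N` permutations position
#' by position (renormalizing over unplaced items), keeps the best
#' `ceiling(rho * N)` by objective, and moves the matrix towards the elite
#' frequencies with smoothing weight `smoothing_w`. Stops when the
#' best-ever objective has not improved for `convergence_window`
#' iterations, or at `max_iter`. Fully reproducible given `seed`.
#'
#' @param lists A [ranked_list_set()].
#' @param distance `"footrule"` or `"kendall"`.
#' @param N Sample size per iteration (default `10 * k^2`).
#' @param rho Elite fraction in (0, 1) (default 0.1).
#' @param smoothing_w Smoothing weight in (0, 1] (default 0.25).
#' @param max_iter Iteration cap (default 1000).
#' @param convergence_window Stop after this many non-improving iterations
#'   (default 15).
#' @param seed Optional integer seed applied via `set.seed()`.
#' @return A `consensus_ranking` with the best permutation found, its
#'   objective `phi`, iteration count and convergence flag.
#' @export
aggregate_ce <- function(lists, distance = c("footrule", "kendall"),
                         N = NULL, rho = 0.1, smoothing_w = 0.25,
                         max_iter = 1000, convergence_window = 15,
                         seed = NULL) {
  distance <- match.arg(distance)
  stopifnot(inherits(lists, "ranked_list_set"))
  k <- length(lists$universe)
  if (k < 2) stop("need >= 2 items")
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  if (smoothing_w <= 0 || smoothing_w > 1)
    stop("smoothing_w must be in (0, 1]")
  if (max_iter < 1 || convergence_window < 1) stop("degenerate params")
  N <- N %||% (10L * k^2)
  if (N < 1) stop("N must be positive")
  if (!is.null(seed)) set.seed(seed)
  res <- ce_consensus(lists_position_matrix(lists),
                      as.numeric(lists$weights),
                      if (distance == "footrule") 0L else 1L,
                      as.integer(N), rho, smoothing_w,
                      as.integer(max_iter), as.integer(convergence_window))
  new_consensus(lists$universe[res$perm + 1L], res$phi, distance, "ce",
                seed = seed %||% NA, iterations = res$iterations,
                converged = res$converged)
}
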