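# Shared fixture builders; everything is generated in code.

random_ct_matrix <- function(n_genes, n_samples, lo = 18, hi = 32) {
  m <- matrix(runif(n_genes * n_samples, lo, hi), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

random_expression_matrix <- function(n_genes = 5, n_samples = 6,
                                     n_experiments = 2) {
  stopifnot(n_samples %% n_experiments == 0)
  m <- matrix(rlnorm(n_genes * n_samples, log(100), 1), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  per <- n_samples / n_experiments
  expression_matrix(m, sprintf("E%d", rep(seq_len(n_experiments),
                                          each = per)))
}

random_permutation_lists <- function(k, n_lists) {
  universe <- sprintf("item%02d", seq_len(k))
  lapply(seq_len(n_lists), function(i) sample(universe))
}

# A small well-formed Ct records data.frame.
toy_ct_records <- function(genes = c("gA", "gB"), samples = c("s1", "s2"),
                           reps = 4, ct = 25) {
  expand.grid(replicate = seq_len(reps), sample_id = samples,
              gene_id = genes, stringsAsFactors = FALSE)[
                c("gene_id", "sample_id", "replicate")] |>
    transform(ct = ct)
}
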