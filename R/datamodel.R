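#' Construct a validated expression matrix
#'
#' An `expression_matrix` couples a gene x sample matrix of FPKM values with
#' a total map from sample to experiment, the unit on which all screening
#' statistics are computed. Every experiment must contribute at least two
#' samples so that within-experiment dispersion is estimable.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. All values must be finite and >= 0.
#' @param experiment Character (or factor) vector naming the experiment of
#'   each sample; either named by sample id or in column order of `values`.
#' @return An object of class `expression_matrix` with elements `values`
#'   and `experiment` (a named character vector, sample -> experiment).
#' @examples
#' m <- matrix(c(100, 110, 90, 95), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' em <- expression_matrix(m, c(s1 = "E1", s2 = "E1", s3 = "E2", s4 = "E2"))
#' @export
expression_matrix <- function(values, experiment) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("non-finite expression values")
  if (any(values < 0)) stop("negative expression")
  experiment <- stats::setNames(as.character(experiment),
                                names(experiment) %||% sample_ids)
  if (!setequal(names(experiment), sample_ids) ||
      length(experiment) != length(sample_ids))
    stop("every sample must map to exactly one experiment")
  experiment <- experiment[sample_ids]
  if (any(is.na(experiment))) stop("sample without experiment assignment")
  if (any(table(experiment) < 2))
    stop("every experiment needs >= 2 samples")
  structure(list(values = values, experiment = experiment),
            class = "expression_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, %d experiments\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$experiment))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Experiment labels of an expression matrix
#' @param x An `expression_matrix`.
#' @return Named character vector, sample id -> experiment label.
#' @export
experiments <- function(x) x$experiment

#' Read a sample sheet
#'
#' CSV with header `sample_id,experiment,cultivar,stage,group,replicate`.
#' Stage labels are kept as an ordered factor in file order of first
#' appearance unless `stage_levels` is given.
#'
#' @param path Path to the CSV file.
#' @param stage_levels Optional character vector declaring the ordered set
#'   of developmental stages (e.g. `c("SG","BG","DG","WT","IT","LT","PR","FR")`).
#' @return A data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, stage_levels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("sample_id", "experiment")
  if (!all(needed %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sheet")
  if ("stage" %in% names(sheet)) {
    lev <- stage_levels %||% unique(sheet$stage)
    if (!all(sheet$stage %in% lev))
      stop("stage label outside the declared ordered set")
    sheet$stage <- factor(sheet$stage, levels = lev, ordered = TRUE)
  }
  if ("replicate" %in% names(sheet)) {
    sheet$replicate <- as.integer(sheet$replicate)
    if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1))
      stop("replicate indices must be positive integers")
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Write a sample sheet
#' @param sheet A `sample_sheet` (or compatible data.frame).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' TSV with header row `gene_id<TAB>sample...`, one gene per row. Samples
#' absent from the sheet are rejected rather than dropped: the sheet is the
#' authority on what an experiment is.
#'
#' @param path Path to the TSV file.
#' @param sheet A `sample_sheet` assigning every sample to an experiment.
#' @return A validated `expression_matrix`.
#' @export
read_expression_matrix <- function(path, sheet) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "gene_id")
    stop("first column must be 'gene_id'")
  gene_ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cell")
  if (any(!is.finite(vals))) stop("non-finite expression cell")
  if (any(vals < 0)) stop("negative expression")
  rownames(vals) <- gene_ids
  missing <- setdiff(colnames(vals), sheet$sample_id)
  if (length(missing))
    stop("sample without experiment assignment: ",
         paste(missing, collapse = ", "))
  expt <- stats::setNames(sheet$experiment, sheet$sample_id)[colnames(vals)]
  expression_matrix(vals, expt)
}

#' Write an FPKM expression matrix
#'
#' Values are serialized with 17 significant digits so that a
#' read-after-write round trip reproduces every double bit-exactly.
#'
#' @param em An `expression_matrix`.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$values),
                   apply(em$values, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a validated Ct (Cq) table
#'
#' Long-format replicated quantification-cycle measurements plus per-gene
#' amplification factors E (fold per cycle; ideal 2.0). The replicate count
#' must be constant over all (gene, sample) cells — ragged designs are a
#' hard error because every downstream statistic assumes complete matrices.
#'
#' @param records data.frame with columns `gene_id`, `sample_id`,
#'   `replicate`, `ct` (cycles, in the open interval (0, 45)).
#' @param efficiency Named numeric vector of amplification factors per gene
#'   (bounds `[1.6, 2.2]`); genes absent from it default to 2.0.
#' @param sample_info Optional `sample_sheet` rows for the samples.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(records, efficiency = NULL, sample_info = NULL) {
  needed <- c("gene_id", "sample_id", "replicate", "ct")
  if (!all(needed %in% names(records)))
    stop("ct records need columns: ", paste(needed, collapse = ", "))
  records <- records[needed]
  records$gene_id <- as.character(records$gene_id)
  records$sample_id <- as.character(records$sample_id)
  if (any(!is.finite(records$ct))) stop("non-finite ct")
  if (any(records$ct <= 0 | records$ct >= 45))
    stop("ct outside (0, 45)")
  counts <- table(records$gene_id, records$sample_id)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    stop("ragged replicates: replicate count must be constant")
  genes <- sort(unique(records$gene_id))
  eff <- stats::setNames(rep(2.0, length(genes)), genes)
  if (!is.null(efficiency)) {
    if (is.null(names(efficiency))) stop("`efficiency` must be named")
    unknown <- setdiff(names(efficiency), genes)
    if (length(unknown))
      stop("efficiency for unknown gene: ", paste(unknown, collapse = ", "))
    eff[names(efficiency)] <- efficiency
  }
  if (any(eff < 1.6 | eff > 2.2)) stop("efficiency outside [1.6, 2.2]")
  structure(list(records = records, efficiency = eff,
                 sample_info = sample_info,
                 replicates = unique(as.vector(counts))),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d genes x %d samples x %d replicates\n",
              length(unique(x$records$gene_id)),
              length(unique(x$records$sample_id)), x$replicates))
  invisible(x)
}

#' Read a Ct table with optional per-gene efficiencies
#'
#' The Ct CSV has header `gene_id,sample_id,replicate,ct`; the efficiency
#' CSV has header `gene_id,efficiency_percent` and is converted with
#' E = 1 + percent/100 (so 100.2 percent -> E = 2.002). Genes without an
#' efficiency entry get the ideal E = 2.0.
#'
#' @param path Path to the Ct CSV.
#' @param efficiencies Optional path to the efficiency CSV.
#' @param sample_info Optional `sample_sheet`.
#' @return A validated `ct_table`.
#' @export
read_ct_table <- function(path, efficiencies = NULL, sample_info = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  eff <- NULL
  if (!is.null(efficiencies)) {
    if (!file.exists(efficiencies)) stop("no such file: ", efficiencies)
    ef <- utils::read.csv(efficiencies, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "efficiency_percent") %in% names(ef)))
      stop("efficiency file needs gene_id,efficiency_percent")
    eff <- stats::setNames(1 + ef$efficiency_percent / 100, ef$gene_id)
  }
  ct_table(rec, efficiency = eff, sample_info = sample_info)
}

#' Write a Ct table (and its efficiencies)
#' @param ct A `ct_table`.
#' @param path Destination CSV path for the Ct records.
#' @param efficiency_path Optional CSV path for per-gene efficiencies,
#'   written as percentages (E = 2.002 -> 100.2).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, efficiency_path = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  rec <- ct$records
  rec$ct <- sprintf("%.17g", rec$ct)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  if (!is.null(efficiency_path)) {
    ef <- data.frame(gene_id = names(ct$efficiency),
                     efficiency_percent =
                       sprintf("%.17g", (ct$efficiency - 1) * 100))
    utils::write.csv(ef, efficiency_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Collapse replicate Ct values to one value per (gene, sample)
#'
#' Biological replicates are collapsed before any stability analysis so
#' that the analysis units are samples, not wells.
#'
#' @param ct A `ct_table`.
#' @param method `"mean"` (default) or `"median"`.
#' @return Numeric matrix of Ct values, genes x samples, with the gene
#'   efficiencies carried in attribute `"efficiency"`.
#' @export
collapse_replicates <- function(ct, method = c("mean", "median")) {
  stopifnot(inherits(ct, "ct_table"))
  method <- match.arg(method)
  f <- if (method == "mean") mean else stats::median
  rec <- ct$records
  genes <- sort(unique(rec$gene_id))
  samples <- sort(unique(rec$sample_id))
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  agg <- stats::aggregate(ct ~ gene_id + sample_id, data = rec, FUN = f)
  m[cbind(agg$gene_id, agg$sample_id)] <- agg$ct
  if (anyNA(m)) stop("missing (gene, sample) cell after collapse")
  attr(m, "efficiency") <- ct$efficiency[genes]
  m
}

#' Convert a collapsed Ct matrix to relative quantities
#'
#' Per gene g, Q = E_g^(Ct_min - Ct), so the sample with the lowest Ct (the
#' most abundant) is the within-gene calibrator with Q = 1 and all
#' quantities are in (0, 1]. This is the linear-scale input convention of
#' the geNorm family of stability statistics.
#'
#' @param ct_matrix Genes x samples Ct matrix (from [collapse_replicates()]).
#' @param efficiency Named per-gene amplification factors; defaults to the
#'   `"efficiency"` attribute of `ct_matrix`, else 2.0.
#' @return A `quantity_matrix`: genes x samples matrix of strictly positive
#'   relative quantities with attribute `provenance = "from-Ct"`.
#' @export
ct_to_quantities <- function(ct_matrix, efficiency = NULL) {
  if (any(!is.finite(ct_matrix))) stop("non-finite Ct")
  eff <- efficiency %||% attr(ct_matrix, "efficiency") %||%
    stats::setNames(rep(2.0, nrow(ct_matrix)), rownames(ct_matrix))
  eff <- eff[rownames(ct_matrix)]
  if (any(is.na(eff))) stop("efficiency missing for some genes")
  q <- eff ^ (apply(ct_matrix, 1, min) - ct_matrix)
  dimnames(q) <- dimnames(ct_matrix)
  quantity_matrix(q, provenance = "from-Ct")
}

#' Construct a quantity matrix
#'
#' Shared strictly-positive input form for all stability estimators; FPKM
#' submatrices and Ct-derived quantities both arrive here.
#'
#' @param values Strictly positive genes x samples matrix.
#' @param provenance `"from-FPKM"` or `"from-Ct"`.
#' @return A `quantity_matrix` (numeric matrix with a provenance attribute).
#' @export
quantity_matrix <- function(values,
                            provenance = c("from-FPKM", "from-Ct")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("quantities must be strictly positive and finite")
  if (provenance == "from-Ct" &&
      any(abs(apply(values, 1, max) - 1) > 1e-9))
    stop("from-Ct quantities must have per-gene max 1")
  structure(values, provenance = provenance,
            class = c("quantity_matrix", class(values)))
}
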