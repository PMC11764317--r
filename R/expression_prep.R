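# Counts -> CPM -> log2(CPM + pseudocount), and assembly of the long
# model table consumed by geneset_anova().

#' Convert raw counts to counts per million
#'
#' `cpm[g, s] = counts[g, s] / sum(counts[, s]) * 1e6` (delegated to
#' \pkg{edgeR}'s `cpm()`, which computes exactly this with default library
#' sizes).  Genes with zero counts in every sample are dropped with a
#' message, since they carry no information for the expression model.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param drop_zero_genes Drop all-zero genes (default `TRUE`).
#' @return CPM matrix with attribute `stage = "cpm"`.
#' @export
counts_to_cpm <- function(counts, drop_zero_genes = TRUE) {
  if (any(counts < 0)) stop("negative raw counts")
  if (!is.null(attr(counts, "stage")) && attr(counts, "stage") != "counts")
    stop("input is not at the raw-count stage")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  if (drop_zero_genes) {
    zero <- rowSums(counts) == 0
    if (any(zero)) {
      message("dropping ", sum(zero), " gene(s) with zero counts in all samples")
      counts <- counts[!zero, , drop = FALSE]
    }
  }
  out <- edgeR::cpm(counts)
  attr(out, "stage") <- "cpm"
  out
}

#' Log2-transform a CPM matrix
#'
#' `log2(CPM + pseudocount)`.  The pseudocount makes zeros finite and is
#' deliberately explicit (default 1, i.e. log2(CPM + 1)).
#'
#' @param m CPM matrix from [counts_to_cpm()].
#' @param pseudocount Positive offset added before the log.
#' @return Matrix with attribute `stage = "log2cpm"`.
#' @export
log2_cpm <- function(m, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  stage <- attr(m, "stage")
  if (!is.null(stage) && stage != "cpm")
    stop("input is not at the CPM stage (stage = ", stage, ")")
  out <- log2(m + pseudocount)
  attr(out, "stage") <- "log2cpm"
  out
}

#' Build the long model table for the gene-set ANOVA
#'
#' Restricts a log2 CPM matrix to one gene set and to the tumour-tissue
#' samples of one subtype plus all healthy-skin samples, and returns the
#' long-format table the model consumes: one row per (sample, gene) with
#' the response `y` (log2 CPM), `tissue` (0 = healthy skin, 1 = tumour),
#' `mut` (1 when the sample's patient carries an associated DEL in
#' `target_gene`; healthy controls are independent patients and always 0)
#' and, when `exposure_threshold` is given, `as_high` (1 when the patient's
#' UACR exceeds the threshold; controls use their own UACR).
#'
#' @param log2cpm Matrix from [log2_cpm()], columns named by tissue
#'   `sample_id`.
#' @param gene_set Character vector of gene symbols; symbols absent from the
#'   matrix are dropped with a warning.
#' @param manifest Validated manifest.
#' @param subtype `"BCC"` or `"SCC"`.
#' @param del_matrix `gene_del_matrix` from [gene_del_status()].
#' @param target_gene Gene whose DEL carrier status defines `mut`.
#' @param exposure_threshold Optional UACR cut (ug/g); low stratum is
#'   `uacr <= threshold`, high is `uacr > threshold`.
#' @return data.frame with columns `sample_id`, `patient_id`, `gene`, `y`,
#'   `tissue`, `mut` and optionally `as_high`.
#' @export
build_model_table <- function(log2cpm, gene_set, manifest, subtype,
                              del_matrix, target_gene,
                              exposure_threshold = NULL) {
  stage <- attr(log2cpm, "stage")
  if (!is.null(stage) && stage != "log2cpm")
    stop("expression matrix is not at the log2cpm stage")
  subtype <- match.arg(subtype, c("BCC", "SCC"))
  manifest <- read_manifest(manifest)
  genes <- intersect(gene_set, rownames(log2cpm))
  if (length(genes) == 0L)
    stop("no gene of the set is present in the expression matrix")
  n_missing <- length(setdiff(gene_set, genes))
  if (n_missing > 0L)
    warning(n_missing, " gene(s) of the set absent from the matrix; dropped")

  tissue <- manifest[manifest$material == "tissue", ]
  keep <- tissue[tissue$tissue_class == "healthy_skin" |
                 (tissue$tissue_class == "tumor" &
                  tissue$tumor_subtype == subtype), , drop = FALSE]
  keep <- keep[keep$sample_id %in% colnames(log2cpm), , drop = FALSE]
  if (!any(keep$tissue_class == "tumor") ||
      !any(keep$tissue_class == "healthy_skin"))
    stop("both tumour and healthy-skin samples are required")

  if (!target_gene %in% colnames(del_matrix$status))
    mut_carriers <- character()
  else
    mut_carriers <- rownames(del_matrix$status)[
      del_matrix$status[, target_gene]]

  n_s <- nrow(keep); n_g <- length(genes)
  out <- data.frame(
    sample_id = rep(keep$sample_id, each = n_g),
    patient_id = rep(keep$patient_id, each = n_g),
    gene = rep(genes, times = n_s),
    y = as.vector(log2cpm[genes, keep$sample_id]),
    tissue = rep(as.integer(keep$tissue_class == "tumor"), each = n_g),
    mut = rep(as.integer(keep$tissue_class == "tumor" &
                         keep$patient_id %in% mut_carriers), each = n_g),
    stringsAsFactors = FALSE)
  if (!is.null(exposure_threshold))
    out$as_high <- rep(as.integer(keep$uacr > exposure_threshold),
                       each = n_g)
  out
}
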