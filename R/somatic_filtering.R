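# Germline subtraction and QC filtering of per-sample variant calls.

#' Quality-control thresholds for somatic calls
#'
#' Defaults follow the low-frequency variant detection settings used for the
#' targeted amplicon panel: minimum coverage 10 reads, minimum variant read
#' count 2, minimum variant allele frequency 2 percent, and a minimum average
#' call quality of Q60.  All boundaries are inclusive ("minimum x" means
#' `>= x`).
#'
#' @param min_coverage,min_count,min_frequency,min_quality Non-negative
#'   thresholds.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_coverage = 10, min_count = 2,
                          min_frequency = 2, min_quality = 60) {
  vals <- c(min_coverage, min_count, min_frequency, min_quality)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all QC thresholds must be finite and non-negative")
  structure(list(min_coverage = min_coverage, min_count = min_count,
                 min_frequency = min_frequency, min_quality = min_quality),
            class = "qc_thresholds")
}

# Identity key of a variant: exact coordinate + alleles, the unit of all
# set algebra downstream.
variant_key <- function(calls) {
  paste(calls$chrom, calls$start, calls$end, calls$ref_allele,
        calls$alt_allele, sep = "|")
}

#' Subtract matched-blood (germline) calls from tissue calls
#'
#' A tissue call is somatic when its identity key (chrom, start, end,
#' ref_allele, alt_allele) does not occur among the same patient's blood
#' calls.  Matching is on exact identity, not positional overlap.  Input
#' order is preserved.
#'
#' @param tissue_calls,blood_calls Variant-call data.frames for one patient's
#'   tissue and blood samples.
#' @param check_patient When both tables carry a `patient_id` column, require
#'   it to agree.
#' @return The somatic subset of `tissue_calls`.
#' @export
subtract_germline <- function(tissue_calls, blood_calls,
                              check_patient = TRUE) {
  if (check_patient && "patient_id" %in% names(tissue_calls) &&
      "patient_id" %in% names(blood_calls) &&
      nrow(tissue_calls) > 0L && nrow(blood_calls) > 0L) {
    pt <- unique(c(tissue_calls$patient_id, blood_calls$patient_id))
    if (length(pt) > 1L)
      stop("tissue and blood calls belong to different patients: ",
           paste(pt, collapse = ", "))
  }
  if (nrow(blood_calls) == 0L) return(tissue_calls)
  keep <- !(variant_key(tissue_calls) %in% variant_key(blood_calls))
  tissue_calls[keep, , drop = FALSE]
}

#' Apply QC thresholds to variant calls
#'
#' Keeps calls with `coverage >= min_coverage`, `alt_count >= min_count`,
#' `frequency >= min_frequency` and `avg_quality >= min_quality`.
#'
#' @param calls Variant-call data.frame.
#' @param thresholds [qc_thresholds()] object.
#' @return Filtered data.frame (possibly empty).
#' @export
apply_qc <- function(calls, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  keep <- calls$coverage >= thresholds$min_coverage &
    calls$alt_count >= thresholds$min_count &
    calls$frequency >= thresholds$min_frequency &
    calls$avg_quality >= thresholds$min_quality
  calls[keep, , drop = FALSE]
}

#' Select calls of one variant type
#'
#' @param calls Variant-call data.frame.
#' @param var_type One of `"SNV"`, `"INS"`, `"DEL"`, `"MNV"`.
#' @return Calls of the requested type, input order preserved.
#' @export
select_by_type <- function(calls, var_type) {
  var_type <- match.arg(var_type, VAR_TYPES)
  calls[calls$var_type == var_type, , drop = FALSE]
}

#' Remove calls matching an exclusion key list
#'
#' Optional stand-in for public-database germline filtering: drops calls
#' whose identity key occurs in a user-supplied exclusion table (columns
#' `chrom`, `start`, `end`, `ref_allele`, `alt_allele`).
#'
#' @param calls Variant-call data.frame.
#' @param exclude data.frame of identity keys, or `NULL` (no-op).
#' @return Filtered data.frame.
#' @export
exclude_keys <- function(calls, exclude = NULL) {
  if (is.null(exclude) || nrow(exclude) == 0L) return(calls)
  calls[!(variant_key(calls) %in% variant_key(exclude)), , drop = FALSE]
}

#' Derive per-patient somatic calls for a whole cohort
#'
#' Convenience wrapper: for every tissue sample in the manifest, subtracts
#' the matched blood sample's calls and applies QC.
#'
#' @param calls Long variant-call table covering all samples (tissue and
#'   blood), with `sample_id` matching the manifest.
#' @param manifest Validated manifest (see [read_manifest()]).
#' @param thresholds [qc_thresholds()].
#' @param exclude Optional exclusion key table (see [exclude_keys()]).
#' @return Long data.frame of somatic calls with a `patient_id` column added.
#' @export
somatic_calls <- function(calls, manifest, thresholds = qc_thresholds(),
                          exclude = NULL) {
  manifest <- read_manifest(manifest)
  tissue <- manifest[manifest$material == "tissue", ]
  out <- vector("list", nrow(tissue))
  for (i in seq_len(nrow(tissue))) {
    blood_id <- manifest$sample_id[manifest$material == "blood" &
                                   manifest$patient_id == tissue$patient_id[i]]
    tc <- calls[calls$sample_id == tissue$sample_id[i], , drop = FALSE]
    bc <- calls[calls$sample_id %in% blood_id, , drop = FALSE]
    som <- subtract_germline(tc, bc, check_patient = FALSE)
    som <- apply_qc(som, thresholds)
    som <- exclude_keys(som, exclude)
    if (nrow(som) > 0L) som$patient_id <- tissue$patient_id[i]
    out[[i]] <- som
  }
  out <- out[vapply(out, nrow, integer(1L)) > 0L]
  if (length(out) == 0L) {
    res <- empty_variant_table(); res$patient_id <- character()
    return(res)
  }
  do.call(rbind, out)
}
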