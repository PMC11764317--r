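# Shared in-code fixtures: tiny call tables, manifests and references used
# across the module tests.  Everything is built programmatically.

# One variant-call row with sensible QC defaults.
make_call <- function(sample_id, chrom, start, end, var_type, ref, alt,
                      coverage = 100L, alt_count = 10L,
                      frequency = 100 * alt_count / coverage,
                      avg_quality = 80) {
  data.frame(sample_id = sample_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), var_type = var_type, ref_allele = ref,
             alt_allele = alt, coverage = as.integer(coverage),
             alt_count = as.integer(alt_count), frequency = frequency,
             avg_quality = avg_quality, stringsAsFactors = FALSE)
}

# Single-base deletion call.
make_del <- function(sample_id, chrom, start, base, ...) {
  make_call(sample_id, chrom, start, start, "DEL", base, "-", ...)
}

# Minimal valid manifest: tumour patients (with matched blood) + controls.
make_manifest <- function(n_bcc = 3L, n_scc = 0L, n_healthy = 2L,
                          uacr = NULL) {
  patients <- c(sprintf("P%02d", seq_len(n_bcc + n_scc)),
                sprintf("C%02d", seq_len(n_healthy)))
  subtype <- c(rep("BCC", n_bcc), rep("SCC", n_scc), rep("none", n_healthy))
  tclass <- c(rep("tumor", n_bcc + n_scc), rep("healthy_skin", n_healthy))
  if (is.null(uacr)) uacr <- rep(100, length(patients))
  rbind(
    data.frame(patient_id = patients, sample_id = paste0(patients, "_T"),
               material = "tissue", tissue_class = tclass,
               tumor_subtype = subtype, uacr = uacr,
               stringsAsFactors = FALSE),
    data.frame(patient_id = patients, sample_id = paste0(patients, "_B"),
               material = "blood", tissue_class = "none",
               tumor_subtype = "none", uacr = uacr,
               stringsAsFactors = FALSE))
}

# Event table (del_events() shape) from (patient, chrom, start, seq) rows.
make_events <- function(patient, chrom, start, seq) {
  df <- data.frame(patient_id = patient, chrom = chrom,
                   start = as.integer(start),
                   end = as.integer(start) + nchar(seq) - 1L,
                   deleted_seq = seq, stringsAsFactors = FALSE)
  df$key <- del_key(df)
  df
}

# DNAStringSet from a plain string.
make_reference <- function(seq, chrom = "chr1") {
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- chrom
  ref
}
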