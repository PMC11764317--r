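# Partition somatic deletions into tumour-only / shared / healthy-only
# classes by unique genomic coordinate and by gene; derive subtype-associated
# DELs and the patient x gene carrier matrix.

#' Deletion identity keys
#'
#' A deletion's identity is its full coordinate plus the deleted sequence
#' (`chrom|start|end|deleted_seq`), so a 1-base and a 3-base deletion
#' starting at the same position are distinct coordinates.  Keys sort
#' deterministically: chromosome lexicographic, then start, end, sequence.
#'
#' @param dels data.frame with `chrom`, `start`, `end` and either
#'   `deleted_seq` or `ref_allele` columns.
#' @return Character vector of keys, one per row.
#' @export
del_key <- function(dels) {
  seqs <- if ("deleted_seq" %in% names(dels)) dels$deleted_seq else
    dels$ref_allele
  paste(dels$chrom, dels$start, dels$end, toupper(seqs), sep = "|")
}

# Split keys back into a data.frame, in deterministic key order.
del_key_table <- function(keys) {
  keys <- unique(keys)
  if (length(keys) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), deleted_seq = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1L], start = as.integer(parts[, 2L]),
                   end = as.integer(parts[, 3L]), deleted_seq = parts[, 4L],
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start, df$end, df$deleted_seq, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

sort_keys <- function(keys) {
  df <- del_key_table(keys)
  del_key(df)
}

#' Extract (patient, DEL) events from somatic calls
#'
#' @param calls Somatic variant-call data.frame with a `patient_id` column
#'   (e.g. from [somatic_calls()]); non-DEL rows are dropped.
#' @return data.frame with `patient_id`, `chrom`, `start`, `end`,
#'   `deleted_seq` and `key` columns, one row per event.
#' @export
del_events <- function(calls) {
  dels <- calls[calls$var_type == "DEL", , drop = FALSE]
  out <- data.frame(patient_id = dels$patient_id, chrom = dels$chrom,
                    start = dels$start, end = dels$end,
                    deleted_seq = toupper(dels$ref_allele),
                    stringsAsFactors = FALSE)
  out$key <- del_key(out)
  rownames(out) <- NULL
  out
}

#' Partition DELs by unique genomic coordinate
#'
#' Classifies the unique deletion coordinates observed in tumour and healthy
#' skin into `tumor_only`, `shared` and `healthy_only` sets, and tallies the
#' patient-level events (one per (patient, coordinate) occurrence in the
#' input) falling in each class.
#'
#' @param tumor_dels,healthy_dels Event tables from [del_events()].
#' @return List of class `del_partition` with character-vector elements
#'   `tumor_only`, `shared`, `healthy_only` (sorted keys) and an integer
#'   vector `event_counts` named by class.
#' @export
partition_by_coordinate <- function(tumor_dels, healthy_dels) {
  tk <- unique(tumor_dels$key)
  hk <- unique(healthy_dels$key)
  shared <- intersect(tk, hk)
  part <- list(
    tumor_only = sort_keys(setdiff(tk, hk)),
    shared = sort_keys(shared),
    healthy_only = sort_keys(setdiff(hk, tk)))
  part$event_counts <- c(
    tumor_only = sum(tumor_dels$key %in% part$tumor_only),
    shared = sum(tumor_dels$key %in% part$shared) +
      sum(healthy_dels$key %in% part$shared),
    healthy_only = sum(healthy_dels$key %in% part$healthy_only))
  class(part) <- "del_partition"
  part
}

#' @export
print.del_partition <- function(x, ...) {
  cat("DEL partition by unique genomic coordinate\n")
  cat(sprintf("  tumor-only   : %5d coordinates, %5d events\n",
              length(x$tumor_only), x$event_counts[["tumor_only"]]))
  cat(sprintf("  shared       : %5d coordinates, %5d events\n",
              length(x$shared), x$event_counts[["shared"]]))
  cat(sprintf("  healthy-only : %5d coordinates, %5d events\n",
              length(x$healthy_only), x$event_counts[["healthy_only"]]))
  invisible(x)
}

#' Map deletion keys to gene symbols
#'
#' A deletion maps to the gene whose interval contains its start coordinate.
#'
#' @param keys Character vector of deletion keys.
#' @param gene_map `GRanges` with a `gene` column (see [read_gene_map()]).
#' @return Named character vector: key -> gene symbol.
#' @export
map_dels_to_genes <- function(keys, gene_map) {
  df <- del_key_table(keys)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$start))
  hits <- IRanges::findOverlaps(gr, gene_map, select = "first")
  if (anyNA(hits)) {
    bad <- del_key(df[is.na(hits), , drop = FALSE])
    stop("deletion key(s) not covered by the gene map: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  }
  stats::setNames(gene_map$gene[hits], del_key(df))
}

#' Partition mutated genes by tissue class
#'
#' Classifies genes (rather than coordinates) as mutated only in tumour, in
#' both tissue classes, or only in healthy skin.  A gene with one DEL in
#' tumour and a different DEL in healthy skin is classed `both`.
#'
#' @param tumor_dels,healthy_dels Event tables from [del_events()].
#' @param gene_map `GRanges` gene map.
#' @return List with sorted character vectors `tumor_only`, `both`,
#'   `healthy_only`.
#' @export
partition_by_gene <- function(tumor_dels, healthy_dels, gene_map) {
  all_keys <- unique(c(tumor_dels$key, healthy_dels$key))
  gene_of <- map_dels_to_genes(all_keys, gene_map)
  tg <- unique(gene_of[unique(tumor_dels$key)])
  hg <- unique(gene_of[unique(healthy_dels$key)])
  list(tumor_only = sort(setdiff(tg, hg)),
       both = sort(intersect(tg, hg)),
       healthy_only = sort(setdiff(hg, tg)))
}

#' Subtype-associated deletions
#'
#' Deletion coordinates observed in at least one tumour patient of the given
#' subtype and in no healthy-skin sample.
#'
#' @param tumor_dels Event table from [del_events()] for tumour samples.
#' @param manifest Validated manifest giving each tumour patient's subtype.
#' @param subtype `"BCC"` or `"SCC"`.
#' @param healthy_dels Event table for healthy-skin samples.
#' @return Sorted character vector of deletion keys.
#' @export
subtype_associated_dels <- function(tumor_dels, manifest, subtype,
                                    healthy_dels) {
  subtype <- match.arg(subtype, c("BCC", "SCC"))
  manifest <- read_manifest(manifest)
  sub_patients <- unique(manifest$patient_id[
    manifest$material == "tissue" & manifest$tumor_subtype == subtype])
  keys <- unique(tumor_dels$key[tumor_dels$patient_id %in% sub_patients])
  sort_keys(setdiff(keys, unique(healthy_dels$key)))
}

#' Patient-by-gene DEL carrier matrix
#'
#' For the patients of one tumour subtype, marks a patient as carrying a DEL
#' in a gene when they have at least one subtype-associated deletion mapped
#' to that gene.  Carrying several distinct deletions in the same gene still
#' counts once.
#'
#' @param associated_dels Keys from [subtype_associated_dels()].
#' @param tumor_dels Event table from [del_events()].
#' @param gene_map `GRanges` gene map.
#' @param manifest Validated manifest.
#' @param subtype `"BCC"` or `"SCC"`.
#' @return List of class `gene_del_matrix`: logical `status` matrix
#'   (patients x genes) and numeric `carrier_freq` per gene.
#' @export
gene_del_status <- function(associated_dels, tumor_dels, gene_map, manifest,
                            subtype) {
  subtype <- match.arg(subtype, c("BCC", "SCC"))
  manifest <- read_manifest(manifest)
  patients <- sort(unique(manifest$patient_id[
    manifest$material == "tissue" & manifest$tumor_subtype == subtype]))
  ev <- tumor_dels[tumor_dels$key %in% associated_dels &
                   tumor_dels$patient_id %in% patients, , drop = FALSE]
  genes <- if (nrow(ev) > 0L) {
    gene_of <- map_dels_to_genes(unique(ev$key), gene_map)
    sort(unique(gene_of))
  } else character()
  status <- matrix(FALSE, nrow = length(patients), ncol = length(genes),
                   dimnames = list(patients, genes))
  if (nrow(ev) > 0L) {
    gene_of <- map_dels_to_genes(unique(ev$key), gene_map)
    for (i in seq_len(nrow(ev)))
      status[ev$patient_id[i], gene_of[[ev$key[i]]]] <- TRUE
  }
  structure(list(status = status,
                 carrier_freq = colMeans(status),
                 subtype = subtype),
            class = "gene_del_matrix")
}

#' @export
print.gene_del_matrix <- function(x, ...) {
  cat(sprintf("gene_del_matrix: %d %s patients x %d genes\n",
              nrow(x$status), x$subtype, ncol(x$status)))
  if (ncol(x$status) > 0L) {
    top <- sort(x$carrier_freq, decreasing = TRUE)
    top <- utils::head(top, 5L)
    cat("  top carrier frequencies:",
        paste(sprintf("%s %.2f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Top recurrently deleted genes
#'
#' Genes ranked by carrier count (number of patients with at least one
#' associated DEL in the gene), descending, ties broken alphabetically.
#'
#' @param matrix A `gene_del_matrix`.
#' @param k Number of genes to return.
#' @return Character vector of up to `k` gene symbols.
#' @export
top_genes <- function(matrix, k) {
  stopifnot(inherits(matrix, "gene_del_matrix"), k >= 1)
  counts <- colSums(matrix$status)
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    warning("no gene has any carrier; empty ranking")
    return(character())
  }
  ord <- order(-counts, names(counts), method = "radix")
  ranked <- names(counts)[ord]
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds the ", length(ranked),
            " genes with carriers; returning all")
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}
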