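# End-to-end orchestration: somatic filtering -> DEL classification ->
# homopolymer annotation -> expression prep -> gene-set screen ->
# co-occurrence, from one configuration, returning a run report of
# per-stage counts.

#' Pipeline configuration
#'
#' Collects inputs and tuning parameters for [run_del_pipeline()].  Defaults
#' equal the study's stated values: QC thresholds coverage 10 / count 2 /
#' frequency 2% / Q60, homopolymer minimum run 3, UACR exposure threshold
#' 192 ug/g, pseudocount 1, target genes APC, MLH1, MTR, DST, MSH6.
#'
#' @param calls Long variant-call table (or path to a variant TSV).
#' @param manifest Manifest data.frame or path.
#' @param reference `DNAStringSet` or FASTA path.
#' @param gene_map `GRanges`, BED-like path, or 1-based data.frame.
#' @param counts Count matrix or TSV path.
#' @param gene_sets Named list of gene sets or GMT path.
#' @param subtype Tumour subtype analysed.
#' @param target_genes Genes whose DEL carrier status is modelled; the first
#'   with at least one carrier drives the exposure screen.
#' @param snv_gene Gene whose somatic ns-SNV status enters the
#'   co-occurrence test.
#' @param thresholds [qc_thresholds()].
#' @param min_run Homopolymer minimum run length.
#' @param exposure_threshold UACR cut (ug/g); `NULL` disables the
#'   gene-environment model.
#' @param pseudocount log2 CPM offset.
#' @param exclude Optional germline exclusion key table.
#' @param output_dir Optional directory; when given, stage tables are
#'   written there as TSV and the configuration is serialized alongside.
#' @return List of class `del_pipeline_config`.
#' @export
pipeline_config <- function(calls, manifest, reference, gene_map, counts,
                            gene_sets, subtype = "BCC",
                            target_genes = c("APC", "MLH1", "MTR", "DST",
                                             "MSH6"),
                            snv_gene = "PTCH1",
                            thresholds = qc_thresholds(), min_run = 3L,
                            exposure_threshold = 192, pseudocount = 1,
                            exclude = NULL, output_dir = NULL) {
  cfg <- list(calls = calls, manifest = manifest, reference = reference,
              gene_map = gene_map, counts = counts, gene_sets = gene_sets,
              subtype = subtype, target_genes = target_genes,
              snv_gene = snv_gene, thresholds = thresholds,
              min_run = min_run, exposure_threshold = exposure_threshold,
              pseudocount = pseudocount, exclude = exclude,
              output_dir = output_dir)
  class(cfg) <- "del_pipeline_config"
  cfg
}

#' Configuration from a synthetic cohort
#'
#' @param cohort `synthetic_cohort` from [generate_cohort()].
#' @param ... Overrides passed to [pipeline_config()].
#' @return `del_pipeline_config`.
#' @export
pipeline_config_from_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  defaults <- list(calls = cohort$calls, manifest = cohort$manifest,
                   reference = cohort$reference, gene_map = cohort$gene_map,
                   counts = cohort$counts, gene_sets = cohort$gene_sets,
                   target_genes = cohort$truth$target_gene,
                   snv_gene = cohort$truth$snv_gene,
                   exposure_threshold = cohort$truth$exposure_threshold)
  do.call(pipeline_config, utils::modifyList(defaults, list(...)))
}

load_input <- function(x, reader) if (is.character(x) && length(x) == 1L)
  reader(x) else x

#' Run the full DEL pipeline
#'
#' Executes every stage in order and returns a run report: somatic filtering
#' (germline subtraction + QC), DEL selection, coordinate and gene
#' partitions, subtype-associated DELs, the patient x gene carrier matrix,
#' homopolymer annotation and summary, CPM/log2 expression prep, the
#' gene-set interaction screen for each target gene with at least one
#' carrier, and the co-occurrence test between the first target gene's DEL
#' status and the configured ns-SNV gene.  Stages are pure functions of the
#' inputs, so repeated runs on the same configuration are identical.
#'
#' @param config `del_pipeline_config`.
#' @return List of class `del_pipeline_report`; see elements `partition`,
#'   `gene_partition`, `str_summary`, `screen` (one data.frame per target
#'   gene), `cooccurrence`, and `counts` (per-stage record counts).
#' @export
run_del_pipeline <- function(config) {
  stopifnot(inherits(config, "del_pipeline_config"))
  calls <- load_input(config$calls, function(p)
    read_variant_table(p, "tsv"))
  manifest <- read_manifest(load_input(config$manifest, read.delim))
  reference <- load_input(config$reference, Biostrings::readDNAStringSet)
  gene_map <- if (inherits(config$gene_map, "GRanges")) config$gene_map
  else read_gene_map(config$gene_map)
  counts <- load_input(config$counts, read_counts_matrix)
  gene_sets <- load_input(config$gene_sets, read_gmt)

  unknown <- setdiff(config$target_genes, gene_map$gene)
  if (length(unknown) > 0L)
    stop("target gene(s) absent from the gene map: ",
         paste(unknown, collapse = ", "))

  ## stage 1: somatic filtering
  som <- somatic_calls(calls, manifest, config$thresholds, config$exclude)

  ## stage 2: DEL classification
  tissue_class_of <- stats::setNames(manifest$tissue_class,
                                     manifest$sample_id)
  som_dels <- select_by_type(som, "DEL")
  tumor_ev <- del_events(som_dels[
    tissue_class_of[som_dels$sample_id] == "tumor", , drop = FALSE])
  healthy_ev <- del_events(som_dels[
    tissue_class_of[som_dels$sample_id] == "healthy_skin", , drop = FALSE])
  part <- partition_by_coordinate(tumor_ev, healthy_ev)
  gene_part <- partition_by_gene(tumor_ev, healthy_ev, gene_map)
  assoc <- subtype_associated_dels(tumor_ev, manifest, config$subtype,
                                   healthy_ev)
  del_matrix <- gene_del_status(assoc, tumor_ev, gene_map, manifest,
                                config$subtype)

  ## stage 3: homopolymer context of subtype-associated DELs
  assoc_ev <- tumor_ev[tumor_ev$key %in% assoc, , drop = FALSE]
  annotations <- homopolymer_context(reference, assoc, config$min_run)
  str_summary <- summarize_str(annotations, assoc_ev)

  ## stage 4: expression prep
  log2cpm <- log2_cpm(counts_to_cpm(counts), config$pseudocount)

  ## stage 5: gene-set interaction screen per target gene with carriers
  screens <- list()
  for (g in config$target_genes) {
    has_carrier <- g %in% colnames(del_matrix$status) &&
      any(del_matrix$status[, g])
    if (!has_carrier) next
    screens[[g]] <- run_pathway_screen(
      log2cpm, gene_sets, manifest, config$subtype, del_matrix, g,
      exposure_threshold = config$exposure_threshold)
  }
  if (length(screens) == 0L)
    warning("no target gene has any DEL carrier; screen skipped")

  ## stage 6: co-occurrence of first target gene's DELs vs ns-SNV status
  cooc <- NULL
  first_target <- config$target_genes[1L]
  if (first_target %in% colnames(del_matrix$status)) {
    patients <- rownames(del_matrix$status)
    del_status <- stats::setNames(del_matrix$status[, first_target],
                                  patients)
    snv_status <- snv_carrier_status(som, manifest, config$snv_gene,
                                     gene_map, patients)
    cooc <- cooccurrence_test(del_status, snv_status)
  }

  report <- list(
    partition = part, gene_partition = gene_part,
    associated_dels = assoc, del_matrix = del_matrix,
    annotations = annotations, str_summary = str_summary,
    screen = screens, cooccurrence = cooc,
    counts = c(input_calls = nrow(calls), somatic_calls = nrow(som),
               somatic_dels = nrow(som_dels),
               tumor_events = nrow(tumor_ev),
               healthy_events = nrow(healthy_ev),
               associated_coords = length(assoc),
               gene_sets_tested = length(gene_sets),
               bonferroni_m = length(gene_sets)),
    config = config)
  class(report) <- "del_pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# Patient-level carrier status of somatic ns-SNVs in one gene.
snv_carrier_status <- function(som, manifest, gene, gene_map, patients) {
  snvs <- select_by_type(som, "SNV")
  tissue_class_of <- stats::setNames(manifest$tissue_class,
                                     manifest$sample_id)
  snvs <- snvs[tissue_class_of[snvs$sample_id] == "tumor", , drop = FALSE]
  if (nrow(snvs) == 0L)
    return(stats::setNames(rep(FALSE, length(patients)), patients))
  gr <- GenomicRanges::GRanges(snvs$chrom,
                               IRanges::IRanges(snvs$start, snvs$start))
  hit <- IRanges::findOverlaps(gr, gene_map, select = "first")
  in_gene <- !is.na(hit) & gene_map$gene[ifelse(is.na(hit), 1L, hit)] == gene
  carriers <- unique(snvs$patient_id[in_gene])
  stats::setNames(patients %in% carriers, patients)
}

#' @export
print.del_pipeline_report <- function(x, ...) {
  cat("DEL pipeline report\n")
  cat("  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-18s %d\n", nm, x$counts[[nm]]))
  print(x$partition)
  cat(sprintf("  homopolymer: %d/%d events, %d/%d coordinates\n",
              x$str_summary$n_events_homopolymer, x$str_summary$n_events,
              x$str_summary$n_coords_homopolymer, x$str_summary$n_coords))
  for (g in names(x$screen)) {
    sig <- sum(x$screen[[g]]$bonferroni_p < 0.05)
    cat(sprintf("  screen[%s]: %d/%d sets Bonferroni-significant\n",
                g, sig, nrow(x$screen[[g]])))
  }
  if (!is.null(x$cooccurrence))
    cat(sprintf("  co-occurrence: OR = %.3g, p = %.4g\n",
                x$cooccurrence$odds_ratio, x$cooccurrence$p_two_sided))
  invisible(x)
}

# Persist the stage tables as TSVs.
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  part <- report$partition
  part_df <- do.call(rbind, lapply(c("tumor_only", "shared", "healthy_only"),
    function(cl) if (length(part[[cl]]) > 0L)
      cbind(del_key_table(part[[cl]]), class = cl)))
  write.table(part_df, file.path(dir, "partition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$annotations, file.path(dir, "str_annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  status <- report$del_matrix$status
  write.table(data.frame(patient_id = rownames(status), status,
                         check.names = FALSE),
              file.path(dir, "gene_del_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in names(report$screen))
    write.table(report$screen[[g]],
                file.path(dir, paste0("screen_", g, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$cooccurrence))
    jsonlite::write_json(
      list(table = report$cooccurrence$table,
           odds_ratio = report$cooccurrence$odds_ratio,
           p_two_sided = report$cooccurrence$p_two_sided),
      file.path(dir, "cooccurrence.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
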