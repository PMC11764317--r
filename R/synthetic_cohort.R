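# Synthetic-cohort generator: a full desk-scale study -- reference sequence
# with embedded homopolymer tracts, matched tissue/blood variant tables with
# shared germline calls and QC-failing decoys, somatic DELs enriched in
# tracts, a gene-count matrix whose gene-set shifts depend on DEL carrier
# status and arsenic stratum -- with the complete ground truth recorded so
# every downstream stage can be verified against what was planted.

#' Inverse of the signed fold-change convention
#'
#' Maps a signed fold change back to a log2 difference: `log2(fc)` for
#' `fc >= 1`, `-log2(-fc)` for `fc <= -1` (values in (-1, 1) do not occur
#' under the convention; `fc = 1` maps to 0).
#'
#' @param fc Signed fold changes (|fc| >= 1).
#' @return log2 differences.
#' @export
inverse_signed_fc <- function(fc) {
  if (any(abs(fc) < 1))
    stop("signed fold changes have |fc| >= 1 by convention")
  d <- numeric(length(fc))
  up <- fc >= 1
  d[up] <- log2(fc[up])
  d[!up] <- -log2(-fc[!up])
  names(d) <- names(fc)
  d
}

#' Ground-truth parameters of a synthetic cohort
#'
#' Defaults reproduce the study conditions of the motivating cohort: 26 BCC
#' and 6 SCC cases plus 16 independent healthy-skin controls, each with a
#' matched blood sample; urinary arsenic-creatinine ratio (UACR) log-normal
#' with population median 192 ug/g (so the dichotomization threshold is the
#' median by construction); 65% of somatic DEL coordinates inside
#' homopolymer tracts of run length 3-25; APC DEL carrier fraction 10/26;
#' and per-stratum gene-set fold changes taken from the published
#' four-subgroup tables (TGF-beta signalling 1.3/2.33/3.91/5.62 and inflamed
#' T-cell 1.2/5.84/5.66/8.88, ordered high-exposure DEL-/DEL+, then
#' low-exposure DEL-/DEL+), alongside a no-interaction control set.
#'
#' @param seed Integer seed; the same truth (including seed) regenerates
#'   identical data.
#' @param n_bcc,n_scc,n_healthy Patient counts per group.
#' @param uacr_meanlog,uacr_sdlog Log-normal UACR parameters (ug/g).
#' @param exposure_threshold UACR cut separating low/high strata.
#' @param p_homopolymer_del Probability a somatic DEL coordinate falls in a
#'   homopolymer tract.
#' @param tract_run_range Inclusive range of planted tract run lengths.
#' @param target_gene Gene whose DELs define carrier status.
#' @param target_carrier_fraction Probability a BCC patient carries a
#'   target-gene DEL.
#' @param snv_gene Gene whose ns-SNV status is tested for co-occurrence.
#' @param p_snv_given_carrier,p_snv_given_noncarrier Conditional ns-SNV
#'   probabilities given target-gene DEL status.
#' @param geneset_effects Named list; each element a length-4 signed FC
#'   vector named `del0_high`, `del1_high`, `del0_low`, `del1_low`.
#' @param genes_per_set Genes simulated per gene set.
#' @param n_background_genes Unaffected background genes in the count matrix.
#' @param sigma Residual SD of log2 CPM.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param qc_fail_fraction Fraction of decoy somatic calls planted to fail
#'   each QC threshold (true events always pass, so recovery is exact).
#' @param n_tumor_only,n_shared,n_healthy_only Sizes of the DEL coordinate
#'   pools by intended class.
#' @param mean_events_tumor,mean_events_healthy Poisson means of somatic DEL
#'   events per tissue sample.
#' @param reference_length Length (bp) of the synthetic reference contig.
#' @return List of class `cohort_truth`.
#' @export
cohort_truth <- function(seed = 1L, n_bcc = 26L, n_scc = 6L, n_healthy = 16L,
                         uacr_meanlog = log(192), uacr_sdlog = 0.8,
                         exposure_threshold = 192,
                         p_homopolymer_del = 0.65,
                         tract_run_range = c(3L, 25L),
                         target_gene = "APC",
                         target_carrier_fraction = 10 / 26,
                         snv_gene = "PTCH1",
                         p_snv_given_carrier = 0.8,
                         p_snv_given_noncarrier = 0.25,
                         geneset_effects = default_geneset_effects(),
                         genes_per_set = 10L,
                         n_background_genes = 1000L,
                         sigma = 1,
                         libsize_meanlog = log(5e6), libsize_sdlog = 0.3,
                         qc_fail_fraction = 0.05,
                         n_tumor_only = 120L, n_shared = 60L,
                         n_healthy_only = 30L,
                         mean_events_tumor = 25, mean_events_healthy = 8,
                         reference_length = 60000L) {
  probs <- c(p_homopolymer_del, target_carrier_fraction,
             p_snv_given_carrier, p_snv_given_noncarrier, qc_fail_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (tract_run_range[1L] < 3L || tract_run_range[2L] < tract_run_range[1L])
    stop("tract_run_range must be increasing and start at >= 3")
  for (nm in names(geneset_effects)) {
    fc <- geneset_effects[[nm]]
    if (length(fc) != 4L || any(!is.finite(fc)))
      stop("geneset_effects[['", nm, "']] must be 4 finite signed FCs")
  }
  truth <- list(seed = as.integer(seed), n_bcc = n_bcc, n_scc = n_scc,
                n_healthy = n_healthy, uacr_meanlog = uacr_meanlog,
                uacr_sdlog = uacr_sdlog,
                exposure_threshold = exposure_threshold,
                p_homopolymer_del = p_homopolymer_del,
                tract_run_range = as.integer(tract_run_range),
                target_gene = target_gene,
                target_carrier_fraction = target_carrier_fraction,
                snv_gene = snv_gene,
                p_snv_given_carrier = p_snv_given_carrier,
                p_snv_given_noncarrier = p_snv_given_noncarrier,
                geneset_effects = geneset_effects,
                genes_per_set = genes_per_set,
                n_background_genes = n_background_genes, sigma = sigma,
                libsize_meanlog = libsize_meanlog,
                libsize_sdlog = libsize_sdlog,
                qc_fail_fraction = qc_fail_fraction,
                n_tumor_only = n_tumor_only, n_shared = n_shared,
                n_healthy_only = n_healthy_only,
                mean_events_tumor = mean_events_tumor,
                mean_events_healthy = mean_events_healthy,
                reference_length = as.integer(reference_length))
  class(truth) <- "cohort_truth"
  truth
}

#' Default per-stratum gene-set effects
#'
#' Signed fold changes per (DEL status x arsenic stratum) subgroup, ordered
#' `del0_high`, `del1_high`, `del0_low`, `del1_low`.  The two affected sets
#' use the published four-subgroup values; the control set has an identical
#' two-fold tumour shift in every stratum (no interaction).
#'
#' @return Named list of length-4 numeric vectors.
#' @export
default_geneset_effects <- function() {
  list(
    TGFB_SIGNALING = c(del0_high = 1.3, del1_high = 2.33,
                       del0_low = 3.91, del1_low = 5.62),
    INFLAMED_TCELL = c(del0_high = 1.2, del1_high = 5.84,
                       del0_low = 5.66, del1_low = 8.88),
    CONTROL_SET = c(del0_high = 2, del1_high = 2, del0_low = 2, del1_low = 2))
}

#' Generate a reference sequence with embedded homopolymer tracts
#'
#' Random background sequence with specified maximal homopolymer runs
#' planted at given positions; the bases flanking each tract are forced to
#' differ from the tract base so the planted run length is exact.
#'
#' @param seed Integer seed.
#' @param length Contig length (bp).
#' @param tracts data.frame with columns `position` (1-based start), `base`
#'   and `run`; tracts must not overlap (flanks included).
#' @param chrom Contig name.
#' @return List: `reference` (`DNAStringSet`), `tracts` (the input, with an
#'   `end` column added).
#' @export
generate_reference <- function(seed, length, tracts = NULL, chrom = "chr1") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, length, replace = TRUE)
  if (!is.null(tracts) && nrow(tracts) > 0L) {
    tracts$end <- tracts$position + tracts$run - 1L
    if (any(tracts$position < 2L) || any(tracts$end > length - 1L))
      stop("tract(s) outside the contig (flanks included)")
    ord <- order(tracts$position)
    t2 <- tracts[ord, ]
    if (any(t2$position[-1L] <= t2$end[-nrow(t2)] + 1L))
      stop("overlapping tracts (flanks included)")
    for (i in seq_len(nrow(tracts))) {
      span <- tracts$position[i]:tracts$end[i]
      seq_chars[span] <- tracts$base[i]
      other <- setdiff(bases, tracts$base[i])
      seq_chars[tracts$position[i] - 1L] <- sample(other, 1L)
      seq_chars[tracts$end[i] + 1L] <- sample(other, 1L)
    }
  }
  ref <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(ref) <- chrom
  list(reference = ref, tracts = tracts)
}

# Non-overlapping random tract layout over [from, to].
random_tract_layout <- function(n, from, to, run_range) {
  runs <- sample(seq(run_range[1L], run_range[2L]), n, replace = TRUE)
  pos <- integer(n)
  taken_lo <- integer(0); taken_hi <- integer(0)
  for (i in seq_len(n)) {
    for (attempt in 1:2000) {
      p <- sample(from:(to - runs[i]), 1L)
      if (!any(p <= taken_hi + 1L & (p + runs[i] - 1L) >= taken_lo - 1L)) {
        pos[i] <- p
        taken_lo <- c(taken_lo, p); taken_hi <- c(taken_hi, p + runs[i] - 1L)
        break
      }
      if (attempt == 2000) stop("could not place tract ", i)
    }
  }
  data.frame(position = pos, base = sample(c("A", "T", "C", "G"), n,
                                           replace = TRUE, prob = c(.4, .4, .1, .1)),
             run = runs, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Realizes a [cohort_truth()]: reference and tract layout, tiled gene map
#' (including the target, ns-SNV and mismatch-repair genes), manifest with
#' matched blood samples and per-patient UACR, per-sample variant tables
#' (germline calls shared between tissue and blood, somatic SNVs/DELs, and
#' QC-failing decoy calls), the gene-count matrix with planted gene-set
#' effects, and the gene-set definitions.  The returned `truth` element
#' records everything planted (carrier status, ns-SNV status, exposure
#' strata, coordinate pools, per-stratum log2 shifts) for recovery tests.
#'
#' @param truth `cohort_truth` object.
#' @return List of class `synthetic_cohort`: `manifest`, `calls` (long
#'   variant table over all samples), `reference`, `tracts`, `gene_map_df`,
#'   `gene_map` (`GRanges`), `counts`, `gene_sets`, `truth` (the input plus
#'   realized assignments).
#' @export
generate_cohort <- function(truth = cohort_truth()) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(truth$seed)
  L <- truth$reference_length

  ## gene map: tile the contig into equal intervals
  panel <- c("APC", "PTCH1", "MLH1", "MTR", "DST", "MSH6", "BRAF", "TP53")
  n_genes <- 40L
  gene_names <- c(panel, sprintf("PANEL%03d", seq_len(n_genes - length(panel))))
  bounds <- floor(seq(1L, L + 1L, length.out = n_genes + 1L))
  gene_map_df <- data.frame(chrom = "chr1", start = bounds[-length(bounds)],
                            end = bounds[-1L] - 1L, gene = gene_names,
                            stringsAsFactors = FALSE)

  ## coordinate pools; tract layout sized so every tract-bound coordinate
  ## gets its own tract, with a reserve inside the target gene
  n_coords <- truth$n_tumor_only + truth$n_shared + truth$n_healthy_only
  in_tract <- stats::runif(n_coords) < truth$p_homopolymer_del
  n_target <- 4L                        # tumour-only coords in the target gene
  target_iv <- gene_map_df[gene_map_df$gene == truth$target_gene, ]
  tr_target <- random_tract_layout(n_target, target_iv$start + 1L,
                                   target_iv$end - 1L,
                                   truth$tract_run_range)
  n_free <- sum(in_tract)
  tr_free <- random_tract_layout(n_free, target_iv$end + 2L, L - 1L,
                                 truth$tract_run_range)
  tracts <- rbind(tr_target, tr_free)
  ref <- generate_reference(truth$seed + 1L, L, tracts)
  reference <- ref$reference
  tracts <- ref$tracts

  ## realize DEL coordinates: tract coords delete 1-3 bases of their run,
  ## non-tract coords delete one base whose maximal run is < 3
  chrom_seq <- reference[[1L]]
  make_tract_del <- function(tr) {
    len <- sample(seq_len(min(3L, tr$run)), 1L)
    s <- tr$position + sample.int(tr$run - len + 1L, 1L) - 1L
    data.frame(chrom = "chr1", start = s, end = s + len - 1L,
               deleted_seq = strrep(tr$base, len), stringsAsFactors = FALSE)
  }
  make_plain_del <- function() {
    repeat {
      p <- sample(seq(target_iv$end + 2L, L - 1L), 1L)
      b <- as.character(Biostrings::subseq(chrom_seq, p, p))
      if (max_run_at(chrom_seq, p, p, b) < 3L)
        return(data.frame(chrom = "chr1", start = p, end = p,
                          deleted_seq = b, stringsAsFactors = FALSE))
    }
  }
  free_tract_row <- 0L
  coord_list <- vector("list", n_coords)
  for (i in seq_len(n_coords)) {
    coord_list[[i]] <- if (in_tract[i]) {
      free_tract_row <- free_tract_row + 1L
      make_tract_del(tr_free[free_tract_row, ])
    } else make_plain_del()
  }
  coords <- do.call(rbind, coord_list)
  coords <- coords[!duplicated(del_key(coords)), , drop = FALSE]
  n_coords <- nrow(coords)
  coords$key <- del_key(coords)
  pool_class <- rep(c("tumor", "shared", "healthy"),
                    c(truth$n_tumor_only, truth$n_shared,
                      truth$n_healthy_only))[seq_len(n_coords)]
  target_coords <- do.call(rbind, lapply(seq_len(n_target), function(i)
    make_tract_del(tr_target[i, ])))
  target_coords <- target_coords[!duplicated(del_key(target_coords)), ,
                                 drop = FALSE]
  target_coords$key <- del_key(target_coords)

  ## patients and manifest
  patients <- c(sprintf("BCC%02d", seq_len(truth$n_bcc)),
                sprintf("SCC%02d", seq_len(truth$n_scc)),
                sprintf("CTRL%02d", seq_len(truth$n_healthy)))
  subtype <- c(rep("BCC", truth$n_bcc), rep("SCC", truth$n_scc),
               rep("none", truth$n_healthy))
  tclass <- c(rep("tumor", truth$n_bcc + truth$n_scc),
              rep("healthy_skin", truth$n_healthy))
  uacr <- stats::rlnorm(length(patients), truth$uacr_meanlog,
                        truth$uacr_sdlog)
  manifest <- rbind(
    data.frame(patient_id = patients,
               sample_id = paste0(patients, "_T"), material = "tissue",
               tissue_class = tclass, tumor_subtype = subtype, uacr = uacr,
               stringsAsFactors = FALSE),
    data.frame(patient_id = patients,
               sample_id = paste0(patients, "_B"), material = "blood",
               tissue_class = "none", tumor_subtype = "none", uacr = uacr,
               stringsAsFactors = FALSE))

  ## per-patient mutation truth
  is_bcc <- subtype == "BCC"
  carrier <- is_bcc & stats::rbinom(length(patients), 1L,
                                    truth$target_carrier_fraction) == 1L
  p_snv <- ifelse(carrier, truth$p_snv_given_carrier,
                  truth$p_snv_given_noncarrier)
  snv_pos <- is_bcc & stats::rbinom(length(patients), 1L, p_snv) == 1L
  names(carrier) <- names(snv_pos) <- patients

  ## germline pool (SNVs at fixed positions, shared tissue+blood)
  n_germ <- 40L
  germ_pos <- sample(seq(target_iv$end + 2L, L - 1L), n_germ)
  germ <- data.frame(chrom = "chr1", start = germ_pos, end = germ_pos,
                     var_type = "SNV",
                     ref_allele = vapply(germ_pos, function(p)
                       as.character(Biostrings::subseq(chrom_seq, p, p)),
                       character(1L)),
                     stringsAsFactors = FALSE)
  germ$alt_allele <- vapply(germ$ref_allele, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))

  ## ns-SNV coordinate inside the snv gene, per positive patient
  snv_iv <- gene_map_df[gene_map_df$gene == truth$snv_gene, ]

  qc_attrs <- function(n, fail = FALSE) {
    cov <- 30L + stats::rpois(n, 70)
    target_freq <- stats::runif(n, 5, 60)
    # floor at 3% of coverage so a passing call never slips under the 2%
    # frequency threshold by binomial chance
    alt <- pmax(2L, as.integer(ceiling(0.03 * cov)),
                stats::rbinom(n, cov, target_freq / 100))
    qual <- stats::runif(n, 62, 90)
    if (fail && n > 0L) {
      # decoys: push exactly one attribute below its threshold
      which_attr <- sample(1:4, n, replace = TRUE)
      cov[which_attr == 1L] <- sample(0:9, sum(which_attr == 1L), TRUE)
      alt[which_attr == 2L] <- 1L
      cov[which_attr == 3L] <- 300L     # with alt = 2 -> frequency 0.67%
      alt[which_attr == 3L] <- 2L
      qual[which_attr == 4L] <- stats::runif(sum(which_attr == 4L), 10, 59.9)
    }
    alt <- pmin(alt, cov)
    freq <- ifelse(cov > 0, 100 * alt / cov, 0)
    data.frame(coverage = as.integer(cov), alt_count = as.integer(alt),
               frequency = freq, avg_quality = qual)
  }

  call_rows <- function(sample_id, df, qc) {
    if (nrow(df) == 0L) return(empty_variant_table())
    cbind(data.frame(sample_id = sample_id, stringsAsFactors = FALSE),
          df[, c("chrom", "start", "end", "var_type", "ref_allele",
                 "alt_allele")],
          qc)
  }

  del_df <- function(cdf) {
    if (nrow(cdf) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), var_type = character(),
                        ref_allele = character(), alt_allele = character(),
                        stringsAsFactors = FALSE))
    data.frame(chrom = cdf$chrom, start = cdf$start, end = cdf$end,
               var_type = "DEL", ref_allele = cdf$deleted_seq,
               alt_allele = "-", stringsAsFactors = FALSE)
  }

  calls <- list()
  somatic_truth <- list()
  for (i in seq_along(patients)) {
    pid <- patients[i]
    tumorish <- tclass[i] == "tumor"
    ## germline: subset shared by tissue and blood
    g_idx <- sample(n_germ, 15L)
    g <- germ[g_idx, , drop = FALSE]
    g_qc <- qc_attrs(nrow(g))
    ## somatic DELs from the class pools
    pool <- if (tumorish) coords[pool_class != "healthy", , drop = FALSE]
    else coords[pool_class != "tumor", , drop = FALSE]
    n_ev <- stats::rpois(1L, if (tumorish) truth$mean_events_tumor else
      truth$mean_events_healthy)
    ev <- pool[sample(nrow(pool), min(n_ev, nrow(pool))), , drop = FALSE]
    ## planted target-gene DELs for carriers
    if (carrier[i]) {
      k <- sample(nrow(target_coords), sample(1:2, 1L))
      ev <- rbind(ev, target_coords[k, , drop = FALSE])
      ev <- ev[!duplicated(ev$key), , drop = FALSE]
    }
    som <- del_df(ev)
    ## somatic ns-SNV in the co-occurrence gene
    if (snv_pos[i]) {
      p <- sample(seq(snv_iv$start + 1L, snv_iv$end - 1L), 1L)
      b <- as.character(Biostrings::subseq(chrom_seq, p, p))
      som <- rbind(som, data.frame(chrom = "chr1", start = p, end = p,
                                   var_type = "SNV", ref_allele = b,
                                   alt_allele = sample(setdiff(
                                     c("A", "C", "G", "T"), b), 1L),
                                   stringsAsFactors = FALSE))
    }
    som_qc <- qc_attrs(nrow(som))
    ## QC-failing decoy somatic calls (true events always pass)
    n_decoy <- stats::rpois(1L, 4 * truth$qc_fail_fraction / 0.05)
    decoy <- NULL
    if (n_decoy > 0L) {
      dp <- sample(seq(target_iv$end + 2L, L - 1L), n_decoy)
      decoy <- data.frame(chrom = "chr1", start = dp, end = dp,
                          var_type = "SNV",
                          ref_allele = vapply(dp, function(p)
                            as.character(Biostrings::subseq(chrom_seq, p, p)),
                            character(1L)),
                          stringsAsFactors = FALSE)
      decoy$alt_allele <- vapply(decoy$ref_allele, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    }
    tissue_calls <- rbind(
      call_rows(paste0(pid, "_T"), g, g_qc),
      call_rows(paste0(pid, "_T"), som, som_qc),
      if (!is.null(decoy))
        call_rows(paste0(pid, "_T"), decoy, qc_attrs(n_decoy, fail = TRUE)))
    blood_calls <- call_rows(paste0(pid, "_B"), g, g_qc)
    calls[[pid]] <- rbind(tissue_calls, blood_calls)
    somatic_truth[[pid]] <- list(germline_keys = variant_key(
      call_rows(paste0(pid, "_B"), g, g_qc)),
      del_keys = del_key(ev))
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  ## expression: log2 CPM with planted per-stratum shifts, then counts
  set_names <- names(truth$geneset_effects)
  gene_sets <- lapply(set_names, function(nm)
    sprintf("%s_G%02d", nm, seq_len(truth$genes_per_set)))
  names(gene_sets) <- set_names
  expr_genes <- c(unlist(gene_sets, use.names = FALSE),
                  sprintf("BG%04d", seq_len(truth$n_background_genes)))
  tissue_samples <- manifest[manifest$material == "tissue", ]
  as_high <- as.integer(tissue_samples$uacr > truth$exposure_threshold)
  mut <- as.integer(tissue_samples$tissue_class == "tumor" &
                    carrier[tissue_samples$patient_id])
  is_tumor <- as.integer(tissue_samples$tissue_class == "tumor")
  d_effects <- lapply(truth$geneset_effects, inverse_signed_fc)
  baseline <- stats::rnorm(length(expr_genes), 6, 1.5)
  names(baseline) <- expr_genes
  y <- matrix(0, length(expr_genes), nrow(tissue_samples),
              dimnames = list(expr_genes, tissue_samples$sample_id))
  for (s in seq_len(nrow(tissue_samples))) {
    mu <- baseline
    if (is_tumor[s] == 1L) {
      stratum <- paste0("del", mut[s], "_", if (as_high[s] == 1L) "high"
                        else "low")
      for (nm in set_names)
        mu[gene_sets[[nm]]] <- mu[gene_sets[[nm]]] + d_effects[[nm]][stratum]
    }
    y[, s] <- mu + stats::rnorm(length(expr_genes), 0, truth$sigma)
  }
  libsize <- stats::rlnorm(nrow(tissue_samples), truth$libsize_meanlog,
                           truth$libsize_sdlog)
  counts <- round(sweep(2^y, 2L, libsize / 1e6, "*"))
  attr(counts, "stage") <- "counts"

  truth$carrier <- carrier
  truth$snv_status <- snv_pos
  truth$uacr <- stats::setNames(uacr, patients)
  truth$as_high <- stats::setNames(
    as.integer(uacr > truth$exposure_threshold), patients)
  truth$d_effects <- d_effects
  truth$pool_class <- stats::setNames(pool_class, coords$key)
  truth$target_coords <- target_coords$key
  truth$somatic <- somatic_truth

  structure(list(manifest = manifest, calls = calls, reference = reference,
                 tracts = tracts, gene_map_df = gene_map_df,
                 gene_map = read_gene_map(gene_map_df), counts = counts,
                 gene_sets = gene_sets, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:",
      sum(x$manifest$tumor_subtype == "BCC" & x$manifest$material == "tissue"),
      "BCC +",
      sum(x$manifest$tumor_subtype == "SCC" & x$manifest$material == "tissue"),
      "SCC tumours,",
      sum(x$manifest$tissue_class == "healthy_skin"), "healthy controls\n")
  cat(sprintf("  %d variant calls, %d x %d count matrix, %d gene sets, seed %d\n",
              nrow(x$calls), nrow(x$counts), ncol(x$counts),
              length(x$gene_sets), x$truth$seed))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `manifest.tsv`, `calls.tsv`, `reference.fa`, `genes.bed` (0-based
#' BED), `counts.tsv`, `sets.gmt` and `truth.json` into `dir`.
#'
#' @param cohort `synthetic_cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_variant_table(cohort$calls, file.path(dir, "calls.tsv"))
  Biostrings::writeXStringSet(cohort$reference,
                              file.path(dir, "reference.fa"))
  bed <- data.frame(cohort$gene_map_df$chrom,
                    cohort$gene_map_df$start - 1L,
                    cohort$gene_map_df$end, cohort$gene_map_df$gene)
  write.table(bed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  counts_df <- data.frame(gene = rownames(cohort$counts), cohort$counts,
                          check.names = FALSE)
  write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "sets.gmt"))
  truth <- cohort$truth
  truth$somatic <- NULL                 # per-patient key lists are bulky
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Simulate a gene-set model table directly on the log2 CPM scale
#'
#' Draws the long model table the gene-set ANOVA consumes, without the
#' count-matrix round trip: healthy samples at per-gene baselines, tumour
#' samples shifted by the stratum's log2 effect, residual noise
#' `N(0, sigma^2)`.  Used for estimator calibration (parameter recovery,
#' type-I error) where the planted contrast must be exact.
#'
#' @param fc Signed fold changes per stratum: length 4 (named or ordered
#'   `del0_high`, `del1_high`, `del0_low`, `del1_low`) for the exposure
#'   model, or length 2 (`del0`, `del1`) for the base model.
#' @param n_per_stratum Tumour samples per stratum.
#' @param n_healthy Healthy control samples (split evenly over exposure
#'   strata in the exposure model).
#' @param n_genes Genes in the set.
#' @param sigma Residual SD (log2 CPM).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @return Long model table (`sample_id`, `gene`, `y`, `tissue`, `mut`, and
#'   `as_high` for the exposure design).
#' @export
simulate_model_table <- function(fc, n_per_stratum = 10L, n_healthy = 16L,
                                 n_genes = 10L, sigma = 1,
                                 baseline_mean = 6, baseline_sd = 1.5) {
  exposure <- length(fc) == 4L
  if (!exposure && length(fc) != 2L)
    stop("fc must have length 2 (base model) or 4 (exposure model)")
  d <- inverse_signed_fc(fc)
  strata <- if (exposure)
    data.frame(mut = c(0L, 1L, 0L, 1L), as_high = c(1L, 1L, 0L, 0L))
  else data.frame(mut = c(0L, 1L))
  genes <- sprintf("G%02d", seq_len(n_genes))
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  rows <- list()
  sample_n <- 0L
  add_sample <- function(tissue, mut, as_high, shift) {
    sample_n <<- sample_n + 1L
    df <- data.frame(sample_id = sprintf("S%03d", sample_n), gene = genes,
                     y = baseline + shift + stats::rnorm(n_genes, 0, sigma),
                     tissue = tissue, mut = mut, stringsAsFactors = FALSE)
    if (exposure) df$as_high <- as_high
    rows[[length(rows) + 1L]] <<- df
  }
  for (j in seq_len(nrow(strata)))
    for (r in seq_len(n_per_stratum))
      add_sample(1L, strata$mut[j],
                 if (exposure) strata$as_high[j] else NA_integer_, d[j])
  healthy_as <- if (exposure) rep_len(c(1L, 0L), n_healthy) else
    rep(NA_integer_, n_healthy)
  for (r in seq_len(n_healthy))
    add_sample(0L, 0L, healthy_as[r], 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
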