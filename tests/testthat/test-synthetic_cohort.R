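test_that("truth objects validate their parameters", {
  expect_s3_class(cohort_truth(), "cohort_truth")
  expect_error(cohort_truth(p_homopolymer_del = 1.2), "probabilities")
  expect_error(cohort_truth(tract_run_range = c(2L, 5L)), "tract_run_range")
  expect_error(cohort_truth(geneset_effects = list(BAD = c(1, 2))),
               "BAD")
})

test_that("reference generation plants exact maximal tracts", {
  tracts <- data.frame(position = c(1000L, 1100L), base = c("A", "T"),
                       run = c(13L, 5L))
  ref <- generate_reference(5L, 2000L, tracts)
  seq <- as.character(ref$reference[[1L]])
  expect_equal(substr(seq, 1000L, 1012L), strrep("A", 13L))
  # flanks differ from the tract base, so the planted run is maximal
  expect_false(substr(seq, 999L, 999L) == "A")
  expect_false(substr(seq, 1013L, 1013L) == "A")
  ann <- homopolymer_context(ref$reference,
                             make_events("P", "chr1", 1003, "A"))
  expect_equal(ann$run_length, 13L)

  expect_error(generate_reference(5L, 2000L, data.frame(
    position = c(100L, 104L), base = "A", run = c(5L, 5L))), "overlap")
  # same seed, same sequence
  ref2 <- generate_reference(5L, 2000L, tracts)
  expect_identical(as.character(ref$reference), as.character(ref2$reference))
})

test_that("cohorts are byte-identical under the same seed", {
  a <- generate_cohort(cohort_truth(seed = 12))
  b <- generate_cohort(cohort_truth(seed = 12))
  expect_identical(a$calls, b$calls)
  expect_identical(a$counts, b$counts)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$truth$carrier, b$truth$carrier)
  c_ <- generate_cohort(cohort_truth(seed = 13))
  expect_false(identical(a$calls, c_$calls))
})

test_that("generated cohorts have the default study layout", {
  co <- generate_cohort(cohort_truth(seed = 3))
  m <- read_manifest(co$manifest)          # passes manifest invariants
  tissue <- m[m$material == "tissue", ]
  expect_equal(sum(tissue$tumor_subtype == "BCC"), 26L)
  expect_equal(sum(tissue$tumor_subtype == "SCC"), 6L)
  expect_equal(sum(tissue$tissue_class == "healthy_skin"), 16L)
  expect_equal(sum(m$material == "blood"), 48L)
  expect_silent(validate_variant_calls(co$calls))
  expect_true(all(co$counts >= 0) && all(co$counts == round(co$counts)))
  expect_equal(ncol(co$counts), 48L)
})

test_that("germline subtraction removes exactly the planted germline calls", {
  co <- generate_cohort(cohort_truth(seed = 4))
  for (pid in c("BCC01", "SCC03", "CTRL09")) {
    tissue <- co$calls[co$calls$sample_id == paste0(pid, "_T"), ]
    blood <- co$calls[co$calls$sample_id == paste0(pid, "_B"), ]
    som <- subtract_germline(tissue, blood, check_patient = FALSE)
    germ_keys <- co$truth$somatic[[pid]]$germline_keys
    som_keys <- skindel:::variant_key(som)
    tis_keys <- skindel:::variant_key(tissue)
    expect_setequal(som_keys, setdiff(tis_keys, germ_keys))
    expect_length(intersect(som_keys, germ_keys), 0L)
  }
})

test_that("planted QC decoys are exactly the calls the filter removes", {
  co <- generate_cohort(cohort_truth(seed = 5))
  som <- somatic_calls(co$calls, co$manifest)
  # the surviving DELs are exactly the planted somatic events: decoys are
  # filtered out, true events never are
  for (pid in unique(som$patient_id)) {
    got <- unique(del_events(som[som$patient_id == pid, ])$key)
    expect_setequal(got, unique(co$truth$somatic[[pid]]$del_keys))
  }
})

test_that("degenerate homopolymer probability puts every DEL in a tract", {
  co <- generate_cohort(cohort_truth(seed = 6, p_homopolymer_del = 1,
                                     n_tumor_only = 40L, n_shared = 20L,
                                     n_healthy_only = 10L))
  som <- somatic_calls(co$calls, co$manifest)
  ev <- del_events(som)
  ann <- homopolymer_context(co$reference, unique(ev$key))
  expect_true(all(ann$in_homopolymer))
})

test_that("carrier fraction tracks its configured value across seeds", {
  carriers <- vapply(1:30, function(s) {
    co <- cohort_truth(seed = s, n_scc = 0L, n_healthy = 2L,
                       n_tumor_only = 20L, n_shared = 10L,
                       n_healthy_only = 5L, mean_events_tumor = 5,
                       mean_events_healthy = 2,
                       n_background_genes = 10L)
    sum(generate_cohort(co)$truth$carrier)
  }, numeric(1L))
  n_total <- 30 * 26
  phat <- sum(carriers) / n_total
  p0 <- 10 / 26
  # 3.5-sigma binomial band around the configured fraction
  expect_lt(abs(phat - p0), 3.5 * sqrt(p0 * (1 - p0) / n_total))
})

test_that("planted expression shifts survive the count round trip", {
  co <- generate_cohort(cohort_truth(seed = 20))
  lg <- log2_cpm(counts_to_cpm(co$counts))
  m <- co$manifest
  tissue <- m[m$material == "tissue", ]
  healthy_ids <- tissue$sample_id[tissue$tissue_class == "healthy_skin"]
  # DEL+ low-exposure BCC tumours vs healthy, inflamed T-cell set
  sel <- tissue$tumor_subtype == "BCC" &
    co$truth$carrier[tissue$patient_id] &
    co$truth$as_high[tissue$patient_id] == 0L
  expect_gte(sum(sel), 2L)   # the fixed seed realizes this stratum
  genes <- co$gene_sets$INFLAMED_TCELL
  d_obs <- mean(lg[genes, tissue$sample_id[sel]]) -
    mean(lg[genes, healthy_ids])
  d_true <- co$truth$d_effects$INFLAMED_TCELL[["del1_low"]]
  se_rough <- sqrt(1 / (length(genes) * sum(sel)) +
                     1 / (length(genes) * length(healthy_ids)))
  # within 4 rough SEs plus the small compositional distortion of CPM
  expect_lt(abs(d_obs - d_true), 4 * se_rough + 0.15)
})

test_that("cohorts write to plain-text files that read back", {
  co <- generate_cohort(cohort_truth(seed = 8, n_background_genes = 20L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "manifest.tsv", "calls.tsv", "reference.fa", "genes.bed", "counts.tsv",
    "sets.gmt", "truth.json")))))
  calls <- read_variant_table(file.path(dir, "calls.tsv"), "tsv")
  expect_equal(nrow(calls), nrow(co$calls))
  expect_equal(read_gmt(file.path(dir, "sets.gmt")), co$gene_sets,
               ignore_attr = TRUE)
  counts <- read_counts_matrix(file.path(dir, "counts.tsv"))
  expect_equal(unname(counts), unname(co$counts), ignore_attr = TRUE)
  gm <- read_gene_map(file.path(dir, "genes.bed"))
  expect_equal(gm$gene, co$gene_map$gene)
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_equal(as.character(ref[[1L]]), as.character(co$reference[[1L]]))
})
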