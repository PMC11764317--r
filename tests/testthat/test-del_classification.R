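test_that("coordinate partition matches set algebra on a toy example", {
  tum <- make_events(c("P1", "P1", "P2"), "chr1", c(10, 20, 30),
                     c("A", "A", "T"))          # keys k1, k2, k3
  hea <- make_events(c("C1", "C2"), "chr1", c(20, 40), c("A", "C"))
  part <- partition_by_coordinate(tum, hea)
  expect_setequal(part$tumor_only, del_key(tum[c(1, 3), ]))
  expect_setequal(part$shared, del_key(tum[2, ]))
  expect_setequal(part$healthy_only, del_key(hea[2, ]))
  expect_equal(unname(part$event_counts),
               c(2L, 2L, 1L))   # tumor-only, shared (both tissues), healthy

  # disjoint inputs
  part2 <- partition_by_coordinate(tum[1:2, ], hea[2, , drop = FALSE])
  expect_length(part2$shared, 0L)
})

test_that("partition arithmetic reproduces the published Venn counts", {
  # 1077 unique tumour coordinates of which 460 shared; 605 unique healthy
  shared_keys <- sprintf("chrS|%d", 1:460)
  tum <- make_events("P1", "chrT", 1:617, "A")
  tum <- rbind(tum, make_events("P2", "chrS", 1:460, "A"))
  hea <- make_events("C1", "chrH", 1:145, "A")
  hea <- rbind(hea, make_events("C2", "chrS", 1:460, "A"))
  part <- partition_by_coordinate(tum, hea)
  expect_length(part$tumor_only, 617L)
  expect_length(part$shared, 460L)
  expect_length(part$healthy_only, 145L)
  expect_equal(length(part$tumor_only) + length(part$shared), 1077L)
  expect_equal(length(part$healthy_only) + length(part$shared), 605L)
})

test_that("event counts partition all events, under random sharing", {
  set.seed(11)
  for (rep in 1:10) {
    tum <- make_events(sample(sprintf("P%d", 1:5), 40, TRUE), "chr1",
                       sample(1:25, 40, TRUE), "A")
    hea <- make_events(sample(sprintf("C%d", 1:3), 15, TRUE), "chr1",
                       sample(1:25, 15, TRUE), "A")
    part <- partition_by_coordinate(tum, hea)
    expect_equal(sum(part$event_counts), nrow(tum) + nrow(hea))
    expect_length(intersect(part$tumor_only, part$shared), 0L)
    expect_length(intersect(part$tumor_only, part$healthy_only), 0L)
    expect_length(union(part$shared,
                        union(part$tumor_only, part$healthy_only)),
                  length(unique(c(tum$key, hea$key))))
  }
})

toy_gene_map <- function() read_gene_map(data.frame(
  chrom = "chr1", start = c(1L, 101L, 201L), end = c(100L, 200L, 300L),
  gene = c("A", "B", "C"), stringsAsFactors = FALSE))

test_that("gene-level partition classes genes, not coordinates", {
  gm <- toy_gene_map()
  # gene B carries different DELs in tumour and healthy -> classed 'both'
  tum <- make_events(c("P1", "P1"), "chr1", c(10, 110), c("A", "A"))
  hea <- make_events("C1", "chr1", c(150, 250), c("A", "A"))
  gp <- partition_by_gene(tum, hea, gm)
  expect_equal(gp$tumor_only, "A")
  expect_equal(gp$both, "B")
  expect_equal(gp$healthy_only, "C")
  # the three classes partition the observed genes
  expect_setequal(c(gp$tumor_only, gp$both, gp$healthy_only),
                  c("A", "B", "C"))
})

test_that("unmapped deletion keys raise an error naming the key", {
  gm <- toy_gene_map()
  tum <- make_events("P1", "chr1", 400, "A")
  expect_error(partition_by_gene(tum, tum[0, ], gm), "chr1|400")
})

test_that("subtype-associated DELs require subtype presence and healthy absence", {
  m <- make_manifest(n_bcc = 2L, n_scc = 1L, n_healthy = 1L)
  tum <- rbind(
    make_events("P01", "chr1", 10, "A"),   # BCC only -> in
    make_events("P02", "chr1", 10, "A"),
    make_events("P01", "chr1", 20, "A"),   # also healthy -> out
    make_events("P03", "chr1", 30, "A"))   # SCC only -> out for BCC
  hea <- make_events("C01", "chr1", 20, "A")
  assoc <- subtype_associated_dels(tum, m, "BCC", hea)
  expect_equal(assoc, del_key(tum[1, ]))
  assoc_scc <- subtype_associated_dels(tum, m, "SCC", hea)
  expect_equal(assoc_scc, del_key(tum[4, ]))
  # associated sets live inside the tumour-only partition class
  part <- partition_by_coordinate(tum, hea)
  expect_true(all(c(assoc, assoc_scc) %in% part$tumor_only))
})

test_that("carrier matrix is idempotent and reports carrier frequency", {
  gm <- toy_gene_map()
  m <- make_manifest(n_bcc = 4L, n_healthy = 1L)
  # P01 carries two distinct DELs in gene A; P02 one in gene B
  tum <- rbind(make_events("P01", "chr1", c(10, 15), c("A", "A")),
               make_events("P02", "chr1", 110, "A"))
  assoc <- subtype_associated_dels(tum, m, "BCC", tum[0, ])
  dm <- gene_del_status(assoc, tum, gm, m, "BCC")
  expect_true(dm$status["P01", "A"])
  expect_false(dm$status["P01", "B"])
  expect_equal(sum(dm$status[, "A"]), 1L)      # two DELs, one carrier
  expect_equal(unname(dm$carrier_freq["A"]), 0.25)
  expect_false(any(dm$status["P03", ]))        # no DELs -> all-false row

  # monotonicity: adding an associated DEL never unsets a carrier
  tum2 <- rbind(tum, make_events("P03", "chr1", 210, "A"))
  assoc2 <- subtype_associated_dels(tum2, m, "BCC", tum2[0, ])
  dm2 <- gene_del_status(assoc2, tum2, gm, m, "BCC")
  for (g in colnames(dm$status))
    expect_true(all(dm2$status[rownames(dm$status), g] >= dm$status[, g]))
})

test_that("a 13-of-26 carrier gene reports frequency 0.50", {
  gm <- toy_gene_map()
  m <- make_manifest(n_bcc = 26L, n_healthy = 2L)
  carriers <- sprintf("P%02d", 1:13)
  tum <- make_events(carriers, "chr1", 50, "A")
  assoc <- subtype_associated_dels(tum, m, "BCC", tum[0, ])
  dm <- gene_del_status(assoc, tum, gm, m, "BCC")
  expect_equal(unname(dm$carrier_freq["A"]), 0.5)
  expect_equal(nrow(dm$status), 26L)
})

test_that("top_genes ranks by carrier count with alphabetical ties", {
  gm <- toy_gene_map()
  m <- make_manifest(n_bcc = 5L, n_healthy = 1L)
  tum <- rbind(make_events(c("P01", "P02"), "chr1", 110, "A"),  # gene B x2
               make_events(c("P01", "P03"), "chr1", 10, "A"),   # gene A x2
               make_events("P04", "chr1", 210, "A"))            # gene C x1
  assoc <- subtype_associated_dels(tum, m, "BCC", tum[0, ])
  dm <- gene_del_status(assoc, tum, gm, m, "BCC")
  expect_equal(top_genes(dm, 2L), c("A", "B"))
  expect_warning(all_of_them <- top_genes(dm, 10L), "exceeds")
  expect_equal(all_of_them, c("A", "B", "C"))

  empty <- dm
  empty$status[] <- FALSE
  expect_warning(ranking <- top_genes(empty, 1L), "no gene")
  expect_length(ranking, 0L)
})
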