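# random small-but-full-rank model table for oracle checks
random_table <- function(n_genes, n_tumor, n_healthy, with_mut = TRUE) {
  genes <- sprintf("G%d", seq_len(n_genes))
  mut <- if (with_mut) c(0L, 1L, sample(0:1, n_tumor - 2L, TRUE)) else
    rep(0L, n_tumor)
  rows <- list()
  for (s in seq_len(n_tumor))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("T%d", s), gene = genes,
      y = rnorm(n_genes, 6), tissue = 1L, mut = mut[s],
      stringsAsFactors = FALSE)
  for (s in seq_len(n_healthy))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("H%d", s), gene = genes,
      y = rnorm(n_genes, 6), tissue = 0L, mut = 0L,
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

test_that("coefficients match a direct normal-equations solve", {
  set.seed(101)
  for (draw in 1:100) {
    tab <- random_table(n_genes = sample(1:6, 1L),
                        n_tumor = sample(3:8, 1L),
                        n_healthy = sample(2:4, 1L))
    fit <- geneset_anova(tab)
    X <- model.matrix(fit$lm)
    beta_oracle <- solve(crossprod(X), crossprod(X, fit$lm$model$y))
    expect_equal(unname(coef(fit)), unname(drop(beta_oracle)),
                 tolerance = 1e-8)
  }
})

test_that("single-gene tissue contrast equals the pooled two-sample t", {
  set.seed(102)
  tab <- random_table(n_genes = 1L, n_tumor = 6L, n_healthy = 5L,
                      with_mut = FALSE)
  expect_message(fit <- geneset_anova(tab), "aliased")  # tissue:mut all-zero
  t_model <- summary(fit$lm)$coefficients["tissue", "t value"]
  tt <- t.test(tab$y[tab$tissue == 1L], tab$y[tab$tissue == 0L],
               var.equal = TRUE)
  expect_equal(t_model, unname(tt$statistic), tolerance = 1e-12)
  # and the stratum contrast is the plain difference of means
  est <- stratum_fc(fit, mut = 0L)
  expect_equal(est$d, mean(tab$y[tab$tissue == 1L]) -
                 mean(tab$y[tab$tissue == 0L]), tolerance = 1e-12)
})

test_that("duplicating every row preserves point estimates", {
  set.seed(103)
  tab <- random_table(3L, 5L, 4L)
  tab2 <- rbind(tab, transform(tab, sample_id = paste0(sample_id, "bis")))
  f1 <- geneset_anova(tab)
  f2 <- geneset_anova(tab2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  # doubled data halves the coefficient variances (up to df scaling of s^2)
  expect_lt(stratum_fc(f2, 0L)$se, stratum_fc(f1, 0L)$se)
})

test_that("signed fold-change conversion follows the reporting convention", {
  expect_equal(signed_fc(1), 2)
  expect_equal(signed_fc(0), 1)
  expect_equal(signed_fc(-1), -2)
  d <- runif(20, -4, 4)
  expect_equal(abs(signed_fc(d)), abs(signed_fc(-d)))       # involution
  expect_equal(inverse_signed_fc(signed_fc(d)), d, tolerance = 1e-12)
  expect_error(inverse_signed_fc(0.5), "convention")
})

test_that("stratum CIs can straddle zero after sign conversion", {
  # tumour and healthy means are equal by construction, so d-hat = 0 and
  # the interval must cross the null
  tab <- expand.grid(sample_id = sprintf("S%d", 1:8),
                     gene = c("G1", "G2"), stringsAsFactors = FALSE)
  tab$tissue <- as.integer(tab$sample_id %in% sprintf("S%d", 1:4))
  tab$mut <- as.integer(tab$sample_id %in% c("S3", "S4"))
  tab$y <- rep(c(5, 7), length.out = nrow(tab))
  fit <- geneset_anova(tab)
  est <- stratum_fc(fit, 0L)
  # a null-ish contrast: interval bounds have opposite signs, like the
  # published "(-1.20 to 1.12)" style
  expect_lt(est$ci_low, 0)
  expect_gt(est$ci_high, 0)
  expect_true(est$ci_low <= est$fc && est$fc <= est$ci_high)
})

test_that("single-coefficient interaction F equals t squared", {
  set.seed(105)
  tab <- random_table(4L, 6L, 4L)
  fit <- geneset_anova(tab)
  it <- interaction_test(fit, "tissue:mut")
  tstat <- summary(fit$lm)$coefficients["tissue:mut", "t value"]
  pval <- summary(fit$lm)$coefficients["tissue:mut", "Pr(>|t|)"]
  expect_equal(it$f_ratio, tstat^2, tolerance = 1e-10)
  expect_equal(it$p, pval, tolerance = 1e-10)
  expect_error(interaction_test(fit, "tissue:nothere"), "not in the fitted")
})

test_that("interaction F matches anova() extra-sum-of-squares", {
  set.seed(106)
  tab <- simulate_model_table(fc = c(1.3, 2.33, 3.91, 5.62),
                              n_per_stratum = 6L, n_healthy = 8L,
                              n_genes = 4L)
  fit <- geneset_anova(tab)
  it <- interaction_test(fit, "tissue:mut:as_high")
  reduced <- lm(y ~ gene + tissue + gene:tissue + tissue:mut +
                  tissue:as_high, data = transform(tab, gene = factor(gene)))
  cmp <- anova(reduced, fit$lm)
  expect_equal(it$f_ratio, cmp$F[2L], tolerance = 1e-10)
  expect_equal(it$p, cmp$`Pr(>F)`[2L], tolerance = 1e-10)
})

test_that("bonferroni adjustment is min(1, m p) and order preserving", {
  expect_equal(bonferroni_adjust(rep(0.001, 50))[1L], 0.05)
  expect_equal(bonferroni_adjust(c(0.1, 0.5)), c(0.2, 1.0))
  p <- runif(20, 0, 1 / 40)     # below the min(1, m p) cap, so no ties
  expect_equal(order(bonferroni_adjust(p)), order(p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("true stratum shifts are recovered from simulated tables", {
  set.seed(107)
  fc_true <- c(del0_high = 1.3, del1_high = 2.33,
               del0_low = 3.91, del1_low = 5.62)
  d_true <- inverse_signed_fc(fc_true)
  tab <- simulate_model_table(fc_true, n_per_stratum = 40L, n_healthy = 40L,
                              n_genes = 10L, sigma = 1)
  fit <- geneset_anova(tab)
  strata <- data.frame(mut = c(0L, 1L, 0L, 1L), as_high = c(1L, 1L, 0L, 0L))
  for (j in 1:4) {
    est <- stratum_fc(fit, strata$mut[j], strata$as_high[j])
    expect_equal(est$d, d_true[[j]], tolerance = 0.25)
    expect_equal(est$n_cases, 40L)
  }
})

test_that("screens are deterministic and rank the interacting set first", {
  set.seed(108)
  co <- generate_cohort(cohort_truth(seed = 31))
  lg <- log2_cpm(counts_to_cpm(co$counts))
  m <- co$manifest
  # carrier matrix straight from the generator truth, bypassing filtering
  carriers <- names(co$truth$carrier)[co$truth$carrier]
  bcc <- sort(unique(m$patient_id[m$tumor_subtype == "BCC"]))
  status <- matrix(bcc %in% carriers, length(bcc), 1L,
                   dimnames = list(bcc, "APC"))
  dm <- structure(list(status = status, carrier_freq = colMeans(status),
                       subtype = "BCC"), class = "gene_del_matrix")

  sets <- c(co$gene_sets, list(INFLAMED_TCELL_COPY =
                                 co$gene_sets$INFLAMED_TCELL))
  res <- run_pathway_screen(lg, sets, m, "BCC", dm, "APC",
                            exposure_threshold = 192)
  # identical gene set listed twice gives identical statistics
  a <- res[res$gene_set == "INFLAMED_TCELL", -1L]
  b <- res[res$gene_set == "INFLAMED_TCELL_COPY", -1L]
  expect_equal(unname(unlist(a)), unname(unlist(b)))
  # the planted interacting set outranks the no-interaction control
  expect_lt(res$interaction_p[res$gene_set == "INFLAMED_TCELL"][1L],
            res$interaction_p[res$gene_set == "CONTROL_SET"])
  expect_lt(res$bonferroni_p[res$gene_set == "INFLAMED_TCELL"][1L], 0.05)
  # rerun is byte-identical
  res2 <- run_pathway_screen(lg, sets, m, "BCC", dm, "APC",
                             exposure_threshold = 192)
  expect_identical(res, res2)
})

test_that("four-subgroup stratum sizes follow the manifest", {
  # replicate the published subgroup layout: n = 11, 6, 5, 4 BCC cases
  # (high/low exposure crossed with DEL status) over shared controls
  n_strata <- c(del0_high = 11L, del1_high = 6L, del0_low = 5L,
                del1_low = 4L)
  uacr_t <- c(rep(300, 17), rep(100, 9))
  m <- make_manifest(n_bcc = 26L, n_healthy = 4L,
                     uacr = c(uacr_t, rep(c(300, 100), 2L)))
  carriers <- c(sprintf("P%02d", 12:17), sprintf("P%02d", 23:26))
  status <- matrix(sort(unique(m$patient_id[m$tumor_subtype == "BCC"]))
                   %in% carriers, 26L, 1L,
                   dimnames = list(sprintf("P%02d", 1:26), "APC"))
  dm <- structure(list(status = status, carrier_freq = colMeans(status),
                       subtype = "BCC"), class = "gene_del_matrix")
  genes <- sprintf("G%d", 1:3)
  lg <- matrix(rnorm(3L * 30L, 6), 3L,
               dimnames = list(genes, m$sample_id[m$material == "tissue"]))
  attr(lg, "stage") <- "log2cpm"
  fit <- geneset_anova(build_model_table(lg, genes, m, "BCC", dm, "APC",
                                         exposure_threshold = 192))
  expect_equal(stratum_fc(fit, 0L, 1L)$n_cases, 11L)
  expect_equal(stratum_fc(fit, 1L, 1L)$n_cases, 6L)
  expect_equal(stratum_fc(fit, 0L, 0L)$n_cases, 5L)
  expect_equal(stratum_fc(fit, 1L, 0L)$n_cases, 4L)
})

test_that("model object supports the standard generics", {
  set.seed(109)
  tab <- random_table(3L, 5L, 4L)
  fit <- geneset_anova(tab)
  expect_s3_class(fit, "geneset_anova")
  expect_output(print(fit), "Gene-set ANOVA")
  s <- summary(fit)
  expect_s3_class(s, "summary.geneset_anova")
  expect_output(print(s), "interaction")
  expect_length(residuals(fit), nrow(tab))
  expect_equal(fitted(fit) + residuals(fit), tab$y, ignore_attr = TRUE)
  expect_equal(unname(predict(fit, newdata = tab[1L, ])),
               unname(fitted(fit)[1L]), tolerance = 1e-10)
  sim <- simulate(fit, nsim = 2L, seed = 1L)
  expect_equal(dim(sim), c(nrow(tab), 2L))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
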