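# The gene-set ANOVA: an ordinary-least-squares model of log2 CPM over all
# genes of a set jointly,
#
#   y = mu + tissue + gene + tissue:gene + tissue:mut
#       [ + tissue:as_high + tissue:mut:as_high ]      (exposure extension)
#
# with treatment (reference-level) coding, a single pooled error variance,
# and the tumour-vs-healthy contrast averaged over the set's genes reported
# per stratum as a signed fold change with a t-based 95% CI.  Healthy-skin
# controls are independent patients, so `mut` is 0 for them by construction
# and the tissue:mut term compares the tumour shift of DEL carriers against
# non-carriers over shared controls.  No arsenic main effect is modelled:
# exposure enters only through its interaction with tissue.

#' Fit the gene-set ANOVA
#'
#' @param table Long model table from [build_model_table()] (columns `y`,
#'   `gene`, `tissue`, `mut`, optionally `as_high`).
#' @param exposure Include the arsenic-exposure interaction terms
#'   (`tissue:as_high`, `tissue:mut:as_high`).  Default: `TRUE` when the
#'   table has an `as_high` column.
#' @return Object of class `geneset_anova`: the underlying `lm` fit plus the
#'   gene levels, stratum sample counts and term bookkeeping.  Aliased
#'   (rank-deficient) columns are dropped with a message.
#' @export
geneset_anova <- function(table, exposure = "as_high" %in% names(table)) {
  req <- c("sample_id", "y", "gene", "tissue", "mut")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L)
    stop("model table is missing column(s): ", paste(missing, collapse = ", "))
  if (exposure && !"as_high" %in% names(table))
    stop("exposure = TRUE requires an as_high column")
  if (length(unique(table$tissue)) < 2L)
    stop("both tissue classes (healthy and tumour) must be present")
  tab <- table
  tab$gene <- factor(tab$gene)
  genes <- levels(tab$gene)
  multi_gene <- length(genes) >= 2L

  rhs <- c(if (multi_gene) c("gene", "tissue", "gene:tissue") else "tissue",
           "tissue:mut",
           if (exposure) c("tissue:as_high", "tissue:mut:as_high"))
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(form, data = tab)

  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) > 0L)
    message("dropping aliased column(s): ", paste(aliased, collapse = ", "))
  if (fit$df.residual <= 0L)
    stop("no residual degrees of freedom; design is saturated")

  # distinct tumour samples per (mut [, as]) stratum
  tum <- unique(tab[tab$tissue == 1L,
                    c("sample_id", "mut", if (exposure) "as_high"),
                    drop = FALSE])
  structure(list(lm = fit, genes = genes, exposure = exposure,
                 formula = form, data = tab, n_tumor = nrow(tum),
                 stratum_table = tum),
            class = "geneset_anova")
}

# Contrast vector for the tumour-minus-healthy mean log2 CPM difference in
# stratum (mut = m, as_high = a), averaged over the set's genes.
stratum_contrast <- function(object, mut, as_high = NULL) {
  fit <- object$lm
  cn <- names(coef(fit))
  w <- stats::setNames(numeric(length(cn)), cn)
  G <- length(object$genes)
  tissue_cols <- cn[cn == "tissue"]
  if (length(tissue_cols) != 1L) stop("tissue term not found in fit")
  w["tissue"] <- 1
  ix <- grepl("^gene.*:tissue$|^tissue:gene", cn)
  if (any(ix)) w[ix] <- 1 / G
  if (mut == 1L) {
    if (!"tissue:mut" %in% cn) stop("tissue:mut term not found in fit")
    w["tissue:mut"] <- 1
  }
  if (!is.null(as_high)) {
    if (!object$exposure)
      stop("model was fitted without exposure terms")
    if (as_high == 1L) w["tissue:as_high"] <- 1
    if (as_high == 1L && mut == 1L) w["tissue:mut:as_high"] <- 1
  }
  w
}

#' Signed fold change from a log2 difference
#'
#' Maps a log2 expression difference `d` to the signed-ratio convention used
#' for reporting: `2^d` when `d >= 0`, `-2^(-d)` when `d < 0`, so a halving
#' reads as -2 rather than 0.5 and `signed_fc(0) == 1` exactly.
#'
#' @param d Numeric vector of log2 differences.
#' @return Signed fold changes.
#' @export
signed_fc <- function(d) ifelse(d >= 0, 2^d, -(2^(-d)))

#' Tumour-vs-healthy fold change for one stratum
#'
#' Estimated marginal contrast: the tumour-minus-healthy difference in mean
#' log2 CPM for tumour samples with DEL status `mut` (and, in the exposure
#' model, arsenic stratum `as_high`), averaged with equal weights over the
#' set's genes.  The 95% CI uses the t distribution on the fit's residual
#' degrees of freedom; point estimate and both bounds are converted to
#' signed fold changes.
#'
#' @param object `geneset_anova` fit.
#' @param mut 0 (no DEL in the target gene) or 1 (carrier).
#' @param as_high For exposure fits: 0 (low) or 1 (high arsenic stratum).
#' @param level Confidence level.
#' @return List: `d` (log2 contrast), `se`, `fc`, `ci_low`, `ci_high`
#'   (signed FC scale), `n_cases` (distinct tumour samples in the stratum).
#' @export
stratum_fc <- function(object, mut, as_high = NULL, level = 0.95) {
  stopifnot(inherits(object, "geneset_anova"))
  w <- stratum_contrast(object, mut, as_high)
  beta <- coef(object$lm)
  if (any(w[is.na(beta)] != 0))
    stop("requested stratum involves aliased (absent) design columns")
  ok <- !is.na(beta)
  V <- stats::vcov(object$lm, complete = FALSE)  # estimable coefs only
  d <- sum(w[ok] * beta[ok])
  se <- sqrt(drop(t(w[ok]) %*% V %*% w[ok]))
  tcrit <- stats::qt(1 - (1 - level) / 2, object$lm$df.residual)
  lo <- d - tcrit * se
  hi <- d + tcrit * se
  st <- object$stratum_table
  n_cases <- if (is.null(as_high)) sum(st$mut == mut) else
    sum(st$mut == mut & st$as_high == as_high)
  if (!is.null(as_high) && !any(st$mut == mut & st$as_high == as_high))
    stop("no tumour samples in stratum mut=", mut, ", as_high=", as_high)
  list(d = d, se = se, fc = signed_fc(d), ci_low = signed_fc(lo),
       ci_high = signed_fc(hi), n_cases = n_cases)
}

#' Extra-sum-of-squares F test of one model term
#'
#' Compares the fitted model against the same model with the named term's
#' design columns removed; F = ((RSS0 - RSS1)/q) / (RSS1/df_res) with q the
#' rank difference, p from the F distribution.  For a single-coefficient
#' term this equals the squared t statistic of that coefficient.
#'
#' @param object `geneset_anova` fit.
#' @param term Term label as in the model formula (e.g. `"tissue:mut"`,
#'   `"tissue:mut:as_high"`).
#' @return List: `f_ratio`, `p`, `df` (numerator), `df_residual`.
#' @export
interaction_test <- function(object, term = if (object$exposure)
                               "tissue:mut:as_high" else "tissue:mut") {
  stopifnot(inherits(object, "geneset_anova"))
  fit <- object$lm
  labels <- attr(stats::terms(fit), "term.labels")
  ti <- match(term, labels)
  if (is.na(ti)) {
    # interaction labels may be stored with factors ordered differently
    norm <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                               function(p) paste(sort(p), collapse = ":"),
                               character(1L))
    ti <- match(norm(term), norm(labels))
  }
  if (is.na(ti))
    stop("term '", term, "' is not in the fitted model (terms: ",
         paste(labels, collapse = ", "), ")")
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  y <- fit$model$y
  keep <- asgn != ti
  fit0 <- stats::lm.fit(X[, keep, drop = FALSE], y)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum(fit0$residuals^2)
  q <- fit$rank - fit0$rank
  if (q <= 0L) stop("term '", term, "' contributes no estimable columns")
  df1 <- fit$df.residual
  f <- ((rss0 - rss1) / q) / (rss1 / df1)
  list(f_ratio = f, p = stats::pf(f, q, df1, lower.tail = FALSE),
       df = q, df_residual = df1)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m = length(pvals)` (delegates to
#' [stats::p.adjust()]) after validating the inputs.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Screen gene sets for tissue-by-DEL (and exposure) interactions
#'
#' Fits the gene-set ANOVA to every gene set, reports per-stratum signed
#' fold changes with 95% CIs, the interaction F test (tissue:mut, or
#' tissue:mut:as_high when an exposure threshold is supplied) and
#' Bonferroni-adjusted p across the sets tested.  Results are sorted by
#' interaction p ascending.
#'
#' @param log2cpm log2 CPM matrix ([log2_cpm()]).
#' @param gene_sets Named list of gene symbol vectors ([read_gmt()]).
#' @param manifest Validated manifest.
#' @param subtype `"BCC"` or `"SCC"`.
#' @param del_matrix `gene_del_matrix` from [gene_del_status()].
#' @param target_gene Gene whose DEL status defines `mut`.
#' @param exposure_threshold Optional UACR cut (ug/g) activating the
#'   gene-environment model.
#' @param stratified When `TRUE` (exposure model only), the four stratum
#'   fold changes come from separate per-stratum fits (each exposure stratum
#'   against its own controls, or against all controls when
#'   `pooled_controls = TRUE`); the interaction p is always from the joint
#'   model.
#' @param pooled_controls In stratified mode, compare each exposure stratum
#'   against all healthy controls instead of stratum-matched controls.
#' @return data.frame, one row per gene set, with fold-change/CI/n columns
#'   per stratum (`del0`/`del1`, crossed with `as_low`/`as_high` in the
#'   exposure model), `f_ratio`, `interaction_term`, `interaction_p` and
#'   `bonferroni_p`.
#' @export
run_pathway_screen <- function(log2cpm, gene_sets, manifest, subtype,
                               del_matrix, target_gene,
                               exposure_threshold = NULL,
                               stratified = FALSE, pooled_controls = FALSE) {
  stopifnot(length(gene_sets) > 0L)
  exposure <- !is.null(exposure_threshold)
  rows <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    tab <- build_model_table(log2cpm, gene_sets[[i]], manifest, subtype,
                             del_matrix, target_gene,
                             exposure_threshold = exposure_threshold)
    fit <- geneset_anova(tab, exposure = exposure)
    it <- interaction_test(fit)
    row <- list(gene_set = names(gene_sets)[i],
                n_genes = length(fit$genes))
    strata <- if (exposure)
      expand.grid(as_high = c(1L, 0L), mut = c(0L, 1L))[, c(2L, 1L)]
    else data.frame(mut = c(0L, 1L))
    for (j in seq_len(nrow(strata))) {
      m <- strata$mut[j]
      a <- if (exposure) strata$as_high[j] else NULL
      est <- if (exposure && stratified)
        stratified_stratum_fc(tab, m, a, pooled_controls)
      else stratum_fc(fit, m, a)
      lab <- paste0("del", m, if (exposure)
        paste0("_", if (a == 1L) "as_high" else "as_low"))
      row[[paste0("fc_", lab)]] <- est$fc
      row[[paste0("ci_low_", lab)]] <- est$ci_low
      row[[paste0("ci_high_", lab)]] <- est$ci_high
      row[[paste0("n_", lab)]] <- est$n_cases
    }
    row$f_ratio <- it$f_ratio
    row$interaction_term <- if (exposure) "tissue:mut:as_high" else
      "tissue:mut"
    row$interaction_p <- it$p
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$bonferroni_p <- bonferroni_adjust(res$interaction_p)
  res <- res[order(res$interaction_p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Stratified alternative: fit the base (no-exposure) model inside one
# exposure stratum, tumour samples of that stratum against stratum-matched
# (or pooled) healthy controls.
stratified_stratum_fc <- function(tab, mut, as_high, pooled_controls) {
  keep <- (tab$tissue == 1L & tab$as_high == as_high) |
    (tab$tissue == 0L & (pooled_controls | tab$as_high == as_high))
  sub <- tab[keep, setdiff(names(tab), "as_high"), drop = FALSE]
  fit <- geneset_anova(sub, exposure = FALSE)
  stratum_fc(fit, mut)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.geneset_anova <- function(x, ...) {
  cat("Gene-set ANOVA (OLS, pooled variance)\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  %d genes, %d observations, residual df %d\n",
              length(x$genes), nrow(x$data), x$lm$df.residual))
  invisible(x)
}

#' @export
summary.geneset_anova <- function(object, ...) {
  strata <- if (object$exposure)
    expand.grid(mut = 0:1, as_high = 0:1) else data.frame(mut = 0:1)
  ests <- lapply(seq_len(nrow(strata)), function(j) {
    a <- if (object$exposure) strata$as_high[j] else NULL
    est <- tryCatch(stratum_fc(object, strata$mut[j], a),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(mut = strata$mut[j],
               as_high = if (object$exposure) strata$as_high[j] else NA,
               n_cases = est$n_cases, log2_diff = est$d, se = est$se,
               fc = est$fc, ci_low = est$ci_low, ci_high = est$ci_high)
  })
  it <- interaction_test(object)
  out <- list(strata = do.call(rbind, ests), interaction = it,
              term = if (object$exposure) "tissue:mut:as_high" else
                "tissue:mut",
              sigma = summary(object$lm)$sigma, formula = object$formula)
  class(out) <- "summary.geneset_anova"
  out
}

#' @export
print.summary.geneset_anova <- function(x, ...) {
  cat("Gene-set ANOVA:", deparse(x$formula), "\n")
  cat(sprintf("residual SD %.3f (log2 CPM)\n\n", x$sigma))
  df <- x$strata
  df$fc <- sprintf("%.2f", df$fc)
  df$ci <- sprintf("(%.2f to %.2f)", x$strata$ci_low, x$strata$ci_high)
  print(df[, c("mut", "as_high", "n_cases", "fc", "ci")], row.names = FALSE)
  cat(sprintf("\n%s interaction: F = %.2f (df %d, %d), p = %.3g\n",
              x$term, x$interaction$f_ratio, x$interaction$df,
              x$interaction$df_residual, x$interaction$p))
  invisible(x)
}

#' @export
coef.geneset_anova <- function(object, ...) coef(object$lm)

#' @export
confint.geneset_anova <- function(object, parm, level = 0.95, ...)
  stats::confint(object$lm, parm, level, ...)

#' @export
predict.geneset_anova <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  newdata$gene <- factor(newdata$gene, levels = object$genes)
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.geneset_anova <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.geneset_anova <- function(object, ...) stats::fitted(object$lm)

#' @export
simulate.geneset_anova <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)

#' Diagnostic plot: per-gene tumour vs healthy means
#'
#' Scatter of each gene's mean log2 CPM in healthy skin (x) against tumour
#' (y), one point per gene and DEL stratum, with the identity line; vertical
#' displacement from the line is the gene's log2 fold change.
#'
#' @param x `geneset_anova` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.geneset_anova <- function(x, ...) {
  tab <- x$data
  healthy <- tapply(tab$y[tab$tissue == 0L], tab$gene[tab$tissue == 0L], mean)
  cols <- c("#1b6ca8", "#c1403d")
  first <- TRUE
  for (m in sort(unique(tab$mut[tab$tissue == 1L]))) {
    sel <- tab$tissue == 1L & tab$mut == m
    tum <- tapply(tab$y[sel], factor(tab$gene[sel], names(healthy)), mean)
    if (first) {
      graphics::plot(healthy, tum, pch = 19, col = cols[m + 1L],
                     xlab = "healthy skin mean log2 CPM",
                     ylab = "tumour mean log2 CPM", ...)
      graphics::abline(0, 1, lty = 2)
      first <- FALSE
    } else graphics::points(healthy, tum, pch = 19, col = cols[m + 1L])
  }
  graphics::legend("topleft", legend = c("DEL -", "DEL +"), col = cols,
                   pch = 19, bty = "n")
  invisible(x)
}
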