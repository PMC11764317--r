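# Readers/writers for the formats the pipeline touches: variant tables
# (CLC-style TSV or VCF), sample manifests, GMT gene sets, gene-count
# matrices and BED-like gene maps.  Everything lands in plain data.frames
# with a fixed column contract so downstream set algebra is
# representation-independent.

#' Canonical variant-table columns
#'
#' Column contract for a variant-call table: one row per called variant in
#' one sample.  Coordinates are 1-based and inclusive; `start` is the first
#' affected reference base and `end` the last.  A pure deletion stores the
#' deleted bases in `ref_allele` and `"-"` in `alt_allele`; an insertion the
#' reverse.  `frequency` is the variant allele frequency in percent (0-100).
#'
#' @return Character vector of required column names.
#' @export
variant_columns <- function() {
  c("sample_id", "chrom", "start", "end", "var_type", "ref_allele",
    "alt_allele", "coverage", "alt_count", "frequency", "avg_quality")
}

VAR_TYPES <- c("SNV", "INS", "DEL", "MNV")

#' Validate a variant-call table
#'
#' Checks the invariants of the internal variant model: required columns,
#' `end >= start`, deletion rows spanning exactly `nchar(ref_allele)` bases
#' with `alt_allele == "-"`, `alt_count <= coverage`, and `frequency`
#' consistent with `alt_count / coverage` within one percentage point when
#' coverage is positive.
#'
#' @param calls data.frame with the columns of [variant_columns()].
#' @return The input, invisibly, after validation.
#' @export
validate_variant_calls <- function(calls) {
  missing <- setdiff(variant_columns(), names(calls))
  if (length(missing) > 0L)
    stop("variant table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(calls))
  bad_type <- !calls$var_type %in% VAR_TYPES
  if (any(bad_type))
    stop("unknown var_type value(s): ",
         paste(unique(calls$var_type[bad_type]), collapse = ", "))
  if (any(calls$end < calls$start))
    stop("found record(s) with end < start")
  is_del <- calls$var_type == "DEL"
  if (any(is_del)) {
    span <- calls$end[is_del] - calls$start[is_del] + 1L
    if (any(nchar(calls$ref_allele[is_del]) != span))
      stop("DEL record(s) where nchar(ref_allele) != end - start + 1")
    if (any(calls$alt_allele[is_del] != "-"))
      stop("DEL record(s) with alt_allele != '-'")
  }
  if (any(calls$alt_count > calls$coverage))
    stop("record(s) with alt_count > coverage")
  if (any(calls$coverage < 0L) || any(calls$alt_count < 0L) ||
      any(calls$avg_quality < 0))
    stop("negative coverage, alt_count or avg_quality")
  has_cov <- calls$coverage > 0L
  if (any(has_cov)) {
    implied <- 100 * calls$alt_count[has_cov] / calls$coverage[has_cov]
    if (any(abs(implied - calls$frequency[has_cov]) > 1 + 1e-9))
      stop("record(s) where frequency disagrees with alt_count/coverage ",
           "by more than 1 percentage point")
  }
  invisible(calls)
}

#' Read a variant table (TSV or VCF dialect)
#'
#' TSV files must carry the columns of [variant_columns()] (any order).  VCF
#' records are normalized on import: the shared anchor base of an
#' indel (REF `"CAA"`, ALT `"C"`) is stripped so a deletion becomes the pure
#' internal representation (start shifted past the anchor, `alt_allele "-"`),
#' making TSV- and VCF-derived coordinate keys directly comparable.
#' Coordinates are 1-based inclusive throughout.  Chromosome names are taken
#' verbatim; set `harmonize_chr = TRUE` to strip a leading `"chr"`.
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_id Sample identifier to assign to VCF records (a TSV carries
#'   its own `sample_id` column).
#' @param harmonize_chr Strip a leading `"chr"` from chromosome names.
#' @return data.frame of validated variant calls.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               sample_id = NULL, harmonize_chr = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  calls <- if (dialect == "tsv") read_variant_tsv(path) else
    read_variant_vcf(path, sample_id)
  if (harmonize_chr) calls$chrom <- sub("^chr", "", calls$chrom)
  if (nrow(calls) == 0L) warning("no variant records in ", path)
  validate_variant_calls(calls)
  calls
}

read_variant_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(variant_columns(), names(df))
  if (length(missing) > 0L)
    stop("variant TSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, variant_columns(), drop = FALSE]
  bad <- which(is.na(suppressWarnings(as.integer(df$start))) |
               is.na(suppressWarnings(as.integer(df$end))))
  if (length(bad) > 0L)
    stop("malformed coordinate at data line ", bad[1L], " of ", path)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$coverage <- as.integer(df$coverage)
  df$alt_count <- as.integer(df$alt_count)
  df$ref_allele <- toupper(df$ref_allele)
  df
}

read_variant_vcf <- function(path, sample_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_variant_table())
  }
  if (is.null(sample_id)) {
    sample_id <- if (ncol(v@gt) >= 2L) colnames(v@gt)[2L] else basename(path)
  }
  dp <- ad_alt <- rep(NA_integer_, nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    gt_dp <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE),
                      error = function(e) NULL)
    if (!is.null(gt_dp)) dp <- as.integer(gt_dp[, 1L])
    gt_ad <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
    if (!is.null(gt_ad))
      ad_alt <- as.integer(vapply(strsplit(gt_ad[, 1L], ","), function(x)
        if (length(x) >= 2L) x[2L] else NA_character_, character(1L)))
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(pos)) stop("malformed coordinate in VCF record ", i, " of ", path)
    norm <- normalize_vcf_alleles(pos, toupper(fix$REF[i]), toupper(fix$ALT[i]))
    cov <- dp[i]; alt_n <- ad_alt[i]
    if (is.na(cov)) cov <- 0L
    if (is.na(alt_n)) alt_n <- 0L
    out[[i]] <- data.frame(
      sample_id = sample_id, chrom = fix$CHROM[i],
      start = norm$start, end = norm$end, var_type = norm$var_type,
      ref_allele = norm$ref, alt_allele = norm$alt,
      coverage = cov, alt_count = alt_n,
      frequency = if (cov > 0L) 100 * alt_n / cov else 0,
      avg_quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df$avg_quality[is.na(df$avg_quality)] <- 0
  df
}

# Strip the shared left anchor of a VCF REF/ALT pair and classify the
# variant.  Idempotent: alleles with no shared prefix pass through unchanged.
normalize_vcf_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) > 1L && nchar(alt) == 1L && substr(ref, 1L, 1L) == alt) {
    # deletion with anchor base still attached: CAA > C
    ref <- substr(ref, 2L, nchar(ref)); pos <- pos + 1L; alt <- "-"
  } else if (nchar(alt) > 1L && nchar(ref) == 1L && substr(alt, 1L, 1L) == ref) {
    alt <- substr(alt, 2L, nchar(alt)); ref <- "-"
  }
  if (ref == "-") {
    list(start = pos, end = pos, var_type = "INS", ref = "-", alt = alt)
  } else if (alt == "-" || nchar(alt) == 0L) {
    list(start = pos, end = pos + nchar(ref) - 1L, var_type = "DEL",
         ref = ref, alt = "-")
  } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
    list(start = pos, end = pos, var_type = "SNV", ref = ref, alt = alt)
  } else {
    list(start = pos, end = pos + nchar(ref) - 1L, var_type = "MNV",
         ref = ref, alt = alt)
  }
}

empty_variant_table <- function() {
  df <- data.frame(sample_id = character(), chrom = character(),
                   start = integer(), end = integer(), var_type = character(),
                   ref_allele = character(), alt_allele = character(),
                   coverage = integer(), alt_count = integer(),
                   frequency = numeric(), avg_quality = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Write a variant table to TSV
#'
#' Writes the canonical column set; [read_variant_table()] on the result
#' reproduces the input field-by-field.
#'
#' @param calls Validated variant-call data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  validate_variant_calls(calls)
  write.table(calls[, variant_columns(), drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest has one row per sequenced sample with columns `patient_id`,
#' `sample_id`, `material` (`tissue`/`blood`), `tissue_class`
#' (`tumor`/`healthy_skin`/`none`), `tumor_subtype` (`BCC`/`SCC`/`none`) and
#' `uacr` (urinary arsenic-creatinine ratio, ug/g).  Invariants enforced:
#' blood samples carry no tissue class, a tumour subtype implies a tumour
#' tissue class, sample ids are unique, and every tissue sample has exactly
#' one matched blood sample from the same patient.
#'
#' @param path File path, or a data.frame to validate in place.
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, stringsAsFactors = FALSE)
  }
  req <- c("patient_id", "sample_id", "material", "tissue_class",
           "tumor_subtype", "uacr")
  missing <- setdiff(req, names(m))
  if (length(missing) > 0L)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  if (!all(m$material %in% c("tissue", "blood")))
    stop("material must be 'tissue' or 'blood'")
  if (!all(m$tissue_class %in% c("tumor", "healthy_skin", "none")))
    stop("tissue_class must be 'tumor', 'healthy_skin' or 'none'")
  if (!all(m$tumor_subtype %in% c("BCC", "SCC", "none")))
    stop("tumor_subtype must be 'BCC', 'SCC' or 'none'")
  if (any(m$material == "blood" & m$tissue_class != "none"))
    stop("blood samples must have tissue_class 'none'")
  if (any(m$tumor_subtype != "none" & m$tissue_class != "tumor"))
    stop("tumor_subtype set for a non-tumor sample")
  if (any(!is.na(m$uacr) & m$uacr <= 0))
    stop("uacr must be positive")
  tissue <- m[m$material == "tissue", ]
  blood_by_patient <- table(m$patient_id[m$material == "blood"])
  n_blood <- as.integer(blood_by_patient[tissue$patient_id])
  n_blood[is.na(n_blood)] <- 0L
  unmatched <- unique(tissue$patient_id[n_blood != 1L])
  if (length(unmatched) > 0L)
    stop("tissue sample(s) without exactly one matched blood sample for ",
         "patient(s): ", paste(unmatched, collapse = ", "))
  m
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line a set name, a description, then tab-separated gene
#' symbols.  Duplicate symbols within a line are collapsed with a warning;
#' empty lines are skipped; a line with fewer than three fields is an error.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " (", fields[1L],
              "): duplicate gene symbols collapsed")
      genes <- unique(genes)
    }
    sets[[fields[1L]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-count matrix (genes x samples TSV)
#'
#' First column gene symbols, remaining columns one per sample.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_counts_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (any(mat < 0, na.rm = TRUE)) stop("negative counts in ", path)
  mat
}

#' Read a BED-like gene map into genomic intervals
#'
#' Tab-separated `chrom`, `start`, `end`, `gene` with BED conventions
#' (0-based half-open intervals).  Used to assign each deletion to the gene
#' whose interval contains its start coordinate.
#'
#' @param path BED-like file, or a data.frame with 1-based inclusive
#'   `chrom`/`start`/`end`/`gene` columns (passed through).
#' @return `GRanges` with a `gene` metadata column (1-based inclusive).
#' @export
read_gene_map <- function(path) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("gene map needs 4 columns: chrom start end gene")
    df <- data.frame(chrom = df[[1L]], start = as.integer(df[[2L]]) + 1L,
                     end = as.integer(df[[3L]]), gene = df[[4L]],
                     stringsAsFactors = FALSE)
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         gene = df$gene)
}
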