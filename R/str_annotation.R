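# Homopolymer / simple-repeat context of deletions on the reference
# sequence.  A deletion is "in" a homopolymer when its deleted bases are all
# one base B and the maximal run of B containing the deleted span (extending
# in both directions on the pre-deletion reference) has length >= min_run.

#' Annotate deletions with their homopolymer context
#'
#' For every unique deletion coordinate, verifies the deleted sequence
#' against the reference and measures the maximal run of identical reference
#' bases containing the deleted span.  Mixed-base deletions get
#' `unit_base = NA` and are never in a homopolymer.
#'
#' @param reference `DNAStringSet` (named by chromosome) or path to a FASTA
#'   file.
#' @param dels Event/key table ([del_events()] output, a `del_partition`
#'   class vector of keys, or any character vector of deletion keys).
#' @param min_run Minimum run length (in reference bases) for
#'   `in_homopolymer`; the shortest repeat tract treated as a homopolymer.
#' @return data.frame with one row per unique key: `key`, `chrom`, `start`,
#'   `end`, `deleted_seq`, `unit_base`, `run_length`, `in_homopolymer`.
#' @export
homopolymer_context <- function(reference, dels, min_run = 3L) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  stopifnot(inherits(reference, "DNAStringSet"), min_run >= 1L)
  names(reference) <- sub("\\s.*$", "", names(reference))
  keys <- if (is.character(dels)) dels else dels$key
  df <- del_key_table(keys)
  n <- nrow(df)
  unit <- rep(NA_character_, n)
  run <- rep(1L, n)
  for (i in seq_len(n)) {
    chrom <- df$chrom[i]
    if (!chrom %in% names(reference))
      stop("chromosome ", chrom, " not in reference")
    chrom_seq <- reference[[chrom]]
    L <- length(chrom_seq)
    if (df$start[i] < 1L || df$end[i] > L)
      stop("deletion span ", del_key(df[i, ]), " outside contig ", chrom)
    ref_span <- as.character(Biostrings::subseq(chrom_seq, df$start[i],
                                                df$end[i]))
    if (ref_span != df$deleted_seq[i])
      stop("reference mismatch at ", chrom, ":", df$start[i], "-", df$end[i],
           " (reference ", ref_span, ", call ", df$deleted_seq[i], ")")
    bases <- strsplit(df$deleted_seq[i], "", fixed = TRUE)[[1L]]
    if (length(unique(bases)) == 1L) {
      unit[i] <- bases[1L]
      run[i] <- max_run_at(chrom_seq, df$start[i], df$end[i], bases[1L])
    } else {
      run[i] <- NA_integer_
    }
  }
  df$key <- del_key(df)
  df$unit_base <- unit
  df$run_length <- run
  df$in_homopolymer <- !is.na(unit) & !is.na(run) & run >= min_run
  rownames(df) <- NULL
  df
}

# Maximal run of `base` in `chrom_seq` containing [start, end], scanning
# outwards in windows so long tracts never truncate.
max_run_at <- function(chrom_seq, start, end, base) {
  L <- length(chrom_seq)
  window <- 64L
  lo <- start
  repeat {
    from <- max(1L, lo - window)
    chars <- strsplit(as.character(Biostrings::subseq(chrom_seq, from,
                                                      lo - 1L)), "",
                      fixed = TRUE)[[1L]]
    ext <- 0L
    for (j in rev(seq_along(chars))) {
      if (chars[j] == base) ext <- ext + 1L else break
    }
    lo <- lo - ext
    if (ext < length(chars) || from == 1L) break
  }
  hi <- end
  repeat {
    to <- min(L, hi + window)
    chars <- strsplit(as.character(Biostrings::subseq(chrom_seq, hi + 1L,
                                                      to)), "",
                      fixed = TRUE)[[1L]]
    ext <- 0L
    for (j in seq_along(chars)) {
      if (chars[j] == base) ext <- ext + 1L else break
    }
    hi <- hi + ext
    if (ext < length(chars) || to == L) break
  }
  hi - lo + 1L
}

#' Summarize homopolymer context over a set of DEL events
#'
#' @param annotations Annotation table from [homopolymer_context()], covering
#'   every key that occurs in `events`.
#' @param events Event table from [del_events()].
#' @return List: `n_events`, `n_events_homopolymer`, `n_coords`,
#'   `n_coords_homopolymer`, the corresponding fractions, `run_range`
#'   (min/max run length among homopolymer deletions) and `run_histogram`
#'   (table of run lengths over homopolymer coordinates).
#' @export
summarize_str <- function(annotations, events) {
  missing <- setdiff(unique(events$key), annotations$key)
  if (length(missing) > 0L)
    stop("events reference unannotated key(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  hp_keys <- annotations$key[annotations$in_homopolymer]
  coords <- unique(events$key)
  ev_hp <- sum(events$key %in% hp_keys)
  co_hp <- sum(coords %in% hp_keys)
  runs <- annotations$run_length[annotations$in_homopolymer &
                                 annotations$key %in% coords]
  list(n_events = nrow(events),
       n_events_homopolymer = ev_hp,
       frac_events_homopolymer = if (nrow(events) > 0L)
         ev_hp / nrow(events) else NA_real_,
       n_coords = length(coords),
       n_coords_homopolymer = co_hp,
       frac_coords_homopolymer = if (length(coords) > 0L)
         co_hp / length(coords) else NA_real_,
       run_range = if (length(runs) > 0L) range(runs) else integer(),
       run_histogram = table(runs))
}
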