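# Trim -> merge -> primer-split chain for paired amplicon reads.

#' Sliding-window quality trimming
#'
#' Keeps, for each read, the longest prefix in which every sliding window of
#' `window_len` bases has mean Phred quality at or above the threshold
#' (whole-prefix mean for prefixes shorter than one window). Reads shorter
#' than `min_len` after trimming are discarded. Trimming never lengthens a
#' read.
#'
#' @param reads `data.frame` with `id`, `seq`, `qual` (Phred+33), e.g. from
#'   [read_fastq()].
#' @param window_len Window size in bases.
#' @param mean_q_threshold Minimum mean window quality.
#' @param min_len Minimum retained length after trimming.
#' @return List with `kept` (trimmed `data.frame`) and `discarded`
#'   (character vector of read ids).
#' @export
quality_trim <- function(reads, window_len = 4L, mean_q_threshold = 20,
                         min_len = 100L) {
  stopifnot(window_len >= 1)
  lens <- trim_lengths_cpp(reads$qual, as.integer(window_len),
                           mean_q_threshold)
  keep <- lens >= min_len
  kept <- reads[keep, , drop = FALSE]
  kept$seq <- substr(kept$seq, 1L, lens[keep])
  kept$qual <- substr(kept$qual, 1L, lens[keep])
  rownames(kept) <- NULL
  list(kept = kept, discarded = reads$id[!keep])
}

#' Merge read pairs by overlap
#'
#' The reverse mate is reverse-complemented and the best overlap of at least
#' `min_overlap` nt is chosen as the one minimising the mismatch fraction,
#' ties going to the longer overlap. At each overlap mismatch the
#' higher-quality base wins. Pairs with no overlap at or below
#' `max_mismatch_frac` are returned unmerged.
#'
#' @param fwd,rev `data.frame`s with `id`, `seq`, `qual`, matched by row.
#' @param min_overlap Minimum acceptable overlap (nt).
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return `data.frame` with `id`, `merged`, `sequence`, `quality`,
#'   `overlap`, `mismatches`; unmerged pairs carry NA sequence.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 30L, max_mismatch_frac = 0.1) {
  stopifnot(nrow(fwd) == nrow(rev))
  if (nrow(fwd) == 0)
    return(data.frame(id = character(), merged = logical(),
                      sequence = character(), quality = character(),
                      overlap = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  if (any(nchar(fwd$seq) == 0) || any(nchar(rev$seq) == 0))
    stop("zero-length mate")
  rev_rc <- revcomp(rev$seq)
  rq <- as.character(Biostrings::reverse(Biostrings::BStringSet(rev$qual)))
  res <- merge_pairs_cpp(fwd$seq, fwd$qual, rev_rc, rq,
                         as.integer(min_overlap), max_mismatch_frac)
  data.frame(id = fwd$id, merged = res$merged, sequence = res$sequence,
             quality = res$quality, overlap = res$overlap,
             mismatches = res$mismatches, stringsAsFactors = FALSE)
}

#' Split merged reads by marker primers
#'
#' Looks for a forward primer anchored at the 5' end and the
#' reverse-complemented reverse primer anchored at the 3' end (within a small
#' slack window), under IUPAC-aware comparison with at most `max_mismatches`
#' mismatches per primer. Both primers must belong to the same marker; reads
#' matching two markers are rejected as ambiguous, and primer-stripped inserts
#' shorter than `min_insert` nt are rejected as short. Ambiguous read bases
#' (including N) count as mismatches unless `allow_ambig_read`.
#'
#' @param sequences Character vector of merged sequences.
#' @param primer_defs List of [primer_def()] objects with unique marker ids.
#' @param max_mismatches Per-primer mismatch tolerance (default 0, strict).
#' @param slack Anchor slack in nt at either end.
#' @param min_insert Minimum primer-stripped insert length.
#' @param allow_ambig_read Whether ambiguous read bases may satisfy a primer
#'   code by intersection.
#' @return `data.frame` with `marker` (NA when rejected), `insert` and
#'   `reason` (`assigned`, `no_primer`, `ambiguous_marker`, `short_insert`).
#' @export
split_by_primers <- function(sequences, primer_defs, max_mismatches = 0L,
                             slack = 2L, min_insert = 270L,
                             allow_ambig_read = FALSE) {
  stopifnot(length(primer_defs) > 0)
  ids <- unname(vapply(primer_defs, `[[`, character(1), "marker_id"))
  if (anyDuplicated(ids)) stop("marker ids must be unique")
  fwd <- vapply(primer_defs, `[[`, character(1), "forward_seq")
  rev_rc <- revcomp(vapply(primer_defs, `[[`, character(1), "reverse_seq"))
  res <- split_reads_cpp(sequences, fwd, rev_rc, as.integer(max_mismatches),
                         as.integer(slack), as.integer(min_insert),
                         allow_ambig_read)
  reason <- c("assigned", "no_primer", "ambiguous_marker",
              "short_insert")[res$reason + 1L]
  data.frame(marker = ids[res$marker], insert = as.character(res$insert),
             reason = reason, stringsAsFactors = FALSE)
}

#' Run the full read-processing chain for one sample
#'
#' trim -> merge -> primer split, with a per-stage accounting that partitions
#' every input pair into assigned / rejected / unmerged / trim-discarded.
#'
#' @param r1,r2 FASTQ paths for the two mates.
#' @param primer_defs Primer definitions.
#' @param window_len,mean_q_threshold,min_trim_len Trimming parameters.
#' @param min_overlap,max_mismatch_frac Merging parameters.
#' @param max_mismatches,slack,min_insert Primer-split parameters.
#' @return List with `inserts` (`data.frame`: `id`, `marker`, `insert`),
#'   `rejects` (`data.frame`: `id`, `stage`, `reason`) and `tally` (named
#'   counts; tally sums to the input pair count).
#' @export
process_sample_reads <- function(r1, r2, primer_defs,
                                 window_len = 4L, mean_q_threshold = 20,
                                 min_trim_len = 100L,
                                 min_overlap = 30L, max_mismatch_frac = 0.1,
                                 max_mismatches = 0L, slack = 2L,
                                 min_insert = 270L) {
  f <- read_fastq(r1)
  r <- read_fastq(r2)
  if (nrow(f) != nrow(r))
    stop("mate files disagree in read count: ", r1, " vs ", r2)
  n_in <- nrow(f)
  tf <- quality_trim(f, window_len, mean_q_threshold, min_trim_len)
  tr <- quality_trim(r, window_len, mean_q_threshold, min_trim_len)
  ok_ids <- intersect(tf$kept$id, tr$kept$id)
  trim_dropped <- setdiff(f$id, ok_ids)
  f2 <- tf$kept[match(ok_ids, tf$kept$id), , drop = FALSE]
  r2df <- tr$kept[match(ok_ids, tr$kept$id), , drop = FALSE]
  m <- merge_pairs(f2, r2df, min_overlap, max_mismatch_frac)
  unmerged_ids <- m$id[!m$merged]
  mm <- m[m$merged, , drop = FALSE]
  sp <- split_by_primers(mm$sequence, primer_defs, max_mismatches, slack,
                         min_insert)
  assigned <- !is.na(sp$marker)
  inserts <- data.frame(id = mm$id[assigned], marker = sp$marker[assigned],
                        insert = sp$insert[assigned], stringsAsFactors = FALSE)
  rejects <- rbind(
    if (length(trim_dropped))
      data.frame(id = trim_dropped, stage = "trim", reason = "low_quality",
                 stringsAsFactors = FALSE),
    if (length(unmerged_ids))
      data.frame(id = unmerged_ids, stage = "merge", reason = "no_overlap",
                 stringsAsFactors = FALSE),
    if (any(!assigned))
      data.frame(id = mm$id[!assigned], stage = "primer_split",
                 reason = sp$reason[!assigned], stringsAsFactors = FALSE))
  if (is.null(rejects))
    rejects <- data.frame(id = character(), stage = character(),
                          reason = character(), stringsAsFactors = FALSE)
  markers <- vapply(primer_defs, `[[`, character(1), "marker_id")
  tally <- c(input = n_in,
             trim_discarded = length(trim_dropped),
             unmerged = length(unmerged_ids),
             rejected = sum(!assigned),
             setNames(as.integer(table(factor(inserts$marker, levels = markers))),
                      paste0("assigned_", markers)))
  list(inserts = inserts, rejects = rejects, tally = tally)
}
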