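# In-silico audit: which checklist species have barcode records with usable
# primer binding sites?

#' Locate a marker's primer binding sites in a barcode record
#'
#' True when both the forward primer and the reverse-complemented reverse
#' primer occur in the sequence under IUPAC-aware comparison with at most
#' `max_mismatch` mismatches each, in consistent orientation (forward site
#' upstream of the reverse site) and with a spacing within +/-10% of the
#' marker's expected insert length.
#'
#' @param sequence Barcode DNA string.
#' @param primer_def A [primer_def()].
#' @param max_mismatch Per-primer mismatch tolerance.
#' @param spacing_tol Relative tolerance on the insert length.
#' @return List with `match` (logical), `fwd_pos`, `rev_pos` (1-based starts)
#'   and `insert_len`.
#' @export
primer_site_match <- function(sequence, primer_def, max_mismatch = 2L,
                              spacing_tol = 0.10) {
  fwd <- primer_scan_cpp(sequence, primer_def$forward_seq,
                         as.integer(max_mismatch))
  rev <- primer_scan_cpp(sequence, revcomp(primer_def$reverse_seq),
                         as.integer(max_mismatch))
  flen <- nchar(primer_def$forward_seq)
  exp_len <- primer_def$expected_insert_len
  lo <- (1 - spacing_tol) * exp_len
  hi <- (1 + spacing_tol) * exp_len
  for (f in fwd$pos) for (r in rev$pos) {
    ins <- r - (f + flen)
    if (ins >= lo && ins <= hi)
      return(list(match = TRUE, fwd_pos = f, rev_pos = r, insert_len = ins))
  }
  list(match = FALSE, fwd_pos = NA_integer_, rev_pos = NA_integer_,
       insert_len = NA_integer_)
}

normalize_name <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

#' Coverage audit of species checklists against database snapshots
#'
#' For every (checklist, database snapshot, marker) combination, counts the
#' checklist species with at least one barcode record (exact name match after
#' case/whitespace normalisation) and, among those, the species with a record
#' carrying both primer binding sites for the marker. The covered fraction is
#' based on intact primer sites; the record-only fraction is reported
#' alongside, since a record without primer sites cannot be amplified.
#'
#' @param checklists Named list of checklist `data.frame`s (`species`,
#'   `phylum`).
#' @param db_snapshots Named list of `reference_db` data frames.
#' @param primer_defs List of [primer_def()] objects.
#' @param max_mismatch Per-primer mismatch tolerance of the site search.
#' @return `data.frame` with one row per combination: `checklist`, `database`,
#'   `marker`, `n_species`, `n_with_record`, `n_with_primer_sites`,
#'   `fraction_with_record`, `fraction_covered`, plus attribute `by_phylum`.
#' @export
coverage_report <- function(checklists, db_snapshots, primer_defs,
                            max_mismatch = 2L) {
  if (!is.list(checklists) || is.data.frame(checklists))
    checklists <- list(checklist = checklists)
  if (is.data.frame(db_snapshots)) db_snapshots <- list(db = db_snapshots)
  rows <- list()
  phyl_rows <- list()
  for (cn in names(checklists)) {
    cl <- checklists[[cn]]
    if (is.null(cl) || nrow(cl) == 0) stop("empty checklist: ", cn)
    nm <- normalize_name(cl$species)
    if (anyDuplicated(nm)) {
      warning("duplicate species collapsed in checklist ", cn)
      cl <- cl[!duplicated(nm), , drop = FALSE]
      nm <- nm[!duplicated(nm)]
    }
    for (dn in names(db_snapshots)) {
      db <- db_snapshots[[dn]]
      db_nm <- normalize_name(db$species_name)
      for (pd in primer_defs) {
        has_rec <- nm %in% db_nm
        has_sites <- vapply(seq_along(nm), function(i) {
          if (!has_rec[i]) return(FALSE)
          seqs <- db$sequence[db_nm == nm[i]]
          any(vapply(seqs, function(s)
            primer_site_match(s, pd, max_mismatch)$match, logical(1)))
        }, logical(1))
        rows[[length(rows) + 1L]] <- data.frame(
          checklist = cn, database = dn, marker = pd$marker_id,
          n_species = nrow(cl), n_with_record = sum(has_rec),
          n_with_primer_sites = sum(has_sites),
          fraction_with_record = sum(has_rec) / nrow(cl),
          fraction_covered = sum(has_sites) / nrow(cl),
          stringsAsFactors = FALSE)
        ph <- do.call(rbind, lapply(sort(unique(cl$phylum)), function(p) {
          sel <- cl$phylum == p
          data.frame(checklist = cn, database = dn, marker = pd$marker_id,
                     phylum = p, n_species = sum(sel),
                     n_with_record = sum(has_rec & sel),
                     n_with_primer_sites = sum(has_sites & sel),
                     fraction_covered = sum(has_sites & sel) / sum(sel),
                     stringsAsFactors = FALSE)
        }))
        phyl_rows[[length(phyl_rows) + 1L]] <- ph
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "by_phylum") <- do.call(rbind, c(phyl_rows,
                                             list(make.row.names = FALSE)))
  out
}
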