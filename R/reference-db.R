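# Mock barcode reference databases (BOLD-style snapshots).
#
# FASTA header dialect: >record_id|species_name|phylum, with an empty species
# field for records lacking a species-level name.

#' Generate a mock reference database from a species pool
#'
#' A chosen fraction of the pool's species receive a barcode record; selection
#' is stratified within checklist class (native / invader / other) so a pool
#' built at fraction 0.46 has 46% of its native species represented, mirroring
#' the incomplete public barcode databases the audit quantifies. The output
#' always contains at least one terrestrial record and one record without a
#' species-level name, so downstream curation filters have work to do.
#'
#' @param pool Species pool from [make_species_pool()].
#' @param fraction_with_barcode Scalar in \[0, 1\], or a named vector with
#'   elements `native`, `invader`, `other` for class-specific fractions.
#' @param seed Integer seed; identical seed and pool give identical databases.
#' @param include_decoys Guarantee the terrestrial and unnamed decoy records.
#' @return A `reference_db` data frame: `record_id`, `species_name` (NA when
#'   unnamed), `phylum`, `sequence`, `flag_terrestrial`, `flag_unnamed`,
#'   `flag_excluded`.
#' @export
generate_reference_db <- function(pool, fraction_with_barcode = 0.46,
                                  seed = 1L, include_decoys = TRUE) {
  if (is.null(pool) || nrow(pool) == 0) stop("no species")
  frac <- fraction_with_barcode
  if (any(frac < 0) || any(frac > 1)) stop("fraction_with_barcode must be in [0, 1]")
  set.seed(seed)
  cls <- ifelse(pool$on_native_checklist, "native",
                ifelse(pool$on_invader_checklist, "invader", "other"))
  frac_of <- function(k) {
    if (length(frac) == 1L && is.null(names(frac))) return(unname(frac))
    if (!is.null(names(frac)) && k %in% names(frac)) return(unname(frac[[k]]))
    unname(frac[[1]])
  }
  keep <- logical(nrow(pool))
  for (k in unique(cls)) {
    idx <- which(cls == k)
    n_keep <- round(frac_of(k) * length(idx))
    keep[sample(idx, n_keep)] <- TRUE
  }
  recs <- data.frame(
    record_id = sprintf("REF%05d", which(keep)),
    species_name = pool$species_name[keep],
    phylum = pool$phylum[keep],
    sequence = pool$barcode_seq[keep],
    stringsAsFactors = FALSE)

  if (include_decoys) {
    if (!any(pool$habitat_class[keep] == "terrestrial")) {
      terr <- which(pool$habitat_class == "terrestrial" & !keep)
      if (length(terr)) {
        i <- terr[1L]
        recs <- rbind(recs, data.frame(
          record_id = sprintf("REF%05d", i), species_name = pool$species_name[i],
          phylum = pool$phylum[i], sequence = pool$barcode_seq[i]))
        keep[i] <- TRUE
      }
    }
    # one record with no species-level name: a diverged copy of a random barcode
    layout <- attr(pool, "layout")
    src <- sample(which(pool$habitat_class != "terrestrial"), 1L)
    nonsite <- setdiff(seq_len(layout$total), layout$site_positions)
    unnamed_seq <- mutate_positions(pool$barcode_seq[src], nonsite, rate = 0.06)
    recs <- rbind(recs, data.frame(
      record_id = "REFUNNAMED01", species_name = NA_character_,
      phylum = pool$phylum[src], sequence = unnamed_seq))
  }
  terr_species <- pool$species_name[pool$habitat_class == "terrestrial"]
  recs$flag_terrestrial <- recs$species_name %in% terr_species
  recs$flag_unnamed <- is.na(recs$species_name)
  recs$flag_excluded <- FALSE
  rownames(recs) <- NULL
  pool$in_reference <- pool$species_name %in% recs$species_name
  attr(recs, "pool_in_reference") <- pool$in_reference
  class(recs) <- c("reference_db", "data.frame")
  recs
}

#' Read and write reference FASTA files
#'
#' Headers follow `record_id|species_name|phylum`; an empty species field
#' marks a record with no species-level name.
#'
#' @param db A `reference_db` data frame.
#' @param path FASTA file path.
#' @return `read_reference_fasta` returns a `reference_db` data frame.
#' @export
write_reference_fasta <- function(db, path) {
  sp <- ifelse(is.na(db$species_name), "", db$species_name)
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- paste(db$record_id, sp, db$phylum, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @param terrestrial_phyla Names treated as terrestrial when flags must be
#'   reconstructed from headers (ignored; flags are re-derived by curation).
#' @export
read_reference_fasta <- function(path, terrestrial_phyla = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed reference header: ", names(seqs)[bad[1L]])
  sp <- vapply(parts, `[`, character(1), 2L)
  sp[sp == ""] <- NA_character_
  db <- data.frame(record_id = vapply(parts, `[`, character(1), 1L),
                   species_name = sp,
                   phylum = vapply(parts, `[`, character(1), 3L),
                   sequence = as.character(seqs),
                   flag_terrestrial = FALSE,
                   flag_unnamed = is.na(sp),
                   flag_excluded = FALSE,
                   stringsAsFactors = FALSE)
  class(db) <- c("reference_db", "data.frame")
  db
}
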