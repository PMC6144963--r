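# Reference curation, >=97% identity species assignment, OTU clustering and
# reference-completeness profiling.

#' Curate a barcode reference database
#'
#' Removes terrestrial records, records without a species-level name, and any
#' species on the exclusion list (the list grows as multiple-hit cases are
#' scrutinised and implausible species are struck from the references). Every
#' removal is logged with its reason.
#'
#' @param raw_db A `reference_db` data frame.
#' @param exclusion_list Character vector of species names to drop.
#' @param terrestrial_species Optional species names to flag terrestrial, for
#'   databases read from FASTA where flags are not stored.
#' @return Curated `reference_db` with attribute `curation_log`
#'   (`data.frame`: `record_id`, `species_name`, `reason`).
#' @export
curate_reference <- function(raw_db, exclusion_list = character(),
                             terrestrial_species = NULL) {
  db <- raw_db
  if (!is.null(terrestrial_species))
    db$flag_terrestrial <- db$flag_terrestrial |
      db$species_name %in% terrestrial_species
  db$flag_unnamed <- db$flag_unnamed | is.na(db$species_name)
  missing <- setdiff(exclusion_list, db$species_name)
  if (length(missing))
    warning("exclusion species absent from database: ",
            paste(missing, collapse = ", "))
  db$flag_excluded <- db$species_name %in% exclusion_list
  reason <- ifelse(db$flag_terrestrial, "terrestrial",
                   ifelse(db$flag_unnamed, "unnamed",
                          ifelse(db$flag_excluded, "excluded_by_list", NA)))
  log <- data.frame(record_id = db$record_id[!is.na(reason)],
                    species_name = db$species_name[!is.na(reason)],
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  out <- db[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curation_log") <- log
  class(out) <- c("reference_db", "data.frame")
  out
}

#' Pairwise identity between a query and a reference sequence
#'
#' Semiglobal alignment in which terminal gaps on the reference are free, so a
#' short amplicon contained in a full-length barcode scores 1 when exact.
#' Identity is matches over aligned columns, excluding the free terminal
#' reference overhangs.
#'
#' @param query,reference DNA strings (IUPAC characters only).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(query, reference) {
  for (s in c(query, reference)) {
    if (nchar(s) == 0) stop("empty sequence")
    if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn-]", s))
      stop("non-IUPAC characters in sequence")
  }
  unname(identity_dp_cpp(query, reference)[["identity"]])
}

#' Assign amplicon inserts to species at an identity threshold
#'
#' Inserts are dereplicated and each unique sequence searched against the
#' curated references with exact k-mer seeding and ungapped diagonal
#' extension (equivalent to the semiglobal alignment on substitution-only
#' data; the equivalence is exercised in the tests). A read is assigned to
#' the single species of its best hit when the best identity reaches the
#' threshold; reads whose equal-best hits span more than one species are held
#' out of the matrix and tallied per species set in the multiple-hit report;
#' everything else is unassigned.
#'
#' @param inserts `data.frame` with `sample_id`, `marker`, `insert`.
#' @param db Curated `reference_db`.
#' @param threshold Identity threshold in (0.5, 1\].
#' @param metadata Optional sample metadata to attach (one row per sample).
#' @param seed_k,seed_step Seeding parameters of the search.
#' @param floor Reporting floor: best identities below it are not resolved.
#' @return List with `matrix` (samples x species counts, summed over markers),
#'   `by_marker` (per-marker matrices), `multi_hits` (`data.frame`: species
#'   set, marker, reads), `unassigned` (per-sample counts), `tally`, and
#'   `seq_map` (per unique sequence: best identity, species, status).
#' @export
assign_reads <- function(inserts, db, threshold = 0.97, metadata = NULL,
                         seed_k = 14L, seed_step = 10L, floor = 0.90) {
  if (is.null(db) || nrow(db) == 0) stop("no references")
  stopifnot(threshold > 0.5, threshold <= 1)
  floor <- min(floor, threshold)
  samples <- unique(inserts$sample_id)
  markers <- sort(unique(inserts$marker))
  species <- sort(unique(db$species_name))
  mats <- list()
  multi <- list()
  maps <- list()
  unassigned <- setNames(integer(length(samples)), samples)
  for (mk in markers) {
    sub <- inserts[inserts$marker == mk, , drop = FALSE]
    uniq <- unique(sub$insert)
    hit <- best_hits_cpp(uniq, db$sequence, as.integer(seed_k),
                         as.integer(seed_step), floor)
    best <- hit$best_identity
    sp_at_best <- lapply(hit$hit_refs, function(ix) unique(db$species_name[ix]))
    status <- ifelse(is.na(best) | best < threshold, "unassigned",
                     ifelse(lengths(sp_at_best) == 1L, "assigned", "multi"))
    one_sp <- vapply(sp_at_best, function(s)
      if (length(s) == 1L) s else NA_character_, character(1))
    key <- match(sub$insert, uniq)
    m <- matrix(0L, length(samples), length(species),
                dimnames = list(samples, species))
    asg <- status[key] == "assigned"
    if (any(asg)) {
      tab <- table(factor(sub$sample_id[asg], levels = samples),
                   factor(one_sp[key][asg], levels = species))
      m <- m + unclass(as.matrix(tab))
    }
    is_multi <- status[key] == "multi"
    if (any(is_multi)) {
      sets <- vapply(sp_at_best[key[is_multi]], function(s)
        paste(sort(s), collapse = ";"), character(1))
      mt <- as.data.frame(table(sets), stringsAsFactors = FALSE)
      names(mt) <- c("species_set", "reads")
      mt$marker <- mk
      multi[[mk]] <- mt[, c("marker", "species_set", "reads")]
    }
    un <- status[key] == "unassigned"
    if (any(un)) {
      ut <- table(factor(sub$sample_id[un], levels = samples))
      unassigned <- unassigned + as.integer(ut)
    }
    mats[[mk]] <- m
    maps[[mk]] <- data.frame(marker = mk, insert = uniq,
                             best_identity = best, species = one_sp,
                             status = status, stringsAsFactors = FALSE)
  }
  total <- Reduce(`+`, mats)
  multi_hits <- if (length(multi))
    do.call(rbind, c(multi, list(make.row.names = FALSE)))
    else data.frame(marker = character(), species_set = character(),
                    reads = integer(), stringsAsFactors = FALSE)
  tally <- c(input = nrow(inserts), assigned = sum(total),
             multi_hit = sum(multi_hits$reads), unassigned = sum(unassigned))
  cm <- community_matrix(total, metadata = metadata, marker = "combined")
  by_marker <- lapply(markers, function(mk)
    community_matrix(mats[[mk]], metadata = metadata, marker = mk))
  names(by_marker) <- markers
  list(matrix = cm, by_marker = by_marker, multi_hits = multi_hits,
       unassigned = unassigned, tally = tally,
       seq_map = do.call(rbind, c(maps, list(make.row.names = FALSE))))
}

#' Community matrix container
#'
#' Bundles a samples x species count matrix with sample metadata and a marker
#' label.
#'
#' @param counts Integer matrix, samples in rows.
#' @param metadata Optional `data.frame` with a `sample_id` column.
#' @param marker Marker label.
#' @return Object of class `community_matrix`.
#' @export
community_matrix <- function(counts, metadata = NULL, marker = "combined") {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!is.null(metadata)) {
    metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                         drop = FALSE]
    if (anyNA(metadata$sample_id))
      stop("metadata missing for some samples")
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, metadata = metadata, marker = marker),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community matrix (", x$marker, "): ", nrow(x$counts), " samples x ",
      ncol(x$counts), " species, ", sum(x$counts), " reads\n", sep = "")
  invisible(x)
}

counts_of <- function(x) {
  if (inherits(x, "community_matrix")) x$counts else as.matrix(x)
}

#' Greedy centroid OTU clustering
#'
#' Unique sequences are sorted by descending abundance (ties lexicographic)
#' and clustered greedily: a sequence joins the first centroid it matches at
#' or above the similarity threshold, otherwise it founds a new OTU. OTUs
#' whose total member read count is 1 (singletons) are removed; the
#' representative of an OTU is its centroid (most abundant member).
#'
#' @param inserts Character vector of insert sequences (one marker), or a
#'   `data.frame` with an `insert` column.
#' @param similarity Identity threshold for joining a centroid.
#' @return `data.frame` with `representative`, `members` (unique sequences)
#'   and `reads` (total member read count), sorted by descending reads.
#' @export
cluster_otus <- function(inserts, similarity = 0.97) {
  seqs <- if (is.data.frame(inserts)) inserts$insert else inserts
  if (length(seqs) == 0)
    return(data.frame(representative = character(), members = integer(),
                      reads = integer(), stringsAsFactors = FALSE))
  tab <- table(seqs)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]; cnt <- cnt[ord]
  memb <- cluster_greedy_cpp(uniq, similarity)
  reads <- tapply(cnt, memb, sum)
  members <- tapply(cnt, memb, length)
  cent <- as.integer(names(reads))
  out <- data.frame(representative = uniq[cent],
                    members = as.integer(members),
                    reads = as.integer(reads), stringsAsFactors = FALSE)
  out <- out[out$reads > 1L, , drop = FALSE]
  out <- out[order(-out$reads, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference-completeness profile of an OTU set
#'
#' Each OTU representative is searched against the reference database; per
#' phylum (of the best reference) the profile reports how many OTUs sit in
#' the species-assignable band \[0.97, 1\] out of those at or above the lower
#' bound, i.e. the fraction of the detected diversity that the reference
#' database can name. OTUs whose best identity falls below the lower bound
#' (or that hit nothing) are reported separately as out of range.
#'
#' @param otus OTU table from [cluster_otus()].
#' @param db Curated `reference_db`.
#' @param lower Lower identity bound of the profiled band (0.80 by default;
#'   0.85 is the common alternative).
#' @param species_level Species-assignability bound.
#' @return List with `by_phylum` (`data.frame`: `phylum`, `n_species_level`,
#'   `n_in_range`, `fraction`), `overall` fraction, and `n_out_of_range`.
#' @export
assignability_profile <- function(otus, db, lower = 0.80,
                                  species_level = 0.97) {
  stopifnot(nrow(otus) > 0)
  hit <- best_hits_cpp(otus$representative, db$sequence, 14L, 1L,
                       max(lower - 0.05, 0.5))
  best <- hit$best_identity
  phyl <- vapply(hit$hit_refs, function(ix)
    if (length(ix)) db$phylum[ix[1L]] else NA_character_, character(1))
  in_range <- !is.na(best) & best >= lower
  sp_level <- in_range & best >= species_level
  by_phylum <- do.call(rbind, lapply(sort(unique(phyl[in_range])), function(p) {
    sel <- in_range & phyl == p
    data.frame(phylum = p, n_species_level = sum(sp_level & sel),
               n_in_range = sum(sel),
               fraction = sum(sp_level & sel) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_phylum))
    by_phylum <- data.frame(phylum = character(), n_species_level = integer(),
                            n_in_range = integer(), fraction = numeric(),
                            stringsAsFactors = FALSE)
  list(by_phylum = by_phylum,
       overall = if (any(in_range)) sum(sp_level) / sum(in_range) else NA_real_,
       n_out_of_range = sum(!in_range),
       best_identity = best, lower = lower)
}
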