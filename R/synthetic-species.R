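# Synthetic species pools with COI-like barcodes.
#
# Every barcode follows one fixed layout so that the two marker amplicons
# overlap the same way the real primers do on the Folmer region:
#
#   flank5 | F2 | A | F1 | B | rc(R2) | C | rc(R1) | flank3
#
# insert2 = A + F1 + B (325 nt, COI2) and insert1 = B + rc(R2) + C (313 nt,
# COI1), so the COI1 forward primer sits inside the COI2 amplicon. Species
# within a phylum descend from a shared scaffold by substitutions, giving the
# within-phylum identities (~0.84) typical of congeneric COI divergence and
# keeping cross-phylum identities below the 0.80 profiling floor; primer
# binding sites stay exact in every amplifiable species, as expected for
# universal primers.

.barcode_layout <- function(realized) {
  f2 <- nchar(realized$F2); f1 <- nchar(realized$F1)
  r2 <- nchar(realized$R2rc); r1 <- nchar(realized$R1rc)
  len_flank5 <- 75L; len_A <- 99L; len_B <- 200L; len_C <- 93L; len_flank3 <- 76L
  p <- list()
  cur <- 0L
  add <- function(name, len) {
    p[[name]] <<- c(start = cur + 1L, end = cur + len)
    cur <<- cur + len
  }
  add("flank5", len_flank5); add("F2", f2); add("A", len_A); add("F1", f1)
  add("B", len_B); add("R2rc", r2); add("C", len_C); add("R1rc", r1)
  add("flank3", len_flank3)
  p$total <- cur
  p$amplicon_COI1 <- c(start = p$F1[["start"]], end = p$R1rc[["end"]])
  p$amplicon_COI2 <- c(start = p$F2[["start"]], end = p$R2rc[["end"]])
  p$insert_COI1 <- c(start = p$B[["start"]], end = p$C[["end"]])
  p$insert_COI2 <- c(start = p$A[["start"]], end = p$B[["end"]])
  p$site_positions <- sort(c(seq(p$F2[["start"]], p$F2[["end"]]),
                             seq(p$F1[["start"]], p$F1[["end"]]),
                             seq(p$R2rc[["start"]], p$R2rc[["end"]]),
                             seq(p$R1rc[["start"]], p$R1rc[["end"]])))
  p
}

mutate_positions <- function(seq, positions, rate = NULL, n_mut = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (!is.null(rate)) {
    hit <- positions[runif(length(positions)) < rate]
  } else {
    hit <- sample(positions, min(n_mut, length(positions)))
  }
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (p in hit) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic species pool with COI-like barcodes
#'
#' Builds a pool of mock species spread over metazoan phyla, each carrying a
#' 640 nt barcode with exact binding sites for both marker primer pairs.
#' Native and potential-invader species are flagged for checklist membership;
#' terrestrial species (never on aquatic checklists) exercise the reference
#' curation filters. Within-phylum barcode identities are kept below 0.90 by
#' rejection sampling; optional "sister pairs" are planted at a configurable
#' higher identity to provoke multiple-hit behaviour during assignment.
#'
#' @param n_native,n_invader Number of native and potential-invader species.
#' @param n_terrestrial Extra terrestrial species (insects, mammals, ...).
#' @param phyla Phylum names over which aquatic species are spread.
#' @param primers Primer set, see [default_primer_set()].
#' @param p_freshwater,p_brackish Probability an aquatic species is classed
#'   freshwater or brackish (the rest are marine).
#' @param species_divergence Per-site substitution probability from the phylum
#'   scaffold (non-primer positions only).
#' @param phylum_divergence Per-site substitution probability of each phylum
#'   scaffold from the shared core.
#' @param n_sister_pairs Number of high-identity sister pairs to plant.
#' @param sister_identity Target barcode identity within a sister pair; use 1
#'   for identical barcodes (guaranteed equal-best assignment hits).
#' @param seed Integer seed; identical seeds give identical pools.
#' @return A `data.frame` with one row per species (fields `species_name`,
#'   `phylum`, `habitat_class`, `barcode_seq`, checklist and amplifiability
#'   flags) and attributes `layout` (barcode coordinates) and `primers`.
#' @export
make_species_pool <- function(n_native = 897L, n_invader = 130L,
                              n_terrestrial = 5L,
                              phyla = c("Annelida", "Arthropoda", "Bryozoa",
                                        "Chordata", "Cnidaria", "Echinodermata",
                                        "Mollusca", "Nemertea", "Porifera",
                                        "Rotifera"),
                              primers = default_primer_set(),
                              p_freshwater = 0.08, p_brackish = 0.07,
                              species_divergence = 0.10,
                              phylum_divergence = 0.12,
                              n_sister_pairs = 0L, sister_identity = 0.97,
                              seed = 1L) {
  n_aquatic <- n_native + n_invader
  if (n_aquatic + n_terrestrial <= 0) stop("no species")
  set.seed(seed)
  realized <- list(F2 = realize_primer(primers$COI2$forward_seq),
                   F1 = realize_primer(primers$COI1$forward_seq),
                   R2rc = revcomp(realize_primer(primers$COI2$reverse_seq)),
                   R1rc = revcomp(realize_primer(primers$COI1$reverse_seq)))
  layout <- .barcode_layout(realized)
  plant_sites <- function(seq) {
    substr(seq, layout$F2[["start"]], layout$F2[["end"]]) <- realized$F2
    substr(seq, layout$F1[["start"]], layout$F1[["end"]]) <- realized$F1
    substr(seq, layout$R2rc[["start"]], layout$R2rc[["end"]]) <- realized$R2rc
    substr(seq, layout$R1rc[["start"]], layout$R1rc[["end"]]) <- realized$R1rc
    seq
  }
  nonsite <- setdiff(seq_len(layout$total), layout$site_positions)
  core <- plant_sites(random_dna(layout$total))
  phylum_scaffold <- setNames(vapply(phyla, function(p)
    plant_sites(mutate_positions(core, nonsite, rate = phylum_divergence)),
    character(1)), phyla)

  # terrestrial species go to insect/vertebrate phyla
  terr_phyla <- sample(c("Arthropoda", "Chordata"), n_terrestrial, replace = TRUE)
  aqu_phyla <- sample(phyla, n_aquatic, replace = TRUE)
  all_phyla <- c(aqu_phyla, terr_phyla)
  n <- length(all_phyla)

  barcodes <- character(n)
  for (ph in unique(all_phyla)) {
    idx <- which(all_phyla == ph)
    seqs <- vapply(idx, function(i)
      mutate_positions(phylum_scaffold[[ph]], nonsite, rate = species_divergence),
      character(1))
    # rejection: within-phylum pairwise identity must stay below 0.90
    for (iter in 1:20) {
      idm <- hamming_identity_matrix_cpp(seqs)
      diag(idm) <- 0
      bad <- which(apply(idm, 1, max) >= 0.90)
      if (!length(bad)) break
      for (b in bad) seqs[b] <-
        mutate_positions(phylum_scaffold[[ph]], nonsite, rate = species_divergence)
    }
    barcodes[idx] <- seqs
  }

  habitat <- c(
    sample(c("marine", "freshwater", "brackish"), n_aquatic, replace = TRUE,
           prob = c(1 - p_freshwater - p_brackish, p_freshwater, p_brackish)),
    rep("terrestrial", n_terrestrial))
  species_name <- sprintf("%s_sp%04d", all_phyla, seq_len(n))

  pool <- data.frame(
    species_name = species_name,
    phylum = all_phyla,
    habitat_class = habitat,
    barcode_seq = barcodes,
    on_native_checklist = c(rep(TRUE, n_native), rep(FALSE, n_invader),
                            rep(FALSE, n_terrestrial)),
    on_invader_checklist = c(rep(FALSE, n_native), rep(TRUE, n_invader),
                             rep(FALSE, n_terrestrial)),
    amplifiable_COI1 = TRUE,
    amplifiable_COI2 = TRUE,
    in_reference = FALSE,
    stringsAsFactors = FALSE)

  if (n_sister_pairs > 0) {
    aq <- which(pool$habitat_class != "terrestrial")
    anchors <- sample(aq, n_sister_pairs)
    partners <- vapply(anchors, function(a) {
      cand <- setdiff(aq[pool$phylum[aq] == pool$phylum[a]], anchors)
      if (!length(cand)) NA_integer_ else sample(cand, 1L)
    }, integer(1))
    for (k in seq_len(n_sister_pairs)) {
      if (is.na(partners[k])) next
      if (sister_identity >= 1) {
        pool$barcode_seq[partners[k]] <- pool$barcode_seq[anchors[k]]
      } else {
        n_mut <- max(1L, round((1 - sister_identity) * layout$total))
        pool$barcode_seq[partners[k]] <-
          mutate_positions(pool$barcode_seq[anchors[k]], nonsite, n_mut = n_mut)
      }
    }
    attr(pool, "sister_pairs") <- cbind(anchor = anchors, partner = partners)
  }

  attr(pool, "layout") <- layout
  attr(pool, "realized_sites") <- realized
  attr(pool, "primers") <- primers
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Knock out a marker's primer sites in selected species
#'
#' Scrambles the binding-site regions of `marker` for the given species, so
#' their barcodes can no longer be amplified in silico. Used to construct
#' reference records that exist but lack usable primer sites.
#'
#' @param pool A species pool from [make_species_pool()].
#' @param species Character vector of species names.
#' @param marker `"COI1"` or `"COI2"`.
#' @return The modified pool.
#' @export
knockout_primer_sites <- function(pool, species, marker = "COI1") {
  layout <- attr(pool, "layout")
  regions <- if (marker == "COI1") list(layout$F1, layout$R1rc) else
    list(layout$F2, layout$R2rc)
  idx <- match(species, pool$species_name)
  if (anyNA(idx)) stop("unknown species: ", paste(species[is.na(idx)], collapse = ", "))
  for (i in idx) {
    s <- pool$barcode_seq[i]
    for (rg in regions) {
      pos <- seq(rg[["start"]], rg[["end"]])
      s <- mutate_positions(s, pos, n_mut = ceiling(length(pos) / 2))
    }
    pool$barcode_seq[i] <- s
    pool[[paste0("amplifiable_", marker)]][i] <- FALSE
  }
  pool
}

#' Extract the amplicon (primer-flanked) sequence of a species barcode
#'
#' @param pool Species pool.
#' @param marker `"COI1"` or `"COI2"`.
#' @return Named character vector of amplicon sequences.
#' @keywords internal
pool_amplicons <- function(pool, marker) {
  layout <- attr(pool, "layout")
  rg <- layout[[paste0("amplicon_", marker)]]
  setNames(substr(pool$barcode_seq, rg[["start"]], rg[["end"]]), pool$species_name)
}

#' Build a species checklist
#'
#' @param pool Species pool.
#' @param list_kind `"native"` or `"invader"`.
#' @return A `data.frame` with columns `species`, `phylum`, `list_kind`.
#' @export
generate_checklist <- function(pool, list_kind = c("native", "invader")) {
  list_kind <- match.arg(list_kind)
  flag <- if (list_kind == "native") pool$on_native_checklist else
    pool$on_invader_checklist
  data.frame(species = pool$species_name[flag],
             phylum = pool$phylum[flag],
             list_kind = rep(list_kind, sum(flag)),
             stringsAsFactors = FALSE)
}

#' Write / read a checklist as TSV
#' @param checklist Checklist data frame.
#' @param path File path.
#' @return `read_checklist` returns the checklist data frame.
#' @export
write_checklist <- function(checklist, path) {
  write.table(checklist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_checklist
#' @export
read_checklist <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
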