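# Paired-end amplicon read synthesis with per-read ground truth.

write_fastq_gz <- function(ids, seqs, quals, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(ids))
    writeLines(as.character(rbind(paste0("@", ids), seqs,
                                  rep("+", length(ids)), quals)), con)
  invisible(path)
}

#' Read a FASTQ file into a data frame
#'
#' Light structural validation (record structure, sequence/quality length
#' agreement) with errors that name the offending record.
#'
#' @param path FASTQ path (plain or gzipped).
#' @return `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): truncated record at line ",
         length(lines) - length(lines) %% 4L + 1L)
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " (", sub("^@", "", ids[bad[1L]]),
         ") in ", path)
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

# substitution errors on n copies of per-read templates; returns mutated
# copies plus realized per-copy error counts
mutate_copies <- function(templates, error_rate) {
  n <- length(templates)
  lens <- nchar(templates)
  n_err <- rbinom(n, lens, error_rate)
  total <- sum(n_err)
  if (total == 0) return(list(seqs = templates, n_errors = n_err))
  which_err <- which(n_err > 0)
  pos_list <- lapply(which_err, function(i) sample.int(lens[i], n_err[i]))
  read_idx <- rep(which_err, n_err[which_err])
  pos <- unlist(pos_list)
  cur <- substring(templates[read_idx], pos, pos)
  repl <- character(length(cur))
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  r3 <- sample.int(3L, length(cur), replace = TRUE)
  for (b in names(alts)) {
    sel <- cur == b
    if (any(sel)) repl[sel] <- alts[[b]][r3[sel]]
  }
  seqs <- apply_substitutions_cpp(templates, read_idx, pos, repl)
  list(seqs = seqs, n_errors = n_err)
}

#' Synthesize paired FASTQ reads from a community truth table
#'
#' Each read pair is cut from one amplicon copy of the species' barcode
#' (forward primer, insert, reverse-complemented reverse primer). Substitution
#' errors are applied to the amplicon copy before the mates are cut, so the
#' per-copy error count is Binomial(amplicon length, `error_rate`) and mates
#' agree over their overlap. Reads are split between the two markers with
#' probability `p_marker1` per read (species lacking a marker's primer sites
#' only emit reads for the other). Negative controls receive 0 to
#' `control_max_reads` stray reads from random species. Qualities follow a
#' fixed high-quality profile with an optional degraded 3' tail.
#'
#' @param truth Output of [simulate_community_matrix()].
#' @param pool Species pool providing barcodes and the layout.
#' @param out_dir Directory for `<sample>_R1.fastq.gz` / `_R2.fastq.gz`.
#' @param read_len Read length; both mates must overlap by at least
#'   `min_overlap` nt over the longest amplicon.
#' @param error_rate Per-base substitution probability; defaults to the
#'   design's rate.
#' @param indel_rate Per-base indel probability (default 0; substitutions
#'   only keeps identity arithmetic exact).
#' @param p_marker1 Probability a read comes from the COI1 amplicon.
#' @param base_quality,tail_len,tail_quality Quality profile (Phred).
#' @param control_max_reads Maximum stray reads per negative control.
#' @param min_overlap Required mate overlap used to validate `read_len`.
#' @param seed Integer seed; same truth and seed give byte-identical FASTQ.
#' @return List with `files` (per-sample R1/R2 paths), `read_truth`
#'   (per-read `data.frame`: `read_id`, `sample_id`, `species`, `marker`,
#'   `n_errors`) and `truth_counts` (samples x species matrix including
#'   control strays).
#' @export
synthesize_reads <- function(truth, pool, out_dir,
                             read_len = 250L,
                             error_rate = NULL,
                             indel_rate = 0,
                             p_marker1 = 0.5,
                             base_quality = 38L, tail_len = 0L,
                             tail_quality = 20L,
                             control_max_reads = 5L,
                             min_overlap = 30L,
                             seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  if (is.null(error_rate)) error_rate <- 0.005
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  amp <- list(COI1 = pool_amplicons(pool, "COI1"),
              COI2 = pool_amplicons(pool, "COI2"))
  amp_len <- vapply(amp, function(a) max(nchar(a)), integer(1))
  if (any(2L * read_len - amp_len < min_overlap))
    stop("read_len ", read_len, " too short for required overlap of ",
         min_overlap, " nt over the longest amplicon (", max(amp_len), " nt)")
  qual_of <- function(len) {
    q <- rep(base_quality, len)
    if (tail_len > 0) q[seq(len - min(tail_len, len) + 1L, len)] <- tail_quality
    intToUtf8(q + 33L, multiple = FALSE)
  }
  meta <- truth$metadata
  counts <- truth$counts
  sp_names <- colnames(counts)
  files <- list()
  rt <- list()
  truth_counts <- counts
  ampl1 <- pool$amplifiable_COI1[match(sp_names, pool$species_name)]
  ampl2 <- pool$amplifiable_COI2[match(sp_names, pool$species_name)]
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    if (meta$is_control[i]) {
      n_stray <- sample.int(control_max_reads + 1L, 1L) - 1L
      species <- if (n_stray > 0)
        sample(sp_names[ampl1 | ampl2], n_stray, replace = TRUE) else character()
      if (n_stray > 0) {
        add <- table(factor(species, levels = sp_names))
        truth_counts[i, ] <- truth_counts[i, ] + as.integer(add)
      }
    } else {
      species <- rep(sp_names, counts[i, ])
      if (length(species)) species <- sample(species)  # shuffle read order
    }
    n <- length(species)
    if (n == 0) {
      f1 <- file.path(out_dir, paste0(sid, "_R1.fastq.gz"))
      f2 <- file.path(out_dir, paste0(sid, "_R2.fastq.gz"))
      write_fastq_gz(character(), character(), character(), f1)
      write_fastq_gz(character(), character(), character(), f2)
      files[[sid]] <- c(R1 = f1, R2 = f2)
      next
    }
    spi <- match(species, sp_names)
    can1 <- ampl1[spi]; can2 <- ampl2[spi]
    u <- runif(n)
    marker <- ifelse(can1 & can2, ifelse(u < p_marker1, "COI1", "COI2"),
                     ifelse(can1, "COI1", ifelse(can2, "COI2", NA)))
    keep <- !is.na(marker)
    species <- species[keep]; marker <- marker[keep]; n <- sum(keep)
    templates <- ifelse(marker == "COI1", amp$COI1[species], amp$COI2[species])
    mut <- mutate_copies(templates, error_rate)
    seqs <- mut$seqs
    if (indel_rate > 0) {
      n_ind <- rbinom(n, nchar(seqs), indel_rate)
      for (j in which(n_ind > 0)) {
        s <- strsplit(seqs[j], "")[[1]]
        for (k in seq_len(n_ind[j])) {
          p <- sample.int(length(s), 1L)
          if (runif(1) < 0.5) s <- s[-p]
          else s <- append(s, sample(c("A", "C", "G", "T"), 1L), after = p)
        }
        seqs[j] <- paste(s, collapse = "")
      }
    }
    lens <- nchar(seqs)
    rl <- pmin(read_len, lens)
    fwd <- substr(seqs, 1L, rl)
    rev <- revcomp(substring(seqs, lens - rl + 1L, lens))
    ids <- sprintf("%s_%06d", sid, seq_len(n))
    q <- vapply(unique(rl), qual_of, character(1))
    names(q) <- as.character(unique(rl))
    quals <- q[as.character(rl)]
    f1 <- file.path(out_dir, paste0(sid, "_R1.fastq.gz"))
    f2 <- file.path(out_dir, paste0(sid, "_R2.fastq.gz"))
    write_fastq_gz(ids, fwd, quals, f1)
    write_fastq_gz(ids, rev, quals, f2)
    files[[sid]] <- c(R1 = f1, R2 = f2)
    rt[[sid]] <- data.frame(read_id = ids, sample_id = sid, species = species,
                            marker = marker, n_errors = mut$n_errors,
                            stringsAsFactors = FALSE)
  }
  read_truth <- if (length(rt)) do.call(rbind, c(rt, list(make.row.names = FALSE)))
    else data.frame(read_id = character(), sample_id = character(),
                    species = character(), marker = character(),
                    n_errors = integer(), stringsAsFactors = FALSE)
  list(files = files, read_truth = read_truth, truth_counts = truth_counts)
}
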