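# Shared fixtures and independent oracles used across the test files.

tiny_pool <- function(n_native = 20, n_invader = 4, n_terrestrial = 2,
                      seed = 42, ...) {
  make_species_pool(n_native = n_native, n_invader = n_invader,
                    n_terrestrial = n_terrestrial, seed = seed, ...)
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_string <- function(s, positions, to = NULL) {
  chars <- strsplit(s, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- if (is.null(to)) alt[1] else to
  }
  paste(chars, collapse = "")
}

# direct windowing oracle for quality trimming: longest prefix whose every
# fully-contained window of size w has mean quality >= thr
trim_oracle <- function(qvec, w, thr) {
  n <- length(qvec)
  ok_prefix <- function(L) {
    if (L < w) return(L == 0 || mean(qvec[seq_len(L)]) >= thr)
    for (s in seq_len(L - w + 1)) {
      if (mean(qvec[s:(s + w - 1)]) < thr) return(FALSE)
    }
    TRUE
  }
  for (L in n:0) if (ok_prefix(L)) return(L)
  0L
}

# exhaustive overlap-scan oracle for pair merging (sequences only)
merge_oracle <- function(f, r_rc, min_overlap, max_frac) {
  lf <- nchar(f); lr <- nchar(r_rc)
  best <- NULL
  for (o in min(lf, lr):min_overlap) {
    a <- substring(f, lf - o + 1, lf)
    b <- substring(r_rc, 1, o)
    mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    frac <- mm / o
    if (frac <= max_frac && (is.null(best) || frac < best$frac - 1e-12))
      best <- list(overlap = o, mismatches = mm, frac = frac)
  }
  best
}

# brute-force greedy clustering oracle on few unique sequences
cluster_oracle <- function(seqs, sim) {
  tab <- table(seqs)
  uniq <- names(tab); cnt <- as.integer(tab)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]; cnt <- cnt[ord]
  cents <- integer(0)
  memb <- integer(length(uniq))
  ident <- function(a, b) {
    if (nchar(a) == nchar(b)) {
      ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
      mean(ca == cb)
    } else pairwise_identity(a, b)
  }
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (cc in cents) {
      if (ident(uniq[cc], uniq[i]) >= sim - 1e-12) { hit <- cc; break }
    }
    if (hit == 0L) { cents <- c(cents, i); memb[i] <- i } else memb[i] <- hit
  }
  reads <- tapply(cnt, memb, sum)
  data.frame(representative = uniq[as.integer(names(reads))],
             reads = as.integer(reads), stringsAsFactors = FALSE)
}

# IUPAC sliding Hamming oracle for primer-site search
iupac_expand <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A","G"), Y = c("C","T"), S = c("C","G"),
                     W = c("A","T"), K = c("G","T"), M = c("A","C"),
                     B = c("C","G","T"), D = c("A","G","T"),
                     H = c("A","C","T"), V = c("A","C","G"),
                     N = c("A","C","G","T"))
primer_scan_oracle <- function(seq, primer, max_mm) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  L <- length(pc)
  hits <- integer(0)
  for (off in 0:(length(sc) - L)) {
    mm <- 0
    for (i in seq_len(L)) {
      base <- sc[off + i]
      if (!(base %in% c("A","C","G","T")) ||
          !(base %in% iupac_expand[[pc[i]]])) mm <- mm + 1
    }
    if (mm <= max_mm) hits <- c(hits, off + 1L)
  }
  hits
}

# one tiny synthetic end-to-end run reused by several test files
run_tiny_synthesis <- function(n_species = 12, reads_per_sample = 300,
                               error_rate = 0, seed = 5, n_wc = 1, n_tp = 1,
                               n_shore = 0, control_every = 0, ...) {
  pool <- tiny_pool(n_native = n_species, n_invader = 0, n_terrestrial = 1,
                    seed = seed)
  aquatic <- pool$species_name[pool$habitat_class %in% c("marine", "brackish")]
  des <- community_design(species = head(aquatic, n_species - 2),
                          n_water_column_sites = n_wc,
                          n_tide_pool_sites = n_tp,
                          n_shore_samples = n_shore,
                          reads_per_sample = reads_per_sample,
                          error_rate = error_rate,
                          control_every = control_every, seed = seed + 1, ...)
  truth <- simulate_community_matrix(des, pool)
  out <- file.path(tempfile("reads"), "fq")
  rd <- synthesize_reads(truth, pool, out, error_rate = error_rate,
                         seed = seed + 2)
  list(pool = pool, design = des, truth = truth, reads = rd)
}

process_all_samples <- function(rd, primers = default_primer_set(),
                                max_mismatches = 2L, ...) {
  res <- lapply(names(rd$files), function(sid) {
    pr <- process_sample_reads(rd$files[[sid]]["R1"], rd$files[[sid]]["R2"],
                               primers, max_mismatches = max_mismatches, ...)
    if (nrow(pr$inserts) == 0) return(NULL)
    data.frame(sample_id = sid, pr$inserts, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
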