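# Synthetic species pools, reference databases and read generation.

test_that("species pool respects barcode and checklist invariants", {
  pool <- tiny_pool(n_native = 24, n_invader = 6, n_terrestrial = 3, seed = 9)
  expect_equal(anyDuplicated(pool$species_name), 0L)
  expect_true(all(nchar(pool$barcode_seq) >= 600 &
                    nchar(pool$barcode_seq) <= 700))
  expect_equal(sum(pool$on_native_checklist), 24)
  expect_equal(sum(pool$on_invader_checklist), 6)
  # terrestrial species are never on aquatic checklists
  terr <- pool$habitat_class == "terrestrial"
  expect_false(any(pool$on_native_checklist[terr] |
                     pool$on_invader_checklist[terr]))
  # exactly one exact binding site per primer of each marker
  primers <- default_primer_set()
  for (i in c(1, 10, nrow(pool))) {
    for (pd in primers) {
      fhits <- primer_scan_oracle(pool$barcode_seq[i], pd$forward_seq, 0)
      rhits <- primer_scan_oracle(pool$barcode_seq[i],
                                  revcomp(pd$reverse_seq), 0)
      expect_length(fhits, 1)
      expect_length(rhits, 1)
    }
  }
  # pairwise identity below 0.90 between distinct species
  idm <- ednacoi:::hamming_identity_matrix_cpp(pool$barcode_seq)
  diag(idm) <- 0
  expect_lt(max(idm), 0.90)
})

test_that("sister pairs are planted at the requested identity", {
  pool <- tiny_pool(n_native = 30, seed = 3, n_sister_pairs = 2,
                    sister_identity = 0.97)
  sp <- attr(pool, "sister_pairs")
  expect_equal(nrow(sp), 2)
  for (k in seq_len(nrow(sp))) {
    id <- pairwise_identity(pool$barcode_seq[sp[k, "anchor"]],
                            pool$barcode_seq[sp[k, "partner"]])
    expect_gt(id, 0.95)
    expect_lt(id, 0.999)
  }
  twin <- tiny_pool(n_native = 30, seed = 3, n_sister_pairs = 1,
                    sister_identity = 1)
  tp <- attr(twin, "sister_pairs")
  expect_identical(twin$barcode_seq[tp[1, "anchor"]],
                   twin$barcode_seq[tp[1, "partner"]])
})

test_that("reference database fraction is honoured per checklist class", {
  pool <- make_species_pool(n_native = 100, n_invader = 50,
                            n_terrestrial = 2, seed = 1)
  db <- generate_reference_db(pool, 0.46, seed = 2, include_decoys = FALSE)
  named <- db[!is.na(db$species_name), ]
  natives <- sum(named$species_name %in%
                   pool$species_name[pool$on_native_checklist])
  invaders <- sum(named$species_name %in%
                    pool$species_name[pool$on_invader_checklist])
  expect_equal(natives, 46)
  expect_equal(invaders, round(0.46 * 50))
  # saturation
  full <- generate_reference_db(pool, 1.0, seed = 2, include_decoys = FALSE)
  expect_true(all(pool$species_name %in% full$species_name))
  # class-specific fractions
  db2 <- generate_reference_db(pool, c(native = 0.46, invader = 0.63,
                                       other = 0), seed = 4,
                               include_decoys = FALSE)
  inv2 <- sum(db2$species_name %in%
                pool$species_name[pool$on_invader_checklist], na.rm = TRUE)
  expect_equal(inv2, round(0.63 * 50))
})

test_that("reference database carries curation decoys and is deterministic", {
  pool <- tiny_pool(seed = 11)
  db1 <- generate_reference_db(pool, 0.5, seed = 7)
  db2 <- generate_reference_db(pool, 0.5, seed = 7)
  expect_identical(db1$sequence, db2$sequence)
  expect_gte(sum(db1$flag_terrestrial), 1)
  expect_gte(sum(db1$flag_unnamed), 1)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_reference_fasta(db1, f1); write_reference_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_reference_fasta(f1)
  expect_equal(back$sequence, db1$sequence)
  expect_equal(back$species_name, db1$species_name)
  expect_error(generate_reference_db(pool[0, ], 0.5), "no species")
})

test_that("community truth obeys the design and conservation", {
  sim <- run_tiny_synthesis(reads_per_sample = 400, error_rate = 0, seed = 21)
  truth <- sim$truth
  non_ctl <- !truth$metadata$is_control
  expect_true(all(rowSums(truth$counts[non_ctl, , drop = FALSE]) == 400))
  # per-read truth sums match per-sample truth (conservation)
  rt <- sim$reads$read_truth
  agg <- table(rt$sample_id, rt$species)
  for (sid in rownames(agg)) {
    tc <- sim$reads$truth_counts[sid, colnames(agg)]
    expect_equal(as.integer(agg[sid, ]), as.integer(tc))
  }
  # zero-depth design gives all-zero rows
  des0 <- community_design(species = sim$design$species,
                           n_water_column_sites = 1, n_tide_pool_sites = 0,
                           n_shore_samples = 0, reads_per_sample = 0,
                           control_every = 0, seed = 1)
  t0 <- simulate_community_matrix(des0, sim$pool)
  expect_true(all(t0$counts == 0))
})

test_that("effect multipliers raise expected abundance shares", {
  pool <- tiny_pool(n_native = 20, seed = 13)
  aquatic <- pool$species_name[pool$habitat_class == "marine"]
  boosted <- head(aquatic, 5)
  # empirical mean share over 200 seeds vs the analytic expectation
  shares_null <- shares_eff <- numeric(200)
  for (s in seq_len(200)) {
    des <- community_design(species = aquatic, n_water_column_sites = 0,
                            n_tide_pool_sites = 1, n_shore_samples = 0,
                            reads_per_sample = 2000, control_every = 0,
                            sdlog = 0,  # equal base abundances: analytic shares
                            effects = list(list(factor = "habitat",
                                                level = "tide_pool",
                                                species = boosted,
                                                multiplier = 3)),
                            seed = s)
    tr <- simulate_community_matrix(des, pool)
    shares_eff[s] <- sum(tr$counts[1, boosted]) / sum(tr$counts[1, ])
  }
  k <- length(boosted); n <- length(aquatic)
  expected <- 3 * k / (3 * k + (n - k))
  expect_equal(mean(shares_eff), expected, tolerance = 0.02)
})

test_that("null multipliers give exchangeable samples", {
  pool <- tiny_pool(n_native = 16, seed = 2)
  aquatic <- pool$species_name[pool$habitat_class == "marine"]
  des <- community_design(species = aquatic, n_water_column_sites = 2,
                          n_tide_pool_sites = 2, n_shore_samples = 0,
                          reads_per_sample = 5000, control_every = 0,
                          seed = 8)
  tr <- simulate_community_matrix(des, pool)
  p <- colMeans(tr$counts / rowSums(tr$counts))
  # every sample's composition is near the common expectation
  for (i in seq_len(nrow(tr$counts)))
    expect_lt(max(abs(tr$counts[i, ] / sum(tr$counts[i, ]) - p)), 0.05)
})

test_that("read synthesis is deterministic and mean error count is binomial", {
  sim1 <- run_tiny_synthesis(reads_per_sample = 200, error_rate = 0.005,
                             seed = 31)
  sim2 <- run_tiny_synthesis(reads_per_sample = 200, error_rate = 0.005,
                             seed = 31)
  f1 <- sim1$reads$files[[1]]["R1"]; f2 <- sim2$reads$files[[1]]["R1"]
  expect_identical(readLines(f1), readLines(f2))

  # error-free reads equal their template amplicon exactly
  sim0 <- run_tiny_synthesis(reads_per_sample = 100, error_rate = 0, seed = 6)
  expect_true(all(sim0$reads$read_truth$n_errors == 0))
  rt <- sim0$reads$read_truth[1, ]
  amp <- ednacoi:::pool_amplicons(sim0$pool, rt$marker)[[rt$species]]
  fq <- read_fastq(sim0$reads$files[[rt$sample_id]]["R1"])
  expect_identical(substr(amp, 1, 250), fq$seq[fq$id == rt$read_id])

  # mean substitutions per amplicon copy ~ Binomial(len, rate)
  pool <- tiny_pool(n_native = 6, seed = 77)
  aquatic <- pool$species_name[pool$habitat_class == "marine"]
  des <- community_design(species = aquatic[1:2], n_water_column_sites = 1,
                          n_tide_pool_sites = 0, n_shore_samples = 0,
                          reads_per_sample = 12000, control_every = 0,
                          seed = 1)
  tr <- simulate_community_matrix(des, pool)
  rd <- synthesize_reads(tr, pool, tempfile("errchk"), error_rate = 0.005,
                         seed = 2)
  # COI1 amplicon is 365 nt -> mean 1.825; insert share is 313/365 of that
  m1 <- mean(rd$read_truth$n_errors[rd$read_truth$marker == "COI1"])
  expect_equal(m1, 365 * 0.005, tolerance = 0.07)
  expect_equal(m1 * 313 / 365, 313 * 0.005, tolerance = 0.07)
})

test_that("negative controls stay near-empty and read_len is validated", {
  sim <- run_tiny_synthesis(reads_per_sample = 300, seed = 15, n_wc = 2,
                            n_tp = 2, n_shore = 0, control_every = 4)
  meta <- sim$truth$metadata
  ctl <- meta$sample_id[meta$is_control]
  expect_gte(length(ctl), 1)
  for (sid in ctl) {
    n <- nrow(read_fastq(sim$reads$files[[sid]]["R1"]))
    expect_lte(n, 5)
    expect_equal(sum(sim$reads$truth_counts[sid, ]), n)
  }
  expect_error(
    synthesize_reads(sim$truth, sim$pool, tempfile(), read_len = 190),
    "too short")
})

test_that("checklists round-trip and match the pool", {
  pool <- tiny_pool(n_native = 10, n_invader = 7, seed = 19)
  inv <- generate_checklist(pool, "invader")
  expect_equal(nrow(inv), 7)
  expect_true(all(inv$species %in% pool$species_name))
  path <- tempfile(fileext = ".tsv")
  write_checklist(inv, path)
  back <- read_checklist(path)
  expect_equal(back$species, inv$species)
  empty <- generate_checklist(tiny_pool(n_native = 5, n_invader = 0,
                                        seed = 1), "invader")
  expect_equal(nrow(empty), 0)
  p2 <- tempfile(fileext = ".tsv")
  write_checklist(empty, p2)
  expect_equal(nrow(read_checklist(p2)), 0)
})
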