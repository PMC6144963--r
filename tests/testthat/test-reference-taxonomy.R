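# Reference curation, pairwise identity, species assignment, OTU clustering
# and the completeness profile.

test_that("curation removes terrestrial, unnamed and excluded records", {
  pool <- tiny_pool(n_native = 8, n_invader = 0, n_terrestrial = 2, seed = 3)
  db <- generate_reference_db(pool, 1.0, seed = 1)
  cur <- curate_reference(db)
  expect_false(any(cur$flag_terrestrial | cur$flag_unnamed))
  log <- attr(cur, "curation_log")
  expect_true(all(c("terrestrial", "unnamed") %in% log$reason))
  # every aquatic named species survives
  aquatic <- pool$species_name[pool$habitat_class != "terrestrial"]
  expect_setequal(cur$species_name, aquatic)
  # exclusion list removal and warning on unknown names
  cur2 <- curate_reference(db, exclusion_list = aquatic[1])
  expect_false(aquatic[1] %in% cur2$species_name)
  expect_warning(curate_reference(db, exclusion_list = "Nomen_dubium"),
                 "absent")
  # empty exclusion list leaves only flag-based removals
  expect_equal(nrow(cur), nrow(db) - nrow(log))
})

test_that("pairwise identity matches count-based oracles", {
  s <- rand_dna(313, seed = 8)
  expect_equal(pairwise_identity(s, s), 1.0)
  # 9 substitutions -> 304/313
  s9 <- mutate_string(s, sample(seq_len(313), 9))
  expect_equal(pairwise_identity(s9, s), 304 / 313, tolerance = 1e-12)
  # containment: internal window of a longer reference scores 1 (free ends)
  ref <- rand_dna(650, seed = 9)
  expect_equal(pairwise_identity(substr(ref, 101, 413), ref), 1.0)
  # symmetry for equal-length gap-free alignments
  a <- rand_dna(200, seed = 10); b <- mutate_string(a, c(5, 50, 110))
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_equal(pairwise_identity(a, b), 197 / 200)
  expect_error(pairwise_identity("ACGTX", "ACGTA"), "non-IUPAC")
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("seeded best-hit search agrees with the alignment on planted reads", {
  pool <- tiny_pool(n_native = 15, seed = 12)
  db <- generate_reference_db(pool, 1.0, seed = 1, include_decoys = FALSE)
  set.seed(30)
  ins <- ednacoi:::pool_amplicons(pool, "COI1")[1:10]
  queries <- vapply(seq_along(ins), function(i) {
    x <- substr(ins[[i]], 27, nchar(ins[[i]]) - 26)
    mutate_string(x, sample(seq_len(nchar(x)), sample(0:6, 1)))
  }, character(1))
  hits <- ednacoi:::best_hits_cpp(queries, db$sequence, 14L, 10L, 0.9)
  for (i in seq_along(queries)) {
    dp <- vapply(db$sequence, function(r)
      pairwise_identity(queries[i], r), numeric(1))
    expect_equal(hits$best_identity[i], max(dp), tolerance = 1e-12)
    expect_setequal(hits$hit_refs[[i]], which(dp >= max(dp) - 1e-9))
  }
})

test_that("assignment recovers truth losslessly and conserves reads", {
  sim <- run_tiny_synthesis(n_species = 14, reads_per_sample = 500,
                            error_rate = 0, seed = 71)
  inserts <- process_all_samples(sim$reads, max_mismatches = 0)
  db <- generate_reference_db(sim$pool, 1.0, seed = 5)
  cur <- curate_reference(db)
  res <- assign_reads(inserts[, c("sample_id", "marker", "insert")], cur,
                      metadata = sim$truth$metadata)
  tc <- sim$reads$truth_counts
  got <- res$matrix$counts[rownames(tc), colnames(tc)[colnames(tc) %in%
                                                        colnames(res$matrix$counts)]]
  for (sp in colnames(got))
    expect_equal(unname(got[, sp]), unname(tc[, sp]))
  expect_equal(sum(res$matrix$counts), sum(tc))
  # conservation: assigned + multi-hit + unassigned = inserts
  expect_equal(res$tally[["assigned"]] + res$tally[["multi_hit"]] +
                 res$tally[["unassigned"]], nrow(inserts))
  expect_error(assign_reads(inserts, cur[0, ]), "no references")
})

test_that("assignment threshold is monotone and sub-threshold reads unassigned", {
  pool <- tiny_pool(n_native = 10, seed = 14)
  db <- curate_reference(generate_reference_db(pool, 1.0, seed = 2))
  amp <- ednacoi:::pool_amplicons(pool, "COI1")[[db$species_name[1]]]
  insert <- substr(amp, 27, nchar(amp) - 26)
  set.seed(41)
  n_mut <- c(0, 3, 6, 9, 12, 15)  # identities 1.0 .. 0.952
  reads <- vapply(n_mut, function(k)
    mutate_string(insert, sample(seq_len(313), k)), character(1))
  ins <- data.frame(sample_id = "s1", marker = "COI1", insert = reads,
                    stringsAsFactors = FALSE)
  counts <- vapply(c(0.95, 0.97, 0.99, 1.0), function(th)
    assign_reads(ins, db, threshold = th)$tally[["assigned"]], numeric(1))
  expect_true(all(diff(counts) <= 0))
  # identity 0.96 (12-13 mutations) at threshold 0.97 -> unassigned
  r13 <- mutate_string(insert, sample(seq_len(313), 13))  # 300/313 = 0.958
  res <- assign_reads(data.frame(sample_id = "s1", marker = "COI1",
                                 insert = r13), db, threshold = 0.97)
  expect_equal(res$tally[["unassigned"]], 1)
  expect_equal(res$tally[["assigned"]], 0)
})

test_that("equal-best hits to several species are held out as multiple hits", {
  pool <- tiny_pool(n_native = 10, seed = 33, n_sister_pairs = 1,
                    sister_identity = 1)
  sp <- attr(pool, "sister_pairs")
  twins <- pool$species_name[c(sp[1, "anchor"], sp[1, "partner"])]
  db <- curate_reference(generate_reference_db(pool, 1.0, seed = 2))
  amp <- ednacoi:::pool_amplicons(pool, "COI1")[[twins[1]]]
  ins <- data.frame(sample_id = "s1", marker = "COI1",
                    insert = substr(amp, 27, nchar(amp) - 26),
                    stringsAsFactors = FALSE)
  res <- assign_reads(ins, db)
  expect_equal(res$tally[["multi_hit"]], 1)
  expect_equal(res$tally[["assigned"]], 0)
  expect_equal(nrow(res$multi_hits), 1)
  expect_setequal(strsplit(res$multi_hits$species_set, ";")[[1]], twins)
  # curation by exclusion resolves the case: rerun finds the top hit only
  db2 <- curate_reference(generate_reference_db(pool, 1.0, seed = 2),
                          exclusion_list = twins[2])
  res2 <- assign_reads(ins, db2)
  expect_equal(res2$tally[["assigned"]], 1)
  expect_false(twins[2] %in% colnames(res2$matrix$counts)[
    colSums(res2$matrix$counts) > 0])
})

test_that("greedy OTU clustering matches the brute-force oracle", {
  # 10 copies of one sequence + 1 copy at ~99% identity -> one OTU, 11 reads
  s <- rand_dna(313, seed = 50)
  near <- mutate_string(s, c(10, 100, 200))
  otus <- cluster_otus(c(rep(s, 10), near))
  expect_equal(nrow(otus), 1)
  expect_equal(otus$reads, 11)
  expect_identical(otus$representative, s)
  # two sequences at ~90% identity, each multiple copies -> two OTUs
  set.seed(51)
  far <- mutate_string(s, sample(seq_len(313), 31))
  otus2 <- cluster_otus(c(rep(s, 3), rep(far, 2)))
  expect_equal(nrow(otus2), 2)
  # singleton-only input -> empty OTU set
  set.seed(52)
  singles <- vapply(1:5, function(i) rand_dna(300), character(1))
  expect_equal(nrow(cluster_otus(singles)), 0)
  # randomized agreement with the oracle on <= 50 unique sequences
  set.seed(53)
  base <- vapply(1:6, function(i) rand_dna(250), character(1))
  seqs <- unlist(lapply(base, function(b) {
    c(replicate(sample(2:5, 1),
                mutate_string(b, sample(250, sample(0:8, 1)))))
  }))
  got <- cluster_otus(seqs, 0.97)
  want <- cluster_oracle(seqs, 0.97)
  want <- want[want$reads > 1, ]
  want <- want[order(-want$reads, want$representative), ]
  expect_equal(got$representative, want$representative)
  expect_equal(got$reads, want$reads)
})

test_that("assignability profile counts the species-level band per phylum", {
  pool <- tiny_pool(n_native = 12, seed = 61)
  db <- curate_reference(generate_reference_db(pool, 1.0, seed = 2))
  ref <- db$sequence[1]
  phy <- db$phylum[1]
  set.seed(62)
  # 5 OTUs at ~0.99 and 5 at ~0.90 against the same reference
  reps <- c(vapply(1:5, function(i)
    mutate_string(substr(ref, 76, 388), sample(313, 3)), character(1)),
    vapply(1:5, function(i)
      mutate_string(substr(ref, 76, 388), sample(313, 31)), character(1)))
  otus <- data.frame(representative = reps, members = 1L, reads = 2L,
                     stringsAsFactors = FALSE)
  prof <- assignability_profile(otus, db[1, , drop = FALSE])
  expect_equal(prof$overall, 0.5)
  row <- prof$by_phylum[prof$by_phylum$phylum == phy, ]
  expect_equal(row$fraction, 0.5)
  expect_equal(row$n_in_range, 10)
  # all representatives identical to references -> fraction 1 everywhere
  all_exact <- data.frame(representative = substr(db$sequence[1:4], 76, 388),
                          members = 1L, reads = 2L, stringsAsFactors = FALSE)
  p2 <- assignability_profile(all_exact, db)
  expect_true(all(p2$by_phylum$fraction == 1))
  expect_equal(p2$n_out_of_range, 0)
})
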