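# Transformation, distances, ordination, PERMANOVA, SIMPER, diversity,
# accumulation curves, Chao similarity and group comparisons.

rand_counts <- function(n, p, seed, lambda = 20) {
  set.seed(seed)
  matrix(rpois(n * p, lambda), n, p,
         dimnames = list(paste0("s", 1:n), paste0("sp", 1:p)))
}

test_that("Hellinger transformation gives unit-norm rows", {
  expect_equal(hellinger_transform(rbind(c(4, 0, 0)))[1, ],
               c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(hellinger_transform(rbind(c(1, 1, 1, 1)))[1, ],
               rep(0.5, 4), ignore_attr = TRUE)
  m <- rand_counts(5, 8, seed = 1)
  h <- hellinger_transform(m)
  expect_equal(unname(sqrt(rowSums(h^2))), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(h), unname(vegan::decostand(m, "hellinger")),
               tolerance = 1e-12, ignore_attr = TRUE)
  m0 <- rbind(m, s6 = 0)
  expect_warning(h0 <- hellinger_transform(m0), "all-zero")
  expect_equal(nrow(h0), 5)
  expect_error(hellinger_transform(m0, zero_rows = "error"), "all-zero")
})

test_that("Bray-Curtis matches the hand oracle and vegan", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.numeric(bray_curtis(m)), 4 / 12, tolerance = 1e-12)
  same <- rbind(a = c(2, 1), b = c(2, 1))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  m2 <- rand_counts(6, 10, seed = 2)
  expect_equal(as.numeric(bray_curtis(m2)),
               as.numeric(vegan::vegdist(m2, "bray")), tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean-embeddable distances", {
  set.seed(3)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  d <- dist(pts)
  ord <- pcoa(d)
  expect_lt(max(abs(dist(ord$coordinates) - d)), 1e-9)
  expect_length(ord$negative_eigenvalues, 0)
  # equidistant simplex of 4 points: three equal eigenvalues
  D4 <- matrix(1, 4, 4) - diag(4)
  e4 <- pcoa(D4)$eigenvalues
  expect_equal(e4[1:3], rep(e4[1], 3), tolerance = 1e-9)
  # non-Euclidean toy has a negative eigenvalue, reported but unused
  Dn <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 2.8,
                 1, 1, 2.8, 0), 4, 4)
  on <- pcoa(Dn)
  expect_gt(length(on$negative_eigenvalues), 0)
  expect_equal(ncol(on$coordinates), sum(on$eigenvalues > 1e-9))
  expect_error(pcoa(dist(pts[1:2, ])), "at least 3")
})

test_that("PERMANOVA equals the direct SS oracle and vegan::adonis2", {
  m <- rand_counts(12, 8, seed = 4)
  grp <- rep(c("a", "b"), each = 6)
  m[grp == "b", 1:3] <- m[grp == "b", 1:3] + 25
  d <- hellinger_distance(m)
  res <- permanova(d, grp, n_perm = 199, seed = 1)
  # direct SS oracle
  D <- as.matrix(d)^2
  N <- 12; a <- 2
  ss_t <- sum(D[upper.tri(D)]) / N
  ss_w <- sum(D[1:6, 1:6][upper.tri(D[1:6, 1:6])]) / 6 +
    sum(D[7:12, 7:12][upper.tri(D[7:12, 7:12])]) / 6
  f_oracle <- ((ss_t - ss_w) / (a - 1)) / (ss_w / (N - a))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-12)
  expect_equal(res$R_squared, (ss_t - ss_w) / ss_t, tolerance = 1e-12)
  ad <- vegan::adonis2(d ~ grp, permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R_squared, ad$R2[1], tolerance = 1e-10)
  expect_error(permanova(d, c("a", rep("b", 11))), "degenerate")
})

test_that("exhaustive permutations reproduce the full F distribution", {
  m <- rand_counts(6, 5, seed = 5)
  grp <- rep(c("a", "b"), each = 3)
  d <- bray_curtis(m)
  res <- permanova(d, grp, exact = TRUE)
  expect_equal(res$n_permutations, factorial(6))
  # brute-force oracle over all 720 index permutations
  D <- as.matrix(d)^2
  ss_t <- sum(D[upper.tri(D)]) / 6
  f_of <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(D[idx, idx][upper.tri(D[idx, idx])]) / length(idx)
    }
    ((ss_t - ssw) / 1) / (ssw / 4)
  }
  perms <- ednacoi:::permutations_of(6)
  f_all <- apply(perms, 1, function(p) f_of(grp[p]))
  expect_equal(sort(res$F_perm), sort(f_all), tolerance = 1e-12)
  expect_equal(res$p_value, mean(f_all >= res$pseudo_F - 1e-12))
})

test_that("SIMPER conserves the mean between-group dissimilarity", {
  # single differing species carries 100%
  m <- rbind(a1 = c(10, 5), a2 = c(10, 5), b1 = c(2, 5), b2 = c(2, 5))
  s <- simper(m, c("a", "a", "b", "b"))
  expect_equal(s$percent[1], 100)
  expect_equal(s$species[1], "sp1")
  # conservation on random matrices
  for (seed in 1:5) {
    m2 <- rand_counts(8, 12, seed = seed + 10)
    grp <- rep(c("a", "b"), each = 4)
    s2 <- simper(m2, grp)
    bc <- as.matrix(bray_curtis(m2))
    expect_equal(sum(s2$average), mean(bc[1:4, 5:8]), tolerance = 1e-10)
    expect_equal(s2$cumulative_percent[nrow(s2)], 100, tolerance = 1e-8)
    # agreement with vegan's average contributions
    vs <- summary(vegan::simper(m2, grp))[[1]]
    expect_equal(s2$average[match(rownames(vs), s2$species)], vs$average,
                 tolerance = 1e-10)
  }
  # tie case: two equal contributors split 50/50, sorted by name
  mt <- rbind(a = c(4, 0, 1), b = c(0, 4, 1))
  colnames(mt) <- c("spB", "spA", "spC")
  st <- simper(mt, c("a", "b"))
  expect_equal(st$percent[1:2], c(50, 50))
  expect_equal(st$species[1:2], c("spA", "spB"))
})

test_that("alpha diversity follows the closed forms", {
  u <- matrix(5, 1, 10, dimnames = list("s", paste0("sp", 1:10)))
  a <- alpha_stats(u)
  expect_equal(a$H, log(10), tolerance = 1e-12)
  expect_equal(a$S, 10)
  single <- matrix(c(7, 0), 1, 2, dimnames = list("s", c("x", "y")))
  expect_equal(alpha_stats(single)$H, 0)
  hand <- matrix(c(5, 3, 2), 1, 3, dimnames = list("s", c("a", "b", "c")))
  expect_equal(alpha_stats(hand)$H,
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  m <- rand_counts(5, 9, seed = 21)
  expect_equal(alpha_stats(m)$H, unname(vegan::diversity(m)),
               tolerance = 1e-12)
  z <- matrix(0, 1, 3, dimnames = list("s", c("a", "b", "c")))
  expect_true(is.na(alpha_stats(z)$H))
})

test_that("accumulation curves match exhaustive subset averaging", {
  m <- rbind(s1 = c(3, 0, 1, 0), s2 = c(0, 2, 1, 0), s3 = c(1, 0, 0, 4))
  acc <- accumulation_curves(m, n_resample = 50, seed = 2)
  # endpoint equals observed pooled richness
  expect_equal(acc$sample_based$expected[3], sum(colSums(m) > 0))
  # t = 2: average richness over all C(3,2) subsets
  pairs <- combn(3, 2)
  rich2 <- mean(apply(pairs, 2, function(ix)
    sum(colSums(m[ix, , drop = FALSE]) > 0)))
  expect_equal(acc$sample_based$expected[2], rich2, tolerance = 1e-12)
  # monotone non-decreasing, read curve starts at 1 read -> 1 species
  expect_true(all(diff(acc$sample_based$expected) >= -1e-12))
  expect_true(all(diff(acc$read_based$expected) >= -1e-12))
  expect_equal(acc$read_based$expected[1], 1, tolerance = 1e-9)
  expect_equal(acc$read_based$expected[nrow(acc$read_based)],
               sum(colSums(m) > 0), tolerance = 1e-9)
  # agreement with vegan's exact estimators
  ve <- vegan::specaccum(m, method = "exact")
  expect_equal(acc$sample_based$expected, ve$richness, tolerance = 1e-10)
  m2 <- rand_counts(6, 15, seed = 23, lambda = 3)
  acc2 <- accumulation_curves(m2, n_resample = 20, seed = 3)
  ve2 <- suppressWarnings(vegan::specaccum(m2, method = "exact"))
  expect_equal(acc2$sample_based$expected, ve2$richness, tolerance = 1e-10)
  expect_error(accumulation_curves(m[1, , drop = FALSE]), "at least two")
})

test_that("Chao similarity follows the U/V formula oracle", {
  # identical assemblages
  x <- c(10, 2, 1, 0)
  r <- chao_similarity(x, x)
  expect_equal(r$chao_jaccard, 1)
  expect_equal(r$chao_sorensen, 1)
  expect_equal(r$jaccard, 1)
  # disjoint assemblages
  r0 <- chao_similarity(c(3, 2, 0, 0), c(0, 0, 4, 1))
  expect_equal(r0$chao_jaccard, 0)
  expect_equal(r0$chao_sorensen, 0)
  expect_equal(r0$sorensen, 0)
  # hand-evaluated fixture: x=(10,2,1,0), y=(5,1,0,3)
  xx <- c(10, 2, 1, 0); yy <- c(5, 1, 0, 3)
  # shared species: 1 and 2. n=13, m=9.
  # U: sum x_shared/n = 12/13; shared singletons in y: species 2 (y=1)
  #    f+1=1, f+2=0 -> use 1; U = 12/13 + (8/9)*(1/2)*(2/13)
  U <- 12 / 13 + (8 / 9) * (1 / 2) * (2 / 13)
  # V: sum y_shared/m = 6/9; shared singletons in x: species 3 not shared...
  #    shared species singleton in x: none (x=10,2) -> f+1=0, f+2=0 -> term 0
  V <- 6 / 9 + (12 / 13) * (0 / 2) * 0
  rr <- chao_similarity(xx, yy)
  expect_equal(rr$U, U, tolerance = 1e-12)
  expect_equal(rr$V, V, tolerance = 1e-12)
  expect_equal(rr$chao_jaccard, U * V / (U + V - U * V), tolerance = 1e-12)
  expect_equal(rr$chao_sorensen, 2 * U * V / (U + V), tolerance = 1e-12)
  expect_equal(rr$jaccard, 2 / 4)
  expect_equal(rr$sorensen, 2 * 2 / (2 * 2 + 1 + 1))
  # Sorensen >= Jaccard always; estimates in [0, 1]
  set.seed(31)
  for (i in 1:20) {
    a <- rpois(12, 2); b <- rpois(12, 2)
    rc <- chao_similarity(a, b)
    expect_gte(rc$chao_sorensen, rc$chao_jaccard - 1e-12)
    expect_true(all(unlist(rc) >= 0 & unlist(rc) <= 1))
  }
})

test_that("Chao estimates approach 1 for samples from one community", {
  set.seed(41)
  p <- rlnorm(40, 0, 1); p <- p / sum(p)
  small <- vapply(1:2, function(i) rmultinom(1, 200, p)[, 1], numeric(40))
  big <- vapply(1:2, function(i) rmultinom(1, 20000, p)[, 1], numeric(40))
  r_small <- chao_similarity(small[, 1], small[, 2])
  r_big <- chao_similarity(big[, 1], big[, 2])
  expect_gte(r_big$chao_sorensen, r_small$chao_sorensen - 0.02)
  expect_gt(r_big$chao_sorensen, 0.97)
  expect_gt(r_big$chao_jaccard, 0.95)
})

test_that("group comparisons reproduce the pooled-t oracle", {
  g <- group_comparison(c(3, 4, 5, 7, 8, 9), rep(c("a", "b"), each = 3))
  expect_equal(g$test, "t")
  expect_equal(g$statistic, -4.9, tolerance = 0.01)
  expect_equal(g$df, 4)
  # equal groups: t near 0, p near 1
  set.seed(51)
  y <- rnorm(400)
  g0 <- group_comparison(y, rep(c("a", "b"), each = 200))
  expect_lt(abs(g0$statistic), 2.5)
  # randomized-block ANOVA agrees with aov on the same model
  set.seed(52)
  blocks <- rep(paste0("site", 1:6), each = 2)
  grp <- rep(c("x", "y"), 6)
  val <- rnorm(12) + rep(rnorm(6, sd = 2), each = 2)
  gb <- group_comparison(val, grp, blocks = blocks)
  ref <- summary(aov(val ~ factor(blocks) + factor(grp)))[[1]]
  expect_equal(gb$statistic, ref[["F value"]][2], tolerance = 1e-10)
  expect_equal(gb$p_value, ref[["Pr(>F)"]][2], tolerance = 1e-10)
  expect_error(group_comparison(1:4, rep("a", 4)), "at least two")
})

test_that("blocked ANOVA holds its size under a block-only effect", {
  set.seed(61)
  rejections <- 0
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    blocks <- rep(paste0("b", 1:5), each = 2)
    grp <- rep(c("x", "y"), 5)
    val <- rep(rnorm(5, sd = 1.5), each = 2) + rnorm(10)
    p <- group_comparison(val, grp, blocks = blocks)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("sites nested in groups are tested against the site stratum", {
  set.seed(71)
  # 2 habitats x 3 sites x 3 depths-as-replicates
  blocks <- rep(paste0("site", 1:6), each = 3)
  grp <- rep(c("wc", "tp"), each = 9)
  val <- rnorm(18) + rep(rnorm(6, sd = 1), each = 3) +
    rep(c(0, 1.5), each = 9)
  g <- group_comparison(val, grp, blocks = blocks)
  expect_equal(g$test, "nested_block_anova")
  # oracle: F = MS_group / MS_site(group)
  gm <- mean(val)
  grp_means <- tapply(val, grp, mean)
  site_means <- tapply(val, blocks, mean)
  site_grp <- tapply(grp, blocks, function(x) x[1])
  ss_g <- sum(9 * (grp_means - gm)^2)
  ss_b <- sum(3 * (site_means - grp_means[site_grp])^2)
  f_oracle <- (ss_g / 1) / (ss_b / 4)
  expect_equal(g$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(g$df, 1)
})
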