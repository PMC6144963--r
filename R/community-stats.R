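# Community-structure statistics: transformation, ordination, PERMANOVA,
# SIMPER, alpha diversity, accumulation curves, Chao similarity and group
# comparisons.

#' Hellinger transformation
#'
#' Square root of per-sample relative abundance: y'_ij = sqrt(y_ij / sum_j
#' y_ij). Each nonzero row of the result has unit Euclidean norm, which makes
#' Euclidean distances on the transformed matrix the Hellinger distance.
#'
#' @param x Samples x species count matrix (or `community_matrix`).
#' @param zero_rows `"exclude"` (drop with a warning) or `"error"`.
#' @return Transformed matrix.
#' @export
hellinger_transform <- function(x, zero_rows = c("exclude", "error")) {
  zero_rows <- match.arg(zero_rows)
  m <- counts_of(x)
  if (any(m < 0)) stop("counts must be nonnegative")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    if (zero_rows == "error") stop("all-zero sample row")
    warning("excluding ", sum(rs == 0), " all-zero sample row(s)")
    m <- m[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  sqrt(sweep(m, 1, rs, "/"))
}

#' Bray-Curtis dissimilarity
#'
#' d(i,j) = sum_k |y_ik - y_jk| / sum_k (y_ik + y_jk), in \[0, 1\].
#'
#' @param x Samples x species matrix.
#' @return A `dist` object with method label `"bray"`.
#' @export
bray_curtis <- function(x) {
  m <- counts_of(x)
  if (nrow(m) < 2) stop("need at least two samples")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(m[i, ] + m[j, ])
    if (denom == 0) {
      if (!warned) { warning("two all-zero rows: distance set to 0"); warned <- TRUE }
      d[i, j] <- d[j, i] <- 0
    } else d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
  }
  stats::as.dist(d)
}

#' Hellinger distance (Euclidean on Hellinger-transformed counts)
#'
#' @param x Samples x species count matrix.
#' @return A `dist` object.
#' @export
hellinger_distance <- function(x) {
  stats::dist(hellinger_transform(x))
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition; axes are
#' eigenvectors scaled by the square roots of the positive eigenvalues,
#' ordered by eigenvalue. Negative eigenvalues (from non-Euclidean
#' dissimilarities) are reported and their axes dropped.
#'
#' @param d A `dist` object or symmetric matrix.
#' @return List with `coordinates`, `eigenvalues` (all, sorted),
#'   `percent_variance` (of positive eigenvalues) and `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = e$values,
       percent_variance = 100 * e$values[pos] / sum(e$values[pos]),
       negative_eigenvalues = e$values[e$values < -tol])
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared dissimilarities into among- and within-group sums
#' of squares; significance of the pseudo-F is assessed by permuting sample
#' labels. With `exact = TRUE` all N! label permutations are enumerated
#' instead of Monte-Carlo sampling.
#'
#' @param d A `dist` object or symmetric matrix.
#' @param groups Factor of group labels (>= 2 groups, each of size >= 2).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Optional seed for the permutations.
#' @param exact Enumerate all permutations (requires <= 8 samples).
#' @return List with `pseudo_F`, `R_squared`, `p_value`, `n_permutations`,
#'   `SS` components and the permutation F distribution (`F_perm`).
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  D <- as.matrix(d)
  N <- nrow(D)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("degenerate group (size 1)")
  a <- nlevels(groups)
  d2 <- D^2
  ss_t <- sum(d2[upper.tri(d2)]) / N
  g <- as.integer(groups)
  f_of <- function(lab) {
    ssw <- permanova_ssw_cpp(d2, matrix(lab, nrow = 1))
    ssa <- ss_t - ssw
    (ssa / (a - 1)) / (ssw / (N - a))
  }
  ssw_obs <- permanova_ssw_cpp(d2, matrix(g, nrow = 1))[1]
  ss_a <- ss_t - ssw_obs
  f_obs <- (ss_a / (a - 1)) / (ssw_obs / (N - a))
  if (exact) {
    if (N > 8) stop("exact enumeration limited to 8 samples")
    perms <- permutations_of(N)
    lab <- t(apply(perms, 1, function(p) g[p]))
  } else {
    if (!is.null(seed)) set.seed(seed)
    lab <- t(replicate(n_perm, g[sample.int(N)]))
  }
  ssw_p <- permanova_ssw_cpp(d2, lab)
  f_perm <- ((ss_t - ssw_p) / (a - 1)) / (ssw_p / (N - a))
  p <- (sum(f_perm >= f_obs - 1e-12) + !exact) / (length(f_perm) + !exact)
  list(pseudo_F = f_obs, R_squared = ss_a / ss_t, p_value = p,
       n_permutations = length(f_perm), seed = seed,
       SS = c(total = ss_t, among = ss_a, within = ssw_obs),
       F_perm = f_perm)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' SIMPER: species contributions to between-group dissimilarity
#'
#' For every between-group sample pair the per-species Bray-Curtis
#' contribution is |y_ik - y_jk| / sum_s (y_is + y_js); species are averaged
#' over all between-group pairs. The summed average contributions equal the
#' mean between-group Bray-Curtis dissimilarity. Ties in the ranking are
#' broken by species name.
#'
#' @param x Samples x species count matrix.
#' @param groups Factor with exactly two levels.
#' @return `data.frame` with `species`, `average`, `percent`,
#'   `cumulative_percent`, sorted by decreasing contribution.
#' @export
simper <- function(x, groups) {
  m <- counts_of(x)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("sp", seq_len(ncol(m)))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("SIMPER needs exactly two groups")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  contrib <- numeric(ncol(m))
  n_pairs <- 0L
  for (i in i1) for (j in i2) {
    denom <- sum(m[i, ] + m[j, ])
    if (denom == 0) next
    contrib <- contrib + abs(m[i, ] - m[j, ]) / denom
    n_pairs <- n_pairs + 1L
  }
  contrib <- contrib / n_pairs
  ord <- order(-contrib, colnames(m))
  out <- data.frame(species = colnames(m)[ord], average = contrib[ord],
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$average / sum(out$average)
  out$cumulative_percent <- cumsum(out$percent)
  out
}

#' Per-sample alpha diversity
#'
#' Shannon H (natural log by default), richness S and read count N.
#' Zero-read samples get NA diversity.
#'
#' @param x Samples x species count matrix.
#' @param base Logarithm base (e is the convention here).
#' @return `data.frame` with `sample_id`, `H`, `S`, `N`.
#' @export
alpha_stats <- function(x, base = exp(1)) {
  m <- counts_of(x)
  if (any(m < 0)) stop("counts must be nonnegative")
  H <- apply(m, 1, function(y) {
    N <- sum(y)
    if (N == 0) return(NA_real_)
    p <- y[y > 0] / N
    -sum(p * log(p, base = base))
  })
  data.frame(sample_id = rownames(m), H = unname(H),
             S = unname(rowSums(m > 0)), N = unname(rowSums(m)),
             stringsAsFactors = FALSE)
}

#' Sample- and read-based species accumulation curves
#'
#' Sample-based expected richness after t samples uses the hypergeometric
#' form E\[S_t\] = sum_i (1 - C(T - O_i, t) / C(T, t)) with O_i the number of
#' samples containing species i; the read-based curve applies the same form
#' to pooled read counts. 95% envelopes come from resampling (random sample
#' orderings, and random read subsamples via shuffled pooled reads).
#'
#' @param x Samples x species count matrix.
#' @param read_grid_len Number of grid points of the read-based curve.
#' @param n_resample Resampling replicates for the envelopes.
#' @param seed Seed for the envelopes.
#' @return List of two `data.frame`s, `sample_based` (`t`, `expected`,
#'   `lower`, `upper`) and `read_based` (`n`, `expected`, `lower`, `upper`).
#' @export
accumulation_curves <- function(x, read_grid_len = 50L, n_resample = 100L,
                                seed = 1L) {
  m <- counts_of(x)
  if (nrow(m) < 2) stop("need at least two samples")
  T_ <- nrow(m)
  O <- colSums(m > 0)
  O <- O[O > 0]
  exp_sample <- function(t) {
    if (t > T_) stop("t exceeds the number of samples")
    sum(1 - exp(lchoose(T_ - O, t) - lchoose(T_, t)))
  }
  pooled <- colSums(m)
  pooled <- pooled[pooled > 0]
  N <- sum(pooled)
  exp_read <- function(n) {
    if (n > N) stop("n exceeds the number of reads")
    sum(1 - exp(lchoose(N - pooled, n) - lchoose(N, n)))
  }
  ts <- seq_len(T_)
  ns <- unique(round(seq(1, N, length.out = min(read_grid_len, N))))
  set.seed(seed)
  rich_sample <- replicate(n_resample, {
    ord <- sample.int(T_)
    seen <- matrix(FALSE, 1, ncol(m))
    cummax_rich <- integer(T_)
    acc <- rep(FALSE, ncol(m))
    for (k in seq_len(T_)) {
      acc <- acc | (m[ord[k], ] > 0)
      cummax_rich[k] <- sum(acc)
    }
    cummax_rich
  })
  reads_vec <- rep(seq_along(pooled), pooled)
  rich_read <- replicate(n_resample, {
    ord <- sample(reads_vec)
    first <- match(seq_along(pooled), ord)
    first <- sort(first[!is.na(first)])
    vapply(ns, function(n) sum(first <= n), numeric(1))
  })
  sb <- data.frame(t = ts,
                   expected = vapply(ts, exp_sample, numeric(1)),
                   lower = apply(rich_sample, 1, quantile, 0.025),
                   upper = apply(rich_sample, 1, quantile, 0.975))
  rb <- data.frame(n = ns,
                   expected = vapply(ns, exp_read, numeric(1)),
                   lower = apply(rich_read, 1, quantile, 0.025),
                   upper = apply(rich_read, 1, quantile, 0.975))
  list(sample_based = sb, read_based = rb)
}

#' Chao abundance-based similarity estimators for two assemblages
#'
#' Computes the abundance-based Chao-Jaccard and Chao-Sorensen estimates,
#' which correct the shared-species probabilities U and V for unseen shared
#' species via the singleton/doubleton counts of the other assemblage, plus
#' the classic incidence-based Jaccard and Sorensen indices.
#'
#' @param x_counts,y_counts Abundance vectors on a shared species index.
#' @return List with `U`, `V`, `chao_jaccard`, `chao_sorensen`, `jaccard`,
#'   `sorensen`.
#' @export
chao_similarity <- function(x_counts, y_counts) {
  stopifnot(length(x_counts) == length(y_counts))
  shared <- x_counts > 0 & y_counts > 0
  a <- sum(shared)
  b <- sum(x_counts > 0 & y_counts == 0)
  c_ <- sum(x_counts == 0 & y_counts > 0)
  jac <- if (a + b + c_ > 0) a / (a + b + c_) else 0
  sor <- if (2 * a + b + c_ > 0) 2 * a / (2 * a + b + c_) else 0
  if (a == 0)
    return(list(U = 0, V = 0, chao_jaccard = 0, chao_sorensen = 0,
                jaccard = jac, sorensen = sor))
  n <- sum(x_counts); m <- sum(y_counts)
  U_of <- function(x, y, n, m) {
    sh <- x > 0 & y > 0
    f1 <- sum(sh & y == 1)   # shared species that are singletons in y
    f2 <- sum(sh & y == 2)   # ... doubletons in y
    if (f2 == 0) f2 <- 1
    u <- sum(x[sh]) / n + ((m - 1) / m) * (f1 / (2 * f2)) *
      sum(x[sh & y == 1]) / n
    min(u, 1)
  }
  U <- U_of(x_counts, y_counts, n, m)
  V <- U_of(y_counts, x_counts, m, n)
  list(U = U, V = V,
       chao_jaccard = if (U + V - U * V > 0) U * V / (U + V - U * V) else 0,
       chao_sorensen = if (U + V > 0) 2 * U * V / (U + V) else 0,
       jaccard = jac, sorensen = sor)
}

#' Group comparisons of diversity summaries
#'
#' One-factor comparisons of a per-sample summary (diversity, richness, read
#' abundance). With a block factor crossed with the groups, a
#' randomized-block ANOVA (`y ~ block + group`) stands in for a mixed model
#' with the block as a random term; with blocks nested in groups (sites
#' within habitats) the factor is tested against the between-block stratum
#' (`y ~ group + Error(block)`). With exactly two groups and no blocks, a
#' pooled-variance Student's t test is used. Read abundances can be
#' log10-transformed first.
#'
#' @param values Numeric response per sample.
#' @param groups Factor of group labels.
#' @param blocks Optional block factor (e.g. site).
#' @param log10_transform Apply log10 to the response first.
#' @return `data.frame` with `test`, `statistic`, `df`, `p_value`.
#' @export
group_comparison <- function(values, groups, blocks = NULL,
                             log10_transform = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  y <- if (log10_transform) log10(values) else values
  if (is.null(blocks)) {
    if (nlevels(groups) == 2) {
      tt <- t.test(y ~ groups, var.equal = TRUE)
      return(data.frame(test = "t", statistic = unname(tt$statistic),
                        df = unname(tt$parameter), p_value = tt$p.value,
                        stringsAsFactors = FALSE))
    }
    fit <- aov(y ~ groups)
    s <- summary(fit)[[1]]
    return(data.frame(test = "anova", statistic = s[["F value"]][1],
                      df = s[["Df"]][1], p_value = s[["Pr(>F)"]][1],
                      stringsAsFactors = FALSE))
  }
  blocks <- factor(blocks)
  nested <- all(rowSums(table(blocks, groups) > 0) == 1)
  if (nested) {
    # blocks nested in groups (e.g. sites within habitats): the factor must
    # be tested against between-block variation, as a site-random model would
    fit <- aov(y ~ groups + Error(blocks))
    s <- summary(fit)
    st <- s[[grep("blocks", names(s))]][[1]]
    i <- grep("groups", rownames(st))
    return(data.frame(test = "nested_block_anova",
                      statistic = st[["F value"]][i], df = st[["Df"]][i],
                      p_value = st[["Pr(>F)"]][i], stringsAsFactors = FALSE))
  }
  fit <- aov(y ~ blocks + groups)
  s <- summary(fit)[[1]]
  i <- grep("groups", rownames(s))
  data.frame(test = "randomized_block_anova", statistic = s[["F value"]][i],
             df = s[["Df"]][i], p_value = s[["Pr(>F)"]][i],
             stringsAsFactors = FALSE)
}
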