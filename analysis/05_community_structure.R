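#!/usr/bin/env Rscript
# Stage 5: the community-structure statistics on the assigned matrix —
# habitat and depth PERMANOVA on Hellinger distances with PCoA ordination,
# SIMPER species contributions, Shannon/richness/read-abundance comparisons
# (sites as blocks), S20-vs-F20 season t tests, accumulation curves and
# Chao similarity between sampling locations.
#
# Outputs: results/05_*.tsv / .json, figures under results/figures/

library(ednacoi)

res <- readRDS("scratch/analysis/assignment.rds")
meta <- res$matrix$metadata
keep <- !meta$is_control & rowSums(res$matrix$counts) > 0
counts <- res$matrix$counts[keep, , drop = FALSE]
meta <- meta[keep, , drop = FALSE]
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
stats_json <- list()

## habitat: water column vs tide pools (summer samples)
s20 <- meta$season == "S20" & meta$habitat %in% c("water_column", "tide_pool")
d_hab <- hellinger_distance(counts[s20, , drop = FALSE])
pm_hab <- permanova(d_hab, meta$habitat[s20], n_perm = 999, seed = 1)
cat(sprintf("Habitat PERMANOVA: R2 = %.3f, F = %.2f, p = %.3g\n",
            pm_hab$R_squared, pm_hab$pseudo_F, pm_hab$p_value))
stats_json$permanova_habitat <- pm_hab[c("pseudo_F", "R_squared", "p_value",
                                         "n_permutations")]
sim_hab <- simper(counts[s20, , drop = FALSE], meta$habitat[s20])
write.table(sim_hab, "results/05_simper_habitat.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Top SIMPER species:", sim_hab$species[1],
    sprintf("(%.1f%%); top-10 cumulative %.1f%%\n", sim_hab$percent[1],
            sim_hab$cumulative_percent[10]))

## depths within the water column
wc <- meta$habitat == "water_column"
pm_dep <- permanova(hellinger_distance(counts[wc, , drop = FALSE]),
                    meta$depth[wc], n_perm = 999, seed = 2)
cat(sprintf("Depth PERMANOVA: R2 = %.3f, p = %.3g\n",
            pm_dep$R_squared, pm_dep$p_value))
stats_json$permanova_depth <- pm_dep[c("pseudo_F", "R_squared", "p_value",
                                       "n_permutations")]

## ordination
ord <- pcoa(hellinger_distance(counts))
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, 1:2],
                     habitat = meta$habitat, depth = meta$depth,
                     season = meta$season)
write.table(coords, "results/05_pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA axes 1-2 explain %.1f%% + %.1f%% of the variance\n",
            ord$percent_variance[1], ord$percent_variance[2]))

## alpha diversity and group comparisons
alpha <- alpha_stats(counts)
alpha <- cbind(alpha, meta[match(alpha$sample_id, meta$sample_id),
                           c("site_id", "habitat", "depth", "season")])
write.table(alpha, "results/05_alpha_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hb <- alpha$habitat %in% c("water_column", "tide_pool") & alpha$season == "S20"
tests <- rbind(
  data.frame(contrast = "habitat_H",
             group_comparison(alpha$H[hb], alpha$habitat[hb],
                              blocks = alpha$site_id[hb])),
  data.frame(contrast = "habitat_S",
             group_comparison(alpha$S[hb], alpha$habitat[hb],
                              blocks = alpha$site_id[hb])),
  data.frame(contrast = "habitat_log10N",
             group_comparison(alpha$N[hb], alpha$habitat[hb],
                              blocks = alpha$site_id[hb],
                              log10_transform = TRUE)),
  data.frame(contrast = "depth_H",
             group_comparison(alpha$H[alpha$habitat == "water_column"],
                              alpha$depth[alpha$habitat == "water_column"],
                              blocks = alpha$site_id[alpha$habitat == "water_column"])))
shore <- alpha$habitat == "shore"
if (length(unique(alpha$season[shore])) == 2) {
  tests <- rbind(tests,
    data.frame(contrast = "season_H",
               group_comparison(alpha$H[shore], alpha$season[shore])),
    data.frame(contrast = "season_S",
               group_comparison(alpha$S[shore], alpha$season[shore])),
    data.frame(contrast = "season_log10N",
               group_comparison(alpha$N[shore], alpha$season[shore],
                                log10_transform = TRUE)))
}
write.table(tests, "results/05_group_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Group comparisons written; habitat Shannon p =",
    signif(tests$p_value[tests$contrast == "habitat_H"], 3), "\n")

## accumulation curves (pooled, per habitat written for plotting)
acc <- accumulation_curves(counts, seed = 3)
write.table(acc$sample_based, "results/05_accumulation_samples.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(acc$read_based, "results/05_accumulation_reads.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## Chao similarity between sampling locations
loc_of <- ifelse(meta$habitat == "water_column",
                 paste0("wc_", meta$depth),
                 ifelse(meta$habitat == "shore",
                        paste0("shore_", meta$season), "tide_pool"))
locs <- sort(unique(loc_of))
pairs <- t(combn(locs, 2))
chao <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  x <- colSums(counts[loc_of == pairs[i, 1], , drop = FALSE])
  y <- colSums(counts[loc_of == pairs[i, 2], , drop = FALSE])
  cs <- chao_similarity(x, y)
  data.frame(a = pairs[i, 1], b = pairs[i, 2],
             chao_sorensen = cs$chao_sorensen, chao_jaccard = cs$chao_jaccard,
             sorensen = cs$sorensen, jaccard = cs$jaccard)
}))
write.table(chao, "results/05_chao_similarity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(stats_json, "results/05_statistics.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

## figures
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  ggsave("results/figures/pcoa.png",
         ggplot(coords, aes(PCo1, PCo2, colour = habitat,
                            shape = season)) +
           geom_point(size = 2.5) + theme_bw() +
           labs(title = "PCoA of Hellinger distances"),
         width = 6, height = 4.5, dpi = 150)
  ggsave("results/figures/accumulation.png",
         ggplot(acc$sample_based, aes(t, expected)) +
           geom_ribbon(aes(ymin = lower, ymax = upper), alpha = 0.2) +
           geom_line() + theme_bw() +
           labs(x = "samples", y = "expected species"),
         width = 6, height = 4, dpi = 150)
  ggsave("results/figures/alpha_by_location.png",
         ggplot(alpha, aes(habitat, H)) + geom_boxplot() + theme_bw() +
           labs(y = "Shannon H"),
         width = 6, height = 4, dpi = 150)
}
cat("Done.\n")
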