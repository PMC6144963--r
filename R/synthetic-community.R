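# Planted community structure: who lives where, and how abundantly.

#' Describe a synthetic sampling design
#'
#' A design couples a sampling layout (sites by habitat, depths, seasons) to
#' an abundance model: a shared log-normal base abundance per species,
#' multiplied by planted effect multipliers for chosen factor levels. The
#' defaults mirror a two-season Arctic port survey: subtidal sites sampled at
#' surface / mid / deep, intertidal tide pools, a shore transect resampled in
#' summer (S20) and fall (F20), and one negative control per ten samples.
#'
#' @param species Character vector of community members (must exist in the
#'   pool used downstream).
#' @param n_water_column_sites,n_tide_pool_sites,n_shore_samples Layout sizes.
#' @param seasons Seasons the shore transect is sampled in.
#' @param effects List of planted effects, each a
#'   `list(factor=, level=, species=, multiplier=)`; multipliers act on the
#'   pre-normalisation abundance of the listed species in samples whose
#'   metadata matches `factor == level`.
#' @param meanlog,sdlog Log-normal base-abundance parameters.
#' @param reads_per_sample Sequencing depth per (non-control) sample.
#' @param error_rate Per-base substitution probability applied to each
#'   amplicon copy.
#' @param river_sites Site ids whose surface samples receive freshwater
#'   species (river influence); freshwater species have zero probability
#'   everywhere else.
#' @param control_every One negative control per this many samples.
#' @param seed Integer seed.
#' @return An object of class `community_design`.
#' @export
community_design <- function(species,
                             n_water_column_sites = 13L,
                             n_tide_pool_sites = 12L,
                             n_shore_samples = 20L,
                             seasons = c("S20", "F20"),
                             effects = list(),
                             meanlog = 0, sdlog = 1.5,
                             reads_per_sample = 10000L,
                             error_rate = 0.005,
                             river_sites = character(),
                             control_every = 10L,
                             seed = 1L) {
  stopifnot(length(species) > 0, reads_per_sample >= 0,
            error_rate >= 0, error_rate < 0.03)
  for (e in effects) {
    stopifnot(all(c("factor", "level", "species", "multiplier") %in% names(e)))
    if (any(e$multiplier <= 0)) stop("effect multipliers must be positive")
  }
  meta <- list()
  if (n_water_column_sites > 0) {
    wc <- expand.grid(site_id = sprintf("WC%02d", seq_len(n_water_column_sites)),
                      depth = c("surface", "mid", "deep"),
                      stringsAsFactors = FALSE)
    meta$wc <- data.frame(site_id = wc$site_id, habitat = "water_column",
                          depth = wc$depth, season = "S20",
                          stringsAsFactors = FALSE)
  }
  if (n_tide_pool_sites > 0)
    meta$tp <- data.frame(site_id = sprintf("TP%02d", seq_len(n_tide_pool_sites)),
                          habitat = "tide_pool", depth = NA_character_,
                          season = "S20", stringsAsFactors = FALSE)
  if (n_shore_samples > 0)
    for (ssn in seasons)
      meta[[paste0("sh", ssn)]] <-
        data.frame(site_id = sprintf("SH01"), habitat = "shore",
                   depth = "surface", season = ssn, stringsAsFactors = FALSE)[
                     rep(1, n_shore_samples), , drop = FALSE]
  metadata <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  metadata$is_control <- FALSE
  if (control_every > 0 && nrow(metadata) >= control_every) {
    n_ctl <- nrow(metadata) %/% control_every
    ctl <- data.frame(site_id = sprintf("CTL%02d", seq_len(n_ctl)),
                      habitat = "control", depth = NA_character_,
                      season = "S20", is_control = TRUE,
                      stringsAsFactors = FALSE)
    metadata <- rbind(metadata, ctl)
  }
  metadata$sample_id <- sprintf("S%03d", seq_len(nrow(metadata)))
  metadata$river_influence <- metadata$site_id %in% river_sites &
    !is.na(metadata$depth) & metadata$depth == "surface"
  metadata <- metadata[, c("sample_id", "site_id", "habitat", "depth",
                           "season", "river_influence", "is_control")]
  structure(list(species = species, metadata = metadata, effects = effects,
                 meanlog = meanlog, sdlog = sdlog,
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_design")
}

#' Simulate true per-sample species read counts
#'
#' Per-species base abundance is drawn once from the design's log-normal
#' model; each sample's species probabilities are the base abundances times
#' all applicable effect multipliers, with freshwater species zeroed outside
#' river-influenced surface samples, normalised and fed to a multinomial draw
#' of `reads_per_sample` reads. Control samples receive all-zero truth (their
#' stray reads are added at read synthesis).
#'
#' @param design A [community_design()].
#' @param pool Species pool (for habitat classes).
#' @return A `truth` list: `counts` (samples x species integer matrix),
#'   `metadata`, and `base_abundance`.
#' @export
simulate_community_matrix <- function(design, pool) {
  stopifnot(inherits(design, "community_design"))
  missing_sp <- setdiff(design$species, pool$species_name)
  if (length(missing_sp)) stop("species not in pool: ", missing_sp[1L])
  set.seed(design$seed)
  sp <- design$species
  nsp <- length(sp)
  meta <- design$metadata
  base <- rlnorm(nsp, design$meanlog, design$sdlog)
  names(base) <- sp
  hab <- pool$habitat_class[match(sp, pool$species_name)]
  counts <- matrix(0L, nrow(meta), nsp,
                   dimnames = list(meta$sample_id, sp))
  for (i in seq_len(nrow(meta))) {
    if (meta$is_control[i]) next
    p <- base
    for (e in design$effects) {
      val <- meta[[e$factor]][i]
      if (!is.na(val) && val == e$level) {
        j <- match(intersect(e$species, sp), sp)
        p[j] <- p[j] * e$multiplier
      }
    }
    p[hab == "freshwater" & !meta$river_influence[i]] <- 0
    if (sum(p) == 0 || design$reads_per_sample == 0) next
    counts[i, ] <- rmultinom(1, design$reads_per_sample, p / sum(p))[, 1]
  }
  structure(list(counts = counts, metadata = meta, base_abundance = base),
            class = "community_truth")
}
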