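# End-to-end orchestration: simulate -> process -> assign -> profile ->
# coverage -> stats, from a single config, with a manifest recording
# read-count conservation and output hashes.

#' Write / read a community matrix as TSV (+ metadata TSV)
#'
#' @param cm A `community_matrix`.
#' @param path Counts TSV path (samples in rows, species in columns); the
#'   metadata is written next to it as `<path>.metadata.tsv`.
#' @return `read_community_matrix` returns a `community_matrix`.
#' @export
write_community_matrix <- function(cm, path) {
  df <- data.frame(sample_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cm$metadata))
    write.table(cm$metadata, paste0(path, ".metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$sample_id
  meta_path <- paste0(path, ".metadata.tsv")
  meta <- if (file.exists(meta_path)) read.delim(meta_path,
                                                 stringsAsFactors = FALSE)
  community_matrix(counts, metadata = meta)
}

#' Default pipeline run configuration
#'
#' Bundles the documented defaults: 97% assignment identity, 30 nt minimum
#' merge overlap, 270 nt minimum insert, 97% OTU similarity, two primer
#' mismatches tolerated at the demultiplexing and audit stages.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @param ... Overrides of the defaults (nested lists are replaced whole).
#' @return A `run_config` list.
#' @export
default_run_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "process", "assign", "profile", "coverage",
               "stats"),
    pool = list(n_native = 60L, n_invader = 10L, n_terrestrial = 3L,
                n_sister_pairs = 0L),
    reference = list(fraction_with_barcode = 1.0),
    design = list(n_water_column_sites = 4L, n_tide_pool_sites = 4L,
                  n_shore_samples = 4L, reads_per_sample = 2000L,
                  error_rate = 0.005, n_community_species = 40L,
                  tide_pool_species = 10L, tide_pool_multiplier = 3),
    read_len = 250L,
    thresholds = list(identity = 0.97, min_overlap = 30L, min_insert = 270L,
                      similarity = 0.97, primer_mismatches = 2L,
                      max_mismatch_frac = 0.1, contamination = 0.01),
    control_max_reads = 5L,
    matrix_path = NULL)
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config(cfg$out_dir %||% ".", seed = cfg$seed %||% 1L)
  for (nm in setdiff(names(cfg), c("out_dir", "seed"))) {
    base[[nm]] <- if (is.list(cfg[[nm]]) && is.list(base[[nm]]))
      utils::modifyList(base[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  base$seed <- as.integer(base$seed)
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline end to end from a configuration
#'
#' Executes the enabled stages in order, writing every intermediate artifact
#' under `config$out_dir` and a manifest JSON recording the config hash,
#' seed, per-stage read tallies and output-file hashes. A rerun with the same
#' config and seed is bit-identical for the deterministic stages.
#'
#' @param config A `run_config`, see [default_run_config()].
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  primers <- default_primer_set()
  manifest <- list(seed = cfg$seed, stages = cfg$stages,
                   config_hash = config_hash(cfg), tallies = list())
  st <- function(s) s %in% cfg$stages
  pool <- db <- truth <- reads <- result <- NULL

  if (st("simulate")) {
    pool <- make_species_pool(n_native = cfg$pool$n_native,
                              n_invader = cfg$pool$n_invader,
                              n_terrestrial = cfg$pool$n_terrestrial,
                              n_sister_pairs = cfg$pool$n_sister_pairs %||% 0L,
                              primers = primers, seed = cfg$seed)
    db <- generate_reference_db(pool, cfg$reference$fraction_with_barcode,
                                seed = cfg$seed + 1L)
    write_reference_fasta(db, file.path(cfg$out_dir, "reference.fasta"))
    write_checklist(generate_checklist(pool, "native"),
                    file.path(cfg$out_dir, "checklist_native.tsv"))
    write_checklist(generate_checklist(pool, "invader"),
                    file.path(cfg$out_dir, "checklist_invader.tsv"))
    dz <- cfg$design
    aquatic <- pool$species_name[pool$habitat_class != "terrestrial"]
    set.seed(cfg$seed + 2L)
    community <- sample(aquatic, min(dz$n_community_species, length(aquatic)))
    effects <- list()
    if ((dz$tide_pool_species %||% 0L) > 0)
      effects <- list(list(factor = "habitat", level = "tide_pool",
                           species = head(community, dz$tide_pool_species),
                           multiplier = dz$tide_pool_multiplier))
    design <- community_design(
      species = community,
      n_water_column_sites = dz$n_water_column_sites,
      n_tide_pool_sites = dz$n_tide_pool_sites,
      n_shore_samples = dz$n_shore_samples,
      effects = effects,
      reads_per_sample = dz$reads_per_sample,
      error_rate = dz$error_rate,
      seed = cfg$seed + 3L)
    truth <- simulate_community_matrix(design, pool)
    reads <- synthesize_reads(truth, pool,
                              out_dir = file.path(cfg$out_dir, "reads"),
                              read_len = cfg$read_len,
                              error_rate = dz$error_rate,
                              control_max_reads = cfg$control_max_reads,
                              seed = cfg$seed + 4L)
    write.table(reads$read_truth, file.path(cfg$out_dir, "read_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$tallies$simulate <- c(
      samples = nrow(truth$metadata),
      reads = nrow(reads$read_truth))
  }

  inserts <- NULL
  if (st("process")) {
    if (is.null(reads)) {
      # resume from reads already on disk
      r1s <- sort(list.files(file.path(cfg$out_dir, "reads"),
                             pattern = "_R1\\.fastq\\.gz$", full.names = TRUE))
      if (!length(r1s)) stop("stage process: no reads found")
      sids <- sub("_R1\\.fastq\\.gz$", "", basename(r1s))
      reads <- list(files = setNames(lapply(seq_along(r1s), function(i)
        c(R1 = r1s[i], R2 = sub("_R1\\.fastq", "_R2.fastq", r1s[i]))), sids))
    }
    per_sample <- list()
    tallies <- list()
    for (sid in names(reads$files)) {
      pr <- tryCatch(
        process_sample_reads(
          reads$files[[sid]]["R1"], reads$files[[sid]]["R2"], primers,
          min_overlap = cfg$thresholds$min_overlap,
          max_mismatch_frac = cfg$thresholds$max_mismatch_frac,
          max_mismatches = cfg$thresholds$primer_mismatches,
          min_insert = cfg$thresholds$min_insert),
        error = function(e) stop("stage process failed for sample ", sid,
                                 ": ", conditionMessage(e), call. = FALSE))
      if (nrow(pr$inserts))
        per_sample[[sid]] <- data.frame(sample_id = sid, pr$inserts,
                                        stringsAsFactors = FALSE)
      tallies[[sid]] <- pr$tally
    }
    inserts <- do.call(rbind, c(per_sample, list(make.row.names = FALSE)))
    tl <- do.call(rbind, tallies)
    write.table(data.frame(sample_id = rownames(tl), tl),
                file.path(cfg$out_dir, "processing_tally.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$tallies$process <- colSums(tl)
  }

  if (st("assign")) {
    if (is.null(inserts)) stop("stage assign: no inserts (enable process)")
    cur <- curate_reference(db)
    result <- assign_reads(inserts[, c("sample_id", "marker", "insert")],
                           cur, threshold = cfg$thresholds$identity,
                           metadata = truth$metadata)
    write_community_matrix(result$matrix,
                           file.path(cfg$out_dir, "community_matrix.tsv"))
    write.table(result$multi_hits, file.path(cfg$out_dir, "multi_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$tallies$assign <- result$tally
    ctl <- control_summary(result$matrix,
                           threshold = cfg$thresholds$contamination)
    write.table(ctl, file.path(cfg$out_dir, "control_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (st("profile")) {
    if (is.null(inserts)) stop("stage profile: no inserts (enable process)")
    cur <- curate_reference(db)
    prof <- list()
    for (mk in unique(inserts$marker)) {
      otus <- cluster_otus(inserts$insert[inserts$marker == mk],
                           cfg$thresholds$similarity)
      if (nrow(otus) == 0) next
      pr <- assignability_profile(otus, cur)
      prof[[mk]] <- data.frame(marker = mk, pr$by_phylum,
                               stringsAsFactors = FALSE)
    }
    prof_df <- do.call(rbind, c(prof, list(make.row.names = FALSE)))
    write.table(prof_df, file.path(cfg$out_dir, "assignability_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (st("coverage")) {
    cl <- list(native = generate_checklist(pool, "native"),
               invader = generate_checklist(pool, "invader"))
    cl <- Filter(function(x) nrow(x) > 0, cl)
    cov <- coverage_report(cl, list(snapshot = db), primers,
                           max_mismatch = cfg$thresholds$primer_mismatches)
    write.table(cov, file.path(cfg$out_dir, "coverage_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cov, file.path(cfg$out_dir, "coverage_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (st("stats")) {
    cm <- if (!is.null(result)) result$matrix
      else if (!is.null(cfg$matrix_path)) read_community_matrix(cfg$matrix_path)
      else stop("stage stats: no community matrix")
    stats_out <- pipeline_stats(cm, seed = cfg$seed,
                                out_dir = cfg$out_dir)
    manifest$tallies$stats <- c(samples = nrow(stats_out$alpha))
  }

  out_files <- setdiff(list.files(cfg$out_dir, recursive = TRUE,
                                  full.names = TRUE),
                       file.path(cfg$out_dir, "manifest.json"))
  manifest$file_hashes <- as.list(tools::md5sum(sort(out_files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# downstream statistics for a pipeline run; kept small on purpose
pipeline_stats <- function(cm, seed, out_dir) {
  meta <- cm$metadata
  keep <- !meta$is_control & rowSums(cm$counts) > 0
  counts <- cm$counts[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  alpha <- alpha_stats(counts)
  write.table(alpha, file.path(out_dir, "alpha_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res <- list(alpha = alpha)
  two_hab <- meta$habitat %in% c("water_column", "tide_pool")
  if (length(unique(meta$habitat[two_hab])) == 2 &&
      all(table(meta$habitat[two_hab]) >= 2)) {
    d <- hellinger_distance(counts[two_hab, , drop = FALSE])
    pm <- permanova(d, meta$habitat[two_hab], n_perm = 999, seed = seed)
    pm$F_perm <- NULL
    jsonlite::write_json(pm, file.path(out_dir, "permanova_habitat.json"),
                         auto_unbox = TRUE, digits = NA)
    sim <- simper(counts[two_hab, , drop = FALSE], meta$habitat[two_hab])
    write.table(sim, file.path(out_dir, "simper_habitat.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$permanova <- pm
  }
  ord <- pcoa(hellinger_distance(counts))
  write.table(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, 1:min(3, ncol(ord$coordinates)),
                                         drop = FALSE]),
              file.path(out_dir, "pcoa_coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  acc <- accumulation_curves(counts, seed = seed)
  write.table(acc$sample_based, file.path(out_dir, "accumulation_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(acc$read_based, file.path(out_dir, "accumulation_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

#' Negative-control read summary
#'
#' Reports, per control sample, the total assigned reads and their percentage
#' of the mean non-control sample total, flagging controls above the
#' contamination threshold.
#'
#' @param cm A `community_matrix` whose metadata flags controls
#'   (`is_control`), or a plain matrix plus `control_ids`.
#' @param control_ids Sample ids of the controls (overrides metadata).
#' @param threshold Contamination flag threshold as a fraction of the mean
#'   non-control sample total.
#' @return `data.frame` with `sample_id`, `reads`, `percent_of_mean_sample`,
#'   `flagged`. Empty (with a note attribute) when there are no controls.
#' @export
control_summary <- function(cm, control_ids = NULL, threshold = 0.01) {
  counts <- counts_of(cm)
  if (is.null(control_ids)) {
    meta <- if (inherits(cm, "community_matrix")) cm$metadata else NULL
    if (!is.null(meta) && "is_control" %in% names(meta))
      control_ids <- meta$sample_id[meta$is_control]
  }
  if (is.null(control_ids) || !length(control_ids)) {
    out <- data.frame(sample_id = character(), reads = integer(),
                      percent_of_mean_sample = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "note") <- "no control samples"
    return(out)
  }
  is_ctl <- rownames(counts) %in% control_ids
  mean_sample <- mean(rowSums(counts[!is_ctl, , drop = FALSE]))
  reads <- rowSums(counts[is_ctl, , drop = FALSE])
  pct <- if (mean_sample > 0) 100 * reads / mean_sample else rep(0, sum(is_ctl))
  data.frame(sample_id = rownames(counts)[is_ctl], reads = unname(reads),
             percent_of_mean_sample = unname(pct),
             flagged = unname(pct > 100 * threshold),
             stringsAsFactors = FALSE)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg$stages <- NULL
  cfg$out_dir <- NULL
  cfg$matrix_path <- NULL
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
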