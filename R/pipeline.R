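# End-to-end drivers: compose the spectratype and repertoire analyses,
# write all result artifacts, and emit a machine-readable run report with
# content hashes for reproducibility checks.

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.vector(h), basename(paths))
}

cfg_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the spectratype perturbation pipeline
#'
#' Executes, in order: segment exclusions, profile normalization, reference
#' construction (the average profile of a chosen reference population),
#' per-sample deviation matrices, the perturbation score matrix,
#' Euclidean/average-linkage clustering of samples, PCA, and a one-way ANOVA
#' with Holm-adjusted pairwise comparisons of the overall perturbation
#' scores. All artifacts are written to \code{out_dir} as TSV/Newick/JSON,
#' and the run report lists every output with its md5 hash: identical input,
#' parameters and seed reproduce identical hashes.
#'
#' @param peaks_path spectratype peak CSV
#'   (\code{\link{read_spectratype_peaks}}).
#' @param out_dir output directory (created if needed).
#' @param reference_group population whose samples define the reference
#'   profile (e.g. \code{"Tfr"} for a group average, or a naive-control
#'   population present in the table).
#' @param excluded TRBV segments to drop
#'   (\code{\link{default_excluded_segments}} by default).
#' @param seed integer seed (recorded; this track is deterministic).
#' @return the run report, invisibly.
#' @export
run_spectratype_pipeline <- function(peaks_path, out_dir,
                                     reference_group = "Tfr",
                                     excluded = default_excluded_segments(),
                                     seed = 1) {
  if (!file.exists(peaks_path)) {
    stop("input file not found: ", peaks_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  peaks <- read_spectratype_peaks(peaks_path)
  peaks <- apply_segment_exclusions(peaks, excluded)
  retained <- attr(peaks, "retained_segments")
  samples <- normalize_profiles(peaks)
  ref_samples <- Filter(function(s) s$population == reference_group, samples)
  if (length(ref_samples) == 0L) {
    stop("validation error: no samples of reference population '",
         reference_group, "'")
  }
  ref <- group_reference(ref_samples,
                         label = paste(reference_group, "group average"))
  devs <- lapply(samples, function(s) {
    d <- deviation_matrix(s, ref)
    d$sample_id <- s$sample_id
    d
  })
  dev_long <- do.call(rbind, c(unname(devs), list(make.row.names = FALSE)))
  pm <- perturbation_scores(samples, ref)
  d <- euclidean_distance(pm$scores)
  tree <- average_linkage(d)
  pc <- pca(pm$scores, center = TRUE, unit_scale = FALSE)
  cmp <- group_comparison(pm$overall, pm$populations)

  f <- function(x) file.path(out_dir, x)
  write_tsv_matrix(pm$scores, f("perturbation_matrix.tsv"))
  utils::write.table(
    dev_long[, c("sample_id", "trbv", "cdr3_length", "deviation")],
    f("deviation_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(pm$overall),
               population = pm$populations,
               overall_perturbation = pm$overall, row.names = NULL),
    f("overall_perturbation.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_newick(tree, f("perturbation_dendrogram.nwk"))
  write_tsv_matrix(pc$scores, f("pca_scores.tsv"))
  utils::write.table(
    data.frame(component = seq_along(pc$var_explained),
               var_explained = pc$var_explained),
    f("pca_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cmp$pairwise, f("group_comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- c("perturbation_matrix.tsv", "deviation_matrix.tsv",
               "overall_perturbation.tsv", "perturbation_dendrogram.nwk",
               "pca_scores.tsv", "pca_variance.tsv", "group_comparison.tsv")
  report <- list(
    track = "spectratype",
    input = normalizePath(peaks_path),
    seed = seed,
    reference = ref$label,
    excluded_segments = excluded,
    retained_segments = retained,
    anova = list(f_statistic = cmp$f_statistic, p_value = cmp$p_value),
    pca_var_explained = pc$var_explained,
    overall_perturbation = as.list(pm$overall),
    files = as.list(hash_files(file.path(out_dir, outputs)))
  )
  jsonlite::write_json(report, f("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the clonotype repertoire pipeline
#'
#' Executes, in order: clonotype table ingestion, depth determination
#' (lowest sample total unless overridden), resampled pairwise sharing at
#' that depth, diversity/clonality (averaged over the same number of
#' independent downsampling draws, with the single-draw alternative
#' recorded), predominant-clonotype tables, the focal-clonotype frequency
#' matrix with its Euclidean/average-linkage tree, and the Morisita-Horn
#' average-linkage dendrogram with multiscale-bootstrap AU/BP support
#' computed on one recorded seeded downsampling draw. Artifacts are written
#' as TSV/Newick plus a JSON summary with md5 hashes of every file.
#'
#' @param clonotype_path clonotype TSV (\code{\link{read_clonotype_table}}).
#' @param out_dir output directory.
#' @param key_mode clonotype key level (see
#'   \code{\link{read_clonotype_table}}).
#' @param depth downsampling depth; default the common depth.
#' @param iterations resampling iterations for sharing and averaged
#'   clonality (default 100).
#' @param k predominant-clonotype list length (default 20).
#' @param n_boot bootstrap replicates per scale for AU (default 1000).
#' @param scales multiscale-bootstrap relative sizes.
#' @param focal_population population whose pooled top-k clonotypes form the
#'   focal list (default \code{"Tfr"}).
#' @param clonality_mode \code{"averaged"} (mean over the downsampling
#'   draws, default) or \code{"fixed"} (one seeded draw).
#' @param seed integer seed, mandatory for reproducibility.
#' @return the run report, invisibly.
#' @export
run_repertoire_pipeline <- function(clonotype_path, out_dir,
                                    key_mode = "v_cdr3_j",
                                    depth = NULL, iterations = 100, k = 20,
                                    n_boot = 1000,
                                    scales = seq(0.5, 1.4, by = 0.1),
                                    focal_population = "Tfr",
                                    clonality_mode = c("averaged", "fixed"),
                                    seed = 1) {
  clonality_mode <- match.arg(clonality_mode)
  if (!file.exists(clonotype_path)) {
    stop("input file not found: ", clonotype_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  reps <- read_clonotype_table(clonotype_path, key_mode = key_mode)
  if (is.null(depth)) depth <- common_depth(reps)
  sharing <- resampled_sharing(reps, depth = depth, iterations = iterations)

  # one recorded draw at the common depth feeds the single-draw statistics
  fixed_draw <- lapply(reps, downsample, depth = depth)
  if (clonality_mode == "averaged") {
    clon <- matrix(0, nrow = length(reps), ncol = iterations)
    for (it in seq_len(iterations)) {
      clon[, it] <- vapply(reps, function(r) clonality(downsample(r, depth)),
                           numeric(1))
    }
    div <- diversity_report(fixed_draw)
    div$clonality <- rowMeans(clon)
  } else {
    div <- diversity_report(fixed_draw)
  }

  cft <- cumulative_frequency_table(fixed_draw, k = k)
  focal_reps <- Filter(function(r) r$population == focal_population,
                       fixed_draw)
  if (length(focal_reps) == 0L) {
    stop("validation error: no samples of focal population '",
         focal_population, "'")
  }
  focal_keys <- unique(unlist(lapply(focal_reps, function(r) {
    top_clonotypes(r, k)$key
  })))
  fm <- focal_clonotype_matrix(focal_keys, fixed_draw)
  focal_tree <- average_linkage(euclidean_distance(t(fm)))

  ov <- overlap_matrix(fixed_draw)
  counts <- repertoire_matrix(fixed_draw)
  mh_tree <- multiscale_bootstrap_au(counts, distance_mode = "morisita_horn",
                                     scales = scales, n_boot = n_boot)

  f <- function(x) file.path(out_dir, x)
  utils::write.table(div, f("diversity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sharing, f("sharing.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv_matrix(ov, f("overlap_matrix.tsv"))
  top_long <- do.call(rbind, c(lapply(names(cft$top_lists), function(sid) {
    data.frame(sample_id = sid, cft$top_lists[[sid]],
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  utils::write.table(top_long, f("top_clonotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cft$per_sample, f("cumulative_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_matrix(fm, f("focal_matrix.tsv"), rowname_header = "key")
  write_newick(focal_tree, f("focal_dendrogram.nwk"))
  write_newick(mh_tree, f("mh_dendrogram.nwk"), annotate = TRUE)

  outputs <- c("diversity.tsv", "sharing.tsv", "overlap_matrix.tsv",
               "top_clonotypes.tsv", "cumulative_frequency.tsv",
               "focal_matrix.tsv", "focal_dendrogram.nwk",
               "mh_dendrogram.nwk")
  report <- list(
    track = "repertoire",
    input = normalizePath(clonotype_path),
    seed = seed,
    key_mode = key_mode,
    depth = depth,
    iterations = iterations,
    k = k,
    n_boot = n_boot,
    scales = scales,
    clonality_mode = clonality_mode,
    focal_population = focal_population,
    clonality = stats::setNames(as.list(div$clonality), div$sample_id),
    overlap = lapply(seq_len(nrow(ov)), function(i) as.list(ov[i, ])),
    clusters = lapply(seq_along(mh_tree$clusters), function(i) {
      list(members = mh_tree$clusters[[i]],
           au = mh_tree$au[i], bp = mh_tree$bp[i])
    }),
    files = as.list(hash_files(file.path(out_dir, outputs)))
  )
  jsonlite::write_json(report, f("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Simulate inputs and write them in the pipeline's file dialects
#'
#' Convenience wrappers around the simulators that write the peak CSV /
#' clonotype TSV (with a provenance header embedding the seed and a hash of
#' the configuration) and the ground truth as JSON.
#'
#' @param cfg simulator configuration.
#' @param out_dir output directory.
#' @return list of written paths, invisibly.
#' @export
write_simulated_spectratypes <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_spectratypes(cfg)
  hdr <- sprintf("tcrep simulate-spectratype seed=%d cfg_md5=%s",
                 cfg$seed, cfg_hash(unclass(cfg)))
  peaks_path <- file.path(out_dir, "spectratype_peaks.csv")
  truth_path <- file.path(out_dir, "spectratype_truth.json")
  write_spectratype_peaks(sim$peaks, peaks_path, header_comment = hdr)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(peaks = peaks_path, truth = truth_path))
}

#' @rdname write_simulated_spectratypes
#' @export
write_simulated_repertoires <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_repertoires(cfg)
  hdr <- sprintf("tcrep simulate-repertoire seed=%d cfg_md5=%s",
                 cfg$seed, cfg_hash(unclass(cfg)))
  table_path <- file.path(out_dir, "clonotypes.tsv")
  truth_path <- file.path(out_dir, "repertoire_truth.json")
  write_clonotype_table(sim$table, table_path, header_comment = hdr)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(table = table_path, truth = truth_path))
}
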