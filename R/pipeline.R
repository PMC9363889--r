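# End-to-end orchestration: ingest -> clonotype -> depth-standardize ->
# summarize -> overlap -> group comparisons, either in memory
# (analyze_cohort) or from files with provenance tracking
# (run_pipeline).

#' Run the full analysis on in-memory records
#'
#' Collapses UMIs, builds repertoires, validates that every sample can
#' be standardized to the common depth (aborting with the full list of
#' shallow samples before any statistic is computed), subsamples,
#' summarizes, computes all within-patient pairwise overlaps, and runs
#' the standard group comparisons.
#'
#' @param samples named list of rearrangement record data.frames (one
#'   per sample), as returned by [read_rearrangements()] or found in a
#'   `synthetic_cohort`.
#' @param manifest sample manifest data.frame.
#' @param depth common analysis depth (default 9,736 molecules).
#' @param seed master seed; each sample is subsampled under a seed
#'   derived from (seed, sample_id).
#' @param hec_threshold HEC frequency threshold.
#' @param top_n top-list size for clonal retrieval.
#' @param mode clone sequence level, `"nt"` or `"aa"`.
#' @param chao_variant see [chao_sorensen()].
#' @param shallow_policy `"error"` (default) or `"keep_all"` for samples
#'   below `depth`.
#' @param plot_pairs comparison classes for which per-clone overlap-plot
#'   data are emitted.
#' @return an object of class `repertoire_analysis`: list with
#'   `summaries`, `overlaps`, `comparisons`, `plot_data`, `repertoires`
#'   (depth-standardized), `seeds` and the call parameters in `params`.
#' @export
analyze_cohort <- function(samples, manifest, depth = DEFAULT_DEPTH,
                           seed = 1L,
                           hec_threshold = DEFAULT_HEC_THRESHOLD,
                           top_n = 25L, mode = c("nt", "aa"),
                           chao_variant = "bias_corrected",
                           shallow_policy = c("error", "keep_all"),
                           plot_pairs = "ST_ST_within_joint") {
  mode <- match.arg(mode)
  shallow_policy <- match.arg(shallow_policy)
  manifest <- validate_manifest(manifest)
  missing <- setdiff(names(samples), manifest$sample_id)
  if (length(missing))
    stop2("sample(s) missing from manifest: %s",
          paste(missing, collapse = ", "))

  reps <- list()
  for (sid in names(samples)) {
    meta <- manifest[manifest$sample_id == sid, ]
    mol <- collapse_umis(samples[[sid]])
    reps[[sid]] <- build_repertoire(mol, meta, mode = mode)
  }
  shallow <- names(reps)[vapply(reps, function(r)
    r$total_molecules < depth, TRUE)]
  if (length(shallow) && shallow_policy == "error")
    stop2("sample(s) below depth %d: %s", depth,
          paste(shallow, collapse = ", "))

  seeds <- vapply(names(reps), function(sid) derive_seed(seed, sid), 0L)
  sub <- lapply(names(reps), function(sid)
    subsample_repertoire(reps[[sid]], depth = depth, seed = seeds[[sid]],
                         shallow_policy = shallow_policy))
  names(sub) <- names(reps)

  summaries <- do.call(rbind, lapply(sub, summarize_repertoire,
                                     hec_threshold = hec_threshold))
  rownames(summaries) <- NULL

  usable <- sub[vapply(sub, function(r) r$depth_standardized, TRUE)]
  overlaps <- pairwise_overlaps(usable, manifest, n_top = top_n,
                                variant = chao_variant)

  plot_data <- list()
  if (nrow(overlaps)) {
    sel <- which(overlaps$comparison_class %in% plot_pairs)
    for (i in sel) {
      pd <- overlap_plot_data(usable[[overlaps$sample_a[i]]],
                              usable[[overlaps$sample_b[i]]],
                              hec_threshold = hec_threshold)
      pd <- data.frame(sample_a = overlaps$sample_a[i],
                       sample_b = overlaps$sample_b[i], pd,
                       stringsAsFactors = FALSE)
      plot_data[[length(plot_data) + 1L]] <- pd
    }
  }
  plot_data <- if (length(plot_data)) do.call(rbind, plot_data)
               else data.frame()

  comparisons <- standard_comparisons(summaries, overlaps)

  structure(list(summaries = summaries, overlaps = overlaps,
                 comparisons = comparisons, plot_data = plot_data,
                 repertoires = sub, seeds = seeds,
                 params = list(depth = depth, seed = seed,
                               hec_threshold = hec_threshold,
                               top_n = top_n, mode = mode,
                               chao_variant = chao_variant,
                               shallow_policy = shallow_policy)),
            class = "repertoire_analysis")
}

# The standard group comparisons: Mann-Whitney between comparison
# classes for both overlap metrics, and ANOVA + Tukey across
# compartments for the summary metrics when three or more compartments
# are present.
standard_comparisons <- function(summaries, overlaps) {
  rows <- list()
  if (nrow(overlaps)) {
    cls <- unique(overlaps$comparison_class)
    cls <- setdiff(cls, "other")
    if (length(cls) >= 2L) {
      for (i in seq_len(length(cls) - 1L)) for (j in seq(i + 1L,
                                                         length(cls))) {
        for (metric in c("topn_retrieval_pct", "chao_sorensen")) {
          va <- overlaps[[metric]][overlaps$comparison_class == cls[i]]
          vb <- overlaps[[metric]][overlaps$comparison_class == cls[j]]
          rows[[length(rows) + 1L]] <-
            compare_groups(va, vb, "mann_whitney_u",
                           group_a = cls[i], group_b = cls[j],
                           metric = metric)
        }
      }
    }
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else data.frame()
  comps <- unique(summaries$compartment)
  if (length(comps) >= 3L) {
    for (metric in c("n_clones", "n_hecs", "hec_impact")) {
      tk <- anova_tukey(summaries[[metric]], summaries$compartment,
                        metric = metric)$tukey
      tk <- data.frame(metric = tk$metric, group_a = tk$group_a,
                       group_b = tk$group_b, test = "anova_tukey",
                       n_a = NA_integer_, n_b = NA_integer_,
                       n_pairs = NA_integer_, mean_a = NA_real_,
                       sd_a = NA_real_, mean_b = NA_real_,
                       sd_b = NA_real_, statistic = tk$diff,
                       p_value = tk$p_adj, significant = tk$significant,
                       degenerate = FALSE, stringsAsFactors = FALSE)
      comparisons <- if (nrow(comparisons)) rbind(comparisons, tk)
                     else tk
    }
  }
  rownames(comparisons) <- NULL
  comparisons
}

#' @export
print.repertoire_analysis <- function(x, ...) {
  cat(sprintf("<repertoire_analysis> %d samples at depth %d, %d pairs\n",
              nrow(x$summaries), x$params$depth, nrow(x$overlaps)))
  cat("\nPer-compartment summary:\n")
  print(aggregate_stats(x$summaries, "n_clones", "compartment"))
  if (nrow(x$overlaps)) {
    cat("\nTop-N retrieval by comparison class:\n")
    print(aggregate_stats(x$overlaps, "topn_retrieval_pct",
                          "comparison_class"))
  }
  invisible(x)
}

#' Run the pipeline from files, with provenance
#'
#' Reads the manifest and rearrangement TSVs, runs [analyze_cohort()],
#' and writes the result tables (clone tables, summary, overlaps, group
#' comparisons, overlap-plot data) plus a JSON run record with the
#' configuration snapshot, package version, per-sample seeds and output
#' checksums. All referenced files are checked before any computation.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `manifest` (path), `rearrangement_files` (named character vector or
#'   list, sample_id -> path; defaults to `<sample_id>.tsv` next to the
#'   manifest), `out_dir`, and optionally `depth`, `seed`,
#'   `hec_threshold`, `top_n`, `mode`, `chao_variant`, `shallow_policy`.
#' @return the `repertoire_analysis`, invisibly, with the output paths
#'   in `attr(, "paths")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$manifest) || is.null(config$out_dir))
    stop2("config must name `manifest` and `out_dir`")
  manifest <- read_manifest(config$manifest)
  files <- config$rearrangement_files
  if (is.null(files)) {
    files <- file.path(dirname(config$manifest),
                       paste0(manifest$sample_id, ".tsv"))
    names(files) <- manifest$sample_id
  }
  files <- unlist(files)
  absent <- files[!file.exists(files)]
  if (length(absent))
    stop2("rearrangement file(s) not found: %s",
          paste(absent, collapse = ", "))
  bad <- setdiff(names(files), manifest$sample_id)
  if (length(bad))
    stop2("rearrangement file(s) for unknown sample(s): %s",
          paste(bad, collapse = ", "))

  samples <- lapply(names(files), function(sid)
    read_rearrangements(files[[sid]], sample_id = sid))
  names(samples) <- names(files)

  ana <- analyze_cohort(
    samples, manifest,
    depth = config$depth %||% DEFAULT_DEPTH,
    seed = config$seed %||% 1L,
    hec_threshold = config$hec_threshold %||% DEFAULT_HEC_THRESHOLD,
    top_n = config$top_n %||% 25L,
    mode = sub("^cdr3-", "", config$mode %||% "nt"),
    chao_variant = config$chao_variant %||% "bias_corrected",
    shallow_policy = config$shallow_policy %||% "error")

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    repertoires = file.path(out, "repertoires.tsv"),
    summary = file.path(out, "summary.tsv"),
    overlap = file.path(out, "overlap.tsv"),
    comparisons = file.path(out, "comparisons.tsv"),
    plot_data = file.path(out, "overlap_plot_data.tsv"))
  clone_tables <- do.call(rbind, lapply(ana$repertoires,
                                        as.data.frame))
  rownames(clone_tables) <- NULL
  write_table(clone_tables, paths[["repertoires"]])
  write_table(ana$summaries, paths[["summary"]])
  write_table(ana$overlaps, paths[["overlap"]], allow_empty = TRUE)
  write_table(ana$comparisons, paths[["comparisons"]],
              allow_empty = TRUE)
  write_table(ana$plot_data, paths[["plot_data"]], allow_empty = TRUE)

  record <- list(
    package = "repshare",
    version = as.character(utils::packageVersion("repshare")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "rearrangement_files")],
    rearrangement_files = as.list(files),
    seeds = as.list(ana$seeds),
    checksums = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(record, file.path(out, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(ana, "paths") <- c(paths,
                          run_record = file.path(out, "run_record.json"))
  invisible(ana)
}

#' Generate and write a synthetic cohort from a configuration
#'
#' @param config a `cohort_config`, a plain list of [cohort_config()]
#'   arguments, or a path to a YAML file of them. Unknown keys are an
#'   error.
#' @param out_dir directory to write the cohort to.
#' @return the `synthetic_cohort`, invisibly.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "cohort_config")) {
    known <- names(formals(cohort_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown))
      stop2("unknown cohort config key(s): %s",
            paste(unknown, collapse = ", "))
    config <- do.call(cohort_config, config)
  }
  cohort <- generate_cohort(config, dir = out_dir)
  invisible(cohort)
}
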