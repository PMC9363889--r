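# Depth standardization and per-sample summary statistics. All samples
# are subsampled to one common depth (default 9,736 molecules) before any
# repertoire statistic or similarity index is computed, so that clone
# counts and overlap measures are comparable across samples of unequal
# sequencing depth. A highly expanded clone (HEC) is a clone whose
# within-sample frequency is >= 0.5% (inclusive); at depth 9,736 this
# corresponds to a floor of 49 molecules.

#' Default analysis depth (molecules per sample)
#' @export
DEFAULT_DEPTH <- 9736L

#' Default highly-expanded-clone frequency threshold
#' @export
DEFAULT_HEC_THRESHOLD <- 0.005

#' Subsample a repertoire to a fixed depth
#'
#' Draws exactly `depth` molecules uniformly at random without
#' replacement from the sample's molecules (clone counts are therefore
#' multivariate hypergeometric), removes clones drawn zero times, and
#' recomputes frequencies over the new depth. Reproducible under a fixed
#' seed.
#'
#' @param r a `repertoire`.
#' @param depth target depth in molecules (default 9,736).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @param shallow_policy what to do when the sample has fewer molecules
#'   than `depth`: `"error"` (default) or `"keep_all"` (return the
#'   repertoire unchanged and unstandardized).
#' @return a depth-standardized `repertoire`.
#' @export
subsample_repertoire <- function(r, depth = DEFAULT_DEPTH, seed = NULL,
                                 shallow_policy = c("error", "keep_all")) {
  stopifnot(inherits(r, "repertoire"))
  shallow_policy <- match.arg(shallow_policy)
  depth <- as.integer(depth)
  if (depth < 1L) stop2("depth must be >= 1")
  if (r$total_molecules < depth) {
    if (shallow_policy == "error")
      stop2("sample %s has %d molecules, %d short of depth %d",
            r$meta$sample_id %||% "?", r$total_molecules,
            depth - r$total_molecules, depth)
    return(r)
  }
  if (r$total_molecules == depth) {
    r$depth_standardized <- TRUE
    return(r)
  }
  counts <- r$clones$molecule_count
  draw <- function() {
    pool <- rep.int(seq_along(counts), counts)
    tabulate(sample(pool, depth), nbins = length(counts))
  }
  new_counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  keep <- new_counts > 0L
  clones <- r$clones[keep, , drop = FALSE]
  clones$molecule_count <- as.integer(new_counts[keep])
  clones$frequency <- clones$molecule_count / depth
  new_repertoire(r$meta, clones, depth, r$mode, cdr3_only = r$cdr3_only,
                 depth_standardized = TRUE)
}

#' Detect highly expanded clones (HECs)
#'
#' Returns the clones whose frequency is greater than or equal to
#' `threshold` (the boundary is inclusive), in rank order.
#'
#' @param r a `repertoire`, normally depth-standardized first.
#' @param threshold dominance threshold as a fraction in (0, 1); default
#'   0.005 (0.5%).
#' @return the subset of the clone table that qualifies as HECs.
#' @export
detect_hecs <- function(r, threshold = DEFAULT_HEC_THRESHOLD) {
  stopifnot(inherits(r, "repertoire"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop2("threshold must be a fraction strictly between 0 and 1")
  r$clones[r$clones$frequency >= threshold, , drop = FALSE]
}

#' Summarize one repertoire
#'
#' Computes the clone count, the number of highly expanded clones and
#' their combined impact (summed frequency, as a percentage) for one
#' sample.
#'
#' @param r a `repertoire`, normally depth-standardized first.
#' @param hec_threshold HEC frequency threshold (fraction).
#' @return a one-row data.frame: sample_id, patient_id, joint,
#'   compartment, depth, n_clones, n_hecs, hec_impact.
#' @export
summarize_repertoire <- function(r, hec_threshold = DEFAULT_HEC_THRESHOLD) {
  stopifnot(inherits(r, "repertoire"))
  hecs <- detect_hecs(r, hec_threshold)
  data.frame(
    sample_id = r$meta$sample_id %||% NA_character_,
    patient_id = r$meta$patient_id %||% NA_character_,
    joint = r$meta$joint %||% NA_character_,
    compartment = r$meta$compartment %||% NA_character_,
    depth = r$total_molecules,
    n_clones = nrow(r$clones),
    n_hecs = nrow(hecs),
    hec_impact = 100 * sum(hecs$frequency),
    stringsAsFactors = FALSE
  )
}
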