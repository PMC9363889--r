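# Pairwise repertoire similarity: top-N clonal retrieval, the
# abundance-based Chao-modified Sorensen index, and overlap-plot data.
# All cross-sample matching is done on CDR3-only clone keys; repertoires
# are projected with project_to_cdr3() on entry if needed.

ensure_cdr3 <- function(r) if (r$cdr3_only) r else project_to_cdr3(r)

#' Top-N clonal retrieval between two repertoires
#'
#' Takes the N most expanded clones of each sample (deterministic
#' tie-break: molecule count descending, then CDR3 lexicographic) and
#' returns the percentage of clone keys common to the two top lists. The
#' measure is symmetric by construction. If either sample has fewer than
#' `n` clones, the overlap is computed over the largest common list size
#' with a warning; the effective N is attached as `attr(, "n_eff")`.
#'
#' @param a,b `repertoire` objects at equal depth (CDR3-projected
#'   internally).
#' @param n size of the top list (default 25).
#' @return percentage in \[0, 100\].
#' @export
topn_retrieval <- function(a, b, n = 25L) {
  a <- ensure_cdr3(a); b <- ensure_cdr3(b)
  n_eff <- min(n, nrow(a$clones), nrow(b$clones))
  if (n_eff < n)
    warning(sprintf("fewer than %d clones (%d / %d); using n = %d",
                    n, nrow(a$clones), nrow(b$clones), n_eff),
            call. = FALSE)
  ka <- a$clones$cdr3[seq_len(n_eff)]
  kb <- b$clones$cdr3[seq_len(n_eff)]
  out <- 100 * length(intersect(ka, kb)) / n_eff
  attr(out, "n_eff") <- n_eff
  out
}

#' Chao-modified abundance-based Sorensen similarity index
#'
#' Estimates the similarity of two repertoires from the abundances of
#' their shared clones, correcting for shared clones missed by
#' incomplete sampling through the singleton/doubleton counts of shared
#' clones (bias-corrected abundance-based estimator). With shared clone
#' counts \eqn{X_i} (sample A, depth n) and \eqn{Y_i} (sample B, depth
#' m):
#' \deqn{U = \sum X_i/n + \frac{m-1}{m}\frac{f_{+1}}{2 f_{+2}}
#'       \sum_{Y_i = 1} X_i/n}
#' and symmetrically for V; a zero doubleton count is replaced by 1, U
#' and V are capped at 1, and the index is \eqn{2UV/(U+V)} (0 when there
#' are no shared clones). Values near 0 mean no overlap; values near 1
#' mean the two repertoires are effectively identical.
#'
#' @param a,b non-empty `repertoire` objects (CDR3-projected
#'   internally).
#' @param variant `"bias_corrected"` (default) includes the unseen
#'   shared-clone correction; `"uncorrected"` uses the raw shared
#'   abundance sums only.
#' @return a list of class `chao_sorensen` with elements `index` (in
#'   \[0, 1\]) and `components` (U, V, f_plus1, f_plus2, f_1plus,
#'   f_2plus, n, m, n_shared).
#' @export
chao_sorensen <- function(a, b, variant = c("bias_corrected",
                                            "uncorrected")) {
  variant <- match.arg(variant)
  a <- ensure_cdr3(a); b <- ensure_cdr3(b)
  if (nrow(a$clones) == 0L || nrow(b$clones) == 0L)
    stop2("chao_sorensen: empty repertoire")
  n <- a$total_molecules
  m <- b$total_molecules
  shared <- intersect(a$clones$cdr3, b$clones$cdr3)
  X <- a$clones$molecule_count[match(shared, a$clones$cdr3)]
  Y <- b$clones$molecule_count[match(shared, b$clones$cdr3)]
  f_plus1 <- sum(Y == 1L); f_plus2 <- sum(Y == 2L)
  f_1plus <- sum(X == 1L); f_2plus <- sum(X == 2L)
  if (length(shared) == 0L) {
    U <- 0; V <- 0
  } else {
    U <- sum(X) / n
    V <- sum(Y) / m
    if (variant == "bias_corrected") {
      U <- U + ((m - 1) / m) * (f_plus1 / (2 * max(f_plus2, 1L))) *
        sum((X / n)[Y == 1L])
      V <- V + ((n - 1) / n) * (f_1plus / (2 * max(f_2plus, 1L))) *
        sum((Y / m)[X == 1L])
    }
    U <- min(U, 1); V <- min(V, 1)
  }
  index <- if (U + V == 0) 0 else 2 * U * V / (U + V)
  structure(list(index = index,
                 components = list(U = U, V = V, f_plus1 = f_plus1,
                                   f_plus2 = f_plus2, f_1plus = f_1plus,
                                   f_2plus = f_2plus, n = n, m = m,
                                   n_shared = length(shared)),
                 variant = variant),
            class = "chao_sorensen")
}

#' @export
print.chao_sorensen <- function(x, ...) {
  cat(sprintf("Chao-Sorensen index (%s): %.4f  [U = %.4f, V = %.4f, %d shared clones]\n",
              x$variant, x$index, x$components$U, x$components$V,
              x$components$n_shared))
  invisible(x)
}

#' Per-clone frequencies for a pairwise overlap plot
#'
#' One row per clone in the union of the two samples, with its frequency
#' (percent) in each sample. Clones absent from one sample are placed at
#' a pseudo-frequency floor and flagged not-detected; each row carries a
#' quadrant label relative to the HEC threshold line.
#'
#' @param a,b `repertoire` objects at equal depth.
#' @param nd_floor pseudo-frequency (fraction) for not-detected clones;
#'   default half the minimum representable frequency, 0.5/depth.
#' @param hec_threshold HEC frequency threshold (fraction).
#' @return data.frame: cdr3, freq_a_pct, freq_b_pct, detected_a,
#'   detected_b, quadrant.
#' @export
overlap_plot_data <- function(a, b, nd_floor = NULL,
                              hec_threshold = DEFAULT_HEC_THRESHOLD) {
  a <- ensure_cdr3(a); b <- ensure_cdr3(b)
  if (a$total_molecules != b$total_molecules)
    warning("samples are at unequal depth; frequencies not comparable",
            call. = FALSE)
  if (is.null(nd_floor)) nd_floor <- 0.5 / a$total_molecules
  keys <- union(a$clones$cdr3, b$clones$cdr3)
  fa <- a$clones$frequency[match(keys, a$clones$cdr3)]
  fb <- b$clones$frequency[match(keys, b$clones$cdr3)]
  detected_a <- !is.na(fa); detected_b <- !is.na(fb)
  hec_a <- detected_a & fa >= hec_threshold
  hec_b <- detected_b & fb >= hec_threshold
  quadrant <- ifelse(hec_a & hec_b, "both_hec",
              ifelse(hec_a, "a_only_hec",
              ifelse(hec_b, "b_only_hec", "neither")))
  out <- data.frame(
    cdr3 = keys,
    freq_a_pct = 100 * ifelse(detected_a, fa, nd_floor),
    freq_b_pct = 100 * ifelse(detected_b, fb, nd_floor),
    detected_a = detected_a,
    detected_b = detected_b,
    quadrant = quadrant,
    stringsAsFactors = FALSE
  )
  out[order_c(-pmax(out$freq_a_pct, out$freq_b_pct), out$cdr3), ,
      drop = FALSE]
}

#' Classify a within-patient sample pair
#'
#' Maps the compartments (and joints) of two samples to a comparison
#' class: `ST_ST_within_joint`, `ST_ST_between_joints`, `ST_SF` (same
#' joint), `ST_PB`, `SF_PB`, or `other`.
#'
#' @param meta_a,meta_b sample metadata (lists or single-row data.frames
#'   with `compartment` and `joint`).
#' @return a character scalar.
#' @export
classify_pair <- function(meta_a, meta_b) {
  meta_a <- as.list(meta_a); meta_b <- as.list(meta_b)
  ca <- meta_a$compartment; cb <- meta_b$compartment
  is_st <- function(x) x %in% c("ST_SP", "ST_IP")
  same_joint <- identical(meta_a$joint, meta_b$joint)
  if (is_st(ca) && is_st(cb))
    return(if (same_joint) "ST_ST_within_joint" else "ST_ST_between_joints")
  comps <- sort(c(ca, cb))
  if (is_st(ca) && cb == "SF" || is_st(cb) && ca == "SF")
    return(if (same_joint) "ST_SF" else "other")
  if (is_st(ca) && cb == "PB" || is_st(cb) && ca == "PB") return("ST_PB")
  if (identical(comps, c("PB", "SF"))) return("SF_PB")
  "other"
}

#' All within-patient pairwise overlaps
#'
#' Computes the top-N clonal retrieval and Chao-Sorensen index for every
#' pair of samples from the same patient (never across patients), with
#' the comparison class derived from compartments and joints. All
#' samples must be at one common depth.
#'
#' @param repertoires a named list of `repertoire` objects (names =
#'   sample ids) or an unnamed list (sample ids taken from metadata).
#' @param manifest validated sample manifest covering all repertoires.
#' @param n_top top-list size (default 25).
#' @param variant Chao-Sorensen variant, see [chao_sorensen()].
#' @return data.frame with one row per within-patient pair: sample_a,
#'   sample_b, patient_id, comparison_class, depth, n_top,
#'   topn_retrieval_pct, chao_sorensen, n_shared_clones, U, V, f_plus1,
#'   f_plus2, f_1plus, f_2plus.
#' @export
pairwise_overlaps <- function(repertoires, manifest, n_top = 25L,
                              variant = "bias_corrected") {
  manifest <- validate_manifest(manifest)
  if (is.null(names(repertoires)))
    names(repertoires) <- vapply(repertoires,
                                 function(r) r$meta$sample_id, "")
  missing <- setdiff(names(repertoires), manifest$sample_id)
  if (length(missing))
    stop2("repertoire(s) not in manifest: %s",
          paste(missing, collapse = ", "))
  proj <- lapply(repertoires, ensure_cdr3)
  rows <- list()
  for (pid in unique(manifest$patient_id)) {
    sids <- intersect(manifest$sample_id[manifest$patient_id == pid],
                      names(proj))
    if (length(sids) < 2L) next
    for (i in seq_len(length(sids) - 1L)) {
      for (j in seq(i + 1L, length(sids))) {
        ra <- proj[[sids[i]]]; rb <- proj[[sids[j]]]
        if (ra$total_molecules != rb$total_molecules)
          stop2("pair %s / %s at unequal depth (%d vs %d)",
                sids[i], sids[j], ra$total_molecules, rb$total_molecules)
        ma <- manifest[manifest$sample_id == sids[i], ]
        mb <- manifest[manifest$sample_id == sids[j], ]
        topn <- topn_retrieval(ra, rb, n_top)
        cs <- chao_sorensen(ra, rb, variant)
        co <- cs$components
        rows[[length(rows) + 1L]] <- data.frame(
          sample_a = sids[i], sample_b = sids[j], patient_id = pid,
          comparison_class = classify_pair(ma, mb),
          depth = ra$total_molecules,
          n_top = attr(topn, "n_eff"),
          topn_retrieval_pct = as.numeric(topn),
          chao_sorensen = cs$index,
          n_shared_clones = co$n_shared,
          U = co$U, V = co$V,
          f_plus1 = co$f_plus1, f_plus2 = co$f_plus2,
          f_1plus = co$f_1plus, f_2plus = co$f_2plus,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample_a = character(), sample_b = character(),
                      patient_id = character(),
                      comparison_class = character(), depth = integer(),
                      n_top = integer(), topn_retrieval_pct = numeric(),
                      chao_sorensen = numeric(),
                      n_shared_clones = integer(), U = numeric(),
                      V = numeric(), f_plus1 = integer(),
                      f_plus2 = integer(), f_1plus = integer(),
                      f_2plus = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
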