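# Clonotype calling: UMI collapse of rearrangement records and
# aggregation into a quantified per-sample repertoire. A clone is a
# unique CDR3 sequence in combination with the V and J gene; for
# cross-sample similarity analyses the key is reduced to the CDR3 alone
# (see project_to_cdr3), because somatic hypermutation diversifies the
# rest of the rearrangement.

clone_sep <- "\r" # never occurs in sequences or gene names

# Deterministic clone ordering: molecule count desc, then CDR3, V, J in
# C-locale lexicographic order.
sort_clones <- function(clones) {
  o <- order_c(-clones$molecule_count, clones$cdr3, clones$v_gene,
               clones$j_gene)
  out <- clones[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_repertoire <- function(meta, clones, total_molecules, mode,
                           cdr3_only = FALSE, depth_standardized = FALSE) {
  structure(list(meta = meta, clones = sort_clones(clones),
                 total_molecules = as.integer(total_molecules),
                 mode = mode, cdr3_only = cdr3_only,
                 depth_standardized = depth_standardized),
            class = "repertoire")
}

#' Collapse sequencing reads to UMI-defined molecules
#'
#' Reads sharing the same UMI and clone key (CDR3 nucleotide sequence, V
#' gene, J gene) are merged into a single molecule whose
#' `duplicate_count` is the total number of reads merged. Reads carrying
#' the same UMI but a different clone key (a UMI collision) are kept as
#' distinct molecules. The operation is idempotent and invariant to input
#' order.
#'
#' @param records data.frame of rearrangement records from one sample, as
#'   returned by [read_rearrangements()].
#' @return a data.frame with one row per molecule, sorted
#'   deterministically.
#' @export
collapse_umis <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop2("collapse_umis: no input records")
  if (length(unique(records$sample_id)) != 1L)
    stop2("collapse_umis: records span multiple samples (%s)",
          paste(unique(records$sample_id), collapse = ", "))
  key <- paste(records$umi, records$cdr3_nt, records$v_gene,
               records$j_gene, sep = clone_sep)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  dc <- rowsum(as.numeric(records$duplicate_count), key)
  out$duplicate_count <- as.integer(dc[match(key[first], rownames(dc)), 1L])
  out <- out[order_c(key[first]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a quantified repertoire from UMI-collapsed molecules
#'
#' Molecules sharing a clone key are aggregated into a clone whose
#' `molecule_count` is the number of molecules (not raw reads: UMIs are
#' the quantification unit) and whose `frequency` is its share of the
#' sample total.
#'
#' @param molecules UMI-collapsed records from [collapse_umis()].
#' @param meta a single-row data.frame or list of sample metadata with at
#'   least `sample_id`, `patient_id`, `joint`, `compartment`.
#' @param mode clone sequence level: `"nt"` (CDR3 nucleotide, default) or
#'   `"aa"` (CDR3 amino acid, requires the `cdr3_aa` field).
#' @return an object of class `repertoire`.
#' @export
build_repertoire <- function(molecules, meta, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  if (is.null(molecules) || nrow(molecules) == 0L)
    stop2("build_repertoire: no molecules")
  meta <- as.list(meta)
  if (!is.null(meta$sample_id)) {
    sid <- unique(molecules$sample_id)
    if (length(sid) != 1L || sid != meta$sample_id)
      stop2("molecules belong to sample(s) %s, meta says %s",
            paste(sid, collapse = ", "), meta$sample_id)
  }
  cdr3 <- if (mode == "nt") molecules$cdr3_nt else molecules$cdr3_aa
  if (mode == "aa" && anyNA(cdr3))
    stop2("mode = 'aa' but %d molecule(s) lack cdr3_aa", sum(is.na(cdr3)))
  key <- paste(cdr3, molecules$v_gene, molecules$j_gene, sep = clone_sep)
  first <- !duplicated(key)
  counts <- c(table(key))
  n <- as.integer(counts[key[first]])
  clones <- data.frame(
    cdr3 = cdr3[first],
    v_gene = molecules$v_gene[first],
    j_gene = molecules$j_gene[first],
    molecule_count = n,
    frequency = n / nrow(molecules),
    stringsAsFactors = FALSE
  )
  new_repertoire(meta, clones, nrow(molecules), mode)
}

#' Merge clones by CDR3 for cross-sample comparison
#'
#' Collapses clones that share a CDR3 sequence but differ in V/J gene, so
#' that cross-sample matching (top-N retrieval, similarity indices) is
#' done on the CDR3 alone. Counts are summed, the total molecule count is
#' conserved, and the operation is idempotent.
#'
#' @param r a `repertoire`.
#' @return a `repertoire` with CDR3-only clone keys (`v_gene`/`j_gene`
#'   set to NA).
#' @export
project_to_cdr3 <- function(r) {
  stopifnot(inherits(r, "repertoire"))
  if (r$cdr3_only) return(r)
  cl <- r$clones
  agg <- rowsum(cl$molecule_count, cl$cdr3)
  clones <- data.frame(
    cdr3 = rownames(agg),
    v_gene = NA_character_,
    j_gene = NA_character_,
    molecule_count = as.integer(agg[, 1L]),
    frequency = agg[, 1L] / r$total_molecules,
    stringsAsFactors = FALSE
  )
  new_repertoire(r$meta, clones, r$total_molecules, r$mode,
                 cdr3_only = TRUE,
                 depth_standardized = r$depth_standardized)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf(
    "<repertoire> sample %s (%s, %s): %d clones, %d molecules%s%s\n",
    x$meta$sample_id %||% "?", x$meta$compartment %||% "?",
    x$meta$joint %||% "?", nrow(x$clones), x$total_molecules,
    if (x$cdr3_only) ", CDR3-projected" else "",
    if (x$depth_standardized) ", depth-standardized" else ""))
  print(utils::head(x$clones, 5L))
  if (nrow(x$clones) > 5L) cat(sprintf("... %d more clones\n",
                                       nrow(x$clones) - 5L))
  invisible(x)
}

#' @method summary repertoire
#' @export
summary.repertoire <- function(object, hec_threshold = 0.005, ...) {
  summarize_repertoire(object, hec_threshold = hec_threshold)
}

#' Serialize a repertoire's clone table
#'
#' @param x a `repertoire`.
#' @param ... ignored.
#' @return data.frame with columns sample_id, cdr3, v_gene, j_gene,
#'   molecule_count, frequency.
#' @method as.data.frame repertoire
#' @export
as.data.frame.repertoire <- function(x, ...) {
  data.frame(sample_id = x$meta$sample_id %||% NA_character_,
             x$clones, stringsAsFactors = FALSE)
}
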