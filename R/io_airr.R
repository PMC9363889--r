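# Reading and writing AIRR-style rearrangement tables and the sample
# manifest. The default column dialect follows the AIRR Rearrangement
# standard (cdr3, v_call, j_call, duplicate_count); other layouts are
# supported through a user-supplied column mapping.

JOINT_LEVELS <- c("left_knee", "right_knee", "ankle", "other")
COMPARTMENT_LEVELS <- c("ST_SP", "ST_IP", "SF", "PB")

#' Column-name dialect for rearrangement tables
#'
#' Maps the logical fields of a rearrangement record to the column names
#' used in a particular TSV layout. The defaults are the AIRR
#' Rearrangement community-standard names plus a `umi` column for the
#' unique molecular identifier.
#'
#' @param sample_id,umi,cdr3,v_call,j_call,cdr3_aa,duplicate_count column
#'   names in the input file for each logical field.
#' @return a named character vector usable as the `dialect` argument of
#'   [read_rearrangements()].
#' @export
airr_dialect <- function(sample_id = "sample_id", umi = "umi",
                         cdr3 = "cdr3", v_call = "v_call",
                         j_call = "j_call", cdr3_aa = "cdr3_aa",
                         duplicate_count = "duplicate_count") {
  c(sample_id = sample_id, umi = umi, cdr3 = cdr3, v_call = v_call,
    j_call = j_call, cdr3_aa = cdr3_aa, duplicate_count = duplicate_count)
}

# Strip the allele suffix ("*01") from a gene call, keeping the gene.
strip_allele <- function(x) sub("\\*.*$", "", x)

#' Read an AIRR rearrangement TSV into validated records
#'
#' Each row of the input becomes either a validated rearrangement record
#' or an entry in the rejection report attached to the result; rows are
#' never silently dropped. Gene calls are normalized to gene level by
#' stripping the allele suffix (configurable off) and CDR3 nucleotide
#' sequences are case-folded to upper case. Records whose CDR3 contains N
#' are kept by default.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect named character vector mapping logical fields to column
#'   names; see [airr_dialect()].
#' @param sample_id sample identifier to assign when the file has no
#'   sample id column.
#' @param strip_alleles drop allele suffixes from V/J calls (default TRUE).
#' @param drop_n reject records whose CDR3 contains an N base.
#' @return a data.frame of records with columns `sample_id`, `umi`,
#'   `cdr3_nt`, `v_gene`, `j_gene`, `cdr3_aa`, `duplicate_count`, carrying
#'   the rejection report in `attr(, "rejects")` (a data.frame with `row`
#'   and `reason`).
#' @export
read_rearrangements <- function(path, dialect = airr_dialect(),
                                sample_id = NULL, strip_alleles = TRUE,
                                drop_n = FALSE) {
  if (!file.exists(path)) stop2("rearrangement file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop2("rearrangement file is empty: %s", path)
  mandatory <- c("umi", "cdr3", "v_call", "j_call")
  for (field in mandatory) {
    if (!dialect[[field]] %in% names(raw))
      stop2("mandatory column '%s' (field %s) missing in %s",
            dialect[[field]], field, path)
  }
  get_col <- function(field, default = NA_character_) {
    nm <- dialect[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else
      rep(default, nrow(raw))
  }
  sid <- get_col("sample_id")
  if (all(is.na(sid))) {
    if (is.null(sample_id))
      stop2("no sample id column in %s and no `sample_id` given", path)
    sid <- rep(sample_id, nrow(raw))
  }
  dc_raw <- get_col("duplicate_count")
  dc <- suppressWarnings(as.integer(dc_raw))
  dc[is.na(dc_raw)] <- 1L
  rec <- data.frame(
    sample_id = sid,
    umi = get_col("umi"),
    cdr3_nt = toupper(get_col("cdr3")),
    v_gene = if (strip_alleles) strip_allele(get_col("v_call"))
             else get_col("v_call"),
    j_gene = if (strip_alleles) strip_allele(get_col("j_call"))
             else get_col("j_call"),
    cdr3_aa = get_col("cdr3_aa"),
    duplicate_count = dc,
    stringsAsFactors = FALSE
  )
  validate_rearrangements(rec, drop_n = drop_n)
}

# Split a record data.frame into valid records (returned, with the reject
# report as an attribute). Validation is total: every row is either kept
# or accounted for in the report.
validate_rearrangements <- function(rec, drop_n = FALSE) {
  reason <- rep(NA_character_, nrow(rec))
  bad_cdr3 <- is.na(rec$cdr3_nt) | rec$cdr3_nt == "" |
    grepl("[^ACGTN]", rec$cdr3_nt)
  reason[bad_cdr3] <- "cdr3_nt empty or outside {A,C,G,T,N}"
  if (drop_n) {
    has_n <- !bad_cdr3 & grepl("N", rec$cdr3_nt, fixed = TRUE)
    reason[has_n] <- "cdr3_nt contains N (drop_n = TRUE)"
  }
  bad_umi <- is.na(rec$umi) | rec$umi == ""
  reason[bad_umi & is.na(reason)] <- "umi missing"
  bad_dc <- is.na(rec$duplicate_count) | rec$duplicate_count < 1L
  reason[bad_dc & is.na(reason)] <- "duplicate_count missing or < 1"
  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  if (nrow(rejects) > 0L)
    warning(sprintf("%d of %d rows rejected (see attr(x, 'rejects'))",
                    nrow(rejects), nrow(rec)), call. = FALSE)
  out
}

#' Read and validate a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `patient_id`, `joint`,
#' `compartment` and optionally `collection_day` (0 = arthroscopy day).
#'
#' @param path path to the manifest CSV.
#' @return a validated data.frame of sample metadata.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop2("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' Validate a sample manifest data.frame
#'
#' Checks column presence, uniqueness of sample ids, the accepted joint
#' and compartment labels, and the compartment/joint consistency rules:
#' synovial-tissue samples (ST_SP, ST_IP) must name a joint, peripheral
#' blood must carry `joint = "other"`.
#'
#' @param df a data.frame of sample metadata.
#' @return the validated data.frame (with `collection_day` defaulted to 0).
#' @export
validate_manifest <- function(df) {
  needed <- c("sample_id", "patient_id", "joint", "compartment")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop2("manifest missing column(s): %s", paste(missing, collapse = ", "))
  if (!"collection_day" %in% names(df)) df$collection_day <- 0L
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop2("duplicate sample_id in manifest: %s",
          paste(unique(dup), collapse = ", "))
  bad_comp <- setdiff(unique(df$compartment), COMPARTMENT_LEVELS)
  if (length(bad_comp))
    stop2("unknown compartment label(s) %s; accepted labels: %s",
          paste(bad_comp, collapse = ", "),
          paste(COMPARTMENT_LEVELS, collapse = ", "))
  bad_joint <- setdiff(unique(df$joint), JOINT_LEVELS)
  if (length(bad_joint))
    stop2("unknown joint label(s) %s; accepted labels: %s",
          paste(bad_joint, collapse = ", "),
          paste(JOINT_LEVELS, collapse = ", "))
  st_no_joint <- df$compartment %in% c("ST_SP", "ST_IP") & df$joint == "other"
  if (any(st_no_joint))
    stop2("synovial tissue sample(s) without a joint: %s",
          paste(df$sample_id[st_no_joint], collapse = ", "))
  pb_joint <- df$compartment == "PB" & df$joint != "other"
  if (any(pb_joint))
    stop2("peripheral blood sample(s) must have joint = 'other': %s",
          paste(df$sample_id[pb_joint], collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write a result table as deterministic delimited text
#'
#' Numeric columns are rounded to a fixed number of significant digits so
#' the file is byte-stable across runs and round-trips exactly.
#'
#' @param x a data.frame.
#' @param path output path.
#' @param sep field separator (tab by default).
#' @param allow_empty permit writing a header-only file.
#' @param digits significant digits for numeric (double) columns.
#' @export
write_table <- function(x, path, sep = "\t", allow_empty = FALSE,
                        digits = 10) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L && !allow_empty)
    stop2("refusing to write empty table to %s (set allow_empty = TRUE)",
          path)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- signif(x[[j]], digits)
  }
  ok <- tryCatch({
    utils::write.table(x, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop2("cannot write table to %s: %s", path,
                         conditionMessage(ok))
  invisible(path)
}
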