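# Synthetic multi-patient, multi-compartment BCR repertoire generator
# with known ground-truth sharing structure. Each patient receives a
# private clone pool; a small set of dominant inflammation-associated
# clones is seeded across compartments through a hierarchical
# presence model calibrated so that the *pairwise* probability that a
# dominant clone of one sample is also dominant in a paired sample
# equals the configured rho for that pair type. Per-compartment clone
# abundances follow a dominant head (the future HECs) plus a Zipf tail
# whose pool size is solved numerically so that the expected number of
# observed clones at the calibration depth matches the configured
# richness.

IGHV_GENES <- c("IGHV1-2", "IGHV1-18", "IGHV1-69", "IGHV3-7", "IGHV3-23",
                "IGHV3-30", "IGHV3-48", "IGHV4-34", "IGHV4-39",
                "IGHV4-59", "IGHV5-51", "IGHV6-1")
IGHJ_GENES <- paste0("IGHJ", 1:6)

#' Configuration for a synthetic repertoire cohort
#'
#' The per-compartment profiles default to the repertoire
#' characteristics of inflamed rheumatoid-arthritis compartments:
#' synovial tissue with roughly 1,300-1,400 observed clones of which
#' about 30 are highly expanded and jointly cover about half of all
#' molecules; peripheral blood with about 5,400 clones, around 5 HECs
#' and about 16% HEC impact; synovial fluid in between. `richness`,
#' `hec_target` and `hec_mass` are the expected observed clone count,
#' HEC count and summed HEC frequency at `calibration_depth`.
#'
#' The sharing block gives, for each pair type, the probability that a
#' dominant clone of one sample is also among the dominant clones of
#' the paired sample (rho). The hierarchy requires
#' `rho_between_joints <= rho_within_joint`,
#' `rho_st_sf <= sqrt(rho_within_joint)` and
#' `rho_blood <= sqrt(rho_between_joints)` (or the respective rho = 0).
#'
#' @param n_patients number of patients; each patient contributes two
#'   ST biopsy sites per joint, one SF sample (first joint) and one PB
#'   sample, subject to `joints`/`compartments`.
#' @param master_seed master seed; per-patient and per-sample seeds are
#'   derived deterministically from it.
#' @param joints joints biopsied per patient.
#' @param compartments compartments to generate.
#' @param sharing list of rho_within_joint, rho_between_joints,
#'   rho_st_sf, rho_blood, all fractions in \[0, 1\].
#' @param profiles per-compartment blocks with richness, hec_target,
#'   hec_mass, molecules.
#' @param abundance tail abundance model: list(model = "zipf",
#'   exponent).
#' @param umi_reads_mean mean raw reads per UMI-tagged molecule.
#' @param plasma_amplification_range multiplier range for BCR mRNA
#'   amplification of plasma-like (dominant) clones in ST/SF.
#' @param calibration_depth analysis depth the profiles refer to.
#' @param hec_floor minimum true frequency of a dominant clone, kept
#'   comfortably above the 0.5% detection threshold so configured HEC
#'   counts survive subsampling.
#' @return a validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2L, master_seed = 1L,
                          joints = c("left_knee", "right_knee"),
                          compartments = c("ST_SP", "ST_IP", "SF", "PB"),
                          sharing = list(rho_within_joint = 0.17,
                                         rho_between_joints = 0.09,
                                         rho_st_sf = 0.08,
                                         rho_blood = 0.10),
                          profiles = list(
                            ST_SP = list(richness = 1337, hec_target = 30,
                                         hec_mass = 0.551,
                                         molecules = 20000),
                            ST_IP = list(richness = 1420, hec_target = 32,
                                         hec_mass = 0.508,
                                         molecules = 20000),
                            SF = list(richness = 2188, hec_target = 23,
                                      hec_mass = 0.317,
                                      molecules = 20000),
                            PB = list(richness = 5407, hec_target = 5,
                                      hec_mass = 0.156,
                                      molecules = 20000)),
                          abundance = list(model = "zipf", exponent = 0.4),
                          umi_reads_mean = 3,
                          plasma_amplification_range = c(5, 50),
                          calibration_depth = 9736L,
                          hec_floor = 0.007) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), master_seed = master_seed,
    joints = joints, compartments = compartments, sharing = sharing,
    profiles = profiles, abundance = abundance,
    umi_reads_mean = umi_reads_mean,
    plasma_amplification_range = plasma_amplification_range,
    calibration_depth = as.integer(calibration_depth),
    hec_floor = hec_floor), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop2("n_patients must be >= 1")
  bad <- setdiff(cfg$compartments, COMPARTMENT_LEVELS)
  if (length(bad)) stop2("unknown compartment(s): %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(cfg$joints, setdiff(JOINT_LEVELS, "other"))
  if (length(bad)) stop2("unknown joint(s): %s", paste(bad, collapse = ", "))
  sh <- cfg$sharing
  for (nm in c("rho_within_joint", "rho_between_joints", "rho_st_sf",
               "rho_blood")) {
    v <- sh[[nm]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
      stop2("sharing$%s must be a fraction in [0, 1]", nm)
  }
  if (sh$rho_between_joints > sh$rho_within_joint)
    stop2("rho_between_joints (%.3g) must not exceed rho_within_joint (%.3g)",
          sh$rho_between_joints, sh$rho_within_joint)
  if (sh$rho_st_sf > 0 && sh$rho_st_sf > sqrt(sh$rho_within_joint))
    stop2("rho_st_sf must not exceed sqrt(rho_within_joint)")
  if (sh$rho_blood > 0 && sh$rho_blood > sqrt(sh$rho_between_joints))
    stop2("rho_blood must not exceed sqrt(rho_between_joints)")
  for (comp in cfg$compartments) {
    pr <- cfg$profiles[[comp]]
    if (is.null(pr)) stop2("no profile for compartment %s", comp)
    if (pr$richness <= pr$hec_target)
      stop2("%s: richness must exceed hec_target", comp)
    if (pr$hec_mass <= 0 || pr$hec_mass >= 1)
      stop2("%s: hec_mass must be in (0, 1)", comp)
    if (pr$molecules < cfg$calibration_depth)
      stop2("%s: molecules (%d) below calibration depth (%d)",
            comp, pr$molecules, cfg$calibration_depth)
    if (pr$hec_target * cfg$hec_floor >= pr$hec_mass)
      stop2("%s: hec_target x hec_floor exceeds hec_mass", comp)
  }
  amp <- cfg$plasma_amplification_range
  if (length(amp) != 2L || amp[1] > amp[2] || amp[1] <= 0)
    stop2("plasma_amplification_range must be an increasing positive pair")
  cfg
}

# Solve the Zipf tail pool size N so that the expected number of tail
# clones observed in a draw of `depth` molecules equals the target.
solve_tail_pool <- function(target_obs, tail_mass, exponent, depth) {
  eobs <- function(N) {
    w <- (1:N)^(-exponent)
    p <- tail_mass * w / sum(w)
    sum(1 - (1 - p)^depth)
  }
  if (target_obs >= depth * tail_mass)
    stop2("tail richness target %d unreachable at depth %d with mass %.3f",
          round(target_obs), depth, tail_mass)
  lo <- max(10, floor(target_obs)); hi <- lo
  while (eobs(hi) < target_obs) {
    hi <- hi * 2L
    if (hi > 5e5) stop2("tail pool solve did not converge")
  }
  as.integer(round(stats::uniroot(function(N) eobs(N) - target_obs,
                                  c(lo, hi))$root))
}

encode_base4 <- function(i, width) {
  alpha <- c("A", "C", "G", "T")
  cols <- vector("list", width)
  x <- i
  for (k in width:1) {
    cols[[k]] <- alpha[x %% 4 + 1]
    x <- x %/% 4
  }
  do.call(paste0, cols)
}

# Generate k novel clones for one patient. CDR3s embed the patient tag
# and a per-batch tag so clones never collide across patients or
# batches; within-batch duplicates are redrawn (bounded retries).
make_clones <- function(k, reg) {
  if (k == 0L)
    return(data.frame(cdr3 = character(), v_gene = character(),
                      j_gene = character(), stringsAsFactors = FALSE))
  reg$batch <- reg$batch + 1L
  prefix <- paste0(reg$patient_tag, encode_base4(reg$batch, 4L))
  lens <- sample(seq(30L, 60L, 3L), k, replace = TRUE) - nchar(prefix)
  gen <- function(lens) {
    chars <- paste(sample(c("A", "C", "G", "T"), sum(lens),
                          replace = TRUE), collapse = "")
    ends <- cumsum(lens)
    substring(chars, ends - lens + 1L, ends)
  }
  cdr3 <- paste0(prefix, gen(lens))
  for (try in 1:10) {
    dup <- duplicated(cdr3)
    if (!any(dup)) break
    cdr3[dup] <- paste0(prefix, gen(lens[dup]))
    if (try == 10L) stop2("could not generate %d unique CDR3s", k)
  }
  data.frame(cdr3 = cdr3,
             v_gene = sample(IGHV_GENES, k, replace = TRUE),
             j_gene = sample(IGHJ_GENES, k, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Dominant-clone frequencies: amplification-driven dispersion around
# hec_mass, clipped from below at hec_floor by iterative water-filling
# so every dominant clone stays safely above the HEC threshold.
head_freqs <- function(h, hec_mass, amplified, amp_range, hec_floor) {
  w <- if (amplified) stats::runif(h, amp_range[1], amp_range[2])
       else stats::runif(h, 1, 3)
  f <- hec_mass * w / sum(w)
  for (it in 1:100) {
    f <- pmax(f, hec_floor)
    f <- f * hec_mass / sum(f)
    if (min(f) >= hec_floor * (1 - 1e-9)) break
  }
  f
}

translate_cdr3 <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

#' Generate a synthetic multi-compartment cohort
#'
#' Produces, per patient, UMI-annotated rearrangement records for two
#' synovial-tissue biopsy sites per joint, a synovial-fluid sample and a
#' peripheral-blood sample (subject to the configured joints and
#' compartments), together with the manifest and the ground truth
#' (dominant clone identities, realized pairwise dominant sharing, and
#' true clone abundances). Fully reproducible from the master seed;
#' per-sample seeds are derived from the sample id so that adding
#' samples leaves existing ones unchanged.
#'
#' @param cfg a [cohort_config()].
#' @param dir optional directory; when given the cohort is also written
#'   to disk via [write_cohort()].
#' @return an object of class `synthetic_cohort`: list with `samples`
#'   (named list of record data.frames), `manifest`, `truth` (list of
#'   `dominant`, `pair_sharing`, `abundance`) and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), dir = NULL) {
  cfg <- validate_cohort_config(cfg)
  sh <- cfg$sharing
  s <- sqrt(sh$rho_within_joint)
  g <- if (s > 0) sqrt(sh$rho_between_joints / sh$rho_within_joint) else 0
  u <- if (s > 0) sh$rho_st_sf / s else 0
  sg <- sqrt(sh$rho_between_joints)
  b <- if (sg > 0) sh$rho_blood / sg else 0

  exponent <- cfg$abundance$exponent %||% 0.4
  if (!identical(cfg$abundance$model %||% "zipf", "zipf"))
    stop2("unsupported abundance model '%s'", cfg$abundance$model)
  tail_pools <- lapply(cfg$profiles, function(pr)
    solve_tail_pool(pr$richness - pr$hec_target, 1 - pr$hec_mass,
                    exponent, cfg$calibration_depth))

  st_comps <- intersect(c("ST_SP", "ST_IP"), cfg$compartments)
  head_max <- max(vapply(cfg$compartments, function(c0)
    cfg$profiles[[c0]]$hec_target, 0))
  joint_code <- c(left_knee = "LK", right_knee = "RK", ankle = "AN")

  samples <- list(); manifest_rows <- list()
  dominant_rows <- list(); abundance_tabs <- list()

  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    reg <- new.env(parent = emptyenv())
    reg$patient_tag <- encode_base4(p, 6L)
    reg$batch <- 0L

    # Patient-level structure: master dominant pool and per-joint heads.
    pat <- with_seed(derive_seed(cfg$master_seed, paste0("pat:", pid)), {
      M <- make_clones(head_max, reg)
      jointheads <- list()
      for (J in cfg$joints) {
        keep <- stats::runif(head_max) < g
        fresh <- make_clones(sum(!keep), reg)
        jh <- M
        if (any(!keep)) jh[!keep, ] <- fresh
        jointheads[[J]] <- jh
      }
      list(M = M, jointheads = jointheads)
    })

    # Sample plan.
    plan <- list()
    for (J in cfg$joints) for (comp in st_comps)
      plan[[length(plan) + 1L]] <- list(
        sample_id = paste(pid, joint_code[[J]], sub("ST_", "", comp),
                          sep = "_"),
        joint = J, compartment = comp)
    if ("SF" %in% cfg$compartments && length(cfg$joints))
      plan[[length(plan) + 1L]] <- list(
        sample_id = paste(pid, joint_code[[cfg$joints[1]]], "SF",
                          sep = "_"),
        joint = cfg$joints[1], compartment = "SF")
    if ("PB" %in% cfg$compartments)
      plan[[length(plan) + 1L]] <- list(
        sample_id = paste(pid, "PB", sep = "_"),
        joint = "other", compartment = "PB")

    for (sp in plan) {
      comp <- sp$compartment
      pr <- cfg$profiles[[comp]]
      h <- pr$hec_target
      res <- with_seed(derive_seed(cfg$master_seed, sp$sample_id), {
        # Head identity: inherit from the parent pool or draw fresh.
        parent <- switch(comp,
          ST_SP = , ST_IP = pat$jointheads[[sp$joint]][seq_len(h), ],
          SF = pat$jointheads[[sp$joint]][seq_len(h), ],
          PB = pat$M[seq_len(h), ])
        keep_p <- switch(comp, ST_SP = s, ST_IP = s, SF = u, PB = b)
        keep <- stats::runif(h) < keep_p
        head <- parent
        if (any(!keep)) head[!keep, ] <- make_clones(sum(!keep), reg)
        amplified <- comp %in% c("ST_SP", "ST_IP", "SF")
        fh <- head_freqs(h, pr$hec_mass, amplified,
                         cfg$plasma_amplification_range, cfg$hec_floor)
        # Zipf tail of patient-private clones.
        N <- tail_pools[[comp]]
        tail <- make_clones(N, reg)
        wt <- (1:N)^(-exponent)
        pt <- (1 - pr$hec_mass) * wt / sum(wt)
        prob <- c(fh, pt)
        clones <- rbind(head, tail)
        cnt <- as.vector(stats::rmultinom(1L, pr$molecules, prob))
        pres <- which(cnt > 0L)
        mol <- rep.int(pres, cnt[pres])
        aa <- rep(NA_character_, nrow(clones))
        aa[pres] <- translate_cdr3(clones$cdr3[pres])
        rec <- data.frame(
          sample_id = sp$sample_id,
          umi = encode_base4(seq_len(pr$molecules), 12L),
          cdr3_nt = clones$cdr3[mol],
          v_gene = clones$v_gene[mol],
          j_gene = clones$j_gene[mol],
          cdr3_aa = aa[mol],
          duplicate_count = 1L + stats::rpois(pr$molecules,
                                              max(cfg$umi_reads_mean - 1,
                                                  0)),
          stringsAsFactors = FALSE)
        list(rec = rec,
             dominant = data.frame(patient_id = pid,
                                   sample_id = sp$sample_id,
                                   slot = seq_len(h),
                                   cdr3 = head$cdr3,
                                   v_gene = head$v_gene,
                                   j_gene = head$j_gene,
                                   freq_true = fh,
                                   inherited = keep,
                                   stringsAsFactors = FALSE),
             abundance = data.frame(sample_id = sp$sample_id,
                                    cdr3 = clones$cdr3,
                                    v_gene = clones$v_gene,
                                    j_gene = clones$j_gene,
                                    prob = prob,
                                    is_dominant =
                                      seq_len(nrow(clones)) <= h,
                                    stringsAsFactors = FALSE))
      })
      samples[[sp$sample_id]] <- res$rec
      dominant_rows[[sp$sample_id]] <- res$dominant
      abundance_tabs[[sp$sample_id]] <- res$abundance
      manifest_rows[[sp$sample_id]] <- data.frame(
        sample_id = sp$sample_id, patient_id = pid, joint = sp$joint,
        compartment = comp, collection_day = 0L,
        stringsAsFactors = FALSE)
    }
  }

  manifest <- do.call(rbind, manifest_rows)
  rownames(manifest) <- NULL
  dominant <- do.call(rbind, dominant_rows)
  rownames(dominant) <- NULL

  # Realized pairwise sharing of dominant clones, per within-patient pair.
  sharing_rows <- list()
  for (pid in unique(manifest$patient_id)) {
    sids <- manifest$sample_id[manifest$patient_id == pid]
    if (length(sids) < 2L) next
    for (i in seq_len(length(sids) - 1L)) for (j in seq(i + 1L,
                                                        length(sids))) {
      da <- dominant$cdr3[dominant$sample_id == sids[i]]
      db <- dominant$cdr3[dominant$sample_id == sids[j]]
      ma <- manifest[manifest$sample_id == sids[i], ]
      mb <- manifest[manifest$sample_id == sids[j], ]
      sharing_rows[[length(sharing_rows) + 1L]] <- data.frame(
        patient_id = pid, sample_a = sids[i], sample_b = sids[j],
        comparison_class = classify_pair(ma, mb),
        n_dominant_a = length(da), n_dominant_b = length(db),
        n_shared_dominant = length(intersect(da, db)),
        true_shared_fraction =
          length(intersect(da, db)) / min(length(da), length(db)),
        stringsAsFactors = FALSE)
    }
  }
  pair_sharing <- if (length(sharing_rows)) do.call(rbind, sharing_rows)
                  else data.frame()
  rownames(pair_sharing) <- NULL

  cohort <- structure(list(samples = samples,
                           manifest = validate_manifest(manifest),
                           truth = list(dominant = dominant,
                                        pair_sharing = pair_sharing,
                                        abundance = abundance_tabs),
                           config = cfg),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d samples, master seed %s\n",
              x$config$n_patients, length(x$samples),
              format(x$config$master_seed)))
  print(x$manifest)
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one AIRR-dialect rearrangement TSV per sample (column names
#' `sample_id`, `umi`, `cdr3`, `v_call`, `j_call`, `cdr3_aa`,
#' `duplicate_count`, gene calls carrying an allele suffix), the
#' manifest CSV, ground-truth tables (dominant clones, pairwise
#' dominant sharing, clone abundances) and the configuration as YAML.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$samples)) {
    rec <- cohort$samples[[sid]]
    out <- data.frame(sample_id = rec$sample_id, umi = rec$umi,
                      cdr3 = rec$cdr3_nt,
                      v_call = paste0(rec$v_gene, "*01"),
                      j_call = paste0(rec$j_gene, "*01"),
                      cdr3_aa = rec$cdr3_aa,
                      duplicate_count = rec$duplicate_count,
                      stringsAsFactors = FALSE)
    write_table(out, file.path(dir, paste0(sid, ".tsv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_table(cohort$truth$dominant,
              file.path(dir, "ground_truth_dominant.tsv"))
  write_table(do.call(rbind, cohort$truth$abundance),
              file.path(dir, "ground_truth_abundance.tsv"))
  write_table(cohort$truth$pair_sharing,
              file.path(dir, "ground_truth_sharing.tsv"),
              allow_empty = TRUE)
  cfg <- cohort$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}

#' Compare pipeline overlap estimates with the generator's ground truth
#'
#' Merges an overlap table with the cohort's realized dominant-clone
#' sharing and reports, per comparison class, the mean estimated top-N
#' retrieval and Chao-Sorensen index against the mean true shared
#' fraction, together with the analytic chance-overlap bound
#' `100 * n_top / min(richness)` (the expected retrieval if the two top
#' lists were unrelated random picks from each sample's observed
#' clones).
#'
#' @param overlaps result of [pairwise_overlaps()] on the cohort.
#' @param cohort the `synthetic_cohort` that produced it.
#' @return data.frame per comparison class: n_pairs, mean_true_shared,
#'   mean_topn_pct, mean_chao, chance_bound_pct.
#' @export
recover_parameters <- function(overlaps, cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- cohort$truth$pair_sharing
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  idx <- match(key(overlaps$sample_a, overlaps$sample_b),
               key(truth$sample_a, truth$sample_b))
  if (anyNA(idx)) stop2("overlap pair(s) missing from ground truth")
  ov <- overlaps
  ov$true_shared_fraction <- truth$true_shared_fraction[idx]
  comp_of <- cohort$manifest$compartment[
    match(ov$sample_a, cohort$manifest$sample_id)]
  comp_of_b <- cohort$manifest$compartment[
    match(ov$sample_b, cohort$manifest$sample_id)]
  rich <- vapply(cohort$config$profiles, function(pr) pr$richness, 0)
  ov$chance_bound_pct <- 100 * ov$n_top /
    pmin(rich[comp_of], rich[comp_of_b])
  cls <- unique(ov$comparison_class)
  out <- data.frame(
    comparison_class = cls,
    n_pairs = vapply(cls, function(k)
      sum(ov$comparison_class == k), 0L),
    mean_true_shared = vapply(cls, function(k)
      mean(ov$true_shared_fraction[ov$comparison_class == k]), 0),
    mean_topn_pct = vapply(cls, function(k)
      mean(ov$topn_retrieval_pct[ov$comparison_class == k]), 0),
    mean_chao = vapply(cls, function(k)
      mean(ov$chao_sorensen[ov$comparison_class == k]), 0),
    chance_bound_pct = vapply(cls, function(k)
      mean(ov$chance_bound_pct[ov$comparison_class == k]), 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
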