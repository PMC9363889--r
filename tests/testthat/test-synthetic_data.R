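# Synthetic cohort generator: structure, determinism, ground truth.

test_that("a two-patient cohort has the full compartment structure", {
  co <- generate_cohort(small_cohort_config(n_patients = 2))
  # 2 joints x 2 ST sites + SF + PB per patient
  expect_length(co$samples, 12L)
  expect_equal(nrow(co$manifest), 12L)
  expect_identical(co$manifest, validate_manifest(co$manifest))
  expect_equal(sum(co$manifest$compartment == "PB"), 2L)
  expect_equal(sum(co$manifest$compartment == "SF"), 2L)
  # every record validates under the io module rules
  for (rec in co$samples) {
    checked <- repshare:::validate_rearrangements(rec)
    expect_equal(nrow(attr(checked, "rejects")), 0L)
  }
})

test_that("generation is deterministic and written files are byte-stable", {
  cfg <- small_cohort_config(n_patients = 1, master_seed = 77)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_cohort(co1, d1); write_cohort(co2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes content but not schema
  co3 <- generate_cohort(small_cohort_config(n_patients = 1,
                                             master_seed = 78))
  expect_identical(names(co3$samples), names(co1$samples))
  expect_false(identical(co3$samples[[1]], co1$samples[[1]]))
})

test_that("clone identities are unique within a patient and traceable", {
  co <- generate_cohort(small_cohort_config(n_patients = 2,
                                            master_seed = 5))
  for (pid in unique(co$manifest$patient_id)) {
    sids <- co$manifest$sample_id[co$manifest$patient_id == pid]
    ab <- do.call(rbind, co$truth$abundance[sids])
    # within a sample every clone is listed once
    expect_false(any(duplicated(paste(ab$sample_id, ab$cdr3))))
    # every emitted record traces to a ground-truth clone of its sample
    for (sid in sids) {
      tr <- co$truth$abundance[[sid]]
      expect_true(all(co$samples[[sid]]$cdr3_nt %in% tr$cdr3))
    }
  }
  # private (non-dominant) clones never recur across samples
  priv <- do.call(rbind, co$truth$abundance)
  priv <- priv[!priv$cdr3 %in% co$truth$dominant$cdr3, ]
  expect_false(any(duplicated(priv$cdr3)))
})

test_that("rho_between_joints = 0 yields no contralateral dominant sharing", {
  cfg <- small_cohort_config(
    n_patients = 2, master_seed = 9,
    sharing = list(rho_within_joint = 0.5, rho_between_joints = 0,
                   rho_st_sf = 0, rho_blood = 0))
  co <- generate_cohort(cfg)
  between <- co$truth$pair_sharing[
    co$truth$pair_sharing$comparison_class == "ST_ST_between_joints", ]
  expect_gt(nrow(between), 0)
  expect_true(all(between$n_shared_dominant == 0L))
})

test_that("full dominant sharing drives top-25 retrieval near 100", {
  co <- generate_cohort(st_pair_config(rho = 1, seed = 15))
  ana <- analyze_cohort(co$samples, co$manifest, seed = 15)
  # both top-25 lists live inside the shared dominant set (30 and 32
  # clones), so the overlap is at least (25 + 25 - 32)/25 = 72%
  expect_gte(ana$overlaps$topn_retrieval_pct, 72)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(sharing = list(
    rho_within_joint = 0.1, rho_between_joints = 0.5,
    rho_st_sf = 0, rho_blood = 0)), "rho_between_joints")
  expect_error(cohort_config(sharing = list(
    rho_within_joint = 0.09, rho_between_joints = 0.09,
    rho_st_sf = 0.9, rho_blood = 0)), "rho_st_sf")
  bad <- small_profiles(); bad$PB$richness <- 2
  expect_error(cohort_config(profiles = bad, calibration_depth = 1000),
               "richness")
})

test_that("blood shows more clones and fewer HECs than synovial tissue", {
  for (seed in 1:6) {
    co <- generate_cohort(cohort_config(
      n_patients = 1, master_seed = seed, joints = "left_knee",
      compartments = c("ST_SP", "PB")))
    ana <- analyze_cohort(co$samples, co$manifest, seed = seed)
    st <- ana$summaries[ana$summaries$compartment == "ST_SP", ]
    pb <- ana$summaries[ana$summaries$compartment == "PB", ]
    expect_gt(pb$n_clones, st$n_clones)
    expect_lt(pb$n_hecs, st$n_hecs)
    expect_lt(pb$hec_impact, st$hec_impact)
  }
})

test_that("recovery reporting links estimates to realized truth", {
  co <- generate_cohort(st_pair_config(rho = 0.5, seed = 23))
  ana <- analyze_cohort(co$samples, co$manifest, seed = 23)
  rec <- recover_parameters(ana$overlaps, co)
  expect_equal(rec$comparison_class, "ST_ST_within_joint")
  expect_equal(rec$n_pairs, 1L)
  expect_true(rec$mean_true_shared >= 0 && rec$mean_true_shared <= 1)
  expect_gt(rec$chance_bound_pct, 0)
})
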