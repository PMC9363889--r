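# Fixture builders and independent oracles used across the suite.

# Rearrangement records for a sample with given clone counts
# (named vector: CDR3 -> molecule count), one unique UMI per molecule.
toy_records <- function(counts, sample_id = "S1", v = NULL, j = NULL,
                        aa = NULL) {
  k <- length(counts)
  if (is.null(v)) v <- rep("IGHV3-23", k)
  if (is.null(j)) j <- rep("IGHJ4", k)
  if (is.null(aa)) aa <- rep(NA_character_, k)
  idx <- rep(seq_len(k), counts)
  data.frame(
    sample_id = sample_id,
    umi = sprintf("U%07d", seq_along(idx)),
    cdr3_nt = names(counts)[idx],
    v_gene = v[idx], j_gene = j[idx], cdr3_aa = aa[idx],
    duplicate_count = 1L,
    stringsAsFactors = FALSE
  )
}

toy_meta <- function(sample_id = "S1", patient_id = "P1",
                     joint = "left_knee", compartment = "ST_SP") {
  list(sample_id = sample_id, patient_id = patient_id, joint = joint,
       compartment = compartment)
}

# Build a repertoire through the real clonotyping path.
toy_repertoire <- function(counts, sample_id = "S1", ...) {
  build_repertoire(collapse_umis(toy_records(counts, sample_id)),
                   toy_meta(sample_id = sample_id, ...))
}

# Independent brute-force evaluation of the abundance-based
# Chao-Sorensen estimator, written as an explicit per-clone loop over
# named count vectors (a code path unrelated to the implementation).
naive_chao <- function(x, y, variant = "bias_corrected") {
  n <- sum(x); m <- sum(y)
  shared <- intersect(names(x)[x > 0], names(y)[y > 0])
  if (length(shared) == 0) return(0)
  U <- 0; V <- 0; cU <- 0; cV <- 0
  f_p1 <- 0; f_p2 <- 0; f_1p <- 0; f_2p <- 0
  for (s in shared) {
    U <- U + x[[s]] / n
    V <- V + y[[s]] / m
    if (y[[s]] == 1) { f_p1 <- f_p1 + 1; cU <- cU + x[[s]] / n }
    if (y[[s]] == 2) f_p2 <- f_p2 + 1
    if (x[[s]] == 1) { f_1p <- f_1p + 1; cV <- cV + y[[s]] / m }
    if (x[[s]] == 2) f_2p <- f_2p + 1
  }
  if (variant == "bias_corrected") {
    U <- U + (m - 1) / m * f_p1 / (2 * max(f_p2, 1)) * cU
    V <- V + (n - 1) / n * f_1p / (2 * max(f_2p, 1)) * cV
  }
  U <- min(U, 1); V <- min(V, 1)
  if (U + V == 0) 0 else 2 * U * V / (U + V)
}

# Random shared/private count-vector pair for estimator tests.
random_count_pair <- function(max_clones = 30, max_count = 50) {
  k_shared <- sample.int(max_clones %/% 2, 1)
  k_a <- sample.int(max_clones %/% 2, 1)
  k_b <- sample.int(max_clones %/% 2, 1)
  nm <- function(p, k) paste0(p, seq_len(k))
  x <- c(stats::setNames(sample.int(max_count, k_shared, replace = TRUE),
                         nm("s", k_shared)),
         stats::setNames(sample.int(max_count, k_a, replace = TRUE),
                         nm("a", k_a)))
  y <- c(stats::setNames(sample.int(max_count, k_shared, replace = TRUE),
                         nm("s", k_shared)),
         stats::setNames(sample.int(max_count, k_b, replace = TRUE),
                         nm("b", k_b)))
  # drop some shared clones from one side to vary the overlap structure
  if (k_shared > 2 && stats::runif(1) < 0.5)
    y <- y[-sample.int(k_shared, 1)]
  list(x = x, y = y)
}

# Exact two-sided Mann-Whitney p-value by enumeration of all
# assignments of the pooled values to the two groups (tie-free input).
mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pool), nx)
  us <- apply(combs, 2, function(ix) u_of(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Fast sweep-style synthetic config: one joint, two ST biopsy sites.
st_pair_config <- function(rho, seed, molecules = 20000) {
  cohort_config(
    n_patients = 1, master_seed = seed, joints = "left_knee",
    compartments = c("ST_SP", "ST_IP"),
    sharing = list(rho_within_joint = rho, rho_between_joints = 0,
                   rho_st_sf = 0, rho_blood = 0))
}

# Reduced-size profiles for fast structural tests.
small_profiles <- function(molecules = 2000) {
  list(ST_SP = list(richness = 300, hec_target = 10, hec_mass = 0.4,
                    molecules = molecules),
       ST_IP = list(richness = 320, hec_target = 11, hec_mass = 0.38,
                    molecules = molecules),
       SF = list(richness = 400, hec_target = 8, hec_mass = 0.3,
                 molecules = molecules),
       PB = list(richness = 600, hec_target = 3, hec_mass = 0.12,
                 molecules = molecules))
}

small_cohort_config <- function(n_patients = 1, master_seed = 1, ...) {
  cohort_config(n_patients = n_patients, master_seed = master_seed,
                profiles = small_profiles(), calibration_depth = 1000,
                ...)
}
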