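# Top-N clonal retrieval and the Chao-Sorensen similarity estimator.

rep_pair <- function(x, y) {
  list(a = toy_repertoire(x, sample_id = "A"),
       b = toy_repertoire(y, sample_id = "B"))
}

test_that("top-N retrieval: identity, disjointness and a constructed overlap", {
  x <- stats::setNames(seq(50, 2, length.out = 25), sprintf("TGTC%02d", 1:25))
  x <- round(x)
  p <- rep_pair(x, x)
  expect_equal(as.numeric(topn_retrieval(p$a, p$b, 25)), 100)

  y <- stats::setNames(x, sprintf("TGTD%02d", 1:25))
  p <- rep_pair(x, y)
  expect_equal(as.numeric(topn_retrieval(p$a, p$b, 25)), 0)

  # b shares exactly the first 5 of a's top-25
  z <- stats::setNames(x, c(sprintf("TGTC%02d", 1:5),
                            sprintf("TGTD%02d", 6:25)))
  p <- rep_pair(x, z)
  expect_equal(as.numeric(topn_retrieval(p$a, p$b, 25)), 20)
})

test_that("top-N retrieval is symmetric, bounded, and warns when short", {
  set.seed(31)
  for (i in 1:15) {
    x <- stats::setNames(sample(1:40, 30, TRUE), sprintf("TGTA%03d", 1:30))
    y <- stats::setNames(sample(1:40, 30, TRUE),
                         sprintf("TGT%s%03d",
                                 sample(c("A", "B"), 30, TRUE), 1:30))
    p <- rep_pair(x, y)
    f <- as.numeric(topn_retrieval(p$a, p$b, 25))
    r <- as.numeric(topn_retrieval(p$b, p$a, 25))
    expect_identical(f, r)
    expect_gte(f, 0); expect_lte(f, 100)
  }
  p <- rep_pair(c(TGTAAA = 5L, TGTCCC = 3L), c(TGTAAA = 4L, TGTGGG = 2L))
  expect_warning(v <- topn_retrieval(p$a, p$b, 25), "fewer than 25")
  expect_equal(attr(v, "n_eff"), 2L)
  expect_equal(as.numeric(v), 50)
})

test_that("promoting a shared clone into the top list never lowers retrieval", {
  set.seed(37)
  x <- stats::setNames(sample(10:60, 30, TRUE), sprintf("TGTA%03d", 1:30))
  y <- stats::setNames(sample(10:60, 30, TRUE), sprintf("TGTB%03d", 1:30))
  p <- rep_pair(x, y)
  base <- as.numeric(topn_retrieval(p$a, p$b, 25))
  # replace one of b's top private clones by one of a's top clones
  y2 <- y
  names(y2)[which.max(y2)] <- names(x)[which.max(x)]
  p2 <- rep_pair(x, y2)
  expect_gte(as.numeric(topn_retrieval(p2$a, p2$b, 25)), base)
})

test_that("Chao-Sorensen reproduces a hand-evaluated shared-abundance case", {
  # A = {a:4, b:1, c:5}, B = {a:3, b:6, d:1}; U = 0.5, V capped at 1
  p <- rep_pair(c(TGTA = 4L, TGTB = 1L, TGTC = 5L),
                c(TGTA = 3L, TGTB = 6L, TGTD = 1L))
  cs <- chao_sorensen(p$a, p$b)
  expect_equal(cs$components$U, 0.5, tolerance = 1e-12)
  expect_equal(cs$components$V, 1.0, tolerance = 1e-12)
  expect_equal(cs$index, 2 * 0.5 * 1 / 1.5, tolerance = 1e-12)
  expect_equal(cs$components$f_plus1, 0L)
  expect_equal(cs$components$f_1plus, 1L)
})

test_that("Chao-Sorensen limits: identical repertoires 1, disjoint 0", {
  x <- stats::setNames(sample(3:30, 20, TRUE), sprintf("TGTA%03d", 1:20))
  p <- rep_pair(x, x)
  expect_equal(chao_sorensen(p$a, p$b)$index, 1, tolerance = 1e-12)
  y <- stats::setNames(x, sprintf("TGTB%03d", 1:20))
  p <- rep_pair(x, y)
  expect_equal(chao_sorensen(p$a, p$b)$index, 0)
})

test_that("Chao-Sorensen equals an independent brute-force oracle", {
  set.seed(41)
  for (i in 1:60) {
    pr <- random_count_pair()
    p <- rep_pair(pr$x, pr$y)
    for (variant in c("bias_corrected", "uncorrected")) {
      cs <- chao_sorensen(p$a, p$b, variant = variant)
      expect_equal(cs$index, naive_chao(pr$x, pr$y, variant),
                   tolerance = 1e-12)
      expect_gte(cs$index, 0); expect_lte(cs$index, 1)
      # symmetry: swapping arguments swaps U and V, index unchanged
      sw <- chao_sorensen(p$b, p$a, variant = variant)
      expect_equal(sw$index, cs$index, tolerance = 1e-12)
      expect_equal(sw$components$U, cs$components$V, tolerance = 1e-12)
    }
  }
})

test_that("U and V components agree with vegan's Chao abundance index", {
  library(vegan)
  set.seed(43)
  checked <- 0
  for (i in 1:40) {
    pr <- random_count_pair()
    keys <- union(names(pr$x), names(pr$y))
    mat <- rbind(a = pr$x[keys], b = pr$y[keys])
    mat[is.na(mat)] <- 0
    cs <- chao_sorensen(rep_pair(pr$x, pr$y)$a, rep_pair(pr$x, pr$y)$b)
    U <- cs$components$U; V <- cs$components$V
    if (U > 0 && V > 0 && U < 1 && V < 1) {
      jac <- U * V / (U + V - U * V)
      expect_equal(jac, 1 - as.numeric(vegdist(mat, method = "chao")),
                   tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 10)
})

test_that("similarity of same-distribution samples rises with depth", {
  set.seed(47)
  probs <- (1:300)^-0.8
  probs <- probs / sum(probs)
  keys <- sprintf("TGTP%04d", 1:300)
  chao_at <- function(depth) {
    x <- stats::setNames(as.vector(stats::rmultinom(1, depth, probs)), keys)
    y <- stats::setNames(as.vector(stats::rmultinom(1, depth, probs)), keys)
    p <- rep_pair(x[x > 0], y[y > 0])
    chao_sorensen(p$a, p$b)$index
  }
  shallow <- replicate(50, chao_at(500))
  deep <- replicate(50, chao_at(5000))
  expect_gt(median(deep), median(shallow))
  expect_gt(median(deep), 0.9)
})

test_that("overlap plot data covers the union with ND floors and quadrants", {
  filler_a <- stats::setNames(rep(2L, 50), sprintf("TGTFA%03d", 1:50))
  filler_b <- stats::setNames(rep(2L, 50), sprintf("TGTFB%03d", 1:50))
  x <- c(c(TGTBOTH = 10L, TGTAONLY = 10L, TGTSMALL = 2L), filler_a)
  y <- c(c(TGTBOTH = 12L, TGTSMALL = 1L), filler_b,
         stats::setNames(9L, "TGTBONLY"))
  p <- rep_pair(x, y)
  pd <- overlap_plot_data(p$a, p$b, hec_threshold = 0.005)
  expect_equal(nrow(pd), length(union(names(x), names(y))))
  both <- pd[pd$cdr3 == "TGTBOTH", ]
  expect_equal(both$quadrant, "both_hec")
  aonly <- pd[pd$cdr3 == "TGTAONLY", ]
  expect_equal(aonly$quadrant, "a_only_hec")
  expect_false(aonly$detected_b)
  expect_equal(aonly$freq_b_pct, 100 * 0.5 / p$b$total_molecules)
})

test_that("pairwise overlaps classify pairs and never cross patients", {
  man <- data.frame(
    sample_id = c("A1", "A2", "A3", "A4", "B1", "B2"),
    patient_id = c("PA", "PA", "PA", "PA", "PB", "PB"),
    joint = c("left_knee", "left_knee", "right_knee", "other",
              "left_knee", "other"),
    compartment = c("ST_SP", "ST_IP", "ST_SP", "PB", "SF", "PB"),
    collection_day = 0L, stringsAsFactors = FALSE)
  counts <- stats::setNames(rep(5L, 20), sprintf("TGTS%03d", 1:20))
  reps <- lapply(man$sample_id, function(s)
    toy_repertoire(counts, sample_id = s,
                   patient_id = man$patient_id[man$sample_id == s],
                   joint = man$joint[man$sample_id == s],
                   compartment = man$compartment[man$sample_id == s]))
  names(reps) <- man$sample_id
  suppressWarnings(ov <- pairwise_overlaps(reps, man, n_top = 25))
  expect_equal(nrow(ov), choose(4, 2) + choose(2, 2))
  expect_false(any(ov$patient_id == "PA" &
                   ov$sample_a %in% c("B1", "B2")))
  cls <- function(a, b) ov$comparison_class[ov$sample_a == a &
                                            ov$sample_b == b]
  expect_equal(cls("A1", "A2"), "ST_ST_within_joint")
  expect_equal(cls("A1", "A3"), "ST_ST_between_joints")
  expect_equal(cls("A1", "A4"), "ST_PB")
  expect_equal(cls("B1", "B2"), "SF_PB")

  shallow <- reps
  shallow$A2 <- toy_repertoire(counts[1:10], sample_id = "A2",
                               joint = "left_knee")
  expect_error(suppressWarnings(pairwise_overlaps(shallow, man)),
               "unequal depth")
})

test_that("ST and SF from the same joint classify as ST_SF", {
  expect_equal(classify_pair(
    list(compartment = "ST_SP", joint = "left_knee"),
    list(compartment = "SF", joint = "left_knee")), "ST_SF")
  expect_equal(classify_pair(
    list(compartment = "ST_SP", joint = "right_knee"),
    list(compartment = "SF", joint = "left_knee")), "other")
})
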