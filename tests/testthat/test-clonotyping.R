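# UMI collapse and clonotype aggregation.

test_that("reads sharing UMI and clone key collapse to one molecule", {
  rec <- toy_records(c(TGTGCGAGA = 1L))
  rec <- rec[rep(1, 5), ]
  rec$umi <- "SAMEUMI"
  out <- collapse_umis(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$duplicate_count, 5L)
})

test_that("UMI collisions across clone keys stay distinct molecules", {
  rec <- toy_records(c(TGTGCGAGA = 1L, TGTGCCAGA = 1L))
  rec$umi <- "SAMEUMI"
  out <- collapse_umis(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$duplicate_count, c(1L, 1L))
})

test_that("collapse matches a naive group-by oracle and is order-invariant", {
  set.seed(11)
  n <- 1000L
  rec <- data.frame(
    sample_id = "S1",
    umi = sample(sprintf("U%03d", 1:40), n, replace = TRUE),
    cdr3_nt = sample(c("TGTAAA", "TGTCCC", "TGTGGG"), n, replace = TRUE),
    v_gene = sample(c("IGHV1-2", "IGHV3-23"), n, replace = TRUE),
    j_gene = "IGHJ4", cdr3_aa = NA_character_,
    duplicate_count = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE)
  out <- collapse_umis(rec)
  # oracle: independent tapply over the concatenated grouping key
  key <- paste(rec$umi, rec$cdr3_nt, rec$v_gene, rec$j_gene)
  oracle <- tapply(rec$duplicate_count, key, sum)
  expect_equal(nrow(out), length(oracle))
  got <- out$duplicate_count
  names(got) <- paste(out$umi, out$cdr3_nt, out$v_gene, out$j_gene)
  expect_equal(unname(got[names(oracle)]), as.vector(oracle))
  # order invariance and idempotence
  perm <- rec[sample(n), ]
  expect_identical(collapse_umis(perm), out)
  expect_identical(collapse_umis(out), out)
})

test_that("collapse rejects empty or multi-sample input", {
  expect_error(collapse_umis(toy_records(c(A = 1L))[0, ]), "no input")
  two <- rbind(toy_records(c(TGTAAA = 1L), sample_id = "S1"),
               toy_records(c(TGTAAA = 1L), sample_id = "S2"))
  expect_error(collapse_umis(two), "multiple samples")
})

test_that("clone frequencies are molecule shares and sum to one", {
  r <- toy_repertoire(c(TGTAAA = 6L, TGTCCC = 3L, TGTGGG = 1L))
  expect_equal(r$total_molecules, 10L)
  expect_equal(r$clones$frequency, c(0.6, 0.3, 0.1))
  expect_equal(sum(r$clones$frequency), 1, tolerance = 1e-9)
})

test_that("the clone key includes the V and J gene", {
  rec <- toy_records(c(TGTAAA = 2L), v = "IGHV1-2")
  rec2 <- toy_records(c(TGTAAA = 3L), v = "IGHV3-23")
  rec2$umi <- sprintf("W%07d", seq_len(nrow(rec2)))
  r <- build_repertoire(collapse_umis(rbind(rec, rec2)), toy_meta())
  expect_equal(nrow(r$clones), 2L)
  expect_setequal(r$clones$v_gene, c("IGHV1-2", "IGHV3-23"))
})

test_that("repertoire construction is invariant to input order", {
  rec <- toy_records(c(TGTAAA = 5L, TGTCCC = 4L, TGTGGG = 2L))
  r1 <- build_repertoire(rec, toy_meta())
  set.seed(3)
  r2 <- build_repertoire(rec[sample(nrow(rec)), ], toy_meta())
  expect_identical(r1$clones, r2$clones)
})

test_that("amino-acid mode requires cdr3_aa", {
  rec <- toy_records(c(TGTAAA = 2L))
  expect_error(build_repertoire(rec, toy_meta(), mode = "aa"),
               "cdr3_aa")
  rec$cdr3_aa <- "CK"
  r <- build_repertoire(rec, toy_meta(), mode = "aa")
  expect_equal(r$clones$cdr3, "CK")
})

test_that("CDR3 projection merges V/J variants and conserves molecules", {
  rec <- rbind(toy_records(c(TGTAAA = 30L), v = "IGHV1-2"),
               transform(toy_records(c(TGTAAA = 10L), v = "IGHV4-34"),
                         umi = sprintf("W%07d", 1:10)),
               transform(toy_records(c(TGTCCC = 5L)),
                         umi = sprintf("X%07d", 1:5)))
  r <- build_repertoire(collapse_umis(rec), toy_meta())
  expect_equal(nrow(r$clones), 3L)
  p <- project_to_cdr3(r)
  expect_equal(nrow(p$clones), 2L)
  expect_equal(p$clones$molecule_count[p$clones$cdr3 == "TGTAAA"], 40L)
  expect_equal(p$total_molecules, r$total_molecules)
  expect_equal(sum(p$clones$frequency), 1, tolerance = 1e-9)
  # idempotence and identity on all-distinct CDR3s
  expect_identical(project_to_cdr3(p), p)
  rd <- toy_repertoire(c(TGTAAA = 3L, TGTCCC = 2L))
  expect_equal(project_to_cdr3(rd)$clones$molecule_count,
               rd$clones$molecule_count)
})

test_that("projection never increases clone count (random repertoires)", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    pool <- paste0("TGT", c("AAA", "CCC", "GGG", "TTT", "ACG", "CAT",
                            "GAT", "TAG"))
    counts <- stats::setNames(sample(1:20, k, replace = TRUE),
                              sample(pool, k, replace = TRUE))
    v <- sample(c("IGHV1-2", "IGHV3-23", "IGHV4-34"), k, replace = TRUE)
    r <- build_repertoire(
      collapse_umis(toy_records(counts, v = v)), toy_meta())
    p <- project_to_cdr3(r)
    expect_lte(nrow(p$clones), nrow(r$clones))
    expect_equal(p$total_molecules, r$total_molecules)
  }
})
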