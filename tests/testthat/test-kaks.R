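test_that("count_sites matches brute-force enumeration on every sense codon", {
  for (codon in SENSE) {
    expect_equal(count_sites(codon), oracle_sites(codon), info = codon)
  }
  # worked examples
  expect_equal(unname(count_sites("TTT")), c(1 / 3, 8 / 3))
  expect_equal(unname(count_sites("ATG")), c(0, 3))
  expect_equal(unname(count_sites("CTT")), c(1, 2))
  expect_error(count_sites("TAA"), "sense")
})

test_that("site counts conserve syn + nonsyn == 3 for all sense codons", {
  totals <- vapply(SENSE, function(c) sum(count_sites(c)), numeric(1))
  expect_equal(unname(totals), rep(3, length(SENSE)))
})

test_that("count_differences matches exhaustive pathway enumeration", {
  # full 61 x 61 oracle equivalence
  for (a in SENSE) {
    for (b in SENSE) {
      got <- suppressWarnings(count_differences(a, b))
      want <- oracle_diffs(a, b)
      expect_equal(got, want, info = paste(a, b))
    }
  }
})

test_that("difference counts sum to the number of mismatches on legal pairs", {
  set.seed(2)
  for (i in 1:200) {
    a <- sample(SENSE, 1); b <- sample(SENSE, 1)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    d <- suppressWarnings(count_differences(a, b))
    expect_equal(sum(d), k, info = paste(a, b))
  }
  expect_equal(unname(count_differences("TTT", "TTT")), c(0, 0))
  expect_equal(unname(count_differences("TTT", "TTC")), c(1, 0))
  expect_equal(unname(count_differences("TTT", "GTA")), c(0.5, 1.5))
})

test_that("back_translate maps columns to codons and drops gapped columns", {
  aln <- back_translate("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(aln$codons_a, c("ATG", "AAA"))
  expect_equal(aln$codons_b, c("ATG", "AAG"))

  aln2 <- back_translate("M-K", "MQK", "ATGAAA", "ATGCAAAAA")
  expect_equal(aln2$codons_a, c("ATG", "---", "AAA"))
  r <- compute_kaks(aln2)
  expect_equal(r$n_codons, 2L)  # gapped column excluded

  expect_error(back_translate("MK", "MK", "ATGAGG", "ATGAAA"),
               "residue 2")
})

test_that("back_translate round-trips randomly translated pairs", {
  set.seed(9)
  for (i in 1:10) {
    cds <- random_cds(40)
    prot <- translate_cds(cds)
    aln <- back_translate(prot, prot, cds, cds)
    expect_equal(paste(aln$codons_a, collapse = ""), cds)
  }
})

test_that("compute_kaks reproduces the hand-computed leucine example", {
  a <- paste(rep("CTT", 10), collapse = "")
  b <- paste(c(rep("CTT", 9), "CTC"), collapse = "")
  r <- kaks_pair(a, b)
  expect_equal(r$S, 10)
  expect_equal(r$N, 20)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.1)
  expect_equal(r$Ks, -0.75 * log(1 - 0.4 / 3))
  expect_equal(round(r$Ks, 5), 0.10733)
  expect_equal(r$Ka, 0)
})

test_that("compute_kaks is symmetric and zero on identical sequences", {
  set.seed(13)
  cds_a <- random_cds(60)
  cds_b <- random_cds(60)
  # unrelated sequences can saturate the correction; symmetry must hold anyway
  ra <- suppressWarnings(kaks_pair(cds_a, cds_b))
  rb <- suppressWarnings(kaks_pair(cds_b, cds_a))
  expect_equal(ra$Ks, rb$Ks)
  expect_equal(ra$Ka, rb$Ka)
  same <- kaks_pair(cds_a, cds_a)
  expect_equal(same$Ks, 0)
  expect_equal(same$Ka, 0)
  expect_equal(same$selection, "undefined")
})

test_that("Jukes-Cantor correction behaves at its limits", {
  # small-p limit: relative error < 1% for p < 0.01
  p <- c(1e-4, 1e-3, 5e-3, 9e-3)
  expect_true(all(abs(jukes_cantor(p) - p) / p < 0.01))
  expect_warning(res <- jukes_cantor(0.8), "undefined")
  expect_true(is.na(res))
})

test_that("selection classification follows the Ka/Ks thresholds", {
  expect_equal(classify_selection(0.593), "purifying")
  expect_equal(classify_selection(1.483), "positive")
  expect_equal(classify_selection(1), "neutral")
  expect_equal(classify_selection(NA), "undefined")
})

test_that("divergence time is Ks/(2r) in Mya and linear in its arguments", {
  expect_equal(round(divergence_time(0.566), 2), 18.87)
  expect_equal(round(divergence_time(0.398), 2), 13.27)
  expect_equal(divergence_time(0), 0)
  set.seed(4)
  ks <- runif(10, 0, 1)
  expect_equal(divergence_time(2 * ks), 2 * divergence_time(ks))
  expect_equal(divergence_time(ks, rate = 3e-8), divergence_time(ks) / 2)
  expect_error(divergence_time(-0.1), "ks")
})

test_that("kaks_report produces one reported row per pair with CDS lookup", {
  set.seed(21)
  cds <- c(g1 = random_cds(50), g2 = random_cds(50))
  pairs <- data.frame(id_a = "g1", id_b = "g2", dup_type = "tandem")
  rep <- suppressWarnings(kaks_report(pairs, cds))
  expect_equal(names(rep), c("id_a", "id_b", "Ks", "Ka", "ratio",
                             "dup_type", "selection", "divergence_mya"))
  expect_error(kaks_report(data.frame(id_a = "g1", id_b = "gX"), cds), "gX")
})
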