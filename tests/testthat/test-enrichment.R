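# Region-set enrichment statistics and the age-related disease tests.

test_that("fold enrichment follows the 2x2 hit-rate ratio", {
  # 10/20 query hits vs 100/2000 background hits -> fold 10
  q <- bed("chr1", seq(0, 19) * 1000, seq(0, 19) * 1000 + 500)
  bg <- bed("chr1", seq(0, 1999) * 1000 + 100000,
            seq(0, 1999) * 1000 + 100500)
  feat <- rbind(bed("chr1", q$start[1:10], q$end[1:10]),
                bed("chr1", bg$start[1:100], bg$end[1:100]))
  fe <- fold_enrichment(q, bg, feat)
  expect_equal(fe$n_query_hits, 10)
  expect_equal(fe$n_background_hits, 100)
  expect_equal(fe$fold, 10)

  # identical query and background -> fold 1, chi-square p = 1
  fe2 <- fold_enrichment(bg, bg, feat)
  expect_equal(fe2$fold, 1)
  expect_equal(fe2$chi2_p, 1)
})

test_that("the chi-square matches the textbook Pearson statistic", {
  # table (50,50 / 100,900): compute by hand from observed vs expected
  tab <- rbind(c(50, 50), c(100, 900))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pearson <- sum((tab - E)^2 / E)
  q <- bed("chr1", seq_len(100) * 1000, seq_len(100) * 1000 + 500)
  bg <- bed("chr1", 10^6 + seq_len(1000) * 1000, 10^6 + seq_len(1000) * 1000 + 500)
  feat <- rbind(q[1:50, ], bg[1:100, ])
  fe <- fold_enrichment(q, bg, feat)
  expect_equal(fe$chi2_stat, pearson, tolerance = 1e-12)
  expect_equal(fe$chi2_p, pchisq(pearson, 1, lower.tail = FALSE))
})

test_that("fold enrichment is symmetric under query/background swap", {
  set.seed(6)
  qs <- sample(seq(0, 1e5, by = 500), 40)
  bs <- sample(seq(2e5, 6e5, by = 500), 300)
  q <- bed("chr1", qs, qs + 500); bg <- bed("chr1", bs, bs + 500)
  fs <- c(sample(qs, 15), sample(bs, 40))
  feat <- bed("chr1", fs, fs + 200)
  f1 <- fold_enrichment(q, bg, feat)
  f2 <- fold_enrichment(bg, q, feat)
  expect_equal(f1$fold, 1 / f2$fold)
  expect_equal(f1$chi2_stat, f2$chi2_stat, tolerance = 1e-10)
  # order of input regions is irrelevant
  f3 <- fold_enrichment(q[sample(nrow(q)), ], bg[sample(nrow(bg)), ], feat)
  expect_equal(f1$fold, f3$fold)
})

test_that("state composition counts multi-state regions in every state", {
  states <- rbind(bed("chr1", 0, 1000, "Enhancer"),
                  bed("chr1", 1000, 2000, "Repressed"))
  bg <- bed("chr1", seq(0, 1500, 500), seq(0, 1500, 500) + 500)
  inside <- bed("chr1", 100, 600)       # 500 bp fully in Enhancer
  straddle <- bed("chr1", 800, 1300)    # 200 bp Enhancer, 300 bp Repressed
  sc_in <- state_composition(inside, bg, states)
  expect_equal(sc_in$frac_query[sc_in$state == "Enhancer"], 1)
  expect_equal(sc_in$frac_query[sc_in$state == "Repressed"], 0)
  sc_st <- state_composition(straddle, bg, states)
  expect_equal(sc_st$frac_query, c(1, 1))
  sc_empty <- state_composition(inside[0, ], bg, states)
  expect_equal(sc_empty$frac_query, c(0, 0))
})

test_that("blood-DHS classification uses the >=50%-of-blood-tracks rule", {
  q <- bed("chr1", c(0, 10000), c(500, 10500))
  bg <- bed("chr1", seq(20, 40) * 1000, seq(20, 40) * 1000 + 500)
  mk <- function(hit1) if (hit1) bed("chr1", 0, 500) else bed("chr1", 90000, 90500)
  tracks <- c(lapply(1:11, function(i) mk(TRUE)),
              lapply(12:22, function(i) mk(FALSE)))
  names(tracks) <- sprintf("blood%02d", 1:22)
  dm <- dhs_multitissue(q, bg, tracks, blood_names = names(tracks))
  # region 1 hits 11 of 22 blood tracks: boundary counts as enriched
  expect_true(dm$blood_enriched[1])
  expect_false(dm$blood_enriched[2])
  expect_equal(dm$blood_hit_counts, c(11, 0))

  dm2 <- dhs_multitissue(q, bg, tracks[1:22][c(1:10, 12:22)],
                         blood_names = names(tracks)[c(1:10, 12:22)])
  # 10 of 21 blood tracks is below half
  expect_false(dm2$blood_enriched[1])
})

test_that("disease-class mapping deduplicates blocks and SNPs, not traits", {
  admrs <- data.frame(dmr_id = c("D1", "D2", "D3"),
                      block_id = c("B1", "B1", "B2"))
  snps <- data.frame(block_id = c("B1", "B1", "B1", "B2"),
                     rsid = c("rs1", "rs1", "rs1", "rs2"),
                     trait = c("t1", "t2", "t3", "t4"),
                     disease_class = c("cancer", "metabolic", "cancer",
                                       "renal"),
                     age_related = c(TRUE, TRUE, TRUE, FALSE))
  mp <- map_disease_classes(admrs, snps)
  expect_equal(mp$n_blocks, 2)
  expect_equal(mp$n_unique_snps, 2)
  expect_equal(mp$n_associations, 4)
  expect_equal(unname(mp$class_counts["cancer"]), 2L)
  expect_error(map_disease_classes(
    data.frame(dmr_id = "D9", block_id = "B99"), snps), "SNP-free")
})

test_that("the age-related disease Fisher test matches the printed design", {
  # reconstructed 2x2: 25 of 64 a-DMR blocks age-related, 723 of 2709 total
  ids <- sprintf("L%04d", 1:2709)
  age_ids <- ids[1:723]
  admr_ids <- c(ids[1:25], ids[724:762])
  fr <- age_disease_fisher(2709, age_ids, admr_ids)
  expect_equal(fr$n_age_related_admr, 25)
  expect_equal(fr$odds_ratio, 25 * 1947 / (39 * 698))
  expect_equal(fr$pct_age_related_all, 100 * 723 / 2709, tolerance = 1e-10)
  expect_lt(fr$fisher_p, 0.05)
  expect_true(fr$ci_low < fr$odds_ratio && fr$odds_ratio < fr$ci_high)

  # degenerate 1/1/1/1 table
  f2 <- age_disease_fisher(4, c("a", "b"), c("a", "c"))
  expect_equal(f2$odds_ratio, 1)
  expect_equal(f2$fisher_p, 1)

  # zero cell triggers the Haldane-corrected sample OR
  f3 <- age_disease_fisher(10, c("a", "b"), c("a", "b"))
  expect_true(f3$haldane)
  expect_true(is.finite(f3$odds_ratio) && f3$odds_ratio > 0)
})

test_that("the permutation null matches the hypergeometric oracle", {
  ids <- sprintf("L%03d", 1:200)
  age_ids <- ids[1:50]
  admr_ids <- c(ids[1:10], ids[51:60])  # observed overlap 10
  pr <- age_disease_permutation(200, age_ids, admr_ids, n_perm = 2000,
                                seed = 11)
  expect_equal(pr$observed, 10)
  exact <- phyper(9, 50, 150, 20, lower.tail = FALSE)
  expect_lt(abs(pr$empirical_p - exact),
            3 * sqrt(exact * (1 - exact) / 2000) + 1e-3)
  # permutation mean approximates the hypergeometric mean
  expect_lt(abs(pr$perm_mean - 20 * 50 / 200), 0.25)

  # no overlap observed -> empirical p = 1
  p0 <- age_disease_permutation(200, ids[1:50], ids[51:70], n_perm = 200,
                                seed = 2)
  expect_equal(p0$empirical_p, 1)
  expect_error(age_disease_permutation(200, ids[1:50], ids[51:70],
                                       n_perm = 0), "n_perm")
})
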