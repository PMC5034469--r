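# Synthetic study generator: determinism, genetic structure of the twin
# cohort, and recoverability of the planted effects.

test_that("the full simulation is reproducible from the seed", {
  s1 <- simulate_study(tiny_config(seed = 5))
  s2 <- simulate_study(tiny_config(seed = 5))
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$cohort$samples, s2$cohort$samples)
  expect_identical(s1$genome$gwas, s2$genome$gwas)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(tiny_config(seed = 6))
  expect_false(identical(s1$matrix, s3$matrix))
})

test_that("written simulation files are byte-identical across runs", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_study(tiny_config(seed = 5)), d1)
  write_simulation(simulate_study(tiny_config(seed = 5)), d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a hotspot-free map yields one block per chromosome", {
  g <- generate_genome(sim_config(seed = 2, hotspot_rate_per_mb = 0))
  b <- build_ld_blocks(g$genetic_map)
  expect_equal(nrow(b), length(g$chrom_sizes))
  expect_equal(unname(b$end - b$start), unname(as.numeric(g$chrom_sizes)))
})

test_that("mean block count per chromosome matches the Poisson-run oracle", {
  # Oracle: K hotspot tiles among N, exchangeably arranged, give
  # E[#low-runs | K] = (N-K)(K+1)/N; average over K ~ Poisson(lambda * L)
  # truncated at N.
  cfg <- sim_config(seed = 1, n_chromosomes = 1L, chrom_length = 1e5,
                    hotspot_rate_per_mb = 10, map_interval = 5000L)
  N <- cfg$chrom_length / cfg$map_interval
  lam <- cfg$hotspot_rate_per_mb * cfg$chrom_length / 1e6
  ks <- 0:N
  pk <- dpois(ks, lam); pk[N + 1] <- pk[N + 1] + ppois(N, lam,
                                                       lower.tail = FALSE)
  expected <- sum(pk * (N - ks) * (ks + 1) / N)
  counts <- vapply(1:200, function(s) {
    cfg$seed <- s
    nrow(build_ld_blocks(generate_genome(cfg)$genetic_map,
                         max_size = Inf))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05)
})

test_that("GWAS p-values straddle the 1e-7 catalogue threshold", {
  g <- generate_genome(sim_config(seed = 4))
  expect_true(any(g$gwas$p < 1e-7) && any(g$gwas$p >= 1e-7))
})

test_that("tiny chromosomes are rejected", {
  expect_error(sim_config(seed = 1, chrom_length = 1000),
               "chrom_length")
})

test_that("MZ co-twins share genotypes; DZ allelic correlation is ~1/2", {
  blocks <- data.frame(block_id = sprintf("B%04d", 1:5))
  cfg <- sim_config(seed = 8, n_families = 150L, mz_fraction = 1,
                    singleton_fraction = 0)
  co <- generate_cohort(cfg, blocks)
  fam <- split(rownames(co$genotype),
               sub("_.*", "", rownames(co$genotype)))
  disc <- vapply(fam, function(ids)
    sum(co$genotype[ids[1], ] != co$genotype[ids[2], ]), numeric(1))
  expect_true(all(disc == 0))
  expect_true(all(co$samples$zygosity == "MZ"))

  cfg0 <- sim_config(seed = 9, n_families = 400L, mz_fraction = 0,
                     singleton_fraction = 0)
  co0 <- generate_cohort(cfg0, blocks)
  ids <- rownames(co0$genotype)
  fam <- split(ids, sub("_.*", "", ids))
  g1 <- unlist(lapply(fam, function(x) co0$genotype[x[1], ]))
  g2 <- unlist(lapply(fam, function(x) co0$genotype[x[2], ]))
  expect_lt(abs(cor(g1, g2) - 0.5), 0.05)
  expect_true(all(co0$samples$zygosity == "DZ"))
})

test_that("longitudinal fraction controls repeat draws and shared ids", {
  blocks <- data.frame(block_id = "B0001")
  co <- generate_cohort(sim_config(seed = 3, longitudinal_fraction = 0),
                        blocks)
  expect_equal(anyDuplicated(co$samples$individual_id), 0)
  co2 <- generate_cohort(sim_config(seed = 3, longitudinal_fraction = 1),
                         blocks)
  tt <- table(co2$samples$individual_id)
  expect_true(all(tt == 2))
  second <- co2$samples[co2$samples$timepoint == 2, ]
  first <- co2$samples[match(second$individual_id,
                             co2$samples$individual_id), ]
  expect_true(all(second$age_at_draw > first$age_at_draw))
  # co-twins share age at the first draw
  p1 <- co2$samples[co2$samples$timepoint == 1 &
                      co2$samples$zygosity != "singleton", ]
  ages <- tapply(p1$age_at_draw, p1$pair_id, function(a) diff(range(a)))
  expect_true(all(ages == 0))
  # cell fractions are proportions
  fr <- co$samples[, c("lymphocyte", "monocyte", "neutrophil", "eosinophil")]
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)))
})

test_that("a noise-free null window equals its CpG-density baseline", {
  cfg <- tiny_config(seed = 5, noise_sd = 0, family_sd = 0, pair_sd = 0,
                     depth_sd = 0, smoking_sd = 0, batch_sd = 0,
                     zero_fraction = 0, zero_heavy_fraction = 0)
  sim <- simulate_study(cfg)
  nulls <- which(sim$truth$effect_class == "null")
  v <- sim$matrix[nulls, ]
  expect_true(all(apply(v, 1, function(x) diff(range(x)) == 0)))
  # baseline reflects CpG count: offset + scale * n_cpg
  w1 <- nulls[1]
  pos <- sim$genome$cpg$pos[sim$genome$cpg$chrom == sim$windows$chrom[w1]]
  ncpg <- sum(pos >= sim$windows$start[w1] & pos < sim$windows$end[w1])
  expect_equal(unname(v[1, 1]), cfg$baseline_offset + cfg$baseline_scale * ncpg)
})

test_that("regressing an age window on age recovers the planted slope", {
  # dropout zeros attenuate a raw-scale regression, so the clean oracle
  # check disables them; dropout behaviour is covered by the filter tests
  sim <- simulate_study(tiny_config(seed = 12, zero_fraction = 0,
                                    zero_heavy_fraction = 0))
  idx <- which(sim$truth$effect_class == "age")
  for (w in idx[1:5]) {
    fit <- lm(sim$matrix[w, ] ~ sim$cohort$samples$age_at_draw)
    est <- coef(summary(fit))[2, ]
    expect_lt(abs(est["Estimate"] - sim$truth$age_slope[w]),
              2 * est["Std. Error"] + 1e-12)
  }
})

test_that("cell windows track their driving blood trait beyond null noise", {
  sim <- simulate_study(tiny_config(seed = 13))
  s <- sim$cohort$samples
  pcor <- function(w, trait) {
    y <- resid(lm(sim$matrix[w, ] ~ s$age_at_draw))
    x <- resid(lm(s[[paste0("trait_", trait)]] ~ s$age_at_draw))
    abs(cor(y, x))
  }
  ci <- which(sim$truth$effect_class == "cell")
  ni <- which(sim$truth$effect_class == "null")[seq_along(ci)]
  pc_cell <- vapply(ci, function(w) pcor(w, sim$truth$cell_trait[w]),
                    numeric(1))
  pc_null <- vapply(seq_along(ni), function(i)
    pcor(ni[i], sim$truth$cell_trait[ci[i]]), numeric(1))
  expect_gt(median(pc_cell), median(pc_null))
  expect_gt(mean(pc_cell), 0.3)
})
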