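# Twin cohort, planted-truth table, and raw-RPM window matrix.
#
# Generative model per window value (raw RPM scale):
#   depth_s * max(0, baseline(CpG count)
#                    + age_slope * (age - mid(age_range))
#                    + geno_beta * allelic count
#                    + interaction_slope * (age - mid) * allelic count
#                    + cell_beta * blood trait (standardised)
#                    + smoking/batch shifts + family + pair + N(0, noise_sd))
# followed by zero-inflation. depth_s is lognormal with mean exactly 1 so
# planted slopes stay unbiased on the raw scale.

#' Generate the twin cohort with genotypes and covariates
#'
#' Families are twin pairs (MZ with probability `mz_fraction`, otherwise DZ)
#' or singletons. Co-twins share age at draw; MZ co-twins share the full
#' genotype vector while DZ co-twins draw alleles from the same simulated
#' parents (expected allelic correlation 1/2). A `longitudinal_fraction` of
#' individuals receive a second draw ~`long_gap_mean` years later under the
#' same individual/pair/family identifiers. Covariates: smoking (never/
#' former/current), batch, four leukocyte fractions (Dirichlet), and six
#' standardised blood-cell traits (CD4 T, CD8 T, T cell, NK, CD34+, B) that
#' load on the lymphocyte fraction except CD34+.
#'
#' @param config a [sim_config()].
#' @param blocks LD-block data frame (needs `block_id`); one
#'   haplotype-tagging SNP genotype is generated per block.
#' @return list with `samples` (one row per blood draw) and `genotype`
#'   (individuals x blocks allelic-count matrix, 0/1/2).
#' @export
generate_cohort <- function(config, blocks) {
  validate_sim_config(config)
  if (!nrow(blocks)) stop("blocks must be non-empty")
  set.seed(config$seed + 1L)
  nf <- config$n_families
  singleton <- runif(nf) < config$singleton_fraction
  zyg_pair <- ifelse(runif(nf) < config$mz_fraction, "MZ", "DZ")
  fam_age <- runif(nf, config$age_range[1], config$age_range[2])

  maf <- runif(nrow(blocks), 0.1, 0.5)
  ind <- list(); geno <- list()
  for (f in seq_len(nf)) {
    fam_id <- sprintf("F%04d", f)
    n_child <- if (singleton[f]) 1L else 2L
    zyg <- if (singleton[f]) "singleton" else zyg_pair[f]
    # parental allele pairs per block
    mo <- cbind(rbinom(nrow(blocks), 1, maf), rbinom(nrow(blocks), 1, maf))
    fa <- cbind(rbinom(nrow(blocks), 1, maf), rbinom(nrow(blocks), 1, maf))
    pick <- function() mo[cbind(seq_len(nrow(blocks)),
                                sample(1:2, nrow(blocks), TRUE))] +
      fa[cbind(seq_len(nrow(blocks)), sample(1:2, nrow(blocks), TRUE))]
    g1 <- pick()
    for (k in seq_len(n_child)) {
      iid <- sprintf("I%04d_%d", f, k)
      g <- if (zyg == "MZ") g1 else if (k == 1L) g1 else pick()
      geno[[iid]] <- g
      ind[[iid]] <- data.frame(
        individual_id = iid, family_id = fam_id,
        pair_id = if (zyg == "singleton") paste0("P", iid) else
          sprintf("P%04d", f),
        zygosity = zyg, age0 = fam_age[f],
        smoking = sample(c("never", "former", "current"), 1,
                         prob = c(0.5, 0.3, 0.2)),
        stringsAsFactors = FALSE)
    }
  }
  ind <- do.call(rbind, ind)
  genotype <- do.call(rbind, geno)
  colnames(genotype) <- blocks$block_id

  long <- runif(nrow(ind)) < config$longitudinal_fraction
  draws <- data.frame(ind, timepoint = 1L, age_at_draw = ind$age0)
  if (any(long))
    draws <- rbind(draws,
                   data.frame(ind[long, , drop = FALSE], timepoint = 2L,
                              age_at_draw = ind$age0[long] +
                                pmax(0.5, rnorm(sum(long),
                                                config$long_gap_mean,
                                                config$long_gap_sd))))
  draws$age0 <- NULL
  n <- nrow(draws)
  draws$sample_id <- sprintf("S%04d", seq_len(n))
  draws$batch <- paste0("b", sample.int(config$n_batches, n, replace = TRUE))

  # leukocyte fractions via Dirichlet(lymph, mono, neut, eos)
  alpha <- c(15, 4, 28, 1.5)
  gam <- matrix(rgamma(n * 4, shape = rep(alpha, each = n)), nrow = n)
  frac <- gam / rowSums(gam)
  draws$lymphocyte <- frac[, 1]; draws$monocyte <- frac[, 2]
  draws$neutrophil <- frac[, 3]; draws$eosinophil <- frac[, 4]

  lz <- as.numeric(scale(draws$lymphocyte))
  loads <- c(CD4T = 0.7, CD8T = 0.7, Tcell = 0.8, NK = 0.5, CD34 = 0, B = 0.6)
  for (tr in names(loads))
    draws[[paste0("trait_", tr)]] <-
      loads[tr] * lz + sqrt(1 - loads[tr]^2) * rnorm(n)

  rownames(draws) <- NULL
  cols <- c("sample_id", "individual_id", "family_id", "pair_id", "zygosity",
            "timepoint", "age_at_draw", "smoking", "batch",
            "lymphocyte", "monocyte", "neutrophil", "eosinophil",
            paste0("trait_", names(loads)))
  list(samples = draws[, cols], genotype = genotype)
}

#' Assign planted effect classes to analysis windows
#'
#' Each window receives exactly one class: `null`, `age` (planted slope,
#' random sign, placed in runs of 1-3 adjacent windows so merged regions
#' arise), `genotype` (obligatory genetic effect), `interaction`
#' (genotype-by-age slope plus a baseline age slope), or `cell` (driven by
#' one of the six blood-cell traits). A small fraction of null windows is
#' marked heavy zero-inflated to exercise the non-zero filter.
#'
#' @param config a [sim_config()].
#' @param windows window data frame from [windows_in_blocks()].
#' @return truth data frame: `window_id`, `effect_class`, `age_slope`,
#'   `geno_beta`, `interaction_slope`, `cell_trait`, `cell_beta`,
#'   `zero_heavy`.
#' @export
generate_truth <- function(config, windows) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(windows)
  need <- config$n_age_windows + config$n_geno_windows +
    config$n_interaction_windows + config$n_cell_windows
  if (need > n) stop("fewer windows (", n, ") than planted effects (", need, ")")
  truth <- data.frame(window_id = windows$window_id,
                      effect_class = "null", age_slope = 0, geno_beta = 0,
                      interaction_slope = 0, cell_trait = NA_character_,
                      cell_beta = 0, zero_heavy = FALSE,
                      stringsAsFactors = FALSE)
  avail <- rep(TRUE, n)

  # age windows in adjacent runs sharing a direction
  n_left <- config$n_age_windows
  while (n_left > 0) {
    anchor <- sample(which(avail), 1)
    len <- min(sample(1:3, 1), n_left)
    run <- anchor
    while (length(run) < len) {
      nxt <- run[length(run)] + 1L
      if (nxt > n || !avail[nxt] ||
          windows$block_id[nxt] != windows$block_id[anchor] ||
          windows$start[nxt] - windows$start[nxt - 1L] != config$window_slide)
        break
      run <- c(run, nxt)
    }
    sgn <- sample(c(-1, 1), 1)
    truth$effect_class[run] <- "age"
    truth$age_slope[run] <- sgn * runif(length(run),
                                        config$age_slope_range[1],
                                        config$age_slope_range[2])
    avail[run] <- FALSE
    n_left <- n_left - length(run)
  }

  pick <- function(k) {
    idx <- sample(which(avail), k)
    avail[idx] <<- FALSE
    idx
  }
  if (config$n_geno_windows > 0) {
    idx <- pick(config$n_geno_windows)
    truth$effect_class[idx] <- "genotype"
    truth$geno_beta[idx] <- sample(c(-1, 1), length(idx), TRUE) *
      runif(length(idx), config$geno_beta_range[1], config$geno_beta_range[2])
  }
  if (config$n_interaction_windows > 0) {
    idx <- pick(config$n_interaction_windows)
    truth$effect_class[idx] <- "interaction"
    sgn <- sample(c(-1, 1), length(idx), TRUE)
    truth$age_slope[idx] <- sgn * runif(length(idx),
                                        config$age_slope_range[1],
                                        config$age_slope_range[2])
    truth$interaction_slope[idx] <- -sgn *
      runif(length(idx), config$interaction_slope_range[1],
            config$interaction_slope_range[2])
  }
  if (config$n_cell_windows > 0) {
    idx <- pick(config$n_cell_windows)
    truth$effect_class[idx] <- "cell"
    truth$cell_trait[idx] <- sample(c("CD4T", "CD8T", "Tcell", "NK",
                                      "CD34", "B"), length(idx), TRUE)
    truth$cell_beta[idx] <- sample(c(-1, 1), length(idx), TRUE) *
      runif(length(idx), config$cell_beta_range[1], config$cell_beta_range[2])
  }
  n_heavy <- floor(config$zero_heavy_fraction * n)
  if (n_heavy > 0 && sum(avail) >= n_heavy)
    truth$zero_heavy[sample(which(avail), n_heavy)] <- TRUE
  truth
}

#' Generate the raw window methylation matrix
#'
#' See the generative model at the top of this file. Values are on a raw
#' RPM-like scale: a CpG-density baseline plus planted effects, nested
#' family/pair random intercepts, Gaussian noise, a mean-one lognormal
#' sample depth factor, flooring at zero and zero-inflation.
#'
#' @param config a [sim_config()].
#' @param cohort output of [generate_cohort()].
#' @param windows window data frame (coordinates + `block_id`).
#' @param truth output of [generate_truth()].
#' @param genome output of [generate_genome()] (CpG positions used for the
#'   baseline).
#' @return numeric matrix windows x samples (dimnames = window/sample ids).
#' @export
generate_methylome <- function(config, cohort, windows, truth, genome) {
  stopifnot(identical(truth$window_id, windows$window_id))
  set.seed(config$seed + 3L)
  s <- cohort$samples
  n <- nrow(s); W <- nrow(windows)

  ncpg <- integer(W)
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    pos <- genome$cpg$pos[genome$cpg$chrom == chr]
    ncpg[wi] <- findInterval(windows$end[wi] - 1L + 0.5, pos) -
      findInterval(windows$start[wi] - 0.5, pos)
  }
  baseline <- config$baseline_offset + config$baseline_scale * ncpg

  agec <- s$age_at_draw - mean(config$age_range)
  smoke_code <- match(s$smoking, c("never", "former", "current")) - 1L
  batch_idx <- as.integer(factor(s$batch))
  fam_idx <- match(s$family_id, unique(s$family_id))
  pair_idx <- match(s$pair_id, unique(s$pair_id))
  n_fam <- max(fam_idx); n_pair <- max(pair_idx)
  depth <- exp(rnorm(n, 0, config$depth_sd) - config$depth_sd^2 / 2)
  geno <- cohort$genotype[s$individual_id, , drop = FALSE]

  smoke_coef <- rnorm(W, 0, config$smoking_sd)
  batch_coef <- matrix(rnorm(W * config$n_batches, 0, config$batch_sd), W)

  mat <- matrix(0, W, n, dimnames = list(windows$window_id, s$sample_id))
  for (w in seq_len(W)) {
    # window-specific family/pair intercepts: epigenetic resemblance is a
    # per-locus realisation, not one shared shift across the methylome
    re <- rnorm(n_fam, 0, config$family_sd)[fam_idx] +
      rnorm(n_pair, 0, config$pair_sd)[pair_idx]
    core <- baseline[w] + re +
      smoke_coef[w] * smoke_code + batch_coef[w, batch_idx] +
      rnorm(n, 0, config$noise_sd)
    if (truth$age_slope[w] != 0) core <- core + truth$age_slope[w] * agec
    if (truth$geno_beta[w] != 0)
      core <- core + truth$geno_beta[w] * geno[, windows$block_id[w]]
    if (truth$interaction_slope[w] != 0)
      core <- core + truth$interaction_slope[w] * agec *
        geno[, windows$block_id[w]]
    if (!is.na(truth$cell_trait[w]))
      core <- core + truth$cell_beta[w] *
        s[[paste0("trait_", truth$cell_trait[w])]]
    v <- depth * pmax(0, core)
    p0 <- if (truth$zero_heavy[w]) config$zero_heavy_prob else
      config$zero_fraction
    if (p0 > 0) v[runif(n) < p0] <- 0
    mat[w, ] <- v
  }
  mat
}

#' Simulate a complete synthetic study
#'
#' One call producing every input of the downstream pipeline: genome and
#' annotations, LD blocks with GWAS SNPs, analysis windows (blacklist
#' filtered), planted truth, twin cohort with genotypes, and the raw window
#' matrix. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param rate_threshold,max_block_size LD-block construction parameters.
#' @return list: `config`, `genome`, `blocks`, `snps`, `genome_fraction`,
#'   `windows`, `truth`, `cohort`, `matrix`.
#' @export
simulate_study <- function(config = sim_config(), rate_threshold = 10,
                           max_block_size = 1e7) {
  genome <- generate_genome(config)
  raw_blocks <- build_ld_blocks(genome$genetic_map, rate_threshold,
                                max_block_size)
  asn <- assign_snps(raw_blocks, genome$gwas, 1e-7, genome$chrom_sizes)
  windows <- windows_in_blocks(asn$blocks, config$window_size,
                               config$window_slide, genome$blacklist)
  if (!nrow(windows)) stop("simulated genome produced no analysis windows")
  truth <- generate_truth(config, windows)
  cohort <- generate_cohort(config, asn$blocks)
  mat <- generate_methylome(config, cohort, windows, truth, genome)
  list(config = config, genome = genome, blocks = asn$blocks,
       snps = asn$snps, genome_fraction = asn$genome_fraction,
       windows = windows, truth = truth, cohort = cohort, matrix = mat)
}

#' Generate an independent replication cohort on the same genome and truth
#'
#' Draws a fresh cohort (new families, ages, covariates, genotypes) and a
#' fresh methylome under the identical planted truth, as input for the
#' replication-concordance stage. Uses a seed stream offset from the
#' discovery seed.
#'
#' @param sim output of [simulate_study()].
#' @param n_families optional replication cohort size (defaults to the
#'   discovery value).
#' @return list with `cohort` and `matrix`.
#' @export
simulate_replication <- function(sim, n_families = NULL) {
  cfg <- sim$config
  cfg$seed <- cfg$seed + 101L
  if (!is.null(n_families)) cfg$n_families <- n_families
  cohort <- generate_cohort(cfg, sim$blocks)
  mat <- generate_methylome(cfg, cohort, sim$windows, sim$truth, sim$genome)
  list(cohort = cohort, matrix = mat)
}

#' Write all simulation outputs as sorted plain-text files
#'
#' Windows as BED4 plus a windows x samples TSV matrix; cohort, genetic
#' map, GWAS SNPs and truth as TSV; annotation tracks as BED. All
#' coordinate files are sorted by (chrom, start) and carry a provenance
#' header line.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- sim$config$seed
  prm <- list(window_size = sim$config$window_size,
              window_slide = sim$config$window_slide)
  wb <- sim$windows; wb$name <- wb$window_id
  write_bed(wb, file.path(dir, "windows.bed"), seed, prm)
  m <- data.frame(window_id = rownames(sim$matrix), sim$matrix,
                  check.names = FALSE)
  write_tsv_hdr(m, file.path(dir, "window_matrix.tsv"), seed, prm)
  write_tsv_hdr(sim$cohort$samples, file.path(dir, "cohort.tsv"), seed)
  write_tsv_hdr(data.frame(individual_id = rownames(sim$cohort$genotype),
                           sim$cohort$genotype, check.names = FALSE),
                file.path(dir, "genotypes.tsv"), seed)
  write_tsv_hdr(sim$genome$genetic_map, file.path(dir, "genetic_map.tsv"),
                seed)
  write_tsv_hdr(sim$genome$gwas, file.path(dir, "gwas_snps.tsv"), seed)
  write_tsv_hdr(sim$truth, file.path(dir, "truth.tsv"), seed)
  bb <- sim$blocks; bb$name <- bb$block_id
  write_bed(bb, file.path(dir, "ld_blocks.bed"), seed)
  write_bed(sim$genome$blacklist, file.path(dir, "blacklist.bed"), seed)
  write_bed(sim$genome$cgi, file.path(dir, "cgi.bed"), seed)
  write_bed(sim$genome$states, file.path(dir, "chromatin_states.bed"), seed)
  dhs_dir <- file.path(dir, "dhs")
  dir.create(dhs_dir, showWarnings = FALSE)
  for (t in names(sim$genome$dhs))
    write_bed(sim$genome$dhs[[t]], file.path(dhs_dir, paste0(t, ".bed")), seed)
  manifest <- data.frame(name = names(sim$genome$dhs),
                         path = paste0("dhs/", names(sim$genome$dhs), ".bed"),
                         category = "DHS",
                         is_blood = names(sim$genome$dhs) %in%
                           sim$genome$blood_tissues)
  write_tsv_hdr(manifest, file.path(dir, "dhs_manifest.tsv"), seed)
  write_tsv_hdr(data.frame(chrom = sim$genome$cpg$chrom,
                           pos = sim$genome$cpg$pos),
                file.path(dir, "cpg_positions.tsv"), seed)
  jsonlite::write_json(
    list(genome_fraction = sim$genome_fraction,
         n_blacklisted = attr(sim$windows, "n_blacklisted")),
    file.path(dir, "sim_stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
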