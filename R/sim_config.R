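#' Simulation configuration for the synthetic twin study
#'
#' Defines the generative conditions for the synthetic cohort: a toy genome
#' with a recombination map (hotspots >= 10 cM/Mb delimiting LD blocks), a
#' GWAS SNP catalogue, twin families (MZ/DZ pairs and singletons, optional
#' longitudinal repeats), covariates (smoking, batch, leukocyte fractions,
#' six blood-cell traits), and a window x sample raw-RPM methylation matrix
#' with planted age, genotype, genotype-by-age and cell-composition effects.
#'
#' Defaults emulate the design of a blood MeDIP-seq twin age-EWAS at desk
#' scale: 500-bp windows with 250-bp slide, ages 19-82 years, roughly equal
#' MZ/DZ split, a fifth of individuals with a second draw ~2.2 years later.
#'
#' @param seed integer RNG seed; every output is deterministic given it.
#' @param n_chromosomes,chrom_length toy genome shape (bp per chromosome).
#' @param hotspot_rate_per_mb Poisson density of recombination hotspots.
#' @param map_interval genetic-map tile width, bp.
#' @param n_gwas_snps GWAS catalogue size (before p filtering).
#' @param n_families number of families; each is a twin pair unless selected
#'   as a singleton.
#' @param mz_fraction fraction of twin pairs that are monozygotic.
#' @param singleton_fraction fraction of families that are singletons.
#' @param longitudinal_fraction fraction of individuals with a second draw.
#' @param long_gap_mean,long_gap_sd years between longitudinal draws.
#' @param age_range sampling range for age at first draw (years).
#' @param window_size,window_slide window geometry, bp.
#' @param n_age_windows,age_slope_range count of age-effect windows and the
#'   magnitude range of the planted slope (raw units/year, random sign).
#' @param n_geno_windows,geno_beta_range genotype-driven ("obligatory")
#'   windows and effect per allele.
#' @param n_interaction_windows,interaction_slope_range genotype-by-age
#'   ("facilitated") windows; slope difference per allele per year.
#' @param n_cell_windows,cell_beta_range windows driven by a blood-cell
#'   trait (units per SD of the trait).
#' @param noise_sd residual SD of the raw window value.
#' @param family_sd,pair_sd SDs of the nested random intercepts.
#' @param smoking_sd,batch_sd SDs of per-window smoking/batch shifts.
#' @param n_batches number of processing batches.
#' @param depth_sd SD of the log sample-depth factor (lognormal, mean 1).
#' @param zero_fraction per-value probability of a zero (dropout).
#' @param zero_heavy_fraction fraction of windows with heavy zero-inflation.
#' @param zero_heavy_prob per-value zero probability in heavy windows.
#' @param baseline_scale raw units per CpG in the window baseline.
#' @param baseline_offset constant added to every window baseline.
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e5,
                       hotspot_rate_per_mb = 10,
                       map_interval = 5000L,
                       n_gwas_snps = 60L,
                       n_families = 80L,
                       mz_fraction = 0.5,
                       singleton_fraction = 0.15,
                       longitudinal_fraction = 0.2,
                       long_gap_mean = 2.18,
                       long_gap_sd = 0.6,
                       age_range = c(19, 82),
                       window_size = 500L,
                       window_slide = 250L,
                       n_age_windows = 30L,
                       age_slope_range = c(0.05, 0.09),
                       n_geno_windows = 20L,
                       geno_beta_range = c(0.5, 1.0),
                       n_interaction_windows = 10L,
                       interaction_slope_range = c(0.02, 0.04),
                       n_cell_windows = 20L,
                       cell_beta_range = c(0.8, 1.5),
                       noise_sd = 1,
                       family_sd = 0.3,
                       pair_sd = 0.3,
                       smoking_sd = 0.1,
                       batch_sd = 0.1,
                       n_batches = 3L,
                       depth_sd = 0.05,
                       zero_fraction = 0.005,
                       zero_heavy_fraction = 0.02,
                       zero_heavy_prob = 0.3,
                       baseline_scale = 0.25,
                       baseline_offset = 2) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(window_slide <= window_size, window_size > 0, window_slide > 0)
    if (chrom_length < 3 * window_size)
      stop("chrom_length must be at least 3 x window_size")
    for (f in c("mz_fraction", "singleton_fraction", "longitudinal_fraction",
                "zero_fraction", "zero_heavy_fraction", "zero_heavy_prob"))
      if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
    for (f in c("n_chromosomes", "n_families", "n_gwas_snps", "n_age_windows",
                "n_geno_windows", "n_interaction_windows", "n_cell_windows"))
      if (cfg[[f]] < 0) stop(f, " must be non-negative")
    stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
    stopifnot(noise_sd >= 0, family_sd >= 0, pair_sd >= 0, depth_sd >= 0)
  })
  invisible(cfg)
}

# Fifteen broad disease classes; the age_related subset marks adult-onset
# and degenerative phenotype classes used for the age-related enrichment.
disease_class_table <- function() {
  classes <- c("cancer", "neurological", "cardiovascular", "metabolic",
               "musculoskeletal", "autoimmune", "haematological",
               "serum_metabolite", "anthropometric", "respiratory",
               "renal", "ophthalmological", "dermatological",
               "psychiatric", "infection")
  data.frame(disease_class = classes,
             age_related = classes %in% c("cancer", "neurological",
                                          "cardiovascular", "metabolic",
                                          "musculoskeletal"),
             stringsAsFactors = FALSE)
}
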