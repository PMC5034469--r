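# End-to-end orchestration: simulate -> LD blocks -> windows -> normalise ->
# EWAS -> a-DMRs -> interaction -> cell-composition controls -> enrichment ->
# replication, with a JSON summary of the headline numbers. All stage
# outputs are plain text with provenance headers; everything is
# deterministic given the seed.

input_error <- function(...) {
  stop(structure(class = c("admr_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Pipeline configuration
#'
#' @param seed integer seed driving simulation and permutation streams.
#' @param outdir run directory (created).
#' @param mode `"all"` (simulate then analyse), `"simulate"` (write the
#'   synthetic study only), or `"run"` (analyse a previously simulated
#'   `outdir`).
#' @param sim a [sim_config()]; defaults to `sim_config(seed)`.
#' @param rate_threshold,max_block_size LD-block parameters (cM/Mb, bp).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param f fractional-overlap parameter for enrichment.
#' @param n_perm permutations for the age-related disease empirical p.
#' @param normalise normalisation method for the EWAS response.
#' @param replication run the replication-concordance stage.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "admr_run", mode = "all",
                            sim = NULL, rate_threshold = 10,
                            max_block_size = 1e7, alpha = 0.05, f = 0.1,
                            n_perm = 1000, normalise = "zscore",
                            replication = TRUE) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- list(seed = as.integer(seed), outdir = outdir, mode = mode,
              sim = sim, rate_threshold = rate_threshold,
              max_block_size = max_block_size, alpha = alpha, f = f,
              n_perm = n_perm, normalise = normalise,
              replication = replication)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a simulated study from a run directory
#'
#' Reads back every file written by [write_simulation()] plus the stored
#' simulation config, reconstructing the object returned by
#' [simulate_study()].
#'
#' @param dir the `sim/` directory of a pipeline run.
#' @return list with the [simulate_study()] layout.
#' @export
load_simulation <- function(dir) {
  need <- function(p) {
    fp <- file.path(dir, p)
    if (!file.exists(fp)) input_error("missing simulation file: ", fp)
    fp
  }
  cfg <- jsonlite::read_json(need("config.json"), simplifyVector = TRUE)
  cfg$age_range <- as.numeric(cfg$age_range)
  config <- do.call(sim_config, cfg)
  map <- read_tsv_hdr(need("genetic_map.tsv"))
  chrom_sizes <- tapply(map$end, map$chrom, max)
  mat_df <- read_tsv_hdr(need("window_matrix.tsv"))
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- mat_df$window_id
  wb <- read_bed(need("windows.bed"))
  windows <- data.frame(chrom = wb$chrom, start = wb$start, end = wb$end,
                        window_id = wb$name, stringsAsFactors = FALSE)
  bb <- read_bed(need("ld_blocks.bed"))
  blocks <- data.frame(chrom = bb$chrom, start = bb$start, end = bb$end,
                       block_id = bb$name, stringsAsFactors = FALSE)
  windows$block_id <- blocks$block_id[
    vapply(seq_len(nrow(windows)), function(i)
      which(blocks$chrom == windows$chrom[i] &
              blocks$start <= windows$start[i] &
              blocks$end >= windows$end[i])[1], integer(1))]
  geno_df <- read_tsv_hdr(need("genotypes.tsv"))
  genotype <- as.matrix(geno_df[, -1, drop = FALSE])
  rownames(genotype) <- geno_df$individual_id
  manifest <- read_tsv_hdr(need("dhs_manifest.tsv"))
  dhs <- lapply(setNames(manifest$path, manifest$name),
                function(p) read_bed(need(p)))
  stats <- jsonlite::read_json(need("sim_stats.json"), simplifyVector = TRUE)
  windows <- windows[, c("chrom", "start", "end", "window_id", "block_id")]
  attr(windows, "n_blacklisted") <- stats$n_blacklisted
  list(config = config,
       genome_fraction = stats$genome_fraction,
       genome = list(chrom_sizes = chrom_sizes, genetic_map = map,
                     gwas = read_tsv_hdr(need("gwas_snps.tsv")),
                     cpg = read_tsv_hdr(need("cpg_positions.tsv")),
                     blacklist = read_bed(need("blacklist.bed")),
                     cgi = read_bed(need("cgi.bed")),
                     states = read_bed(need("chromatin_states.bed")),
                     dhs = dhs,
                     blood_tissues = manifest$name[manifest$is_blood]),
       blocks = blocks,
       snps = {
         g <- read_tsv_hdr(need("gwas_snps.tsv"))
         asn <- assign_snps(blocks, g, 1e-7, chrom_sizes)
         asn$snps
       },
       windows = windows,
       truth = read_tsv_hdr(need("truth.tsv")),
       cohort = list(samples = read_tsv_hdr(need("cohort.tsv")),
                     genotype = genotype),
       matrix = mat)
}

#' Run the regional age-EWAS pipeline
#'
#' Executes the stages selected by `config$mode` and writes all outputs
#' under `config$outdir`: the simulated study (`sim/`), per-window EWAS and
#' interaction results, a-DMR BED and table, cell-composition control
#' report, enrichment tables, replication concordance, and `summary.json`
#' with the headline counts.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly (`NULL` in pure simulate mode).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  simdir <- file.path(config$outdir, "sim")
  seed <- config$seed

  if (config$mode %in% c("simulate", "all")) {
    message("[admrscan] simulating synthetic study (seed ", seed, ")")
    sim <- simulate_study(config$sim, config$rate_threshold,
                          config$max_block_size)
    write_simulation(sim, simdir)
    cfg_plain <- unclass(config$sim)
    jsonlite::write_json(cfg_plain, file.path(simdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    if (config$mode == "simulate") return(invisible(NULL))
  }
  if (!dir.exists(simdir))
    input_error("run mode requires a simulated study under ", simdir)
  sim <- load_simulation(simdir)

  message("[admrscan] EWAS: ", nrow(sim$windows), " windows, ",
          ncol(sim$matrix), " samples")
  ewas <- ewas_age(sim$matrix, sim$cohort, sim$windows,
                   normalise = config$normalise)
  thr <- bonferroni_threshold(attr(ewas, "n_tests"), config$alpha)
  write_tsv_hdr(ewas, file.path(config$outdir, "ewas_age.tsv"), seed,
                list(normalise = config$normalise, threshold = thr))

  admrs <- call_admrs(ewas, thr, sim$genome$cpg)
  admr_summary <- summarise_admrs(admrs)
  write_tsv_hdr(admrs, file.path(config$outdir, "admrs.tsv"), seed)
  if (nrow(admrs))
    write_admr_bed(admrs, file.path(config$outdir, "admrs.bed"), seed)
  admr_windows <- unlist(strsplit(admrs$window_ids, ","))

  message("[admrscan] interaction testing")
  inter <- ewas_interaction(sim$matrix, sim$cohort, sim$windows,
                            normalise = config$normalise)
  write_tsv_hdr(inter, file.path(config$outdir, "interaction.tsv"), seed)
  inter_hits <- inter$window_id[!is.na(inter$p) & inter$p < 0.05]
  admr_interacting <- if (nrow(admrs)) admrs$dmr_id[
    vapply(strsplit(admrs$window_ids, ","), function(ids)
      any(ids %in% inter_hits), logical(1))] else character()

  message("[admrscan] cell-composition controls")
  keep <- window_nonzero_filter(sim$matrix, 0.9)
  traits <- c("CD4T", "CD8T", "Tcell", "NK", "CD34", "B")
  km <- sim$matrix[keep, , drop = FALSE]
  blood_p <- vapply(traits, function(tr)
    mz_discordance_test(km, sim$cohort, tr)$p, numeric(nrow(km)))
  rownames(blood_p) <- keep
  cell_chk <- if (any(keep %in% admr_windows))
    admr_bloodtrait_enrichment(blood_p, admr_windows) else NULL
  # synthetic leukocyte-DMP analogue: midpoints of the planted cell windows
  cellw <- sim$windows[sim$windows$window_id %in%
                         sim$truth$window_id[sim$truth$effect_class == "cell"],
                       , drop = FALSE]
  ldmp <- data.frame(chrom = cellw$chrom,
                     pos = (cellw$start + cellw$end) %/% 2L)
  n_ldmp_overlap <- ldmp_overlap(admrs, ldmp)

  message("[admrscan] enrichment")
  background <- windows_in_blocks(sim$blocks, config$sim$window_size,
                                  config$sim$window_size,
                                  sim$genome$blacklist)
  enr_cgi <- fold_enrichment(admrs, background, sim$genome$cgi, config$f)
  states <- state_composition(admrs, background, sim$genome$states, config$f)
  dhs <- dhs_multitissue(admrs, background, sim$genome$dhs,
                         sim$genome$blood_tissues, config$f)
  write_tsv_hdr(states, file.path(config$outdir, "state_composition.tsv"),
                seed)
  write_tsv_hdr(dhs$per_tissue, file.path(config$outdir,
                                          "dhs_enrichment.tsv"), seed)
  dclass <- if (nrow(admrs)) map_disease_classes(admrs, sim$snps) else NULL
  age_ids <- unique(sim$snps$block_id[sim$snps$age_related])
  admr_blocks <- unique(admrs$block_id)
  fisher <- age_disease_fisher(nrow(sim$blocks), age_ids, admr_blocks)
  perm <- age_disease_permutation(nrow(sim$blocks), age_ids, admr_blocks,
                                  config$n_perm, seed + 7L)

  repl <- NULL
  if (config$replication) {
    message("[admrscan] replication")
    rp <- simulate_replication(sim)
    rewas <- ewas_age(rp$matrix, rp$cohort, sim$windows,
                      normalise = config$normalise, include = "batch")
    write_tsv_hdr(rewas, file.path(config$outdir, "ewas_replication.tsv"),
                  seed)
    disc_sig <- ewas[!is.na(ewas$p) & ewas$p < thr, , drop = FALSE]
    if (nrow(disc_sig)) {
      repl <- concordance(disc_sig, rewas, admrs, thr)
      repl$missing_windows <- NULL
    }
  }

  summary <- list(
    seed = seed,
    n_blocks = nrow(sim$blocks),
    genome_fraction = sim$genome_fraction,
    n_windows_tested = attr(ewas, "n_tests"),
    n_blacklisted = attr(sim$windows, "n_blacklisted"),
    bonferroni_threshold = thr,
    n_significant_windows = sum(!is.na(ewas$p) & ewas$p < thr),
    admrs = admr_summary,
    n_interaction_admrs = length(admr_interacting),
    cell_control = if (!is.null(cell_chk))
      cell_chk[c("frac_all", "frac_admr", "chi2_p")] else NULL,
    n_ldmp_overlap = n_ldmp_overlap,
    cgi_fold = enr_cgi$fold,
    disease = list(n_admr_blocks = fisher$n_admr_blocks,
                   pct_age_related_all = fisher$pct_age_related_all,
                   pct_age_related_admr = fisher$pct_age_related_admr,
                   odds_ratio = fisher$odds_ratio,
                   fisher_p = fisher$fisher_p,
                   empirical_p = perm$empirical_p),
    n_disease_associations = if (!is.null(dclass)) dclass$n_associations
      else 0L,
    replication = repl)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
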