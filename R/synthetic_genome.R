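# Toy genome: recombination map with hotspots, GWAS SNP catalogue,
# CpG positions, and annotation tracks (blacklist, CGI, chromatin states,
# per-tissue DHS). Everything is deterministic given config$seed.

#' Generate the toy genome and its annotations
#'
#' Builds, from a [sim_config()]:
#' a genetic map tiling each chromosome (baseline rate ~0.5 cM/Mb with
#' Poisson-placed hotspots at >= 10 cM/Mb, so LD blocks of varied size
#' arise); a GWAS SNP catalogue with p-values straddling 1e-7, traits drawn
#' from 15 broad disease classes and an age-related flag; CpG positions
#' (denser inside CpG islands); and BED annotation tracks: mappability
#' blacklist, CpG islands, a chromatin-state segmentation, and a set of
#' per-tissue DHS tracks of which a named subset is blood-related.
#'
#' @param config a [sim_config()].
#' @return list with `chrom_sizes`, `genetic_map`, `gwas`, `cpg`, `blacklist`,
#'   `cgi`, `states`, `dhs` (named list of BED data frames), `blood_tissues`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- setNames(rep(as.integer(config$chrom_length),
                              config$n_chromosomes), chroms)

  # genetic map: fixed tiles, low baseline rate, hotspot tiles >= 10 cM/Mb
  map <- do.call(rbind, lapply(chroms, function(chr) {
    starts <- seq(0L, config$chrom_length - 1L, by = config$map_interval)
    ends <- pmin(starts + config$map_interval, config$chrom_length)
    n <- length(starts)
    rate <- runif(n, 0.1, 2)
    n_hot <- rpois(1, config$hotspot_rate_per_mb * config$chrom_length / 1e6)
    if (n_hot > 0) {
      hot <- sample.int(n, min(n_hot, n))
      rate[hot] <- runif(length(hot), 12, 60)
    }
    data.frame(chrom = chr, start = starts, end = ends, rate = rate,
               stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL

  # CpG islands and CpG positions (10x density inside islands)
  cgi <- do.call(rbind, lapply(chroms, function(chr) {
    n_isl <- max(1L, rpois(1, config$chrom_length / 2e4))
    st <- sort(sample.int(config$chrom_length - 2000L, n_isl))
    data.frame(chrom = chr, start = st,
               end = pmin(st + sample(300:2000, n_isl, replace = TRUE),
                          config$chrom_length),
               stringsAsFactors = FALSE)
  }))
  cpg <- do.call(rbind, lapply(chroms, function(chr) {
    pos <- sort(sample.int(chrom_sizes[chr],
                           rpois(1, chrom_sizes[chr] / 100)))
    isl <- cgi[cgi$chrom == chr, , drop = FALSE]
    extra <- unlist(lapply(seq_len(nrow(isl)), function(i)
      sort(sample(seq(isl$start[i], isl$end[i] - 1L),
                  max(1L, rpois(1, (isl$end[i] - isl$start[i]) / 12)),
                  replace = FALSE))))
    data.frame(chrom = chr, pos = sort(unique(c(pos, extra))),
               stringsAsFactors = FALSE)
  }))
  rownames(cpg) <- NULL

  # mappability blacklist: a few short intervals per chromosome
  blacklist <- do.call(rbind, lapply(chroms, function(chr) {
    n_bl <- 2L
    st <- sort(sample.int(config$chrom_length - 3000L, n_bl))
    data.frame(chrom = chr, start = st,
               end = st + sample(500:2000, n_bl, replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  # chromatin-state segmentation: labelled segments tiling each chromosome
  state_labels <- c("TSS", "PF", "PoisedPromoter", "Enhancer", "WeakEnhancer",
                    "CTCF", "Transcribed", "Repressed")
  state_probs <- c(0.03, 0.04, 0.03, 0.08, 0.08, 0.04, 0.3, 0.4)
  states <- do.call(rbind, lapply(chroms, function(chr) {
    pos <- 0L
    seg <- list()
    while (pos < config$chrom_length) {
      len <- sample(500:5000, 1)
      lab <- sample(state_labels, 1, prob = state_probs)
      seg[[length(seg) + 1L]] <- data.frame(
        chrom = chr, start = pos,
        end = min(pos + len, config$chrom_length), name = lab,
        stringsAsFactors = FALSE)
      pos <- pos + len
    }
    do.call(rbind, seg)
  }))
  rownames(states) <- NULL

  # DHS tracks: 12 tissues, 4 blood-related
  tissues <- c("Tcell", "Bcell", "Monocyte", "NKcell", "Liver", "Lung",
               "Brain", "Kidney", "Muscle", "Skin", "Heart", "ESC")
  blood_tissues <- c("Tcell", "Bcell", "Monocyte", "NKcell")
  dhs <- lapply(setNames(tissues, tissues), function(t) {
    do.call(rbind, lapply(chroms, function(chr) {
      n_site <- rpois(1, config$chrom_length / 2500)
      st <- sort(sample.int(config$chrom_length - 500L, max(1L, n_site)))
      data.frame(chrom = chr, start = st,
                 end = st + sample(150:400, length(st), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  })

  # GWAS catalogue: p-values straddle 1e-7; 1-3 trait entries per SNP
  dct <- disease_class_table()
  n_snp <- config$n_gwas_snps
  snp_chrom <- sample(chroms, n_snp, replace = TRUE)
  snp_pos <- vapply(snp_chrom, function(chr) sample.int(chrom_sizes[chr], 1),
                    integer(1))
  logp <- c(runif(ceiling(n_snp * 0.75), 8, 30),
            runif(floor(n_snp * 0.25), 4, 6.9))[seq_len(n_snp)]
  gwas <- data.frame(chrom = snp_chrom, pos = as.integer(snp_pos),
                     rsid = sprintf("rs%05d", seq_len(n_snp)),
                     p = 10^(-logp), stringsAsFactors = FALSE)
  gwas <- gwas[rep(seq_len(n_snp), sample(1:3, n_snp, replace = TRUE)), ]
  gwas$disease_class <- sample(dct$disease_class, nrow(gwas), replace = TRUE)
  gwas$trait <- paste0(gwas$disease_class, "_trait_",
                       sample.int(40, nrow(gwas), replace = TRUE))
  gwas$age_related <- dct$age_related[match(gwas$disease_class,
                                            dct$disease_class)]
  gwas <- gwas[order(gwas$chrom, gwas$pos), ]
  rownames(gwas) <- NULL

  list(chrom_sizes = chrom_sizes, genetic_map = map, gwas = gwas, cpg = cpg,
       blacklist = blacklist, cgi = cgi, states = states, dhs = dhs,
       blood_tissues = blood_tissues)
}
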