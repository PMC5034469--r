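# Shared fixtures: small interval sets and a compact simulated study used
# by several files. Heavy simulations live in the files that need them.

bed <- function(chrom, start, end, name = NULL) {
  x <- data.frame(chrom = chrom, start = start, end = end,
                  stringsAsFactors = FALSE)
  if (!is.null(name)) x$name <- name
  x
}

# brute-force per-base overlap oracle for the fractional-overlap engine
overlap_oracle <- function(query, features, f) {
  vapply(seq_len(nrow(query)), function(i) {
    qb <- seq(query$start[i], query$end[i] - 1L)
    fb <- unlist(lapply(which(features$chrom == query$chrom[i]), function(j)
      seq(features$start[j], features$end[j] - 1L)))
    ov <- length(intersect(qb, unique(fb)))
    if (is.null(f)) ov >= 1 else ov >= f * length(qb)
  }, logical(1))
}

# compact study for fast module tests (~230 windows, ~70 samples)
tiny_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 3e4,
             n_families = 30L, n_age_windows = 10L, n_geno_windows = 5L,
             n_interaction_windows = 3L, n_cell_windows = 5L,
             n_gwas_snps = 30L, ...)
}

# minimal EWAS-result rows for DMR-calling tests
ewas_rows <- function(chrom, start, beta, p, size = 500L,
                      block_id = "B0001") {
  data.frame(window_id = sprintf("W%06d", seq_along(start)),
             chrom = chrom, start = start, end = start + size,
             block_id = block_id, beta_age = beta, p = p,
             stringsAsFactors = FALSE)
}
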