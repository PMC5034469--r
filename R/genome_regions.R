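# LD-block construction, window enumeration inside blocks, and the
# fractional-overlap engine (bedtools intersectBed -f semantics) used by
# every enrichment step. Coordinates throughout are BED-style: 0-based,
# half-open [start, end).

#' Build LD blocks from a genetic map
#'
#' An LD block is a maximal run of genetic-map intervals whose recombination
#' rate is below `rate_threshold` (cM/Mb), bounded by hotspot intervals
#' (rate >= threshold) or chromosome ends. Hotspot intervals themselves are
#' boundary regions and belong to no block. Blocks longer than `max_size`
#' are dropped.
#'
#' @param genetic_map data frame with columns `chrom`, `start`, `end`,
#'   `rate` (cM/Mb); intervals must tile each chromosome without overlap.
#' @param rate_threshold hotspot boundary rate, default 10 cM/Mb.
#' @param max_size maximum retained block size in bp, default 10 Mb.
#' @return data frame of blocks: `chrom`, `start`, `end`, `block_id`.
#' @export
build_ld_blocks <- function(genetic_map, rate_threshold = 10, max_size = 1e7) {
  check_intervals(genetic_map, "genetic map")
  stopifnot("rate" %in% names(genetic_map))
  out <- list()
  for (chr in unique(genetic_map$chrom)) {
    m <- genetic_map[genetic_map$chrom == chr, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)]))
      stop("overlapping genetic-map intervals on ", chr)
    low <- m$rate < rate_threshold
    r <- rle(low)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    keep <- which(r$values)
    if (length(keep))
      out[[chr]] <- data.frame(
        chrom = chr,
        start = m$start[idx_start[keep]],
        end   = m$end[idx_end[keep]],
        stringsAsFactors = FALSE)
  }
  blocks <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer())
  blocks <- blocks[blocks$end - blocks$start <= max_size, , drop = FALSE]
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks$block_id <- if (nrow(blocks)) sprintf("B%04d", seq_len(nrow(blocks))) else character()
  blocks
}

#' Assign GWAS catalogue SNPs to LD blocks
#'
#' Retains SNPs below the genome-wide `p_cut` that fall inside a block,
#' keeps blocks containing at least one such SNP ("GWAS LD blocks"),
#' collapses SNPs within the same block for the distinct-block count, and
#' reports the genome fraction covered by the retained blocks.
#'
#' @param blocks output of [build_ld_blocks()].
#' @param gwas_table data frame with `chrom`, `pos`, `rsid`, `p` and
#'   optionally `trait`, `disease_class`, `age_related`.
#' @param p_cut GWAS significance cut-off, default 1e-7 (SNPs with
#'   `p >= p_cut` are excluded).
#' @param chrom_sizes named vector of chromosome lengths (bp), used for the
#'   genome-fraction denominator.
#' @return list with `blocks` (retained blocks + `n_snps`), `snps` (retained
#'   SNPs + `block_id`), `n_distinct_blocks`, `genome_fraction`.
#' @export
assign_snps <- function(blocks, gwas_table, p_cut = 1e-7, chrom_sizes) {
  snps <- gwas_table[gwas_table$p < p_cut, , drop = FALSE]
  if (nrow(snps)) {
    bad <- snps$pos < 0 | snps$pos >= chrom_sizes[snps$chrom]
    if (any(is.na(bad)) || any(bad)) stop("SNP positions outside genome bounds")
  }
  snps$block_id <- rep(NA_character_, nrow(snps))
  for (i in seq_len(nrow(blocks))) {
    hit <- snps$chrom == blocks$chrom[i] &
      snps$pos >= blocks$start[i] & snps$pos < blocks$end[i]
    snps$block_id[hit] <- blocks$block_id[i]
  }
  snps <- snps[!is.na(snps$block_id), , drop = FALSE]
  rownames(snps) <- NULL
  keep <- blocks$block_id %in% snps$block_id
  gb <- blocks[keep, , drop = FALSE]
  gb$n_snps <- as.integer(table(factor(snps$block_id, levels = gb$block_id)))
  rownames(gb) <- NULL
  list(blocks = gb,
       snps = snps,
       n_distinct_blocks = nrow(gb),
       genome_fraction = if (sum(chrom_sizes) > 0)
         sum(gb$end - gb$start) / sum(chrom_sizes) else 0)
}

#' Enumerate analysis windows inside GWAS LD blocks
#'
#' Emits every `window_size`-bp window on the `window_slide` grid that lies
#' fully inside a block (containment, so the background set is exactly
#' "windows within LD blocks"). Windows overlapping a blacklist interval by
#' one or more bp are removed, mirroring whole-window blacklist exclusion.
#'
#' @param blocks data frame of blocks (`chrom`, `start`, `end`, `block_id`).
#' @param window_size window width in bp (default 500).
#' @param window_slide slide in bp (default 250); must not exceed the size.
#' @param blacklist optional BED-like data frame of regions to exclude.
#' @return data frame of windows (`chrom`, `start`, `end`, `window_id`,
#'   `block_id`) with attribute `n_blacklisted` (count removed).
#' @export
windows_in_blocks <- function(blocks, window_size = 500, window_slide = 250,
                              blacklist = NULL) {
  if (window_size <= 0) stop("window_size must be positive")
  stopifnot(window_slide <= window_size, window_slide > 0)
  res <- list()
  for (i in seq_len(nrow(blocks))) {
    s0 <- ceiling(blocks$start[i] / window_slide) * window_slide
    starts <- seq(s0, by = window_slide,
                  length.out = max(0, floor((blocks$end[i] - window_size - s0) /
                                              window_slide) + 1))
    starts <- starts[starts >= blocks$start[i] &
                       starts + window_size <= blocks$end[i]]
    if (length(starts))
      res[[i]] <- data.frame(chrom = blocks$chrom[i], start = starts,
                             end = starts + window_size,
                             block_id = blocks$block_id[i],
                             stringsAsFactors = FALSE)
  }
  w <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               block_id = character())
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  n_bl <- 0L
  if (!is.null(blacklist) && nrow(w) && nrow(blacklist)) {
    hit <- overlap_fraction(w, blacklist, min_fraction = NULL)  # any overlap
    n_bl <- sum(hit)
    w <- w[!hit, , drop = FALSE]
  }
  rownames(w) <- NULL
  w$window_id <- if (nrow(w)) sprintf("W%06d", seq_len(nrow(w))) else character()
  w <- w[, c("chrom", "start", "end", "window_id", "block_id")]
  attr(w, "n_blacklisted") <- n_bl
  w
}

#' Fractional interval overlap (intersectBed -f semantics)
#'
#' For each query interval, computes its overlap with the union of the
#' feature intervals and reports a hit when the overlap length is at least
#' `min_fraction` times the query length (boundary equality counts). With
#' `min_fraction = NULL`, any overlap of >= 1 bp is a hit.
#'
#' @param query,features BED-like data frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param min_fraction required overlap fraction in (0, 1], or `NULL` for
#'   any-overlap.
#' @return logical vector, one element per query row.
#' @export
overlap_fraction <- function(query, features, min_fraction = 0.1) {
  check_intervals(query, "query")
  check_intervals(features, "features")
  if (!is.null(min_fraction))
    stopifnot(min_fraction > 0, min_fraction <= 1)
  hit <- logical(nrow(query))
  if (!nrow(query) || !nrow(features)) return(hit)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    fs <- features[features$chrom == chr, , drop = FALSE]
    if (!nrow(fs)) next
    q <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    fr <- IRanges::reduce(IRanges::IRanges(fs$start + 1L, fs$end))
    ov <- IRanges::findOverlaps(q, fr)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(ov)], fr[S4Vectors::subjectHits(ov)]))
    tot <- tapply(w, S4Vectors::queryHits(ov), sum)
    idx <- as.integer(names(tot))
    if (is.null(min_fraction)) {
      hit[qi[idx]] <- tot >= 1
    } else {
      hit[qi[idx]] <- tot >= min_fraction * IRanges::width(q)[idx]
    }
  }
  hit
}
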