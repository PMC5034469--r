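# a-DMR calling: merge Bonferroni-significant windows that overlap or are
# book-ended (0-bp gap) and share the direction of the age effect;
# summaries; replication concordance; per-CpG probe validation.

#' Merge significant windows into a-DMRs
#'
#' Windows with `p < threshold` are sorted by coordinate; two significant
#' windows merge when they overlap or touch (gap = 0 bp) and their age
#' coefficients share sign. Adjacent windows of opposite sign are split
#' into separate regions, so every a-DMR is directional (hyper- or
#' hypomethylated with age).
#'
#' @param results data frame from [ewas_age()] (needs coordinates,
#'   `beta_age`, `p`, `block_id`).
#' @param threshold significance cut-off, from [bonferroni_threshold()].
#' @param cpg_positions optional data frame (`chrom`, `pos`) used to count
#'   CpGs inside each region.
#' @return data frame of a-DMRs: `chrom`, `start`, `end`, `dmr_id`,
#'   `direction` (`hyper`/`hypo`), `n_windows`, `peak_p`, `n_cpgs`,
#'   `block_id`, `window_ids` (comma-separated).
#' @export
call_admrs <- function(results, threshold, cpg_positions = NULL) {
  sig <- results[!is.na(results$p) & results$p < threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), dmr_id = character(),
                      direction = character(), n_windows = integer(),
                      peak_p = numeric(), n_cpgs = integer(),
                      block_id = character(), window_ids = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$start, sig$end), , drop = FALSE]
  sig$sign <- sign(sig$beta_age)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               direction = if (cur$sign > 0) "hyper" else "hypo",
               n_windows = cur$n, peak_p = cur$peak_p,
               block_id = cur$block_id,
               window_ids = paste(cur$ids, collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sig))) {
    r <- sig[i, ]
    if (!is.null(cur) && r$chrom == cur$chrom && r$start <= cur$end &&
        r$sign == cur$sign) {
      cur$end <- max(cur$end, r$end)
      cur$n <- cur$n + 1L
      cur$peak_p <- min(cur$peak_p, r$p)
      cur$ids <- c(cur$ids, r$window_id)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = r$chrom, start = r$start, end = r$end,
                  sign = r$sign, n = 1L, peak_p = r$p,
                  block_id = r$block_id, ids = r$window_id)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  admrs <- do.call(rbind, out)
  admrs$dmr_id <- sprintf("DMR%03d", seq_len(nrow(admrs)))
  admrs$n_cpgs <- NA_integer_
  if (!is.null(cpg_positions)) {
    for (i in seq_len(nrow(admrs))) {
      pos <- cpg_positions$pos[cpg_positions$chrom == admrs$chrom[i]]
      admrs$n_cpgs[i] <- sum(pos >= admrs$start[i] & pos < admrs$end[i])
    }
  }
  admrs[, c("chrom", "start", "end", "dmr_id", "direction", "n_windows",
            "peak_p", "n_cpgs", "block_id", "window_ids")]
}

#' Summarise a set of a-DMRs
#'
#' @param admrs data frame from [call_admrs()].
#' @return list: `n_admrs`, `n_hyper`, `n_hypo`, `frac_hyper`, `frac_hypo`
#'   (as fractions summing to 1), `mean_size_kb`, `total_cpgs`,
#'   `n_blocks` (distinct LD blocks hosting an a-DMR).
#' @export
summarise_admrs <- function(admrs) {
  n <- nrow(admrs)
  if (!n)
    return(list(n_admrs = 0L, n_hyper = 0L, n_hypo = 0L, frac_hyper = 0,
                frac_hypo = 0, mean_size_kb = 0, total_cpgs = 0L,
                n_blocks = 0L))
  nh <- sum(admrs$direction == "hyper")
  list(n_admrs = n, n_hyper = nh, n_hypo = n - nh,
       frac_hyper = nh / n, frac_hypo = (n - nh) / n,
       mean_size_kb = mean(admrs$end - admrs$start) / 1000,
       total_cpgs = if (all(is.na(admrs$n_cpgs))) NA_integer_ else
         sum(admrs$n_cpgs, na.rm = TRUE),
       n_blocks = length(unique(admrs$block_id)))
}

#' Replication concordance of significant windows and a-DMRs
#'
#' Window level: a discovery-significant window is same-direction when its
#' replication age coefficient shares sign; nominal when additionally
#' `p_rep < 0.05`; Bonferroni when additionally `p_rep < threshold`. DMR
#' level: an a-DMR qualifies in a tier when at least one of its windows
#' does. Windows absent from the replication results stay in the
#' denominator and are flagged.
#'
#' @param discovery [ewas_age()] rows for the discovery-significant windows
#'   only.
#' @param replication full [ewas_age()] result on the replication cohort.
#' @param admrs a-DMRs from [call_admrs()] on the discovery results.
#' @param threshold the discovery Bonferroni threshold.
#' @return list of window- and DMR-level counts and fractions (percent),
#'   plus `missing_windows`.
#' @export
concordance <- function(discovery, replication, admrs, threshold) {
  if (!nrow(discovery)) stop("empty discovery set")
  m <- match(discovery$window_id, replication$window_id)
  missing <- discovery$window_id[is.na(m)]
  rep_beta <- replication$beta_age[m]
  rep_p <- replication$p[m]
  same <- !is.na(rep_beta) & sign(rep_beta) == sign(discovery$beta_age)
  nominal <- same & !is.na(rep_p) & rep_p < 0.05
  bonf <- same & !is.na(rep_p) & rep_p < threshold
  n <- nrow(discovery)

  dmr_tier <- function(qualifies) {
    if (!nrow(admrs)) return(0L)
    ok <- vapply(strsplit(admrs$window_ids, ","), function(ids)
      any(qualifies[match(ids, discovery$window_id)], na.rm = TRUE),
      logical(1))
    sum(ok)
  }
  nd <- nrow(admrs)
  list(n_discovery_windows = n,
       n_same_direction = sum(same),
       n_nominal = sum(nominal),
       n_bonferroni = sum(bonf),
       pct_same_direction = 100 * sum(same) / n,
       pct_nominal = 100 * sum(nominal) / n,
       pct_bonferroni = 100 * sum(bonf) / n,
       n_admrs = nd,
       n_admr_same_direction = dmr_tier(same),
       n_admr_nominal = dmr_tier(nominal),
       n_admr_bonferroni = dmr_tier(bonf),
       missing_windows = missing)
}

#' Validate a-DMRs against per-CpG probe results
#'
#' A region is `validated_nominal` when at least one contained probe has
#' the same direction of effect and `p < 0.05`; `validated_strict` when
#' that probe reaches `p < strict_p` (default 1e-7); regions without any
#' contained probe are reported as `no_coverage`.
#'
#' @param admrs a-DMR data frame.
#' @param probe_results data frame: `chrom`, `pos`, `beta_age`, `p`.
#' @param strict_p strict validation threshold.
#' @return `admrs` with added columns `n_probes`, `status` (one of
#'   `no_coverage`, `not_validated`, `validated_nominal`,
#'   `validated_strict`).
#' @export
probe_validation <- function(admrs, probe_results, strict_p = 1e-7) {
  admrs$n_probes <- 0L
  admrs$status <- "no_coverage"
  dir_sign <- ifelse(admrs$direction == "hyper", 1, -1)
  for (i in seq_len(nrow(admrs))) {
    pr <- probe_results[probe_results$chrom == admrs$chrom[i] &
                          probe_results$pos >= admrs$start[i] &
                          probe_results$pos < admrs$end[i], , drop = FALSE]
    admrs$n_probes[i] <- nrow(pr)
    if (!nrow(pr)) next
    samedir <- sign(pr$beta_age) == dir_sign[i]
    if (any(samedir & pr$p < strict_p)) admrs$status[i] <- "validated_strict"
    else if (any(samedir & pr$p < 0.05))
      admrs$status[i] <- "validated_nominal"
    else admrs$status[i] <- "not_validated"
  }
  admrs
}

#' Write a-DMRs as BED6 (name = direction, score = -log10 peak p)
#' @param admrs a-DMR data frame.
#' @param path output path.
#' @param seed,params provenance header fields.
#' @return `path`, invisibly.
#' @export
write_admr_bed <- function(admrs, path, seed = NA, params = list()) {
  x <- data.frame(chrom = admrs$chrom, start = admrs$start, end = admrs$end,
                  name = admrs$direction,
                  score = round(-log10(pmax(admrs$peak_p, 1e-300)), 2),
                  strand = ".")
  write_bed(x, path, seed, params)
}
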