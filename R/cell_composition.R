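# Cell-composition negative controls: the >=90% non-zero window filter,
# the monozygotic-discordant blood-cell EWAS (residualise -> rank inverse
# normal -> paired one-sided t), the a-DMR vs background chi-square
# comparison, and the leukocyte-DMP overlap check.

#' Filter windows by fraction of samples with non-zero signal
#'
#' @param mat raw windows x samples matrix.
#' @param min_fraction minimum fraction of samples with value > 0
#'   (boundary counts), default 0.9.
#' @return character vector of retained window ids.
#' @export
window_nonzero_filter <- function(mat, min_fraction = 0.9) {
  frac <- rowMeans(mat > 0)
  rownames(mat)[frac >= min_fraction]
}

rank_inverse_normal <- function(x, k = 3 / 8) {
  qnorm((rank(x, ties.method = "average") - k) / (length(x) + 1 - 2 * k))
}

#' MZ-discordant blood-cell EWAS
#'
#' For one blood-cell trait: MZ pairs are ordered into trait-high and
#' trait-low co-twins (pairs with zero discordance are dropped). Per
#' window, raw methylation is regressed on smoking, the four leukocyte
#' fractions, age at draw and batch; the residuals are rank
#' inverse-normalised (Blom offset 3/8) and the per-pair high-minus-low
#' differences are tested by a one-sided one-sample t-test (mean > 0).
#' Only the first draw of each individual is used.
#'
#' @param mat raw windows x samples matrix (apply
#'   [window_nonzero_filter()] first).
#' @param cohort cohort list (`samples` with `trait_*` columns).
#' @param trait one of `"CD4T"`, `"CD8T"`, `"Tcell"`, `"NK"`, `"CD34"`,
#'   `"B"`.
#' @param min_pairs minimum usable MZ pairs, default 3.
#' @param adjust regress out smoking, leukocyte fractions, age and batch
#'   before rank-normalising (the standard procedure). With `adjust =
#'   FALSE` only the intercept is removed, which makes the p-value exactly
#'   invariant to monotone transforms of the raw values.
#' @return data frame: `window_id`, `t`, `p` (one-sided), `n_pairs`.
#' @export
mz_discordance_test <- function(mat, cohort, trait, min_pairs = 3,
                                adjust = TRUE) {
  s <- cohort$samples
  s <- s[s$timepoint == 1, , drop = FALSE]
  s <- s[s$zygosity == "MZ", , drop = FALSE]
  tv <- s[[paste0("trait_", trait)]]
  if (is.null(tv)) stop("unknown trait: ", trait)
  pairs <- split(seq_len(nrow(s)), s$pair_id)
  pairs <- pairs[vapply(pairs, length, 1L) == 2]
  pairs <- pairs[vapply(pairs, function(ix) tv[ix[1]] != tv[ix[2]],
                        logical(1))]
  if (length(pairs) < min_pairs)
    stop("need at least ", min_pairs, " MZ pairs with trait discordance")
  hi <- vapply(pairs, function(ix) ix[which.max(tv[ix])], integer(1))
  lo <- vapply(pairs, function(ix) ix[which.min(tv[ix])], integer(1))

  X <- if (adjust)
    model.matrix(~ smoking + lymphocyte + monocyte + neutrophil +
                   eosinophil + age_at_draw + batch,
                 data.frame(smoking = factor(s$smoking),
                            batch = factor(s$batch),
                            s[, c("lymphocyte", "monocyte", "neutrophil",
                                  "eosinophil", "age_at_draw")]))
  else matrix(1, nrow(s), 1)
  sm <- mat[, s$sample_id, drop = FALSE]
  qr_x <- qr(X)
  out <- data.frame(window_id = rownames(sm), t = NA_real_, p = NA_real_,
                    n_pairs = length(pairs), stringsAsFactors = FALSE)
  for (w in seq_len(nrow(sm))) {
    res <- qr.resid(qr_x, sm[w, ])
    if (sd(res) < 1e-10) {  # constant window: no discordance information
      out$t[w] <- 0; out$p[w] <- 0.5
      next
    }
    rn <- rank_inverse_normal(res)
    d <- rn[hi] - rn[lo]
    if (sd(d) == 0) {
      out$t[w] <- 0; out$p[w] <- 0.5
    } else {
      tt <- t.test(d, alternative = "greater")
      out$t[w] <- unname(tt$statistic); out$p[w] <- tt$p.value
    }
  }
  out
}

#' Blood-trait signal in a-DMR windows versus background
#'
#' A window carries blood-cell signal when its minimum p over the six
#' traits is below 0.05 (no multiplicity adjustment, matching the
#' 5%-expectation framing). Compares the fraction of such windows inside
#' the a-DMR set against all other windows by a 2x2 chi-square test
#' (continuity corrected).
#'
#' @param blood_pvals windows x traits matrix (or data frame) of one-sided
#'   p-values, rownames = window ids.
#' @param admr_window_ids ids of windows belonging to called a-DMRs.
#' @return list: `frac_all`, `frac_admr` (percent), counts, `chi2_stat`,
#'   `chi2_p`.
#' @export
admr_bloodtrait_enrichment <- function(blood_pvals, admr_window_ids) {
  bp <- as.matrix(blood_pvals)
  in_admr <- rownames(bp) %in% admr_window_ids
  if (!any(in_admr)) stop("no a-DMR windows present in blood_pvals")
  hit <- apply(bp, 1, min, na.rm = TRUE) < 0.05
  tab <- rbind(admr = c(sum(hit & in_admr), sum(!hit & in_admr)),
               other = c(sum(hit & !in_admr), sum(!hit & !in_admr)))
  ct <- suppressWarnings(chisq.test(tab))
  list(frac_all = 100 * mean(hit),
       frac_admr = 100 * mean(hit[in_admr]),
       frac_background = 100 * mean(hit[!in_admr]),
       n_admr = sum(in_admr), n_windows = nrow(bp),
       chi2_stat = unname(ct$statistic), chi2_p = ct$p.value)
}

#' Count a-DMRs containing leukocyte-DMP positions
#'
#' Containment against `[start, end)`: a position equal to the end
#' coordinate is outside.
#'
#' @param admrs a-DMR data frame.
#' @param ldmp_positions data frame (`chrom`, `pos`) of 1-bp sites.
#' @return integer count of a-DMRs containing at least one position.
#' @export
ldmp_overlap <- function(admrs, ldmp_positions) {
  if (!nrow(admrs) || !nrow(ldmp_positions)) return(0L)
  n <- 0L
  for (i in seq_len(nrow(admrs))) {
    p <- ldmp_positions$pos[ldmp_positions$chrom == admrs$chrom[i]]
    if (any(p >= admrs$start[i] & p < admrs$end[i])) n <- n + 1L
  }
  n
}
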