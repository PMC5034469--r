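# Region-set enrichment against LD-block background windows: fold
# enrichment with Pearson chi-square, chromatin-state composition,
# per-tissue DHS log2 folds with blood classification, disease-class
# mapping, and the age-related disease Fisher + permutation tests.

#' Fold enrichment of a query region set for a feature track
#'
#' Hit status uses [overlap_fraction()] with fraction `f` (the moderate
#' -f 0.1 convention). The background should be the non-overlapping
#' LD-block windows, never the whole genome. Fold =
#' (query hit rate) / (background hit rate); chi-square is Pearson on the
#' 2x2 hit table, without continuity correction by default.
#'
#' @param query_regions,background_windows,feature_track BED-like data
#'   frames.
#' @param f overlap fraction, default 0.1.
#' @param correct apply Yates continuity correction, default FALSE.
#' @return list: `n_query_hits`, `n_query`, `n_background_hits`,
#'   `n_background`, `fold`, `chi2_stat`, `chi2_p`.
#' @export
fold_enrichment <- function(query_regions, background_windows, feature_track,
                            f = 0.1, correct = FALSE) {
  qh <- sum(overlap_fraction(query_regions, feature_track, f))
  bh <- sum(overlap_fraction(background_windows, feature_track, f))
  nq <- nrow(query_regions); nb <- nrow(background_windows)
  fold <- if (bh > 0 && nq > 0) (qh / nq) / (bh / nb) else NA_real_
  tab <- rbind(c(qh, nq - qh), c(bh, nb - bh))
  ct <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    suppressWarnings(chisq.test(tab, correct = correct)) else
      list(statistic = c(X = 0), p.value = 1)
  list(n_query_hits = qh, n_query = nq, n_background_hits = bh,
       n_background = nb, fold = fold,
       chi2_stat = unname(ct$statistic), chi2_p = ct$p.value)
}

#' Chromatin-state composition of a query set versus background
#'
#' A region counts toward a state when it hits that state's intervals
#' under the fractional-overlap rule; a region straddling several states
#' counts toward each, so per-state fractions need not sum to 1.
#'
#' @param query_regions,background_windows BED-like data frames.
#' @param states BED data frame with a `name` column of state labels.
#' @param f overlap fraction, default 0.1.
#' @return data frame per state: query/background fractions, fold,
#'   chi-square statistic and p.
#' @export
state_composition <- function(query_regions, background_windows, states,
                              f = 0.1) {
  labs <- sort(unique(states$name))
  rows <- lapply(labs, function(lab) {
    fe <- fold_enrichment(query_regions, background_windows,
                          states[states$name == lab, , drop = FALSE], f)
    data.frame(state = lab,
               frac_query = if (fe$n_query) fe$n_query_hits / fe$n_query else 0,
               frac_background = if (fe$n_background)
                 fe$n_background_hits / fe$n_background else 0,
               fold = fe$fold, chi2_stat = fe$chi2_stat, chi2_p = fe$chi2_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multi-tissue DHS enrichment and per-region blood classification
#'
#' Per DHS track: fold enrichment (log2 reported) of the query against the
#' background. Per query region: blood-enriched when it hits at least 50%
#' of the blood-related tracks.
#'
#' @param query_regions,background_windows BED-like data frames.
#' @param dhs_tracks named list of BED data frames (one per tissue).
#' @param blood_names names of the blood-related tracks (subset of
#'   `names(dhs_tracks)`).
#' @param f overlap fraction, default 0.1.
#' @return list: `per_tissue` data frame (tissue, is_blood, fold,
#'   log2_fold, chi2_p) and `blood_enriched` logical per query region
#'   (with `n_blood_hits` attribute matrix omitted; counts in
#'   `blood_hit_counts`).
#' @export
dhs_multitissue <- function(query_regions, background_windows, dhs_tracks,
                            blood_names = character(), f = 0.1) {
  stopifnot(all(blood_names %in% names(dhs_tracks)))
  per <- do.call(rbind, lapply(names(dhs_tracks), function(t) {
    fe <- fold_enrichment(query_regions, background_windows,
                          dhs_tracks[[t]], f)
    data.frame(tissue = t, is_blood = t %in% blood_names, fold = fe$fold,
               log2_fold = log2(fe$fold),
               n_query_hits = fe$n_query_hits,
               n_background_hits = fe$n_background_hits,
               chi2_stat = fe$chi2_stat, chi2_p = fe$chi2_p,
               stringsAsFactors = FALSE)
  }))
  hits <- vapply(blood_names, function(t)
    overlap_fraction(query_regions, dhs_tracks[[t]], f),
    logical(nrow(query_regions)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(query_regions))
  counts <- if (length(blood_names)) rowSums(hits) else
    rep(0L, nrow(query_regions))
  list(per_tissue = per,
       blood_hit_counts = counts,
       blood_enriched = counts >= 0.5 * length(blood_names) &
         length(blood_names) > 0)
}

#' Map a-DMRs to the diseases and traits of their LD blocks
#'
#' DMR -> enclosing GWAS LD block -> the block's retained SNPs -> trait
#' associations. SNPs are deduplicated by rsid; trait associations keep
#' multiplicity (one SNP can carry several co-associations).
#'
#' @param admrs a-DMR data frame (needs `block_id`).
#' @param snps SNP data frame from [assign_snps()] (`rsid`, `block_id`,
#'   `trait`, `disease_class`, `age_related`).
#' @return list: `table` (per-DMR trait rows), `n_blocks`,
#'   `n_unique_snps`, `n_associations`, `class_counts` (named vector).
#' @export
map_disease_classes <- function(admrs, snps) {
  if (any(!admrs$block_id %in% snps$block_id))
    stop("a-DMR in a SNP-free block: blocks must be retained only with SNPs")
  tab <- merge(admrs[, c("dmr_id", "block_id")], snps, by = "block_id")
  blocks <- unique(admrs$block_id)
  sub <- snps[snps$block_id %in% blocks, , drop = FALSE]
  list(table = tab,
       n_blocks = length(blocks),
       n_unique_snps = length(unique(sub$rsid)),
       n_associations = nrow(sub),
       class_counts = sort(table(sub$disease_class), decreasing = TRUE))
}

#' Fisher test for age-related disease enrichment of a-DMR blocks
#'
#' 2x2 table of GWAS LD blocks: hosts an a-DMR (yes/no) x flagged
#' age-related (yes/no). Reports the sample (cross-product) odds ratio
#' with Haldane 0.5 correction when a cell is zero, plus the exact-test
#' conditional-MLE OR, two-sided p and CI.
#'
#' @param n_total total number of GWAS LD blocks.
#' @param age_related_ids block ids flagged age-related.
#' @param admr_block_ids block ids hosting at least one a-DMR.
#' @param all_block_ids optional full id vector (defaults to the union,
#'   padded to `n_total`).
#' @return list: counts, `odds_ratio` (sample), `or_conditional`,
#'   `fisher_p`, `ci_low`, `ci_high`, `haldane` flag.
#' @export
age_disease_fisher <- function(n_total, age_related_ids, admr_block_ids,
                               all_block_ids = NULL) {
  a <- length(intersect(admr_block_ids, age_related_ids))
  b <- length(setdiff(admr_block_ids, age_related_ids))
  c_ <- length(setdiff(age_related_ids, admr_block_ids))
  d <- n_total - a - b - c_
  if (d < 0) stop("inconsistent counts: n_total too small")
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  ft <- fisher.test(tab)
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  list(n_admr_blocks = a + b, n_age_related = a + c_, n_total = n_total,
       n_age_related_admr = a,
       pct_age_related_all = 100 * (a + c_) / n_total,
       pct_age_related_admr = if (a + b > 0) 100 * a / (a + b) else NA_real_,
       odds_ratio = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]),
       or_conditional = unname(ft$estimate),
       fisher_p = ft$p.value,
       ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
       haldane = haldane)
}

#' Permutation empirical p for age-related disease enrichment
#'
#' Each permutation draws `|age_related_ids|` block ids uniformly without
#' replacement from the `n_total` blocks; the statistic is the overlap
#' with the a-DMR block set. The empirical p is
#' `(1 + #{perm >= observed}) / (n_perm + 1)` (add-one smoothing, so the
#' smallest attainable value is `1/(n_perm+1)`). Converges to the exact
#' hypergeometric upper tail.
#'
#' @param n_total total number of GWAS LD blocks.
#' @param age_related_ids age-related block ids.
#' @param admr_block_ids a-DMR block ids.
#' @param n_perm number of permutations, default 1000.
#' @param seed RNG seed.
#' @return list: `observed`, `empirical_p`, `n_perm`, `perm_mean`,
#'   `exact_p` (hypergeometric upper tail).
#' @export
age_disease_permutation <- function(n_total, age_related_ids, admr_block_ids,
                                    n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  k <- length(age_related_ids)
  stopifnot(k <= n_total)
  ids <- unique(c(age_related_ids, admr_block_ids))
  if (length(ids) < n_total)
    ids <- c(ids, paste0("pad", seq_len(n_total - length(ids))))
  observed <- length(intersect(age_related_ids, admr_block_ids))
  set.seed(seed)
  stat <- vapply(seq_len(n_perm), function(i)
    length(intersect(sample(ids, k), admr_block_ids)), integer(1))
  list(observed = observed,
       empirical_p = (1 + sum(stat >= observed)) / (n_perm + 1),
       n_perm = n_perm,
       perm_mean = mean(stat),
       exact_p = phyper(observed - 1, k, n_total - k,
                        length(admr_block_ids), lower.tail = FALSE))
}
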