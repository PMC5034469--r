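# Per-window age EWAS: normalisation, ML linear mixed models with nested
# family/pair random intercepts (lme4), likelihood-ratio tests for the age
# term and the age x genotype interaction, Bonferroni control.
#
# Models are fit by maximum likelihood (REML = FALSE) because the LRT
# compares models differing in fixed effects. Windows within an LD block
# share the identical design, so the model is fit once per block and
# refitted per window response (lme4::refit), which is exact and fast.

lmm_control <- function(maxit = 200) {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.conv.singular = "ignore",
                    optCtrl = list(maxfun = maxit * 100))
}

#' Normalise a window methylation matrix
#'
#' `zscore` centres and scales each window to mean 0, SD 1 across samples
#' (the default, matching per-probe standardisation in array practice);
#' `inverse_normal` maps each window to rank-based normal quantiles (Blom
#' offset 3/8, ties averaged), which is invariant to any monotone transform
#' of the raw values; `none` passes raw values through. Windows with zero
#' variance are emitted as all-zero and flagged for exclusion from
#' modelling.
#'
#' @param mat windows x samples numeric matrix.
#' @param method one of `"zscore"`, `"inverse_normal"`, `"none"`.
#' @return matrix of the same shape with attribute `flagged` — character
#'   vector of zero-variance window ids.
#' @export
normalise_windows <- function(mat,
                              method = c("zscore", "inverse_normal", "none")) {
  method <- match.arg(method)
  sds <- apply(mat, 1, sd)
  flagged <- rownames(mat)[is.na(sds) | sds == 0]
  out <- switch(method,
    none = mat,
    zscore = {
      m <- rowMeans(mat)
      s <- ifelse(sds > 0, sds, 1)
      (mat - m) / s
    },
    inverse_normal = {
      n <- ncol(mat)
      t(apply(mat, 1, function(x)
        qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))))
    })
  if (length(flagged) && method != "none") out[flagged, ] <- 0
  dimnames(out) <- dimnames(mat)
  attr(out, "flagged") <- flagged
  out
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_tests number of windows tested (failed fits included).
#' @param alpha family-wise error rate, default 0.05.
#' @return per-test p-value threshold `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(2708462)  # 1.85e-08 at 3 s.f.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Fit one linear mixed model by maximum likelihood
#'
#' Thin wrapper over [lme4::lmer()] with the package's conventions: ML
#' fitting, random intercepts listed by grouping column, aliased fixed
#' effects dropped (with a message from lme4), variance components
#' constrained non-negative (boundary fits allowed).
#'
#' @param y response vector.
#' @param data data frame of covariates (must contain the grouping columns).
#' @param fixed right-hand-side formula of fixed effects, e.g. `~ age + batch`.
#' @param random character vector of grouping columns for random intercepts.
#' @param maxit optimiser iteration budget.
#' @return list: `fit` (merMod), `beta`, `se` (named vectors), `ll`
#'   (ML log-likelihood), `varcomp` (named: groups + residual),
#'   `converged` logical.
#' @export
fit_lmm <- function(y, data, fixed, random = c("family_id", "pair_id"),
                    maxit = 200) {
  if (length(unique(data$family_id)) < 2)
    stop("need at least 2 families")
  rhs <- paste(c(deparse(fixed[[2]]),
                 sprintf("(1 | %s)", random)), collapse = " + ")
  fml <- as.formula(paste("y ~", rhs))
  data$y <- y
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = FALSE, control = lmm_control(maxit))))
  summarise_lmm_fit(fit)
}

summarise_lmm_fit <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, vc$grp)
  conv <- length(fit@optinfo$conv$lme4) == 0 ||
    is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code >= 0
  beta <- lme4::fixef(fit)
  list(fit = fit,
       beta = beta,
       se = tryCatch(sqrt(diag(as.matrix(vcov(fit)))),
                     error = function(e)
                       setNames(rep(NA_real_, length(beta)), names(beta))),
       ll = as.numeric(logLik(fit)),
       varcomp = varcomp,
       converged = isTRUE(conv))
}

# Build the per-block model data frame. `include` selects optional fixed
# covariates; genotype g is the block's haplotype-tagging SNP allelic count.
block_model_data <- function(cohort, block_id,
                             include = c("genotype", "smoking", "batch",
                                         "cells")) {
  s <- cohort$samples
  d <- data.frame(age = s$age_at_draw,
                  family_id = factor(s$family_id),
                  pair_id = factor(s$pair_id))
  terms <- c("age")
  if ("genotype" %in% include && !is.null(block_id)) {
    d$g <- as.numeric(cohort$genotype[s$individual_id, block_id])
    if (var(d$g) > 0) terms <- c(terms, "g")
  }
  if ("smoking" %in% include) {
    d$smoking <- factor(s$smoking)
    if (nlevels(droplevels(d$smoking)) > 1) terms <- c(terms, "smoking")
  }
  if ("batch" %in% include) {
    d$batch <- factor(s$batch)
    if (nlevels(droplevels(d$batch)) > 1) terms <- c(terms, "batch")
  }
  if ("cells" %in% include) {
    d$lymphocyte <- s$lymphocyte; d$monocyte <- s$monocyte
    d$neutrophil <- s$neutrophil; d$eosinophil <- s$eosinophil
    terms <- c(terms, "lymphocyte", "monocyte", "neutrophil", "eosinophil")
  }
  attr(d, "terms_full") <- terms
  d
}

lrt_from_fits <- function(full, null) {
  stat <- 2 * (full$ll - null$ll)
  if (stat < 0) {
    if (stat < -1e-6) warning("negative LRT statistic clipped: ", stat)
    stat <- 0
  }
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

fit_pair_refit <- function(template_full, template_null, y) {
  ff <- tryCatch(suppressMessages(suppressWarnings(
    summarise_lmm_fit(lme4::refit(template_full, newresp = y)))),
    error = function(e) NULL)
  nn <- tryCatch(suppressMessages(suppressWarnings(
    summarise_lmm_fit(lme4::refit(template_null, newresp = y)))),
    error = function(e) NULL)
  list(full = ff, null = nn)
}

#' Per-window likelihood-ratio age EWAS
#'
#' For every window, fits the full model
#' `m ~ age + SNP allelic count + smoking + batch + cell fractions +
#' (1|family) + (1|pair)` and the null model without `age`, both by ML on
#' the identical samples, and reports the 1-df chi-square LRT p-value for
#' age. The response is normalised per [normalise_windows()]; constant
#' windows are flagged `constant` and skipped; windows whose fit fails are
#' flagged `failed` but remain in the Bonferroni denominator.
#'
#' @param mat raw windows x samples matrix.
#' @param cohort list with `samples` and `genotype` (see
#'   [generate_cohort()] for the layout).
#' @param windows window data frame (`window_id`, coordinates, `block_id`).
#' @param normalise normalisation method, see [normalise_windows()].
#' @param include optional fixed covariates to adjust for; the replication
#'   setting uses `c("batch")` only.
#' @param maxit per-fit optimiser budget.
#' @return data frame (one row per window): coordinates, `beta_age`,
#'   `se_age`, `ll_full`, `ll_null`, `lrt_stat`, `p`, variance components,
#'   `n_samples`, `status`; attribute `n_tests` for the Bonferroni
#'   denominator.
#' @export
ewas_age <- function(mat, cohort, windows,
                     normalise = c("zscore", "inverse_normal", "none"),
                     include = c("genotype", "smoking", "batch", "cells"),
                     maxit = 200) {
  normalise <- match.arg(normalise)
  stopifnot(identical(rownames(mat), windows$window_id))
  nm <- normalise_windows(mat, normalise)
  flagged <- attr(nm, "flagged")
  res <- windows[, c("window_id", "chrom", "start", "end", "block_id")]
  res$beta_age <- NA_real_; res$se_age <- NA_real_
  res$ll_full <- NA_real_; res$ll_null <- NA_real_
  res$lrt_stat <- NA_real_; res$p <- NA_real_
  res$var_family <- NA_real_; res$var_pair <- NA_real_
  res$var_residual <- NA_real_
  res$n_samples <- ncol(mat); res$status <- "ok"
  res$status[res$window_id %in% flagged] <- "constant"

  for (bid in unique(windows$block_id)) {
    widx <- which(windows$block_id == bid & res$status != "constant")
    if (!length(widx)) next
    d <- block_model_data(cohort, bid, include)
    terms <- attr(d, "terms_full")
    d$y <- nm[widx[1], ]
    fml_full <- as.formula(paste("y ~", paste(
      c(terms, "(1 | family_id)", "(1 | pair_id)"), collapse = " + ")))
    fml_null <- as.formula(paste("y ~", paste(
      c(setdiff(terms, "age"), "(1 | family_id)", "(1 | pair_id)"),
      collapse = " + ")))
    tf <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml_full, d, REML = FALSE, control = lmm_control(maxit)))),
      error = function(e) NULL)
    tn <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml_null, d, REML = FALSE, control = lmm_control(maxit)))),
      error = function(e) NULL)
    if (is.null(tf) || is.null(tn)) {
      res$status[widx] <- "failed"
      next
    }
    for (w in widx) {
      pr <- fit_pair_refit(tf, tn, nm[w, ])
      if (is.null(pr$full) || is.null(pr$null) ||
          !pr$full$converged || !pr$null$converged) {
        res$status[w] <- "failed"
        next
      }
      lrt <- lrt_from_fits(pr$full, pr$null)
      res$beta_age[w] <- unname(pr$full$beta["age"])
      res$se_age[w] <- unname(pr$full$se["age"])
      res$ll_full[w] <- pr$full$ll
      res$ll_null[w] <- pr$null$ll
      res$lrt_stat[w] <- lrt$stat
      res$p[w] <- lrt$p
      res$var_family[w] <- unname(pr$full$varcomp["family_id"])
      res$var_pair[w] <- unname(pr$full$varcomp["pair_id"])
      res$var_residual[w] <- unname(pr$full$varcomp["Residual"])
    }
  }
  attr(res, "n_tests") <- nrow(res)
  res
}

#' Per-window genotype-by-age interaction test
#'
#' Compares the full model augmented with the `age:g` interaction against
#' the full model, by a 1-df ML likelihood-ratio test. Windows in blocks
#' whose haplotype-tagging SNP is monomorphic in the cohort are flagged
#' `monomorphic` and not tested.
#'
#' @inheritParams ewas_age
#' @return data frame: `window_id`, `block_id`, `beta_interaction`,
#'   `lrt_stat`, `p`, `status`.
#' @export
ewas_interaction <- function(mat, cohort, windows,
                             normalise = c("zscore", "inverse_normal", "none"),
                             include = c("genotype", "smoking", "batch",
                                         "cells"),
                             maxit = 200) {
  normalise <- match.arg(normalise)
  stopifnot(identical(rownames(mat), windows$window_id))
  nm <- normalise_windows(mat, normalise)
  flagged <- attr(nm, "flagged")
  res <- windows[, c("window_id", "chrom", "start", "end", "block_id")]
  res$beta_interaction <- NA_real_
  res$lrt_stat <- NA_real_; res$p <- NA_real_
  res$status <- "ok"
  res$status[res$window_id %in% flagged] <- "constant"

  for (bid in unique(windows$block_id)) {
    widx <- which(windows$block_id == bid & res$status != "constant")
    if (!length(widx)) next
    d <- block_model_data(cohort, bid, include)
    terms <- attr(d, "terms_full")
    if (!"g" %in% terms) {
      res$status[widx] <- "monomorphic"
      next
    }
    d$y <- nm[widx[1], ]
    fml_int <- as.formula(paste("y ~", paste(
      c(terms, "age:g", "(1 | family_id)", "(1 | pair_id)"),
      collapse = " + ")))
    fml_base <- as.formula(paste("y ~", paste(
      c(terms, "(1 | family_id)", "(1 | pair_id)"), collapse = " + ")))
    ti <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml_int, d, REML = FALSE, control = lmm_control(maxit)))),
      error = function(e) NULL)
    tb <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml_base, d, REML = FALSE, control = lmm_control(maxit)))),
      error = function(e) NULL)
    if (is.null(ti) || is.null(tb)) {
      res$status[widx] <- "failed"
      next
    }
    for (w in widx) {
      pr <- fit_pair_refit(ti, tb, nm[w, ])
      if (is.null(pr$full) || is.null(pr$null) ||
          !pr$full$converged || !pr$null$converged) {
        res$status[w] <- "failed"
        next
      }
      lrt <- lrt_from_fits(pr$full, pr$null)
      res$beta_interaction[w] <- unname(pr$full$beta["age:g"])
      res$lrt_stat[w] <- lrt$stat
      res$p[w] <- lrt$p
    }
  }
  res
}
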