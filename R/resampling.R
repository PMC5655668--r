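#' Bootstrap resampling plan
#'
#' @param n_boot number of bootstrap resamples (>= 2; default 100).
#' @param seed integer seed; with the plan, resample indices are drawn once
#'   per (drug, study) and shared across all features so paired tests are
#'   valid.
#' @return An object of class `BootstrapPlan`.
#' @export
bootstrap_plan <- function(n_boot = 100, seed = 1234L) {
  stopifnot(n_boot >= 2)
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "BootstrapPlan")
}

# Out-of-bag bootstrap concordance engine.
# y: AAC vector; X: n x F matrix of feature values; f: tissue factor.
# For each resample: draw cell lines with replacement (retry until the
# out-of-bag set has >= 2 cell lines), standardize y and X in-bag, fit the
# tissue-only null model and tissue+feature model per feature in-bag
# (rank-deficient designs from in-bag-missing tissue levels get zeroed
# coefficients), and score the concordance index of the full linear
# prediction on the out-of-bag cell lines.  Resamples whose out-of-bag AAC
# values are all tied are recorded as missing.
.bootstrap_engine <- function(y, X, f, plan, stream = "boot") {
  n <- length(y)
  D <- .tissue_design(f)
  set.seed(.substream_seed(plan$seed, stream))
  ci <- matrix(NA_real_, plan$n_boot, ncol(X),
               dimnames = list(NULL, colnames(X)))
  ci_null <- rep(NA_real_, plan$n_boot)
  for (b in seq_len(plan$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- which(!(seq_len(n) %in% idx))
      if (length(oob) >= 2) break
    }
    yoob <- y[oob]
    if (length(unique(yoob)) < 2) next      # all-tied out-of-bag: missing
    sy <- sd(y[idx])
    if (!is.finite(sy) || sy == 0) next
    yin <- (y[idx] - mean(y[idx])) / sy
    mx <- colMeans(X[idx, , drop = FALSE])
    sx <- apply(X[idx, , drop = FALSE], 2, sd)
    ok <- is.finite(sx) & sx > 0
    sx[!ok] <- 1
    Xin <- scale(X[idx, , drop = FALSE], center = mx, scale = sx)
    Din <- D[idx, , drop = FALSE]
    fit <- lm.fit(Din, cbind(yin, Xin))
    co <- as.matrix(fit$coefficients)
    co[is.na(co)] <- 0
    res <- as.matrix(fit$residuals)
    ry <- res[, 1]
    RX <- res[, -1, drop = FALSE]
    sxx <- colSums(RX^2)
    bx <- colSums(RX * ry) / sxx
    bx[!ok | sxx < 1e-10] <- NA_real_
    Doob <- D[oob, , drop = FALSE]
    p0 <- drop(Doob %*% co[, 1])
    Xoob <- scale(X[oob, , drop = FALSE], center = mx, scale = sx)
    # full linear prediction: tissue part of the feature model + beta * x
    PF <- p0 + (Xoob - Doob %*% co[, -1, drop = FALSE]) *
      rep(bx, each = length(oob))
    ci_null[b] <- concordance_index(p0, yoob)
    ci[b, ] <- .ci_multi(PF, yoob)
  }
  list(ci = ci, ci_null = ci_null)
}

#' Out-of-bag bootstrap concordance indices for one feature
#'
#' Draws `plan$n_boot` resamples of the cell lines with replacement, fits
#' the tissue-only null model and the tissue+expression model on the in-bag
#' cell lines (roughly 2/3 of the panel; standardization is recomputed
#' in-bag and applied out-of-bag), and scores the concordance index of both
#' models' predictions on the out-of-bag cell lines (roughly 1/3).
#' Identical resample indices are used for the null and expression models so
#' downstream signed-rank tests are paired.
#'
#' @inheritParams fit_models
#' @param plan a [bootstrap_plan()].
#' @return List with `ci_vector` (feature model) and `null_ci_vector`, each
#'   of length `plan$n_boot`; resamples with all-tied out-of-bag AAC are
#'   `NA`.
#' @export
bootstrap_ci <- function(expr, sens, drug, feature,
                         level = c("gene", "isoform"), study = NULL,
                         plan = bootstrap_plan(), n_min = 20) {
  level <- match.arg(level)
  if (is.null(study)) {
    st <- unique(sens$study_id)
    if (length(st) > 1) stop("sens holds several studies; pass `study`")
    study <- st
  }
  dc <- .drug_cells(expr, sens, drug, study, n_min)
  if (is.null(dc)) {
    stop(sprintf("fewer than %d cell lines with expression and AAC", n_min))
  }
  x <- .feature_values(expr, feature, level)[dc$cells]
  f <- .tissue_factor(expr$tissues[dc$cells])
  eng <- .bootstrap_engine(dc$y, matrix(x, ncol = 1,
                                        dimnames = list(NULL, feature)),
                           f, plan, stream = paste0("boot:", drug, ":", study))
  list(ci_vector = eng$ci[, 1], null_ci_vector = eng$ci_null)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; with twelve or fewer informative pairs the
#' null distribution of the signed-rank statistic (midranks for tied
#' absolute differences) is enumerated exactly over all sign assignments,
#' otherwise the large-sample test from [stats::wilcox.test()] is used.
#' Identical vectors give p = 1 (no evidence either way).
#'
#' @param x,y paired numeric vectors (`NA` pairs dropped).
#' @param alternative `"greater"` (x tends above y), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max_n largest n for exact sign-assignment enumeration.
#' @return List with `statistic` (W+, the rank sum of positive differences)
#'   and `p_value`.
#' @export
signed_rank_test <- function(x, y = NULL,
                             alternative = c("greater", "less", "two.sided"),
                             exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p_ge <- mean(ws >= w - 1e-12)
    p_le <- mean(ws <= w + 1e-12)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    p <- suppressWarnings(
      wilcox.test(d, alternative = alternative, exact = FALSE)$p.value)
  }
  list(statistic = w, p_value = p)
}

#' Compare paired bootstrap concordance-index vectors
#'
#' A model's out-of-bag concordance vector is compared with the paired null
#' (tissue-only) vector by a one-sided signed-rank test, and optionally with
#' an alternative model (gene versus isoform) by a two-sided signed-rank
#' test.  Pairs with a missing value in either vector are dropped; fewer
#' than `min_pairs` informative pairs yields `NA` ("not evaluable").
#'
#' @param ci_model,ci_null paired concordance-index vectors.
#' @param ci_alternative optional paired vector for the two-sided
#'   comparison.
#' @param min_pairs minimum number of non-missing pairs.
#' @return List with `p_vs_null`, `p_model_vs_alternative` (or `NA`), and
#'   `n_pairs`.
#' @export
compare_models <- function(ci_model, ci_null, ci_alternative = NULL,
                           min_pairs = 10) {
  stopifnot(length(ci_model) == length(ci_null))
  ok <- !is.na(ci_model) & !is.na(ci_null)
  p1 <- if (sum(ok) < min_pairs) NA_real_ else {
    signed_rank_test(ci_model[ok], ci_null[ok], "greater")$p_value
  }
  p2 <- NA_real_
  if (!is.null(ci_alternative)) {
    ok2 <- !is.na(ci_model) & !is.na(ci_alternative)
    if (sum(ok2) >= min_pairs) {
      p2 <- signed_rank_test(ci_model[ok2], ci_alternative[ok2],
                             "two.sided")$p_value
    }
  }
  list(p_vs_null = p1, p_model_vs_alternative = p2, n_pairs = sum(ok))
}

#' Combine fitted models across two studies
#'
#' Coefficients and p-values are averaged, weighted by the number of cell
#' lines in each study: `meta_beta = (n1*b1 + n2*b2) / (n1 + n2)` and
#' likewise for p.  When only one study is evaluable the result passes that
#' study through, flagged `single_study`.  A sign disagreement between the
#' studies is flagged, not an error.
#'
#' @param fit1,fit2 lists (or one-row data.frames) with `beta`, `p`, `n`;
#'   `fit2` may be `NULL` or have `n = 0`.
#' @return List with `beta`, `p`, `n` (total), `single_study`,
#'   `sign_disagreement`.
#' @export
meta_combine <- function(fit1, fit2 = NULL) {
  g <- function(f, what) if (is.null(f)) NA_real_ else as.numeric(f[[what]])
  b <- c(g(fit1, "beta"), g(fit2, "beta"))
  p <- c(g(fit1, "p"), g(fit2, "p"))
  n <- c(g(fit1, "n"), g(fit2, "n"))
  n[is.na(n)] <- 0
  ev <- n > 0 & !is.na(b) & !is.na(p)
  if (!any(ev)) {
    return(list(beta = NA_real_, p = NA_real_, n = 0L,
                single_study = FALSE, sign_disagreement = FALSE))
  }
  list(beta = sum(n[ev] * b[ev]) / sum(n[ev]),
       p = sum(n[ev] * p[ev]) / sum(n[ev]), n = as.integer(sum(n[ev])),
       single_study = sum(ev) == 1L,
       sign_disagreement = sum(ev) == 2L && sign(b[1]) != sign(b[2]) &&
         all(b[ev] != 0))
}

#' Call biomarkers from meta-combined records
#'
#' Benjamini-Hochberg FDR is applied across all genes (one family) and
#' across all best isoforms (a second family), separately.  A level is
#' significant when its FDR is below `fdr_threshold`, its median out-of-bag
#' concordance index exceeds `ci_threshold`, and the one-sided signed-rank
#' test against the null model passes at `wilcoxon_alpha`; missing
#' concordance or test values fail the gate.  The biomarker category is
#' `gene_specific` (gene level only), `isoform_specific` (best isoform
#' only), `common` (both), or `none`.
#'
#' @param records data.frame with one row per gene x drug, columns
#'   `gene_id`, `best_isoform_id`, `drug`, `meta_beta_gene`, `meta_p_gene`,
#'   `meta_beta_isoform`, `meta_p_isoform`, `ci_gene`, `ci_isoform`,
#'   `p_wilcox_gene`, `p_wilcox_isoform`.
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param ci_threshold median out-of-bag concordance cutoff (default 0.55).
#' @param wilcoxon_alpha level of the signed-rank test versus the null.
#' @return The records with `fdr_gene`, `fdr_isoform`, `significant_gene`,
#'   `significant_isoform`, and `category` columns appended.
#' @export
call_biomarkers <- function(records, fdr_threshold = 0.01,
                            ci_threshold = 0.55, wilcoxon_alpha = 0.05) {
  if (is.null(records) || nrow(records) == 0) {
    out <- if (is.null(records)) data.frame() else records
    out$fdr_gene <- out$fdr_isoform <- numeric(0)
    out$significant_gene <- out$significant_isoform <- logical(0)
    out$category <- character(0)
    return(out)
  }
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  records$fdr_gene <- p.adjust(records$meta_p_gene, method = "BH")
  records$fdr_isoform <- p.adjust(records$meta_p_isoform, method = "BH")
  gate <- function(fdr, ci, pw) {
    !is.na(fdr) & fdr < fdr_threshold &
      !is.na(ci) & ci > ci_threshold &
      !is.na(pw) & pw < wilcoxon_alpha
  }
  records$significant_gene <- gate(records$fdr_gene, records$ci_gene,
                                   records$p_wilcox_gene)
  records$significant_isoform <- gate(records$fdr_isoform,
                                      records$ci_isoform,
                                      records$p_wilcox_isoform)
  records$category <- ifelse(
    records$significant_gene & records$significant_isoform, "common",
    ifelse(records$significant_gene, "gene_specific",
           ifelse(records$significant_isoform, "isoform_specific", "none")))
  records
}

#' Discover biomarkers for one drug across studies
#'
#' The full discovery engine: per study, tissue-adjusted standardized OLS
#' of AAC on every gene and every isoform; per gene, selection of the most
#' significant isoform by Bonferroni-corrected p-value (pooled across
#' studies by sample-size weighting); sample-size-weighted meta-combination
#' of coefficients and p-values across studies; BH-FDR within the gene and
#' best-isoform families; and, for features passing the FDR gate (or for
#' all features when `bootstrap = "all"`), out-of-bag bootstrap concordance
#' with identical resamples for the null, gene, and isoform models, pooled
#' across studies, followed by one-sided signed-rank tests against the
#' null.  Calls are made by [call_biomarkers()].
#'
#' @inheritParams fit_models
#' @param plan a [bootstrap_plan()].
#' @param fdr_threshold,ci_threshold,wilcoxon_alpha calling thresholds.
#' @param bootstrap `"candidates"` evaluates concordance only for features
#'   passing the FDR gate (the other calling gates are conjunctive, so the
#'   calls are identical and the run is much faster); `"all"` evaluates
#'   every gene and its best isoform.
#' @return List of class `BiomarkerDiscovery`: `calls` (one row per gene,
#'   see [call_biomarkers()]), `associations` (per-study per-feature fits),
#'   `drug`, `studies`, `plan`, thresholds.
#' @export
discover_biomarkers <- function(expr, sens, drug, plan = bootstrap_plan(),
                                fdr_threshold = 0.01, ci_threshold = 0.55,
                                wilcoxon_alpha = 0.05, n_min = 20,
                                bootstrap = c("candidates", "all")) {
  bootstrap <- match.arg(bootstrap)
  studies <- unique(sens$study_id[sens$drug == drug])
  if (length(studies) == 0) stop(sprintf("drug '%s' absent", drug))
  if (length(studies) > 2) {
    stop("meta-combination supports at most two training studies")
  }
  ga <- list(); ia <- list(); nstudy <- list()
  for (s in studies) {
    ga[[s]] <- fit_associations(expr, sens, drug, "gene", study = s,
                                n_min = n_min)
    ia[[s]] <- fit_associations(expr, sens, drug, "isoform", study = s,
                                n_min = n_min)
  }
  ok <- !vapply(ga, is.null, logical(1)) & !vapply(ia, is.null, logical(1))
  studies <- studies[ok]
  if (length(studies) == 0) {
    stop(sprintf("no study has %d+ cell lines for drug '%s'", n_min, drug))
  }
  ga <- ga[studies]; ia <- ia[studies]

  genes <- ga[[1]]$feature_id
  # per-study Bonferroni within gene, then sample-size-weighted pooling of
  # the corrected p-values to pick one best isoform per gene
  iso_tab <- ia[[1]][c("feature_id", "gene_id")]
  pb <- sapply(studies, function(s) {
    d <- ia[[s]]
    ntest <- ave(!is.na(d$p), d$gene_id, FUN = sum)
    pmin(1, d$p * ntest)
  })
  pb <- matrix(pb, ncol = length(studies))
  bmat <- sapply(studies, function(s) ia[[s]]$beta)
  bmat <- matrix(bmat, ncol = length(studies))
  wts <- vapply(studies, function(s) ia[[s]]$n[1], numeric(1))
  # sample-size-weighted mean over the studies where the fit is evaluable
  wsum <- function(m) {
    W <- matrix(wts, nrow(m), length(wts), byrow = TRUE)
    W[is.na(m)] <- 0
    den <- rowSums(W)
    ifelse(den > 0, rowSums(m * W, na.rm = TRUE) / den, NA_real_)
  }
  score <- wsum(pb)
  betaw <- wsum(bmat)
  sel <- tapply(seq_len(nrow(iso_tab)), iso_tab$gene_id, function(ii) {
    sc <- score[ii]
    if (all(is.na(sc))) return(NA_integer_)
    ord <- order(sc, -abs(betaw[ii]), iso_tab$feature_id[ii],
                 na.last = TRUE)
    ii[ord[1]]
  })
  best_iso <- setNames(iso_tab$feature_id[sel], names(sel))[genes]

  meta_row <- function(tabs, idx_fun, p_col = "p") {
    fits <- lapply(studies, function(s) {
      d <- tabs[[s]]
      i <- idx_fun(d, s)
      if (is.na(i)) NULL else list(beta = d$beta[i], p = d[[p_col]][i],
                                   n = if (is.na(d$beta[i])) 0 else d$n[i])
    })
    if (length(fits) == 1) meta_combine(fits[[1]]) else
      meta_combine(fits[[1]], fits[[2]])
  }
  mg <- lapply(genes, function(g) {
    meta_row(ga, function(d, s) match(g, d$feature_id))
  })
  # Bonferroni-corrected per-study p for the selected isoform enters meta
  for (s in studies) ia[[s]]$p_bonf <- pb[, match(s, studies)]
  mi <- lapply(genes, function(g) {
    iso <- best_iso[[g]]
    if (is.na(iso)) return(meta_combine(NULL))
    meta_row(ia, function(d, s) match(iso, d$feature_id), p_col = "p_bonf")
  })
  records <- data.frame(
    gene_id = genes, best_isoform_id = unname(best_iso), drug = drug,
    meta_beta_gene = vapply(mg, `[[`, numeric(1), "beta"),
    meta_p_gene = vapply(mg, `[[`, numeric(1), "p"),
    meta_beta_isoform = vapply(mi, `[[`, numeric(1), "beta"),
    meta_p_isoform = vapply(mi, `[[`, numeric(1), "p"),
    n_gene = vapply(mg, `[[`, integer(1), "n"),
    n_isoform = vapply(mi, `[[`, integer(1), "n"),
    sign_disagreement_gene = vapply(mg, `[[`, logical(1),
                                    "sign_disagreement"),
    sign_disagreement_isoform = vapply(mi, `[[`, logical(1),
                                       "sign_disagreement"),
    ci_gene = NA_real_, ci_isoform = NA_real_,
    p_wilcox_gene = NA_real_, p_wilcox_isoform = NA_real_,
    stringsAsFactors = FALSE)

  fdr_gene <- p.adjust(records$meta_p_gene, method = "BH")
  fdr_iso <- p.adjust(records$meta_p_isoform, method = "BH")
  cand <- if (bootstrap == "all") seq_len(nrow(records)) else {
    which((!is.na(fdr_gene) & fdr_gene < fdr_threshold) |
            (!is.na(fdr_iso) & fdr_iso < fdr_threshold))
  }
  if (length(cand)) {
    gfeat <- records$gene_id[cand]
    ifeat <- records$best_isoform_id[cand]
    have_iso <- !is.na(ifeat)
    ci_g <- ci_i <- NULL
    null_all <- NULL
    for (s in studies) {
      dc <- .drug_cells(expr, sens, drug, s, n_min)
      Xg <- t(expr$gene_matrix[gfeat, dc$cells, drop = FALSE])
      Xi <- matrix(NA_real_, length(dc$cells), length(cand))
      if (any(have_iso)) {
        Xi[, have_iso] <-
          t(expr$isoform_matrix[ifeat[have_iso], dc$cells, drop = FALSE])
      }
      Xi[is.na(Xi)] <- 0
      f <- .tissue_factor(expr$tissues[dc$cells])
      eng <- .bootstrap_engine(dc$y, cbind(Xg, Xi), f, plan,
                               stream = paste0("boot:", drug, ":", s))
      k <- length(cand)
      ci_g <- rbind(ci_g, eng$ci[, seq_len(k), drop = FALSE])
      ci_i <- rbind(ci_i, eng$ci[, k + seq_len(k), drop = FALSE])
      null_all <- c(null_all, eng$ci_null)
    }
    for (j in seq_along(cand)) {
      i <- cand[j]
      records$ci_gene[i] <- median(ci_g[, j], na.rm = TRUE)
      records$p_wilcox_gene[i] <-
        compare_models(ci_g[, j], null_all)$p_vs_null
      if (have_iso[j]) {
        records$ci_isoform[i] <- median(ci_i[, j], na.rm = TRUE)
        records$p_wilcox_isoform[i] <-
          compare_models(ci_i[, j], null_all)$p_vs_null
      }
    }
  }
  calls <- call_biomarkers(records, fdr_threshold, ci_threshold,
                           wilcoxon_alpha)
  assoc_cols <- names(ga[[1]])
  structure(
    list(calls = calls,
         associations = rbind(do.call(rbind, lapply(ga, `[`, assoc_cols)),
                              do.call(rbind, lapply(ia, `[`, assoc_cols))),
         drug = drug, studies = studies, plan = plan,
         fdr_threshold = fdr_threshold, ci_threshold = ci_threshold,
         wilcoxon_alpha = wilcoxon_alpha),
    class = "BiomarkerDiscovery")
}

#' @export
print.BiomarkerDiscovery <- function(x, ...) {
  tab <- table(factor(x$calls$category,
                      levels = c("gene_specific", "isoform_specific",
                                 "common", "none")))
  cat(sprintf(
    "BiomarkerDiscovery for '%s' (%s): %d genes; %d gene-specific, %d isoform-specific, %d common\n",
    x$drug, paste(x$studies, collapse = " + "), nrow(x$calls),
    tab["gene_specific"], tab["isoform_specific"], tab["common"]))
  invisible(x)
}
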