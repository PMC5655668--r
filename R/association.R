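#' Concordance index of predictions against observed sensitivity
#'
#' The fraction of evaluable cell-line pairs (pairs with distinct observed
#' AAC) whose prediction ordering matches the observation ordering.
#' Prediction ties count 0.5; pairs tied on the observation are excluded
#' from the denominator.  0.5 is random, 1 perfect, 0 perfectly reversed.
#'
#' @param pred numeric vector of predicted scores.
#' @param obs numeric vector of observed sensitivity values (same length).
#' @return Concordance index in `[0,1]`, or `NA` when no pair is evaluable
#'   (all observations tied).
#' @export
concordance_index <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  keep <- is.finite(pred) & is.finite(obs)
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(obs)
  if (n < 2) return(NA_real_)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  s_obs <- sign(obs[ij[, 2]] - obs[ij[, 1]])
  ev <- s_obs != 0
  if (!any(ev)) return(NA_real_)
  s <- sign(pred[ij[ev, 2]] - pred[ij[ev, 1]]) * s_obs[ev]
  mean((s > 0) + 0.5 * (s == 0))
}

# concordance of many prediction columns against one observation vector,
# sharing the evaluable-pair structure (internal fast path for bootstraps)
.ci_multi <- function(pred_mat, obs) {
  n <- length(obs)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  s_obs <- sign(obs[ij[, 2]] - obs[ij[, 1]])
  ev <- s_obs != 0
  if (!any(ev)) return(rep(NA_real_, ncol(pred_mat)))
  s <- sign(pred_mat[ij[ev, 2], , drop = FALSE] -
              pred_mat[ij[ev, 1], , drop = FALSE]) * s_obs[ev]
  colMeans((s > 0) + 0.5 * (s == 0))
}

# align sensitivity with expression columns for one (drug, study);
# returns list(cells, y) or NULL when too few cell lines
.drug_cells <- function(expr, sens, drug, study = NULL, n_min = 20) {
  rows <- sens$drug == drug
  if (!is.null(study)) rows <- rows & sens$study_id == study
  s <- sens[rows, , drop = FALSE]
  cells <- intersect(colnames(expr$isoform_matrix), s$cell_line)
  if (length(cells) < n_min) return(NULL)
  list(cells = cells, y = s$aac[match(cells, s$cell_line)])
}

# Batch OLS of standardized y on tissue + each standardized feature column.
# Y: n vector; X: n x F matrix; f: tissue factor.  Frisch-Waugh
# residualization against the tissue design gives, per feature, the same
# coefficient, t-statistic and p-value as the full lm fit.
.fit_linear_batch <- function(y, X, f) {
  D <- .tissue_design(f)
  qrD <- qr(D)
  y <- .standardize(y)
  Xs <- scale(X)
  const <- !is.finite(colSums(Xs)) | apply(X, 2, sd) == 0
  Xs[, const] <- 0
  res <- qr.resid(qrD, cbind(y, Xs))
  ry <- res[, 1]
  RX <- res[, -1, drop = FALSE]
  sxx <- colSums(RX^2)
  sxy <- colSums(RX * ry)
  syy <- sum(ry^2)
  df <- length(y) - qrD$rank - 1L
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df)
  bad <- const | sxx < 1e-10 | df < 1
  beta[bad] <- NA_real_
  p[bad] <- NA_real_
  data.frame(feature_id = colnames(X), beta = beta, p = p,
             n = length(y), df = df,
             reason = ifelse(bad, "constant_feature", NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the nested tissue-adjusted linear models for one feature
#'
#' Ordinary least squares of the standardized AAC on the tissue-of-origin
#' one-hot design (null model), and on tissue plus the standardized
#' expression of one gene or isoform (expression model).  Standardization
#' (mean 0, SD 1) uses exactly the cell lines entering the fit.  Tissues
#' with a single cell line are merged into `"other"`; the most frequent
#' tissue is the reference level.
#'
#' @param expr an [expression_dataset()].
#' @param sens a [sensitivity_table()] for a single study.
#' @param drug drug identifier.
#' @param feature gene or isoform identifier.
#' @param level `"gene"` or `"isoform"`.
#' @param study study identifier (required when `sens` holds several).
#' @param n_min minimum number of cell lines with both expression and AAC.
#' @return List with `m0` (null model: `n`, `r_squared`, fitted tissue
#'   coefficients) and `fit` (expression model: `beta`, `p`, `n`, `sign`).
#' @export
fit_models <- function(expr, sens, drug, feature,
                       level = c("gene", "isoform"), study = NULL,
                       n_min = 20) {
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
  if (sd(x) == 0) {
    return(list(m0 = NULL, fit = list(beta = NA_real_, p = NA_real_,
                                      n = length(dc$cells), sign = NA_real_,
                                      reason = "constant_feature")))
  }
  f <- .tissue_factor(expr$tissues[dc$cells])
  y <- .standardize(dc$y)
  D <- .tissue_design(f)
  m0 <- lm.fit(D, y)
  b <- .fit_linear_batch(dc$y, matrix(x, ncol = 1,
                                      dimnames = list(NULL, feature)), f)
  list(m0 = list(n = length(y), coefficients = m0$coefficients,
                 r_squared = 1 - sum(m0$residuals^2) / sum(y^2)),
       fit = list(beta = b$beta, p = b$p, n = b$n,
                  sign = sign(b$beta), reason = b$reason))
}

#' Fit associations for all features of one level
#'
#' Vectorized version of [fit_models()]: standardized tissue-adjusted OLS of
#' AAC on every gene (or every isoform) of the expression dataset for one
#' (drug, study), returning the standardized coefficient, its two-sided
#' t-test p-value and the number of cell lines per feature.  Constant
#' features are reported with `NA` and a reason rather than dropped.
#'
#' @inheritParams fit_models
#' @param features optional subset of feature identifiers.
#' @return data.frame with columns `feature_id`, `gene_id`, `level`, `drug`,
#'   `study`, `beta`, `p`, `n`, `reason`, or `NULL` when fewer than `n_min`
#'   cell lines are available.
#' @export
fit_associations <- function(expr, sens, drug, level = c("gene", "isoform"),
                             study = NULL, features = NULL, n_min = 20) {
  level <- match.arg(level)
  if (is.null(study)) {
    st <- unique(sens$study_id)
    if (length(st) > 1) stop("sens holds several studies; pass `study`")
    study <- st
  }
  dc <- .drug_cells(expr, sens, drug, study, n_min)
  if (is.null(dc)) return(NULL)
  m <- if (level == "gene") expr$gene_matrix else expr$isoform_matrix
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing)) {
      stop(sprintf("unknown %s features: %s", level,
                   paste(missing, collapse = ", ")))
    }
    m <- m[features, , drop = FALSE]
  }
  X <- t(m[, dc$cells, drop = FALSE])
  f <- .tissue_factor(expr$tissues[dc$cells])
  out <- .fit_linear_batch(dc$y, X, f)
  gene_id <- if (level == "gene") out$feature_id else {
    expr$isoform_map$gene_id[match(out$feature_id,
                                   expr$isoform_map$isoform_id)]
  }
  cbind(data.frame(feature_id = out$feature_id, gene_id = gene_id,
                   level = level, drug = drug, study = study,
                   stringsAsFactors = FALSE),
        out[c("beta", "p", "n", "reason")])
}

#' Select a gene's most significant isoform
#'
#' Bonferroni-corrects each isoform's p-value by the number of isoforms of
#' the gene actually tested (non-missing fits), caps corrected p-values at
#' 1, and selects the smallest.  Ties on the corrected p-value are broken by
#' the larger absolute coefficient, then by the lexicographically smallest
#' isoform identifier, so the choice is invariant to input order.
#'
#' @param per_isoform_fits data.frame with columns `isoform_id` (or
#'   `feature_id`), `beta`, `p` for the isoforms of one gene.
#' @return One-row data.frame: `isoform_id`, `beta`, `p`, `p_bonferroni`,
#'   `n_tested`.
#' @export
select_best_isoform <- function(per_isoform_fits) {
  df <- as.data.frame(per_isoform_fits)
  if (!"isoform_id" %in% names(df) && "feature_id" %in% names(df)) {
    df$isoform_id <- df$feature_id
  }
  stopifnot(all(c("isoform_id", "beta", "p") %in% names(df)),
            nrow(df) >= 1)
  tested <- !is.na(df$p)
  m <- sum(tested)
  if (m == 0) {
    return(data.frame(isoform_id = NA_character_, beta = NA_real_,
                      p = NA_real_, p_bonferroni = NA_real_, n_tested = 0L,
                      stringsAsFactors = FALSE))
  }
  df <- df[tested, , drop = FALSE]
  df$p_bonferroni <- pmin(1, df$p * m)
  ord <- order(df$p_bonferroni, -abs(df$beta), df$isoform_id)
  best <- df[ord[1], , drop = FALSE]
  data.frame(isoform_id = best$isoform_id, beta = best$beta, p = best$p,
             p_bonferroni = best$p_bonferroni, n_tested = m,
             stringsAsFactors = FALSE, row.names = NULL)
}
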