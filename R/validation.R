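#' Validation rule
#'
#' @param alpha unadjusted significance level for the validation fit.
#' @param require_same_sign require the validation coefficient to share the
#'   sign of the training coefficient.
#' @param tissue_adjusted include the tissue covariate in the validation
#'   fit (pan-cancer validation); single-tissue validation sets omit it.
#' @return An object of class `ValidationRule`.
#' @export
validation_rule <- function(alpha = 0.05, require_same_sign = TRUE,
                            tissue_adjusted = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, require_same_sign = require_same_sign,
                 tissue_adjusted = tissue_adjusted),
            class = "ValidationRule")
}

#' Extract validation candidates from a discovery result
#'
#' One candidate row per significant level of each called biomarker (the
#' gene for `gene_specific` and `common` calls, the best isoform for
#' `isoform_specific` and `common` calls), carrying the sign of the
#' meta-combined training coefficient.
#'
#' @param discovery a `BiomarkerDiscovery` from [discover_biomarkers()], or
#'   its `calls` data.frame.
#' @return data.frame with `feature_id`, `level`, `gene_id`, `drug`,
#'   `sign_train`, `beta_train`.
#' @export
biomarker_candidates <- function(discovery) {
  calls <- if (inherits(discovery, "BiomarkerDiscovery")) {
    discovery$calls
  } else discovery
  g <- calls[calls$significant_gene, , drop = FALSE]
  i <- calls[calls$significant_isoform, , drop = FALSE]
  out <- rbind(
    if (nrow(g)) data.frame(feature_id = g$gene_id, level = "gene",
                            gene_id = g$gene_id, drug = g$drug,
                            sign_train = sign(g$meta_beta_gene),
                            beta_train = g$meta_beta_gene,
                            stringsAsFactors = FALSE),
    if (nrow(i)) data.frame(feature_id = i$best_isoform_id,
                            level = "isoform", gene_id = i$gene_id,
                            drug = i$drug,
                            sign_train = sign(i$meta_beta_isoform),
                            beta_train = i$meta_beta_isoform,
                            stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), level = character(),
                      gene_id = character(), drug = character(),
                      sign_train = numeric(), beta_train = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Tissue-restricted pre-selection of candidates
#'
#' Restricts the training data to one tissue, refits the association for
#' each candidate without the tissue covariate (a single tissue makes it
#' redundant), pools out-of-bag bootstrap concordance across the training
#' studies, and keeps candidates whose median concordance exceeds
#' `ci_threshold` and whose sample-size-weighted p-value is below `alpha`.
#'
#' @param candidates data.frame from [biomarker_candidates()].
#' @param expr training [expression_dataset()].
#' @param sens training [sensitivity_table()] (one or two studies).
#' @param drug drug identifier.
#' @param tissue tissue label to restrict to.
#' @param ci_threshold concordance cutoff on the tissue-restricted median
#'   out-of-bag concordance index.
#' @param alpha significance level for the tissue-restricted fit.
#' @param n_min minimum cell lines per study after restriction; studies
#'   below it are dropped, and an empty result (with a warning) is returned
#'   when none remain.
#' @param plan a [bootstrap_plan()].
#' @return The kept candidate rows with `ci_tissue` and `p_tissue` columns.
#' @export
preselect_tissue <- function(candidates, expr, sens, drug,
                             tissue = "breast", ci_threshold = 0.55,
                             alpha = 0.05, n_min = 20,
                             plan = bootstrap_plan()) {
  empty <- cbind(candidates[0, , drop = FALSE],
                 data.frame(ci_tissue = numeric(), p_tissue = numeric()))
  if (nrow(candidates) == 0) return(empty)
  candidates <- candidates[candidates$drug == drug, , drop = FALSE]
  if (nrow(candidates) == 0) return(empty)
  cells <- names(expr$tissues)[expr$tissues == tissue]
  if (length(cells) < n_min) {
    warning(sprintf("fewer than %d '%s' cell lines", n_min, tissue))
    return(empty)
  }
  texpr <- .subset_cells(expr, cells)
  studies <- unique(sens$study_id[sens$drug == drug])
  fits <- list(); ci <- NULL; used <- character(0)
  for (s in studies) {
    dc <- .drug_cells(texpr, sens, drug, s, n_min)
    if (is.null(dc)) next
    used <- c(used, s)
    X <- sapply(seq_len(nrow(candidates)), function(i) {
      .feature_values(texpr, candidates$feature_id[i],
                      candidates$level[i])[dc$cells]
    })
    X <- matrix(X, ncol = nrow(candidates))
    colnames(X) <- candidates$feature_id
    f <- factor(rep("single", length(dc$cells)))
    fits[[s]] <- .fit_linear_batch(dc$y, X, f)
    eng <- .bootstrap_engine(dc$y, X, f, plan,
                             stream = paste0("preval:", drug, ":", s))
    ci <- rbind(ci, eng$ci)
  }
  if (length(used) == 0) {
    warning(sprintf("no study retains %d '%s' cell lines", n_min, tissue))
    return(empty)
  }
  wts <- vapply(used, function(s) fits[[s]]$n[1], numeric(1))
  pmat <- sapply(used, function(s) fits[[s]]$p)
  pmat <- matrix(pmat, ncol = length(used))
  W <- matrix(wts, nrow(pmat), length(wts), byrow = TRUE)
  W[is.na(pmat)] <- 0
  den <- rowSums(W)
  p_tissue <- ifelse(den > 0, rowSums(pmat * W, na.rm = TRUE) / den, NA)
  ci_med <- apply(ci, 2, median, na.rm = TRUE)
  out <- cbind(candidates,
               data.frame(ci_tissue = ci_med, p_tissue = p_tissue))
  keep <- !is.na(ci_med) & ci_med > ci_threshold &
    !is.na(p_tissue) & p_tissue < alpha
  out[keep, , drop = FALSE]
}

#' Validate candidates in an independent dataset
#'
#' Refits the association of each candidate feature with drug sensitivity
#' on the validation dataset (tissue-adjusted if the rule says so) and
#' declares a candidate validated when the unadjusted p-value is below
#' `rule$alpha` and the coefficient carries the training sign.  Candidate
#' features absent from the validation expression matrices are reported
#' with status `"missing_feature"`, never silently dropped; a drug absent
#' from the validation sensitivity table is an error ("not testable").
#'
#' @param candidates data.frame with `feature_id`, `level`, `drug`,
#'   `sign_train` (e.g. from [biomarker_candidates()] or
#'   [preselect_tissue()]).
#' @param expr validation [expression_dataset()].
#' @param sens validation [sensitivity_table()] (single study).
#' @param rule a [validation_rule()].
#' @param n_min minimum cell lines in the validation fit.
#' @return data.frame with one row per candidate: `validated`,
#'   `p_validation`, `beta_validation`, `sign_train`, `sign_validation`,
#'   `status`; the fraction validated among testable candidates is attached
#'   as the `validation_rate` attribute.
#' @export
validate_biomarkers <- function(candidates, expr, sens,
                                rule = validation_rule(), n_min = 10) {
  stopifnot(inherits(rule, "ValidationRule"))
  out <- candidates
  out$beta_validation <- NA_real_
  out$p_validation <- NA_real_
  out$sign_validation <- NA_real_
  out$validated <- NA
  out$status <- "pending"
  if (nrow(out) == 0) {
    attr(out, "validation_rate") <- NA_real_
    return(out)
  }
  for (drug in unique(out$drug)) {
    rows <- which(out$drug == drug)
    if (!drug %in% sens$drug) {
      stop(sprintf("drug '%s' not testable: absent from validation set",
                   drug))
    }
    dc <- .drug_cells(expr, sens, drug, study = NULL, n_min = n_min)
    if (is.null(dc)) {
      stop(sprintf("fewer than %d validation cell lines for '%s'",
                   n_min, drug))
    }
    f <- if (rule$tissue_adjusted) {
      .tissue_factor(expr$tissues[dc$cells])
    } else factor(rep("single", length(dc$cells)))
    for (i in rows) {
      m <- if (out$level[i] == "gene") expr$gene_matrix else
        expr$isoform_matrix
      if (!out$feature_id[i] %in% rownames(m)) {
        out$status[i] <- "missing_feature"
        next
      }
      x <- m[out$feature_id[i], dc$cells]
      b <- .fit_linear_batch(dc$y,
                             matrix(x, ncol = 1,
                                    dimnames = list(NULL,
                                                    out$feature_id[i])), f)
      out$beta_validation[i] <- b$beta
      out$p_validation[i] <- b$p
      out$sign_validation[i] <- sign(b$beta)
      if (is.na(b$p)) {
        out$status[i] <- "not_evaluable"
        next
      }
      ok_sign <- !rule$require_same_sign ||
        (!is.na(out$sign_train[i]) &&
           sign(b$beta) == out$sign_train[i])
      out$validated[i] <- b$p < rule$alpha && ok_sign
      out$status[i] <- "tested"
    }
  }
  tested <- out$status == "tested"
  attr(out, "validation_rate") <-
    if (any(tested)) mean(out$validated[tested]) else NA_real_
  out
}

#' Signed display effect size
#'
#' The display statistic for validated associations: the concordance index
#' minus 0.5, multiplied by the sign of the regression coefficient, so
#' positive values mark sensitizing associations and the magnitude reflects
#' predictive value beyond chance.
#'
#' @param ci concordance index in `[0,1]` (vectorized).
#' @param beta regression coefficient; a zero coefficient gives 0.
#' @return `(ci - 0.5) * sign(beta)`.
#' @export
effect_display <- function(ci, beta) {
  stopifnot(all(is.na(ci) | (ci >= 0 & ci <= 1)))
  (ci - 0.5) * sign(beta)
}

#' Isoform correlation table for a candidate isoform
#'
#' Pearson correlation of the candidate isoform's expression with every
#' isoform of the same gene, a reporting helper for inspecting whether a
#' predictive isoform tracks or departs from its siblings.
#'
#' @param expr an [expression_dataset()].
#' @param isoform candidate isoform identifier.
#' @return data.frame with `isoform_id`, `correlation`, sorted decreasing,
#'   the candidate itself first.
#' @export
isoform_correlations <- function(expr, isoform) {
  gene <- expr$isoform_map$gene_id[match(isoform,
                                         expr$isoform_map$isoform_id)]
  if (is.na(gene)) stop(sprintf("unknown isoform '%s'", isoform))
  sibs <- expr$isoform_map$isoform_id[expr$isoform_map$gene_id == gene]
  x <- expr$isoform_matrix[isoform, ]
  r <- vapply(sibs, function(s) {
    suppressWarnings(cor(x, expr$isoform_matrix[s, ]))
  }, numeric(1))
  out <- data.frame(isoform_id = sibs, correlation = r,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$isoform_id != isoform, -out$correlation), , drop = FALSE]
}
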