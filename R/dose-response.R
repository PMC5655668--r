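# Hill viability curve: v(d) = e_inf + (1 - e_inf) / (1 + (d/ec50)^slope)
.hill_viability <- function(d, ec50, slope, e_inf) {
  e_inf + (1 - e_inf) / (1 + (d / ec50)^slope)
}

#' Construct a dose-response experiment
#'
#' Holds one (cell line, drug) plate: a strictly increasing dose grid,
#' a replicate-by-dose matrix of signals, and optional untreated control and
#' cell-free blank wells used by the SRB preprocessing.
#'
#' @param doses positive, strictly increasing concentrations (micromolar).
#' @param viabilities numeric matrix, replicates x doses (raw signals, or
#'   normalized viabilities when `normalized = TRUE`).
#' @param cell_line,drug identifiers.
#' @param control_wells,blank_wells numeric vectors of raw well signals.
#' @param normalized `TRUE` when `viabilities` are already on the viability
#'   scale (blank-subtracted, control-normalized).
#' @return An object of class `DoseResponseExperiment`.
#' @export
dose_response_experiment <- function(doses, viabilities, cell_line = "",
                                     drug = "", control_wells = NULL,
                                     blank_wells = NULL,
                                     normalized = FALSE) {
  doses <- as.numeric(doses)
  if (length(doses) < 2) stop("need at least two doses")
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (is.vector(viabilities)) viabilities <- matrix(viabilities, nrow = 1)
  stopifnot(is.matrix(viabilities), ncol(viabilities) == length(doses),
            nrow(viabilities) >= 1)
  structure(
    list(cell_line = cell_line, drug = drug, doses = doses,
         viabilities = viabilities,
         control_wells = control_wells, blank_wells = blank_wells,
         normalized = isTRUE(normalized), n_discarded = 0L),
    class = "DoseResponseExperiment")
}

#' @export
print.DoseResponseExperiment <- function(x, ...) {
  cat(sprintf(
    "DoseResponseExperiment %s / %s: %d doses x %d replicates (%s)\n",
    x$cell_line, x$drug, length(x$doses), nrow(x$viabilities),
    if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' SRB preprocessing and replicate quality control
#'
#' Subtracts the mean blank (PBS) well signal from all wells, normalizes
#' treated wells to the mean control well, and discards any dose whose
#' replicate viabilities have a standard deviation or coefficient of
#' variation above `qc_threshold`.  Applying the function twice gives the
#' same result as applying it once.
#'
#' @param exp a [dose_response_experiment()] with raw signals and non-empty
#'   control and blank wells (already-normalized experiments skip the
#'   normalization and only re-apply the replicate filter).
#' @param qc_threshold replicate SD / CV cutoff (default 0.2).
#' @return The filtered experiment, normalized, with the cumulative number
#'   of discarded doses in the `n_discarded` field.
#' @export
preprocess_srb <- function(exp, qc_threshold = 0.2) {
  stopifnot(inherits(exp, "DoseResponseExperiment"), qc_threshold > 0)
  v <- exp$viabilities
  if (!exp$normalized) {
    if (is.null(exp$blank_wells) || length(exp$blank_wells) == 0 ||
        is.null(exp$control_wells) || length(exp$control_wells) == 0) {
      stop("raw experiments need control and blank wells")
    }
    blank <- mean(exp$blank_wells)
    ctrl <- mean(exp$control_wells - blank)
    if (!is.finite(ctrl) || ctrl <= 0) {
      stop("non-positive mean control signal after blank subtraction")
    }
    v <- (v - blank) / ctrl
  }
  sds <- apply(v, 2, sd)
  mns <- colMeans(v)
  cvs <- ifelse(abs(mns) > 0, sds / abs(mns), ifelse(sds > 0, Inf, 0))
  bad <- !is.na(sds) & (sds > qc_threshold | cvs > qc_threshold)
  if (all(bad)) stop("unfittable: all doses discarded by replicate QC")
  out <- exp
  out$doses <- exp$doses[!bad]
  out$viabilities <- v[, !bad, drop = FALSE]
  out$normalized <- TRUE
  out$n_discarded <- exp$n_discarded + sum(bad)
  if (length(out$doses) < 2) stop("unfittable: fewer than two doses left")
  out
}

#' Fit a three-parameter Hill (log-logistic) curve
#'
#' Least-squares fit of `v(d) = e_inf + (1 - e_inf)/(1 + (d/ec50)^slope)`
#' on the log10-dose axis, with viabilities clipped to `[0, 1.2]` to
#' tolerate modest over-growth.  The optimizer is bounded (L-BFGS-B) and
#' multi-started over a fixed grid of initial values (`ec50` at the lowest,
#' middle, and highest dose; `slope` in 0.5/1/2; `e_inf` in 0/0.5); the
#' start with the smallest residual sum of squares wins, ties broken by the
#' smallest slope.  Deterministic for a fixed input.
#'
#' @param exp a [dose_response_experiment()]; raw experiments with control
#'   wells are passed through [preprocess_srb()] first.
#' @param qc_threshold replicate QC cutoff forwarded to [preprocess_srb()].
#' @return An object of class `HillFit`: list with `ec50`, `slope`, `e_inf`,
#'   `residual_sse`, `converged`, `dose_range`.
#' @export
fit_hill <- function(exp, qc_threshold = 0.2) {
  stopifnot(inherits(exp, "DoseResponseExperiment"))
  if (!exp$normalized) exp <- preprocess_srb(exp, qc_threshold)
  if (length(exp$doses) < 3) stop("need at least three usable doses")
  d <- rep(exp$doses, each = nrow(exp$viabilities))
  y <- pmin(pmax(as.vector(exp$viabilities), 0), 1.2)
  ld <- log10(d)
  lo <- c(log10(min(exp$doses)) - 3, log(0.05), 0)
  hi <- c(log10(max(exp$doses)) + 3, log(20), 1)
  sse <- function(th) {
    # th = (log10 ec50, log slope, e_inf); (d/ec50)^slope on log10 axis
    f <- th[3] + (1 - th[3]) / (1 + 10^(base::exp(th[2]) * (ld - th[1])))
    sum((y - f)^2)
  }
  starts <- expand.grid(
    l10ec50 = log10(c(min(exp$doses),
                      exp$doses[ceiling(length(exp$doses) / 2)],
                      max(exp$doses))),
    lslope = log(c(0.5, 1, 2)), e_inf = c(0, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
            lower = lo, upper = hi,
            control = list(maxit = 500, factr = 1e2, pgtol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("Hill fit diverged at all starts")
  structure(
    list(ec50 = 10^best$par[1], slope = base::exp(best$par[2]),
         e_inf = best$par[3], residual_sse = best$value,
         converged = best$convergence == 0,
         dose_range = range(exp$doses)),
    class = "HillFit")
}

#' @export
print.HillFit <- function(x, ...) {
  cat(sprintf(
    "HillFit: ec50 = %.4g, slope = %.3f, e_inf = %.3f (SSE %.3g%s)\n",
    x$ec50, x$slope, x$e_inf, x$residual_sse,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Predict viability from a Hill fit
#'
#' @param object a `HillFit`.
#' @param doses concentrations at which to evaluate the fitted curve.
#' @param ... ignored.
#' @return Numeric vector of fitted viabilities.
#' @export
predict.HillFit <- function(object, doses, ...) {
  .hill_viability(doses, object$ec50, object$slope, object$e_inf)
}

#' Area above the dose-response curve
#'
#' AUC is the mean of the fitted viability (clipped to `[0,1]`) over the
#' log10-dose interval, computed by a composite trapezoidal rule with at
#' least 1000 points; AAC = 1 - AUC, clipped to `[0,1]`, so higher AAC means
#' higher drug sensitivity.
#'
#' @param fit a `HillFit` (or any list with `ec50`, `slope`, `e_inf`).
#' @param dose_range length-2 positive vector `(d_min, d_max)`; defaults to
#'   the tested dose range stored in the fit.
#' @param n_points number of grid points (>= 1000 enforced).
#' @return AAC in `[0,1]`.
#' @export
compute_aac <- function(fit, dose_range = NULL, n_points = 1001) {
  dose_range <- dose_range %||% fit$dose_range
  if (is.null(dose_range) || length(dose_range) != 2 ||
      any(dose_range <= 0) || dose_range[1] >= dose_range[2]) {
    stop("invalid dose range")
  }
  n_points <- max(as.integer(n_points), 1000L)
  x <- seq(log10(dose_range[1]), log10(dose_range[2]),
           length.out = n_points)
  v <- .clamp01(.hill_viability(10^x, fit$ec50, fit$slope, fit$e_inf))
  dx <- diff(x)
  auc <- sum((v[-1] + v[-n_points]) / 2 * dx) / (x[n_points] - x[1])
  .clamp01(1 - auc)
}

#' Summarize a plate into an AAC value
#'
#' Convenience wrapper: SRB preprocessing (when requested), Hill fit, and
#' AAC over the tested dose range.
#'
#' @param exp a [dose_response_experiment()].
#' @param qc apply the replicate SD/CV filter.
#' @param qc_threshold replicate QC cutoff.
#' @return List with `fit` (`HillFit`), `aac`, `n_discarded`.
#' @export
summarize_plate <- function(exp, qc = TRUE, qc_threshold = 0.2) {
  if (!exp$normalized) {
    exp <- preprocess_srb(exp, qc_threshold = if (qc) qc_threshold else Inf)
  } else if (qc) {
    exp <- preprocess_srb(exp, qc_threshold)
  }
  fit <- fit_hill(exp)
  list(fit = fit, aac = compute_aac(fit), n_discarded = exp$n_discarded)
}
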