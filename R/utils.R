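# shared internal helpers

.clamp01 <- function(x) pmin(1, pmax(0, x))

# Deterministic, platform-stable substream seed derived from a base seed and
# a text label.  Keeps results reproducible when several independent random
# streams (expression, per-study sensitivity noise, bootstrap draws) are
# derived from one user-facing seed.  Always < 2^31.
.substream_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * ((seq_along(v) - 1L) %% 31L + 1L)) %% 1048573
  as.integer((abs(as.numeric(seed)) %% 1e9 * 7919 + h * 2039 + 17) %% 2147483629)
}

# Tissue labels -> factor with singleton tissues merged into "other" and the
# most frequent tissue as reference level.
.tissue_factor <- function(x) {
  f <- factor(as.character(x))
  if (nlevels(f) > 1L) {
    tab <- table(f)
    if (any(tab == 1L)) {
      lv <- levels(f)
      lv[lv %in% names(tab)[tab == 1L]] <- "other"
      levels(f) <- lv
    }
  }
  tab <- table(f)
  relevel(f, ref = names(tab)[which.max(tab)])
}

# Design matrix for the tissue-only null model (intercept if single tissue).
.tissue_design <- function(f) {
  n <- length(f)
  if (nlevels(f) <= 1L) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(~f)
  }
}

.standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
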