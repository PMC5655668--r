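#' Configure a synthetic pharmacogenomic simulation
#'
#' Defines a fully synthetic multi-study pharmacogenomic dataset: expression
#' on the log2(FPKM+1) scale for genes carrying one or more correlated
#' isoforms, tissue-structured baselines, and drug sensitivity (AAC) driven
#' by planted linear effects of designated features plus noise.  The seed
#' fully determines every downstream draw.
#'
#' @param n_cell_lines number of cell lines (>= `n_tissues`).
#' @param n_tissues number of tissue-of-origin groups (>= 1).
#' @param n_genes number of genes.
#' @param isoform_probs probability of a gene carrying 1, 2, ... isoforms;
#'   length gives the maximum isoform count.
#' @param planted_effects `NULL` or a data.frame with columns `gene`
#'   (a gene id such as `"g0001"` or an integer index), `beta` (effect size
#'   in standardized units) and `mode` (one of `"gene_level"`,
#'   `"isoform_specific"`, `"both"`).  For `isoform_specific` the first
#'   isoform of the gene carries the signal while high-expressed sibling
#'   isoforms are independent noise, so gene-level FPKM aggregation dilutes
#'   it; for `"both"` the gene is forced to a single isoform so gene and
#'   isoform coincide.
#' @param noise_sd standard deviation of the per-study sensitivity noise
#'   added to the linear predictor (ignored when `inter_study_rho` is set).
#' @param inter_study_rho optional target Spearman correlation in `[0,1]`
#'   between the AAC vectors of two study replicates; when given, the
#'   per-study noise is calibrated to reach it.
#' @param expression_noise_sd scale of cell-level expression variation
#'   (log2 units).
#' @param isoform_cor within-gene correlation of non-signal isoforms.
#' @param aac_center,aac_scale affine map from the linear predictor to AAC,
#'   clamped to `[0,1]`.
#' @param seed integer random seed.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cell_lines = 100, n_tissues = 4,
                              n_genes = 100,
                              isoform_probs = c(0.45, 0.35, 0.20),
                              planted_effects = NULL,
                              noise_sd = 0.3, inter_study_rho = NULL,
                              expression_noise_sd = 1, isoform_cor = 0.3,
                              aac_center = 0.5, aac_scale = 0.15,
                              seed = 1L) {
  stopifnot(n_cell_lines >= 1, n_tissues >= 1, n_genes >= 1,
            n_cell_lines >= n_tissues,
            all(isoform_probs >= 0), sum(isoform_probs) > 0,
            noise_sd >= 0, expression_noise_sd >= 0,
            isoform_cor >= 0, isoform_cor < 1)
  if (!is.null(inter_study_rho)) {
    stopifnot(length(inter_study_rho) == 1,
              inter_study_rho >= 0, inter_study_rho <= 1)
  }
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("gene", "beta", "mode") %in% names(planted_effects)),
              all(is.finite(planted_effects$beta)),
              all(planted_effects$mode %in%
                    c("gene_level", "isoform_specific", "both")))
    if (is.numeric(planted_effects$gene)) {
      stopifnot(all(planted_effects$gene >= 1),
                all(planted_effects$gene <= n_genes))
      planted_effects$gene <- sprintf("g%04d", planted_effects$gene)
    }
    if (anyDuplicated(planted_effects$gene)) {
      stop("at most one planted effect per gene")
    }
  }
  structure(
    list(n_cell_lines = as.integer(n_cell_lines),
         n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
         isoform_probs = isoform_probs / sum(isoform_probs),
         planted_effects = planted_effects, noise_sd = noise_sd,
         inter_study_rho = inter_study_rho,
         expression_noise_sd = expression_noise_sd,
         isoform_cor = isoform_cor, aac_center = aac_center,
         aac_scale = aac_scale, seed = as.integer(seed)),
    class = "SimulationConfig")
}

# designated feature carrying each planted effect (internal)
.planted_features <- function(config) {
  pe <- config$planted_effects
  if (is.null(pe) || nrow(pe) == 0) {
    return(data.frame(gene_id = character(), feature_id = character(),
                      level = character(), beta = numeric(),
                      mode = character(), stringsAsFactors = FALSE))
  }
  level <- ifelse(pe$mode == "isoform_specific", "isoform", "gene")
  feature <- ifelse(pe$mode == "isoform_specific",
                    paste0(pe$gene, ".t1"), pe$gene)
  data.frame(gene_id = pe$gene, feature_id = feature, level = level,
             beta = pe$beta, mode = pe$mode, stringsAsFactors = FALSE)
}

#' Simulate an expression dataset
#'
#' Draws isoform expression on the log2(FPKM+1) scale (clamped at zero) with
#' tissue-structured baselines shared by a gene's isoforms, a within-gene
#' shared factor inducing the configured isoform correlation, and
#' independent idiosyncratic noise.  The gene matrix is computed from the
#' isoform matrix by FPKM summation ([aggregate_isoforms()]).  For planted
#' `isoform_specific` effects the signal isoform is generated independently
#' of its siblings and at a lower baseline (mean log2 expression 3 versus 6
#' for at least two siblings), so gene-level aggregation dilutes the signal.
#'
#' @param config a [simulation_config()].
#' @return An [expression_dataset()] with a `truth` attribute: a data.frame
#'   of planted (gene_id, feature_id, level, beta, mode).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.substream_seed(config$seed, "expression"))
  n <- config$n_cell_lines
  cells <- sprintf("cl%04d", seq_len(n))
  tissue_names <- sprintf("tissue%02d", seq_len(config$n_tissues))
  tissues <- setNames(sample(rep_len(tissue_names, n)), cells)
  tiss_idx <- match(tissues, tissue_names)

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  k_max <- length(config$isoform_probs)
  k <- sample.int(k_max, config$n_genes, replace = TRUE,
                  prob = config$isoform_probs)
  names(k) <- genes

  pe <- config$planted_effects
  iso_mode <- gene_mode <- character(0)
  if (!is.null(pe)) {
    iso_mode <- pe$gene[pe$mode == "isoform_specific"]
    gene_mode <- pe$gene[pe$mode == "both"]
    k[iso_mode] <- pmax(k[iso_mode], 3L)   # signal isoform + >= 2 siblings
    k[gene_mode] <- 1L                     # gene == isoform
  }

  w0 <- sqrt(config$isoform_cor)
  rows <- vector("list", config$n_genes)
  ids <- vector("list", config$n_genes)
  for (g in seq_along(genes)) {
    kg <- k[g]
    tbase <- rnorm(config$n_tissues)          # tissue-structured baseline
    shared <- rnorm(n)                        # within-gene shared factor
    mus <- runif(kg, 2, 6)
    w <- rep(w0, kg)
    if (genes[g] %in% iso_mode) {
      w[1] <- 0                               # signal isoform independent
      mus <- c(3, pmax(mus[-1], 6))           # share-diluting siblings
    }
    vals <- matrix(0, kg, n)
    for (i in seq_len(kg)) {
      eps <- rnorm(n)
      vals[i, ] <- mus[i] + tbase[tiss_idx] +
        config$expression_noise_sd * (w[i] * shared + sqrt(1 - w[i]^2) * eps)
    }
    rows[[g]] <- pmax(vals, 0)
    ids[[g]] <- paste0(genes[g], ".t", seq_len(kg))
  }
  iso <- do.call(rbind, rows)
  rownames(iso) <- unlist(ids)
  colnames(iso) <- cells
  map <- data.frame(isoform_id = rownames(iso),
                    gene_id = rep(genes, k), stringsAsFactors = FALSE)
  out <- expression_dataset(iso, map, tissues)
  attr(out, "truth") <- .planted_features(config)
  out
}

#' Simulate drug sensitivity (AAC) for one study
#'
#' The linear predictor is a tissue effect (i.i.d. standard normal per
#' tissue, shared across studies) plus the sum of planted effects times the
#' standardized designated feature, plus per-study Gaussian noise; AAC is a
#' clamped affine map of the predictor onto `[0,1]`.  Two calls with
#' different `study_id` share the signal and draw independent noise.  When
#' `inter_study_rho` is set, the per-study noise standard deviation is
#' calibrated so the Spearman correlation of the two study AAC vectors
#' approaches the target; otherwise `noise_sd` is used directly.
#'
#' @param expr an [expression_dataset()] produced by [simulate_expression()].
#' @param config the same [simulation_config()].
#' @param study_id study label; determines the noise substream.
#' @param drug drug label.
#' @return A [sensitivity_table()] with one row per cell line.
#' @export
simulate_sensitivity <- function(expr, config, study_id = "study1",
                                 drug = "drug1") {
  stopifnot(inherits(expr, "ExpressionDataset"),
            inherits(config, "SimulationConfig"))
  cells <- colnames(expr$isoform_matrix)
  n <- length(cells)
  tissue_names <- sort(unique(expr$tissues))
  tiss_idx <- match(expr$tissues, tissue_names)

  pf <- .planted_features(config)
  for (i in seq_len(nrow(pf))) {
    m <- if (pf$level[i] == "gene") expr$gene_matrix else expr$isoform_matrix
    if (!pf$feature_id[i] %in% rownames(m)) {
      stop(sprintf("unknown planted feature '%s'", pf$feature_id[i]))
    }
  }

  set.seed(.substream_seed(config$seed, paste0("signal:", drug)))
  tissue_eff <- rnorm(length(tissue_names))
  L <- tissue_eff[tiss_idx]
  for (i in seq_len(nrow(pf))) {
    z <- .standardize(.feature_values(expr, pf$feature_id[i], pf$level[i]))
    L <- L + pf$beta[i] * z
  }

  if (is.null(config$inter_study_rho)) {
    sig <- config$noise_sd
  } else {
    # Gaussian rank-correlation inversion: Pearson r giving Spearman rho
    r <- 2 * sin(pi * config$inter_study_rho / 6)
    sL <- sd(L)
    if (r >= 1 - 1e-12 || sL == 0) {
      sig <- 0
    } else {
      r <- max(r, 1e-6)
      sig <- sL * sqrt((1 - r) / r)
    }
  }
  set.seed(.substream_seed(config$seed,
                           paste0("noise:", drug, ":", study_id)))
  noise <- rnorm(n, 0, sig)
  aac <- .clamp01(config$aac_center + config$aac_scale * (L + noise))
  sensitivity_table(cells, drug, aac, study_id)
}

#' Simulate a multi-study synthetic dataset
#'
#' One expression profile (as when a single RNA-seq resource is paired with
#' several drug screens) plus one sensitivity table per study, all from one
#' config.
#'
#' @param config a [simulation_config()].
#' @param study_ids character vector of study labels.
#' @param drug drug label.
#' @return List with `expression` (an `ExpressionDataset`), `sensitivity`
#'   (a `SensitivityTable` stacking all studies), and `truth` (planted
#'   features).
#' @export
simulate_study <- function(config, study_ids = c("study1", "study2"),
                           drug = "drug1") {
  expr <- simulate_expression(config)
  sens <- do.call(rbind, lapply(study_ids, function(s) {
    simulate_sensitivity(expr, config, study_id = s, drug = drug)
  }))
  class(sens) <- c("SensitivityTable", "data.frame")
  list(expression = expr, sensitivity = sens, truth = attr(expr, "truth"))
}

#' Simulate a dose-response plate
#'
#' Generates raw well signals around a Hill curve, with replicate noise of a
#' given coefficient of variation, plus untreated control wells and
#' cell-free blank wells, so the full SRB preprocessing path (blank
#' subtraction, control normalization, replicate QC) can be exercised.
#'
#' @param hill_params list with `ec50` (concentration), `slope` (>0) and
#'   `e_inf` (lower viability asymptote in `[0,1]`).
#' @param dose_grid positive, strictly increasing concentrations.
#' @param replicate_cv coefficient of variation of replicate noise; 0 puts
#'   replicates exactly on the curve.
#' @param n_replicates replicates per dose.
#' @param blank_signal mean raw signal of cell-free wells.
#' @param signal_scale raw signal corresponding to viability 1.
#' @param cell_line,drug identifiers carried through.
#' @param seed integer seed.
#' @return A [dose_response_experiment()] with raw (unnormalized) signals.
#' @export
simulate_plates <- function(hill_params, dose_grid, replicate_cv = 0.05,
                            n_replicates = 3, blank_signal = 0.1,
                            signal_scale = 1, cell_line = "cl0001",
                            drug = "drug1", seed = 1L) {
  stopifnot(all(dose_grid > 0))
  if (any(diff(dose_grid) <= 0)) stop("doses must be strictly increasing")
  stopifnot(replicate_cv >= 0, n_replicates >= 1)
  set.seed(.substream_seed(seed, paste0("plate:", cell_line, ":", drug)))
  v <- .hill_viability(dose_grid, hill_params$ec50, hill_params$slope,
                       hill_params$e_inf)
  noise <- function(m) m * (1 + replicate_cv * rnorm(length(m)))
  treated <- matrix(rep(v, each = n_replicates), n_replicates,
                    length(dose_grid))
  treated <- blank_signal + signal_scale * noise(treated)
  controls <- blank_signal + signal_scale * noise(rep(1, n_replicates * 2))
  blanks <- noise(rep(blank_signal, n_replicates * 2))
  dose_response_experiment(dose_grid, treated, cell_line = cell_line,
                           drug = drug, control_wells = controls,
                           blank_wells = blanks)
}
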