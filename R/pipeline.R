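#' Pipeline run configuration
#'
#' Validates paths and thresholds for an end-to-end run
#' (load or simulate -> identity filter -> discover -> optionally
#' pre-validate and validate) before any computation starts.
#'
#' @param expression_dir directory of training expression TSVs
#'   (see [read_expression_dataset()]).
#' @param sensitivity_paths named character vector of per-study AAC TSV
#'   paths (names are study identifiers); one study is accepted, exactly
#'   two are required for meta-combination.
#' @param out_dir output directory.
#' @param drugs drugs to analyze; `NULL` means every drug shared by all
#'   training studies.
#' @param identity_path optional TSV with `cell_line`, `concordance` for
#'   the cross-study identity filter.
#' @param validation_expression_dir,validation_sensitivity_path optional
#'   independent validation dataset.
#' @param prevalidation_tissue optional tissue label; when set, candidates
#'   are pre-selected on the tissue-restricted training data before
#'   validation, and the validation fit drops the tissue covariate.
#' @param fdr_threshold,ci_threshold,alpha,qc_threshold,identity_cutoff
#'   pipeline thresholds.
#' @param n_boot,seed bootstrap plan.
#' @param n_min minimum cell lines per (drug, study) fit.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(expression_dir, sensitivity_paths, out_dir,
                       drugs = NULL, identity_path = NULL,
                       validation_expression_dir = NULL,
                       validation_sensitivity_path = NULL,
                       prevalidation_tissue = NULL,
                       fdr_threshold = 0.01, ci_threshold = 0.55,
                       alpha = 0.05, qc_threshold = 0.2,
                       identity_cutoff = 0.80, n_boot = 100,
                       seed = 1234L, n_min = 20) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            ci_threshold >= 0, ci_threshold < 1,
            alpha > 0, alpha < 1, qc_threshold > 0,
            identity_cutoff >= 0, identity_cutoff <= 1,
            n_boot >= 2, n_min >= 3)
  if (is.null(names(sensitivity_paths)) ||
      any(names(sensitivity_paths) == "")) {
    stop("sensitivity_paths must be named by study identifier")
  }
  if (length(sensitivity_paths) > 2) {
    stop("at most two training studies are supported")
  }
  paths <- c(file.path(expression_dir, "isoforms.tsv"),
             unname(sensitivity_paths), identity_path,
             validation_sensitivity_path,
             if (!is.null(validation_expression_dir))
               file.path(validation_expression_dir, "isoforms.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input files: ", paste(missing, collapse = ", "))
  }
  structure(
    list(expression_dir = expression_dir,
         sensitivity_paths = sensitivity_paths, out_dir = out_dir,
         drugs = drugs, identity_path = identity_path,
         validation_expression_dir = validation_expression_dir,
         validation_sensitivity_path = validation_sensitivity_path,
         prevalidation_tissue = prevalidation_tissue,
         fdr_threshold = fdr_threshold, ci_threshold = ci_threshold,
         alpha = alpha, qc_threshold = qc_threshold,
         identity_cutoff = identity_cutoff,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         n_min = as.integer(n_min)),
    class = "RunConfig")
}

#' Filter cell lines by cross-study identity concordance
#'
#' Removes from every study the cell lines whose identity concordance
#' across studies falls below the cutoff (the boundary is inclusive: a
#' concordance equal to the cutoff is retained), then restricts all studies
#' to the shared cell lines and drugs.  Identity fingerprinting itself is
#' upstream; this consumes its concordance table.
#'
#' @param study_tables list of [sensitivity_table()]s, one per study.
#' @param identity_table data.frame with `cell_line`, `concordance` in
#'   `[0,1]`; cell lines absent from the table are retained.
#' @param cutoff concordance cutoff (default 0.80).
#' @return List of filtered `SensitivityTable`s in the same order.
#' @export
filter_shared_cell_lines <- function(study_tables, identity_table = NULL,
                                     cutoff = 0.80) {
  stopifnot(length(study_tables) >= 1)
  if (!is.null(identity_table)) {
    stopifnot(all(c("cell_line", "concordance") %in%
                    names(identity_table)))
    drop <- identity_table$cell_line[identity_table$concordance < cutoff]
    study_tables <- lapply(study_tables, function(s) {
      s[!s$cell_line %in% drop, , drop = FALSE]
    })
  }
  shared_cells <- Reduce(intersect, lapply(study_tables,
                                           function(s) s$cell_line))
  shared_drugs <- Reduce(intersect, lapply(study_tables,
                                           function(s) s$drug))
  if (length(shared_cells) == 0 || length(shared_drugs) == 0) {
    stop("empty cell-line/drug intersection across studies")
  }
  lapply(study_tables, function(s) {
    out <- s[s$cell_line %in% shared_cells & s$drug %in% shared_drugs, ,
             drop = FALSE]
    class(out) <- c("SensitivityTable", "data.frame")
    out
  })
}

.stage <- function(name, log, fun) {
  log(sprintf("[%s] start", name))
  res <- tryCatch(fun(), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("[%s] done", name))
  res
}

#' Run the full discovery/validation pipeline
#'
#' Executes the stages in order -- load, identity filter, per-drug
#' discovery, optional tissue pre-selection, optional independent
#' validation -- writing every intermediate table as TSV, a JSON manifest
#' (input hashes, thresholds, seed, per-stage counts, output hashes) and a
#' human-readable log into `config$out_dir`.  Re-running with an identical
#' configuration reproduces byte-identical outputs; the manifest carries no
#' wall-clock information for that reason.  Any stage failure aborts with a
#' stage-named error and leaves a `FAILED` marker next to the partial
#' outputs.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  unlink(c(log_path, file.path(config$out_dir, "FAILED")))
  log <- function(msg) cat(msg, "\n", sep = "", file = log_path,
                           append = TRUE)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(config$out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    expr <- .stage("load", log, function() {
      read_expression_dataset(config$expression_dir)
    })
    tables <- .stage("load", log, function() {
      lapply(names(config$sensitivity_paths), function(s) {
        t <- read_sensitivity(config$sensitivity_paths[[s]])
        if (!all(t$study_id == s)) {
          stop(sprintf("study_id mismatch in '%s'",
                       config$sensitivity_paths[[s]]))
        }
        t
      })
    })
    identity_table <- if (!is.null(config$identity_path)) {
      .read_tsv(config$identity_path)
    }
    tables <- .stage("filter", log, function() {
      filter_shared_cell_lines(tables, identity_table,
                               cutoff = config$identity_cutoff)
    })
    sens <- do.call(rbind, tables)
    class(sens) <- c("SensitivityTable", "data.frame")
    drugs <- config$drugs %||% Reduce(intersect,
                                      lapply(tables, function(t) t$drug))
    plan <- bootstrap_plan(config$n_boot, config$seed)
    calls <- .stage("discover", log, function() {
      do.call(rbind, lapply(drugs, function(d) {
        log(sprintf("  discover: drug %s", d))
        discover_biomarkers(expr, sens, d, plan = plan,
                            fdr_threshold = config$fdr_threshold,
                            ci_threshold = config$ci_threshold,
                            wilcoxon_alpha = config$alpha,
                            n_min = config$n_min)$calls
      }))
    })
    .write_tsv(calls, file.path(config$out_dir, "biomarkers.tsv"))
    skip <- calls[is.na(calls$meta_p_gene) & is.na(calls$meta_p_isoform), ,
                  drop = FALSE]
    .write_tsv(data.frame(gene_id = skip$gene_id, drug = skip$drug,
                          reason = rep("no_evaluable_fit", nrow(skip))),
               file.path(config$out_dir, "skip_report.tsv"))
    candidates <- do.call(rbind, lapply(split(calls, calls$drug),
                                        biomarker_candidates))
    validation <- NULL
    if (!is.null(config$validation_sensitivity_path)) {
      vexpr <- if (!is.null(config$validation_expression_dir)) {
        read_expression_dataset(config$validation_expression_dir)
      } else expr
      vsens <- read_sensitivity(config$validation_sensitivity_path)
      if (!is.null(config$prevalidation_tissue)) {
        candidates <- .stage("prevalidate", log, function() {
          do.call(rbind, lapply(unique(candidates$drug), function(d) {
            preselect_tissue(candidates, expr, sens, d,
                             tissue = config$prevalidation_tissue,
                             ci_threshold = config$ci_threshold,
                             alpha = config$alpha, n_min = config$n_min,
                             plan = plan)
          }))
        })
      }
      rule <- validation_rule(
        alpha = config$alpha,
        tissue_adjusted = is.null(config$prevalidation_tissue))
      validation <- .stage("validate", log, function() {
        validate_biomarkers(candidates, vexpr,
                            vsens[vsens$drug %in% candidates$drug, ,
                                  drop = FALSE],
                            rule = rule)
      })
      .write_tsv(validation, file.path(config$out_dir, "validation.tsv"))
    }
    manifest <- .stage("manifest", log, function() {
      outputs <- list.files(config$out_dir, pattern = "\\.tsv$",
                            full.names = TRUE)
      inputs <- c(file.path(config$expression_dir, "isoforms.tsv"),
                  unname(config$sensitivity_paths))
      list(
        package = "isopharm",
        version = as.character(packageVersion("isopharm")),
        seed = config$seed,
        thresholds = list(fdr = config$fdr_threshold,
                          ci = config$ci_threshold, alpha = config$alpha,
                          qc = config$qc_threshold,
                          identity = config$identity_cutoff,
                          n_min = config$n_min, n_boot = config$n_boot),
        inputs = as.list(setNames(as.vector(tools::md5sum(inputs)),
                                  basename(inputs))),
        outputs = as.list(setNames(as.vector(tools::md5sum(sort(outputs))),
                                   basename(sort(outputs)))),
        counts = list(
          drugs = length(drugs),
          genes = nrow(expr$gene_matrix),
          isoforms = nrow(expr$isoform_matrix),
          cell_lines = length(unique(sens$cell_line)),
          biomarkers = sum(calls$category != "none", na.rm = TRUE),
          candidates = nrow(candidates),
          validated = if (is.null(validation)) NA else
            sum(validation$validated, na.rm = TRUE)))
    })
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = on_fail)
}
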