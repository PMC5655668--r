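# Tab-separated I/O for every table the pipeline consumes or emits.
# All files carry a header row; cell-line identifiers are case-sensitive
# exact-match keys.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

.write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path)
}

.read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an expression dataset as TSV files
#'
#' Writes `isoforms.tsv` and `genes.tsv` (feature x cell-line matrices),
#' `isoform_map.tsv` (`isoform_id`, `gene_id`) and `tissues.tsv`
#' (`cell_line`, `tissue`) into a directory.
#'
#' @param expr an [expression_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_expression_dataset <- function(expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_matrix_tsv(expr$isoform_matrix, file.path(dir, "isoforms.tsv"),
                    "isoform_id")
  .write_matrix_tsv(expr$gene_matrix, file.path(dir, "genes.tsv"),
                    "gene_id")
  .write_tsv(expr$isoform_map, file.path(dir, "isoform_map.tsv"))
  .write_tsv(data.frame(cell_line = names(expr$tissues),
                        tissue = unname(expr$tissues)),
             file.path(dir, "tissues.tsv"))
  invisible(dir)
}

#' Read an expression dataset from TSV files
#'
#' @param dir directory holding the files written by
#'   [write_expression_dataset()] (`genes.tsv` is optional and recomputed
#'   from the isoform matrix when absent).
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(dir) {
  iso <- .read_matrix_tsv(file.path(dir, "isoforms.tsv"))
  map <- .read_tsv(file.path(dir, "isoform_map.tsv"))
  td <- .read_tsv(file.path(dir, "tissues.tsv"))
  gene_path <- file.path(dir, "genes.tsv")
  gm <- if (file.exists(gene_path)) .read_matrix_tsv(gene_path) else NULL
  expression_dataset(iso, map, setNames(td$tissue, td$cell_line),
                     gene_matrix = gm)
}

#' Write / read a sensitivity table
#'
#' @param sens a [sensitivity_table()].
#' @param path TSV path.
#' @return `write_sensitivity` the path invisibly; `read_sensitivity` a
#'   `SensitivityTable`.
#' @export
write_sensitivity <- function(sens, path) .write_tsv(sens, path)

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path) {
  df <- .read_tsv(path)
  sensitivity_table(df$cell_line, df$drug, df$aac, df$study_id)
}

#' Read dose-response plates from a long-format table
#'
#' Expects columns `cell_line`, `drug`, `dose_uM`, `replicate`,
#' `raw_signal`, `well_type` (one of `treated`, `control`, `blank`;
#' control and blank rows may carry any dose).
#'
#' @param path TSV path.
#' @return A list of [dose_response_experiment()]s, one per
#'   (cell line, drug).
#' @export
read_plate_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("cell_line", "drug", "dose_uM", "replicate", "raw_signal",
            "well_type")
  if (!all(need %in% names(df))) {
    stop("plate table needs columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(df[c("cell_line", "drug")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$cell_line == keys$cell_line[i] & df$drug == keys$drug[i], ]
    tr <- d[d$well_type == "treated", ]
    doses <- sort(unique(tr$dose_uM))
    reps <- sort(unique(tr$replicate))
    v <- matrix(NA_real_, length(reps), length(doses))
    v[cbind(match(tr$replicate, reps), match(tr$dose_uM, doses))] <-
      tr$raw_signal
    dose_response_experiment(
      doses, v, cell_line = keys$cell_line[i], drug = keys$drug[i],
      control_wells = d$raw_signal[d$well_type == "control"],
      blank_wells = d$raw_signal[d$well_type == "blank"])
  })
}

#' Write dose-response experiments as a long-format table
#'
#' @param experiments list of [dose_response_experiment()]s with raw
#'   signals.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_plate_table <- function(experiments, path) {
  rows <- lapply(experiments, function(e) {
    nr <- nrow(e$viabilities)
    rbind(
      data.frame(cell_line = e$cell_line, drug = e$drug,
                 dose_uM = rep(e$doses, each = nr),
                 replicate = rep(seq_len(nr), length(e$doses)),
                 raw_signal = as.vector(e$viabilities),
                 well_type = "treated", stringsAsFactors = FALSE),
      if (length(e$control_wells))
        data.frame(cell_line = e$cell_line, drug = e$drug,
                   dose_uM = e$doses[1],
                   replicate = seq_along(e$control_wells),
                   raw_signal = e$control_wells, well_type = "control",
                   stringsAsFactors = FALSE),
      if (length(e$blank_wells))
        data.frame(cell_line = e$cell_line, drug = e$drug,
                   dose_uM = e$doses[1],
                   replicate = seq_along(e$blank_wells),
                   raw_signal = e$blank_wells, well_type = "blank",
                   stringsAsFactors = FALSE))
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' Fit all plates of a study into a sensitivity table
#'
#' SRB preprocessing, Hill fit, and AAC for every experiment.
#'
#' @param experiments list of [dose_response_experiment()]s.
#' @param study_id study label for the output table.
#' @param qc,qc_threshold forwarded to [summarize_plate()].
#' @return A [sensitivity_table()]; unfittable plates are dropped with a
#'   warning.
#' @export
fit_curves <- function(experiments, study_id = "study1", qc = TRUE,
                       qc_threshold = 0.2) {
  rows <- lapply(experiments, function(e) {
    res <- tryCatch(summarize_plate(e, qc = qc,
                                    qc_threshold = qc_threshold),
                    error = function(err) {
                      warning(sprintf("%s / %s dropped: %s", e$cell_line,
                                      e$drug, conditionMessage(err)))
                      NULL
                    })
    if (is.null(res)) return(NULL)
    data.frame(cell_line = e$cell_line, drug = e$drug, aac = res$aac,
               study_id = study_id, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no fittable plates")
  sensitivity_table(df$cell_line, df$drug, df$aac, df$study_id)
}
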