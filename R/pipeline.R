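#' Run the MxIHC proximity pipeline end to end
#'
#' Orchestrates the slide-level analysis: per-slide proximity metrics,
#' per-patient pre/post log2 fold-changes, a paired Wilcoxon signed-rank
#' test per metric (pre vs post), and a Spearman correlation of each
#' metric's fold-change against progression-free survival, per radius.
#' Undefined fold-changes propagate as flagged missing values and are
#' excluded pairwise (logged); a metric whose correlation cannot be computed
#' is reported with the reason rather than failing the run. The run is
#' deterministic given fixed inputs.
#'
#' @param slides Named list of [slide_cell_table()] objects, or a character
#'   vector of cell-table CSV paths (read with `panel`).
#' @param clinical Clinical pair records data.frame, or a CSV path.
#' @param panel Marker panel used when reading CSV paths.
#' @param target_marker,reference_marker Proximity pairing markers.
#' @param radii Radii in microns; `Inf` denotes the any-distance variant.
#' @param pseudocount Passed to [log2_fold_change()] (default 0, off).
#' @param pairing_mode `"cells"` or `"edges"` (see [count_paired_cells()]).
#' @return A list of class `mx_report`: `metrics`, `fold_changes`,
#'   `wilcoxon` (per metric/radius), `spearman_vs_pfs` (per metric/radius),
#'   `log` (defaults and exclusions that fired).
#' @export
run_mxihc_pipeline <- function(slides, clinical,
                               panel = c("SOX10", "CD8"),
                               target_marker = "SOX10",
                               reference_marker = "CD8",
                               radii = c(45, Inf), pseudocount = 0,
                               pairing_mode = "cells") {
  if (is.character(slides)) {
    slides <- lapply(slides, read_cell_table, panel = panel)
    names(slides) <- vapply(slides, function(s) s$slide_id, character(1))
  }
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  needed <- c(clinical$pre_slide_id, clinical$post_slide_id)
  missing_slides <- setdiff(needed, names(slides))
  if (length(missing_slides) > 0L) {
    bad <- clinical$patient_id[clinical$pre_slide_id %in% missing_slides |
                               clinical$post_slide_id %in% missing_slides]
    stop("unresolved slide linkage for patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  metrics <- do.call(rbind, lapply(slides, proximity_metrics,
                                   target_marker = target_marker,
                                   reference_marker = reference_marker,
                                   radii = radii, mode = pairing_mode))
  rownames(metrics) <- NULL
  fc <- fold_change_table(metrics, clinical, pseudocount = pseudocount)

  run_log <- character(0)
  note <- function(fmt, ...) {
    run_log <<- c(run_log, sprintf(fmt, ...))
  }

  keys <- unique(fc[, c("metric", "radius_um")])
  wilcoxon <- list(); spearman_rows <- list()
  for (i in seq_len(nrow(keys))) {
    m <- keys$metric[i]; r <- keys$radius_um[i]
    sub <- fc[fc$metric == m & fc$radius_um == r, ]
    key <- if (r == "-") m else paste0(m, "@", r)

    wres <- tryCatch(wilcoxon_signed_rank(sub$pre_value, sub$post_value),
                     error = function(e) conditionMessage(e))
    if (is.character(wres)) {
      note("wilcoxon %s: degenerate (%s)", key, wres)
      wres <- list(statistic = NA_real_, p_value = NA_real_,
                   n_used = 0L, method = "degenerate")
    }
    wilcoxon[[key]] <- wres

    ok <- is.finite(sub$log2_fc)
    n_excl <- sum(!ok)
    if (n_excl > 0L) {
      note("spearman %s: %d undefined fold-change(s) excluded", key, n_excl)
    }
    sres <- tryCatch(spearman_cor(sub$log2_fc, sub$pfs_months),
                     error = function(e) conditionMessage(e))
    if (is.character(sres)) {
      note("spearman %s: skipped (%s)", key, sres)
      spearman_rows[[key]] <- data.frame(
        metric = m, radius_um = r, rho = NA_real_, p_value = NA_real_,
        n_used = sum(ok), skipped_reason = sres, stringsAsFactors = FALSE)
    } else {
      spearman_rows[[key]] <- data.frame(
        metric = m, radius_um = r, rho = sres$rho, p_value = sres$p_value,
        n_used = sres$n, skipped_reason = "", stringsAsFactors = FALSE)
    }
  }
  spearman_df <- do.call(rbind, spearman_rows)
  rownames(spearman_df) <- NULL
  structure(list(metrics = metrics, fold_changes = fc,
                 wilcoxon = wilcoxon, spearman_vs_pfs = spearman_df,
                 log = run_log),
            class = "mx_report")
}

#' @export
print.mx_report <- function(x, ...) {
  cat(sprintf("<mx_report> %d slides, %d patients\n",
              length(unique(x$metrics$slide_id)),
              length(unique(x$fold_changes$patient_id))))
  cat("Spearman (log2 FC vs PFS):\n")
  print(x$spearman_vs_pfs, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits deterministic artifacts: per-slide metrics TSV, per-patient
#' fold-change TSV, and a JSON report with the test results keyed by the
#' operation that produced them.
#'
#' @param report An `mx_report` from [run_mxihc_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mx_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                       eol = "\n")
  }
  p_metrics <- file.path(dir, "proximity_metrics.tsv")
  p_fc <- file.path(dir, "fold_changes.tsv")
  p_json <- file.path(dir, "report.json")
  write_tsv(report$metrics, p_metrics)
  write_tsv(report$fold_changes, p_fc)
  payload <- list(
    wilcoxon_pre_vs_post = lapply(report$wilcoxon, function(w) {
      list(statistic = w$statistic, p_value = w$p_value,
           n_used = w$n_used, method = w$method)
    }),
    spearman_fc_vs_pfs = report$spearman_vs_pfs,
    log = report$log
  )
  jsonlite::write_json(payload, p_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(metrics = p_metrics, fold_changes = p_fc, report = p_json))
}
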