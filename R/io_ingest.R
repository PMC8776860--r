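#' Construct a slide cell table
#'
#' A slide cell table holds the single-cell segmentation output for one
#' whole-slide MxIHC image: cell centroids in microns, binary marker calls
#' drawn from a declared panel, and a nucleated flag. It is the contract
#' every downstream spatial quantification consumes.
#'
#' @param slide_id Single string identifying the slide.
#' @param cells A data.frame with columns `cell_id` (unique strings), `x_um`,
#'   `y_um` (finite, non-negative centroid coordinates in microns, origin at
#'   the slide top-left with y increasing downward), `nucleated` (logical),
#'   and one logical/0-1 column per panel marker.
#' @param panel Character vector of marker names (e.g.
#'   `c("SOX10", "CD8", "CD11c", "CD40", "CD80")`).
#' @param region_area_mm2 Analyzed tissue area in mm^2. When `NULL` it is
#'   computed as the axis-aligned bounding-box area of all nucleated cells,
#'   with a logged warning, so densities remain computable.
#' @return An object of class `slide_cell_table`.
#' @export
slide_cell_table <- function(slide_id, cells, panel, region_area_mm2 = NULL) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L, nzchar(slide_id))
  stopifnot(is.data.frame(cells))
  required <- c("cell_id", "x_um", "y_um", "nucleated")
  missing_cols <- setdiff(c(required, panel), names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
    stop("duplicate cell_id within slide '", slide_id, "': ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  for (col in c("x_um", "y_um")) {
    if (!is.numeric(cells[[col]]) || anyNA(cells[[col]]) ||
        any(!is.finite(cells[[col]]))) {
      stop("column '", col, "' must be finite numeric", call. = FALSE)
    }
    if (any(cells[[col]] < 0)) {
      stop("column '", col, "' must be non-negative (microns)", call. = FALSE)
    }
  }
  cells$nucleated <- as.logical(cells$nucleated)
  for (m in panel) cells[[m]] <- as.logical(cells[[m]])
  if (is.null(region_area_mm2)) {
    nuc <- cells[cells$nucleated, , drop = FALSE]
    if (nrow(nuc) == 0L) {
      stop("region_area_mm2 absent and no nucleated cells to infer it from",
           call. = FALSE)
    }
    region_area_mm2 <-
      diff(range(nuc$x_um)) * diff(range(nuc$y_um)) / 1e6
    mx_log("slide %s: region_area_mm2 absent; using nucleated bounding box (%.4f mm^2)",
           slide_id, region_area_mm2)
  }
  if (!is.numeric(region_area_mm2) || length(region_area_mm2) != 1L ||
      !is.finite(region_area_mm2) || region_area_mm2 <= 0) {
    stop("region_area_mm2 must be a single positive number", call. = FALSE)
  }
  structure(
    list(slide_id = slide_id,
         cells = cells[, c(required, panel), drop = FALSE],
         panel = panel,
         region_area_mm2 = as.numeric(region_area_mm2)),
    class = "slide_cell_table"
  )
}

#' @export
print.slide_cell_table <- function(x, ...) {
  cat(sprintf("<slide_cell_table> %s: %d cells (%d nucleated), %.4f mm^2\n",
              x$slide_id, nrow(x$cells), sum(x$cells$nucleated),
              x$region_area_mm2))
  for (m in x$panel) {
    cat(sprintf("  %-6s %d+\n", m, sum(x$cells[[m]])))
  }
  invisible(x)
}

#' Read a cell-centroid CSV for one slide
#'
#' Expects header columns `slide_id,cell_id,x_um,y_um,nucleated` plus one
#' 0/1 column per panel marker. Unknown columns are ignored with a logged
#' warning. Coordinates may be rescaled at read time with
#' `microns_per_pixel` when the upstream segmentation emitted pixels.
#'
#' @param path Path to the CSV file.
#' @param panel Character vector of expected marker column names.
#' @param microns_per_pixel Scalar applied to both coordinates (default 1).
#' @param region_area_mm2 Optional known tissue area; if the CSV carries a
#'   constant `region_area_mm2` column that value is used instead.
#' @return A [slide_cell_table()].
#' @export
read_cell_table <- function(path, panel, microns_per_pixel = 1,
                            region_area_mm2 = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("slide_id", "cell_id", "x_um", "y_um", "nucleated")
  missing_cols <- setdiff(c(required, panel), names(df))
  if (length(missing_cols) > 0L) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, panel, "region_area_mm2"))
  if (length(extra) > 0L) {
    mx_log("%s: ignoring unknown column(s): %s", basename(path),
           paste(extra, collapse = ", "))
  }
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop("'", path, "' line ", bad[1] + 1L, ": non-numeric ", col,
           " value '", df[[col]][bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- v * microns_per_pixel
  }
  sid <- unique(df$slide_id)
  if (length(sid) != 1L) {
    stop("'", path, "' contains ", length(sid),
         " slide_id values; one slide per file expected", call. = FALSE)
  }
  if (is.null(region_area_mm2) && "region_area_mm2" %in% names(df)) {
    region_area_mm2 <- unique(df$region_area_mm2)
    if (length(region_area_mm2) != 1L) {
      stop("'", path, "': region_area_mm2 column is not constant",
           call. = FALSE)
    }
  }
  slide_cell_table(as.character(sid),
                   df[, c("cell_id", "x_um", "y_um", "nucleated", panel)],
                   panel, region_area_mm2)
}

#' Write a slide cell table to CSV
#'
#' Writer is the inverse of [read_cell_table()]: canonical column order,
#' UTF-8, LF line endings, deterministic output.
#'
#' @param table A [slide_cell_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "slide_cell_table"))
  out <- data.frame(slide_id = table$slide_id, table$cells,
                    region_area_mm2 = table$region_area_mm2,
                    check.names = FALSE)
  for (m in table$panel) out[[m]] <- as.integer(out[[m]])
  out$nucleated <- as.integer(out$nucleated)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a pre/post clinical linkage table
#'
#' One row per patient: the pre-treatment and at-progression slide ids,
#' progression-free survival in months, and event/therapy flags.
#'
#' @param path CSV with columns
#'   `patient_id,pre_slide_id,post_slide_id,pfs_months,progression_event`
#'   and optionally `prior_immunotherapy`.
#' @return A data.frame of validated patient pair records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "pre_slide_id", "post_slide_id",
                "pfs_months", "progression_event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("prior_immunotherapy" %in% names(df))) df$prior_immunotherapy <- FALSE
  validate_clinical_table(df[, c(required, "prior_immunotherapy")])
}

validate_clinical_table <- function(df) {
  df$pfs_months <- as.numeric(df$pfs_months)
  if (anyNA(df$pfs_months) || any(!is.finite(df$pfs_months))) {
    stop("pfs_months must be finite", call. = FALSE)
  }
  if (any(df$pfs_months < 0)) {
    stop("pfs_months must be >= 0 (got ",
         min(df$pfs_months), ")", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  if (any(df$pre_slide_id == df$post_slide_id)) {
    stop("pre and post slide ids must be distinct per patient", call. = FALSE)
  }
  df$progression_event <- as.logical(df$progression_event)
  df$prior_immunotherapy <- as.logical(df$prior_immunotherapy)
  df
}

#' Write a clinical linkage table to CSV
#' @param clinical Data.frame from [read_clinical_table()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  cols <- c("patient_id", "pre_slide_id", "post_slide_id", "pfs_months",
            "progression_event", "prior_immunotherapy")
  out <- clinical[, cols]
  out$progression_event <- as.integer(out$progression_event)
  out$prior_immunotherapy <- as.integer(out$prior_immunotherapy)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Map AJCC stage strings to the early/late/excluded grouping
#'
#' Sub-stages IA..IIC map to early (I+II), IIIA..IV to late (III+IV);
#' "Stage 0" and "Stage I/II NOS" are excluded, as is any string that cannot
#' be parsed (with a warning). The mapping is total: every input yields
#' exactly one of `early`, `late`, `excluded`; `NA` input maps to excluded.
#'
#' @param stage Character vector of stage annotations
#'   (e.g. `"Stage IIIC"`, `"STAGE IA"`).
#' @return Character vector over `{"early","late","excluded"}`.
#' @export
map_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  out <- rep("excluded", length(s))
  early <- c("I", "IA", "IB", "II", "IIA", "IIB", "IIC")
  late <- c("III", "IIIA", "IIIB", "IIIC", "IV")
  out[s %in% early] <- "early"
  out[s %in% late] <- "late"
  known_excluded <- c("0", "I/II NOS")
  unparsed <- !(s %in% c(early, late, known_excluded)) & !is.na(s)
  if (any(unparsed)) {
    warning("unparseable stage string(s) mapped to 'excluded': ",
            paste(unique(s[unparsed]), collapse = ", "), call. = FALSE)
  }
  out
}

read_cbioportal_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a cBioPortal-style melanoma cohort (clinical + expression)
#'
#' Joins a clinical TSV (patient id, OS months/status, AJCC stage, sex,
#' optionally a precomputed immune score) with a genes-by-samples expression
#' TSV, maps stages via [map_stage()], and attaches per-gene z-scores. When
#' the expression matrix holds raw expression, z-scores are computed as
#' (x - mean) / sd over the joined samples; when it is already a z-score
#' matrix set `expression_is_zscore = TRUE` to pass values through.
#'
#' The returned table is unfiltered; apply [filter_tcga_cohort()] before
#' survival modelling.
#'
#' @param clinical_path TSV with columns `PATIENT_ID`, `OS_MONTHS`,
#'   `OS_STATUS` (e.g. "1:DECEASED"/"0:LIVING" or 0/1), `AJCC_STAGE`, `SEX`,
#'   optional `IMMUNE_SCORE`. Lines starting with `#` are skipped.
#' @param expression_path TSV: first column `Hugo_Symbol`, remaining columns
#'   one per sample/patient id.
#' @param z_genes Genes whose z-scores become `<gene>_z` columns
#'   (lower-cased), default SOX10 and MLANA.
#' @param expr_genes Genes carried through as raw `expr_<GENE>` columns.
#' @param expression_is_zscore Declare the matrix already z-scored.
#' @return A cohort data.frame with columns `patient_id, os_months, os_event,
#'   stage_group, sex, immune_score, sox10_z, mlana_z, cd8a_expr` and one
#'   `expr_<GENE>` column per requested gene.
#' @export
read_tcga_cohort <- function(clinical_path, expression_path,
                             z_genes = c("SOX10", "MLANA"),
                             expr_genes = c("CD8A", "PDCD1", "CD274",
                                            "IFNG", "GZMB"),
                             expression_is_zscore = FALSE) {
  clin <- read_cbioportal_tsv(clinical_path)
  need <- c("PATIENT_ID", "OS_MONTHS", "OS_STATUS", "AJCC_STAGE", "SEX")
  missing_cols <- setdiff(need, names(clin))
  if (length(missing_cols) > 0L) {
    stop("clinical file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  expr <- read_cbioportal_tsv(expression_path)
  if (!("Hugo_Symbol" %in% names(expr))) {
    stop("expression file missing 'Hugo_Symbol' column", call. = FALSE)
  }
  genes <- unique(c(z_genes, expr_genes))
  missing_genes <- setdiff(genes, expr$Hugo_Symbol)
  if (length(missing_genes) > 0L) {
    stop("expression matrix missing gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(expr), "Hugo_Symbol")
  shared <- intersect(clin$PATIENT_ID, samples)
  if (length(shared) == 0L) {
    stop(sprintf(
      "no shared sample ids: %d clinical vs %d expression samples",
      nrow(clin), length(samples)), call. = FALSE)
  }
  dropped <- nrow(clin) - length(shared)
  if (dropped > 0L) {
    mx_log("cohort join: %d clinical rows without expression dropped (%d kept)",
           dropped, length(shared))
  }
  clin <- clin[match(shared, clin$PATIENT_ID), ]

  emat <- as.matrix(expr[match(genes, expr$Hugo_Symbol), shared, drop = FALSE])
  rownames(emat) <- genes
  storage.mode(emat) <- "double"

  zscore <- function(x, gene) {
    if (expression_is_zscore) return(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("gene ", gene, " is constant across samples; z-score undefined",
           call. = FALSE)
    }
    (x - mean(x)) / s
  }
  os_event <- parse_os_status(clin$OS_STATUS)
  out <- data.frame(
    patient_id = clin$PATIENT_ID,
    os_months = suppressWarnings(as.numeric(clin$OS_MONTHS)),
    os_event = os_event,
    stage_group = map_stage(clin$AJCC_STAGE),
    sex = tolower(clin$SEX),
    immune_score = if ("IMMUNE_SCORE" %in% names(clin)) {
      as.numeric(clin$IMMUNE_SCORE)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  for (g in z_genes) {
    out[[paste0(tolower(g), "_z")]] <- zscore(emat[g, ], g)
  }
  out$cd8a_expr <- emat["CD8A", ]
  for (g in expr_genes) out[[paste0("expr_", g)]] <- emat[g, ]
  out
}

parse_os_status <- function(x) {
  s <- toupper(trimws(as.character(x)))
  ev <- rep(NA, length(s))
  ev[grepl("DECEASED|^1", s)] <- TRUE
  ev[grepl("LIVING|^0", s)] <- FALSE
  ev[s %in% c("", "NA", "[NOT AVAILABLE]")] <- NA
  ev
}
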