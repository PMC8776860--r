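marker_coords <- function(slide, marker) {
  stopifnot(inherits(slide, "slide_cell_table"))
  if (!(marker %in% slide$panel)) {
    stop("marker '", marker, "' is not in the slide panel (",
         paste(slide$panel, collapse = ", "), ")", call. = FALSE)
  }
  keep <- slide$cells[[marker]]
  cbind(slide$cells$x_um[keep], slide$cells$y_um[keep])
}

#' Marker-positive cell density (cells per mm^2)
#'
#' @param slide A [slide_cell_table()].
#' @param marker Panel marker name.
#' @return Cells per square millimetre; `density * region_area_mm2`
#'   reconstructs the integer count exactly.
#' @export
cell_density <- function(slide, marker) {
  nrow(marker_coords(slide, marker)) / slide$region_area_mm2
}

#' Marker frequency as percent of nucleated cells
#'
#' 100 * (# nucleated marker-positive cells) / (# nucleated cells), the
#' "frequency (%) normalized to the count of all nucleated cells" readout.
#'
#' @inheritParams cell_density
#' @return Percentage in [0, 100].
#' @export
marker_frequency <- function(slide, marker) {
  if (!(marker %in% slide$panel)) {
    stop("marker '", marker, "' is not in the slide panel", call. = FALSE)
  }
  nuc <- slide$cells$nucleated
  if (!any(nuc)) {
    stop("slide ", slide$slide_id,
         ": no nucleated cells; frequency undefined", call. = FALSE)
  }
  100 * sum(slide$cells[[marker]] & nuc) / sum(nuc)
}

# Fixed-radius neighbor existence via a uniform grid of bucket size r.
# For each target point only the 3x3 neighborhood of its bucket can contain
# a reference point within distance r. Squared distances are compared so
# boundary ties at exactly d == r are resolved without sqrt rounding.
grid_has_neighbor <- function(tx, ty, rx, ry, radius) {
  n_t <- length(tx)
  if (n_t == 0L) return(logical(0))
  if (length(rx) == 0L) return(rep(FALSE, n_t))
  r2 <- radius * radius
  x0 <- min(tx, rx); y0 <- min(ty, ry)
  gx_r <- floor((rx - x0) / radius)
  gy_r <- floor((ry - y0) / radius)
  key_r <- paste(gx_r, gy_r, sep = ",")
  buckets <- split(seq_along(rx), key_r)
  gx_t <- floor((tx - x0) / radius)
  gy_t <- floor((ty - y0) / radius)
  out <- logical(n_t)
  for (i in seq_len(n_t)) {
    found <- FALSE
    for (dx in -1:1) {
      for (dy in -1:1) {
        b <- buckets[[paste(gx_t[i] + dx, gy_t[i] + dy, sep = ",")]]
        if (!is.null(b)) {
          d2 <- (rx[b] - tx[i])^2 + (ry[b] - ty[i])^2
          if (any(d2 <= r2)) { found <- TRUE; break }
        }
      }
      if (found) break
    }
    out[i] <- found
  }
  out
}

# Count of (target, reference) edges within radius, grid-accelerated.
grid_pair_edges <- function(tx, ty, rx, ry, radius) {
  n_t <- length(tx)
  if (n_t == 0L || length(rx) == 0L) return(0L)
  r2 <- radius * radius
  x0 <- min(tx, rx); y0 <- min(ty, ry)
  key_r <- paste(floor((rx - x0) / radius), floor((ry - y0) / radius),
                 sep = ",")
  buckets <- split(seq_along(rx), key_r)
  gx_t <- floor((tx - x0) / radius)
  gy_t <- floor((ty - y0) / radius)
  total <- 0L
  for (i in seq_len(n_t)) {
    for (dx in -1:1) {
      for (dy in -1:1) {
        b <- buckets[[paste(gx_t[i] + dx, gy_t[i] + dy, sep = ",")]]
        if (!is.null(b)) {
          d2 <- (rx[b] - tx[i])^2 + (ry[b] - ty[i])^2
          total <- total + sum(d2 <= r2)
        }
      }
    }
  }
  total
}

#' Count target cells paired with a reference cell within a radius
#'
#' Default mode counts DISTINCT target cells having at least one reference
#' cell at Euclidean centroid-to-centroid distance <= `radius_um` (boundary
#' inclusive); each target contributes once no matter how many reference
#' cells are near. `mode = "edges"` instead counts all (target, reference)
#' pairs within the radius. `radius_um = "any"` (or `Inf`) pairs every
#' target iff at least one reference cell exists on the slide.
#'
#' The grid-accelerated search returns exactly the brute-force O(n^2)
#' result, including ties at exactly d == r (squared-distance comparison).
#'
#' On simulated slides with wrap-around (torus) boundaries, pass
#' `torus_dims_um = c(width, height)`: reference points are augmented with
#' their eight periodic images so distances follow the torus metric and the
#' Poisson void-probability closed form holds exactly (requires
#' `radius_um < min(dims)/2`). Real slides use the default planar metric.
#'
#' @param slide A [slide_cell_table()].
#' @param target_marker,reference_marker Distinct panel marker names.
#' @param radius_um Positive radius in microns, `Inf`, or `"any"`.
#' @param mode `"cells"` (default) or `"edges"`.
#' @param torus_dims_um Optional `c(width, height)` enabling the torus
#'   metric; default `NULL` (planar Euclidean distance).
#' @return Integer count.
#' @export
count_paired_cells <- function(slide, target_marker, reference_marker,
                               radius_um = 45, mode = c("cells", "edges"),
                               torus_dims_um = NULL) {
  mode <- match.arg(mode)
  if (identical(target_marker, reference_marker)) {
    stop("target and reference markers must differ (self-pairing undefined)",
         call. = FALSE)
  }
  tgt <- marker_coords(slide, target_marker)
  ref <- marker_coords(slide, reference_marker)
  any_radius <- identical(radius_um, "any") ||
    (is.numeric(radius_um) && is.infinite(radius_um))
  if (!any_radius && (!is.numeric(radius_um) || radius_um <= 0)) {
    stop("radius_um must be > 0, Inf, or \"any\"", call. = FALSE)
  }
  if (nrow(tgt) == 0L) return(0L)
  if (any_radius) {
    if (nrow(ref) == 0L) return(0L)
    return(if (mode == "cells") nrow(tgt) else nrow(tgt) * nrow(ref))
  }
  if (!is.null(torus_dims_um)) {
    stopifnot(length(torus_dims_um) == 2L, all(torus_dims_um > 0))
    if (radius_um >= min(torus_dims_um) / 2) {
      stop("torus metric requires radius_um < min(torus_dims_um)/2",
           call. = FALSE)
    }
    if (nrow(ref) > 0L) {
      shifts <- expand.grid(dx = c(-1, 0, 1) * torus_dims_um[1],
                            dy = c(-1, 0, 1) * torus_dims_um[2])
      ref <- cbind(rep(ref[, 1], nrow(shifts)) +
                     rep(shifts$dx, each = nrow(ref)),
                   rep(ref[, 2], nrow(shifts)) +
                     rep(shifts$dy, each = nrow(ref)))
    }
  }
  if (mode == "cells") {
    as.integer(sum(grid_has_neighbor(tgt[, 1], tgt[, 2],
                                     ref[, 1], ref[, 2], radius_um)))
  } else {
    as.integer(grid_pair_edges(tgt[, 1], tgt[, 2],
                               ref[, 1], ref[, 2], radius_um))
  }
}

#' Paired-cell count normalized to the reference population
#'
#' `count_paired_cells / reference_count`, the slide-level proximity
#' statistic (e.g. paired SOX10+ cells per CD8+ cell). When the slide has
#' zero reference cells the statistic is undefined and returned as `NA`
#' (flagged, logged, excluded pairwise from downstream correlations).
#'
#' @inheritParams count_paired_cells
#' @return Non-negative ratio, or `NA_real_` when undefined.
#' @export
pair_statistic <- function(slide, target_marker, reference_marker,
                           radius_um = 45, mode = c("cells", "edges")) {
  mode <- match.arg(mode)
  n_ref <- nrow(marker_coords(slide, reference_marker))
  if (n_ref == 0L) {
    mx_log("slide %s: zero %s+ cells; pair statistic undefined",
           slide$slide_id, reference_marker)
    return(NA_real_)
  }
  count_paired_cells(slide, target_marker, reference_marker,
                     radius_um, mode) / n_ref
}

#' Log2 fold-change of a per-slide metric
#'
#' `log2(post / pre)` when both values are strictly positive; otherwise the
#' value is undefined and returned as `NA` — no silent pseudocount. An
#' explicit `pseudocount` may be supplied (added to both values) and its use
#' is logged.
#'
#' @param pre_value,post_value Non-negative numeric vectors.
#' @param pseudocount Optional epsilon added to both values; default 0 (off).
#' @return Numeric vector; `NA` where undefined.
#' @export
log2_fold_change <- function(pre_value, post_value, pseudocount = 0) {
  if (any(pre_value < 0, na.rm = TRUE) || any(post_value < 0, na.rm = TRUE)) {
    stop("fold-change inputs must be >= 0", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount > 0) {
    mx_log("log2 fold-change computed with pseudocount %g", pseudocount)
    pre_value <- pre_value + pseudocount
    post_value <- post_value + pseudocount
  }
  out <- ifelse(pre_value > 0 & post_value > 0,
                log2(post_value / pre_value), NA_real_)
  n_undef <- sum(is.na(out) & !is.na(pre_value) & !is.na(post_value))
  if (n_undef > 0L) {
    mx_log("log2 fold-change undefined for %d pair(s) (zero pre or post)",
           n_undef)
  }
  out
}

#' Per-slide proximity metrics
#'
#' Computes, for one slide, the full quantification consumed by the paired
#' pre/post analysis: per-marker densities (cells/mm^2), per-marker
#' frequencies (% of nucleated cells), and the paired-cell count and
#' normalized pair statistic for each requested radius.
#'
#' @param slide A [slide_cell_table()].
#' @param target_marker Tumor-cell marker (default `"SOX10"`).
#' @param reference_marker Reference population marker (default `"CD8"`).
#' @param radii Numeric vector of radii in microns; `Inf` is reported as
#'   radius `"any"`. Default `c(45, Inf)`.
#' @param mode Pairing mode passed to [count_paired_cells()].
#' @return A one-row-per-radius data.frame with columns `slide_id`, one
#'   `density_<marker>` and `frequency_<marker>` column per panel marker,
#'   `radius_um`, `paired_count`, `pair_statistic`.
#' @export
proximity_metrics <- function(slide, target_marker = "SOX10",
                              reference_marker = "CD8",
                              radii = c(45, Inf), mode = "cells") {
  base <- data.frame(slide_id = slide$slide_id, stringsAsFactors = FALSE)
  for (m in slide$panel) {
    base[[paste0("density_", m)]] <- cell_density(slide, m)
    base[[paste0("frequency_", m)]] <- marker_frequency(slide, m)
  }
  rows <- lapply(radii, function(r) {
    row <- base
    row$radius_um <- if (is.infinite(r)) "any" else as.character(r)
    row$paired_count <- count_paired_cells(slide, target_marker,
                                           reference_marker, r, mode)
    row$pair_statistic <- pair_statistic(slide, target_marker,
                                         reference_marker, r, mode)
    row
  })
  do.call(rbind, rows)
}

#' Per-patient pre/post log2 fold-changes of proximity metrics
#'
#' Joins per-slide metrics with the clinical pre/post linkage and computes
#' log2 fold-changes (post over pre) for every metric column, per radius.
#'
#' @param metrics Data.frame from stacking [proximity_metrics()] over slides.
#' @param clinical Clinical pair records ([read_clinical_table()]).
#' @param pseudocount Passed to [log2_fold_change()].
#' @return Long data.frame: `patient_id, pfs_months, radius_um, metric,
#'   pre_value, post_value, log2_fc` (`NA` log2_fc flags undefined).
#' @export
fold_change_table <- function(metrics, clinical, pseudocount = 0) {
  unresolved <- setdiff(c(clinical$pre_slide_id, clinical$post_slide_id),
                        metrics$slide_id)
  if (length(unresolved) > 0L) {
    stop("clinical slide id(s) not found in metrics: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  metric_cols <- setdiff(names(metrics),
                         c("slide_id", "radius_um", "paired_count"))
  out <- list()
  for (i in seq_len(nrow(clinical))) {
    pre <- metrics[metrics$slide_id == clinical$pre_slide_id[i], ]
    post <- metrics[metrics$slide_id == clinical$post_slide_id[i], ]
    for (r in unique(metrics$radius_um)) {
      pre_r <- pre[pre$radius_um == r, ]
      post_r <- post[post$radius_um == r, ]
      for (mc in metric_cols) {
        pre_v <- pre_r[[mc]][1]
        post_v <- post_r[[mc]][1]
        fc <- if (is.na(pre_v) || is.na(post_v)) NA_real_ else {
          log2_fold_change(pre_v, post_v, pseudocount)
        }
        out[[length(out) + 1L]] <- data.frame(
          patient_id = clinical$patient_id[i],
          pfs_months = clinical$pfs_months[i],
          radius_um = r, metric = mc,
          pre_value = pre_v, post_value = post_v, log2_fc = fc,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  # density/frequency metrics do not depend on radius; drop duplicate rows
  rad_free <- grepl("^(density|frequency)_", res$metric)
  first_rad <- unique(metrics$radius_um)[1]
  keep <- !rad_free | res$radius_um == first_rad
  res <- res[keep, , drop = FALSE]
  res$radius_um[rad_free[keep]] <- "-"
  rownames(res) <- NULL
  res
}
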