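# Independent oracles and fixture builders used across the suite.

# Exhaustive O(n^2) count of distinct target cells with >= 1 reference
# within radius (squared-distance comparison, boundary inclusive).
brute_force_paired_cells <- function(tx, ty, rx, ry, radius) {
  if (length(tx) == 0L || length(rx) == 0L) return(0L)
  d2 <- outer(tx, rx, function(a, b) (a - b)^2) +
    outer(ty, ry, function(a, b) (a - b)^2)
  sum(apply(d2 <= radius^2, 1L, any))
}

brute_force_paired_edges <- function(tx, ty, rx, ry, radius) {
  if (length(tx) == 0L || length(rx) == 0L) return(0L)
  d2 <- outer(tx, rx, function(a, b) (a - b)^2) +
    outer(ty, ry, function(a, b) (a - b)^2)
  sum(d2 <= radius^2)
}

# Full enumeration of all 2^n sign assignments for the signed-rank test:
# two-sided p as the probability of a statistic at least as far from the
# null center as observed.
enum_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1L, function(pos) sum(r[unlist(pos)]))
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# Build a slide table directly from coordinate vectors.
make_slide <- function(tx, ty, rx, ry, slide_id = "T",
                       other_x = numeric(0), other_y = numeric(0),
                       area_mm2 = 1) {
  n <- length(tx) + length(rx) + length(other_x)
  cells <- data.frame(
    cell_id = paste0("c", seq_len(n)),
    x_um = c(tx, rx, other_x),
    y_um = c(ty, ry, other_y),
    nucleated = TRUE,
    SOX10 = rep(c(TRUE, FALSE, FALSE),
                c(length(tx), length(rx), length(other_x))),
    CD8 = rep(c(FALSE, TRUE, FALSE),
              c(length(tx), length(rx), length(other_x))),
    stringsAsFactors = FALSE)
  slide_cell_table(slide_id, cells, panel = c("SOX10", "CD8"),
                   region_area_mm2 = area_mm2)
}

# Small unfiltered cohort data.frame for filter/survival unit tests.
make_cohort <- function(n = 50, seed = 42) {
  cfg <- surv_sim_config(n = n, betas = c(sox10_z = 0.3),
                         baseline_hazard = 0.02, censor_rate = 0.005,
                         seed = seed)
  simulate_survival_cohort(cfg)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
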