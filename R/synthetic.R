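#' Configuration for a simulated MxIHC slide
#'
#' Describes a marked point pattern emulating one whole-slide centroid table:
#' reference (CD8-like) cells from a homogeneous Poisson process, target
#' (SOX10-like) cells partly attracted to reference cells, and a background
#' of unlabeled nucleated cells.
#'
#' @param width_um,height_um Slide dimensions in microns.
#' @param lambda_ref Intensity of reference cells (cells per square micron).
#' @param lambda_target Intensity of target cells.
#' @param attract_frac Fraction in [0,1] of target cells placed by Gaussian
#'   displacement from a uniformly chosen reference cell; the remainder are
#'   uniform. Emulates biologically coupled proximity.
#' @param attract_sigma_um Standard deviation of the attraction displacement.
#' @param lambda_other Intensity of unlabeled nucleated background cells.
#' @param boundary `"torus"` (wrap-around; exact closed-form proximity
#'   expectations) or `"bounded"` (coordinates clamped to the window;
#'   realistic edge effects).
#' @param seed Integer seed; the pattern is deterministic given the seed.
#' @return A `slide_sim_config` list.
#' @export
slide_sim_config <- function(width_um = 1000, height_um = 1000,
                             lambda_ref = 2e-4, lambda_target = 2e-4,
                             attract_frac = 0, attract_sigma_um = 15,
                             lambda_other = 1e-3,
                             boundary = c("torus", "bounded"), seed = 1L) {
  boundary <- match.arg(boundary)
  stopifnot(width_um > 0, height_um > 0, attract_sigma_um > 0)
  for (lam in c(lambda_ref, lambda_target, lambda_other)) {
    if (!is.finite(lam) || lam < 0) stop("intensities must be >= 0",
                                         call. = FALSE)
  }
  if (attract_frac < 0 || attract_frac > 1) {
    stop("attract_frac must be in [0, 1]", call. = FALSE)
  }
  if (lambda_ref == 0 && attract_frac > 0) {
    stop("attract_frac > 0 requires lambda_ref > 0 (no cells to attract to)",
         call. = FALSE)
  }
  structure(list(width_um = width_um, height_um = height_um,
                 lambda_ref = lambda_ref, lambda_target = lambda_target,
                 attract_frac = attract_frac,
                 attract_sigma_um = attract_sigma_um,
                 lambda_other = lambda_other, boundary = boundary,
                 seed = as.integer(seed)),
            class = "slide_sim_config")
}

#' Simulate one slide-level marked point pattern
#'
#' Reference cells are homogeneous Poisson with intensity `lambda_ref`;
#' target cells number Poisson(`lambda_target` * area), of which a binomial
#' `attract_frac` share is placed as a Gaussian displacement (sd
#' `attract_sigma_um`) from a uniformly chosen reference cell and the rest
#' uniformly; unlabeled nucleated cells are Poisson(`lambda_other`).
#' Under `boundary = "torus"` displaced coordinates wrap, so the Poisson
#' void-probability formula for the paired fraction,
#' 1 - exp(-lambda_ref * pi * r^2), is exact when `attract_frac = 0`.
#'
#' @param cfg A [slide_sim_config()].
#' @param slide_id Identifier for the generated slide.
#' @return A [slide_cell_table()] with panel `c("SOX10","CD8")`.
#' @export
simulate_slide <- function(cfg, slide_id = "SIM") {
  stopifnot(inherits(cfg, "slide_sim_config"))
  with_seed(cfg$seed, {
    w <- cfg$width_um; h <- cfg$height_um
    area <- w * h
    n_ref <- stats::rpois(1L, cfg$lambda_ref * area)
    n_tgt <- stats::rpois(1L, cfg$lambda_target * area)
    n_oth <- stats::rpois(1L, cfg$lambda_other * area)

    ref_x <- stats::runif(n_ref, 0, w)
    ref_y <- stats::runif(n_ref, 0, h)

    n_att <- if (n_tgt > 0L) stats::rbinom(1L, n_tgt, cfg$attract_frac) else 0L
    if (n_att > 0L && n_ref == 0L) {
      # attract_frac > 0 with lambda_ref > 0 can still realize zero reference
      # cells; fall back to uniform placement for this slide.
      n_att <- 0L
    }
    n_uni <- n_tgt - n_att
    if (n_att > 0L) {
      anchor <- sample.int(n_ref, n_att, replace = TRUE)
      ax <- ref_x[anchor] + stats::rnorm(n_att, 0, cfg$attract_sigma_um)
      ay <- ref_y[anchor] + stats::rnorm(n_att, 0, cfg$attract_sigma_um)
      if (cfg$boundary == "torus") {
        ax <- ax %% w; ay <- ay %% h
      } else {
        ax <- pmin(pmax(ax, 0), w); ay <- pmin(pmax(ay, 0), h)
      }
    } else {
      ax <- numeric(0); ay <- numeric(0)
    }
    tgt_x <- c(ax, stats::runif(n_uni, 0, w))
    tgt_y <- c(ay, stats::runif(n_uni, 0, h))
    oth_x <- stats::runif(n_oth, 0, w)
    oth_y <- stats::runif(n_oth, 0, h)

    n <- n_ref + n_tgt + n_oth
    cells <- data.frame(
      cell_id = sprintf("%s_c%06d", slide_id, seq_len(max(n, 0L))),
      x_um = c(tgt_x, ref_x, oth_x),
      y_um = c(tgt_y, ref_y, oth_y),
      nucleated = TRUE,
      SOX10 = rep(c(TRUE, FALSE, FALSE), c(n_tgt, n_ref, n_oth)),
      CD8 = rep(c(FALSE, TRUE, FALSE), c(n_tgt, n_ref, n_oth)),
      stringsAsFactors = FALSE
    )
    slide_cell_table(slide_id, cells, panel = c("SOX10", "CD8"),
                     region_area_mm2 = area / 1e6)
  })
}

#' Configuration for a simulated paired pre/post cohort
#'
#' Programs a monotone link between the pre-to-post expansion of target
#' (tumor-like) cells and progression-free survival: per patient, PFS is
#' uniform on `pfs_range_months` and the programmed log2 fold-change of the
#' target intensity is `slope * standardize(-PFS) + N(0, noise_sd)`, so a
#' positive slope always encodes "faster progression goes with greater
#' tumor-cell expansion".
#'
#' @param n_patients Number of patients (>= 2).
#' @param baseline A [slide_sim_config()] for the pre-treatment slides.
#' @param slope Expansion-model slope (log2 units per SD of -PFS).
#' @param noise_sd Gaussian noise on the programmed log2 fold-change.
#' @param pfs_range_months Length-2 numeric, min < max.
#' @param seed Integer master seed; each patient/slide uses a derived
#'   substream so cohorts are reproducible under partial regeneration.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 11, baseline = slide_sim_config(),
                              slope = 1.5, noise_sd = 0.3,
                              pfs_range_months = c(2, 30), seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  stopifnot(inherits(baseline, "slide_sim_config"),
            length(pfs_range_months) == 2L,
            pfs_range_months[1] < pfs_range_months[2],
            noise_sd >= 0)
  structure(list(n_patients = as.integer(n_patients), baseline = baseline,
                 slope = slope, noise_sd = noise_sd,
                 pfs_range_months = pfs_range_months, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a paired pre/post slide cohort with known ground truth
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list with `slides` (named list of [slide_cell_table()], two per
#'   patient), `clinical` (patient pair records), and `truth` (per-patient
#'   PFS and programmed log2 fold-change of the target intensity).
#' @export
simulate_paired_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  n <- cfg$n_patients
  pars <- with_seed(substream_seed(cfg$seed, 0L), {
    pfs <- stats::runif(n, cfg$pfs_range_months[1], cfg$pfs_range_months[2])
    z <- as.numeric(scale(-pfs))
    fc <- cfg$slope * z + stats::rnorm(n, 0, cfg$noise_sd)
    list(pfs = pfs, fc = fc)
  })
  patient_id <- sprintf("P%03d", seq_len(n))
  slides <- vector("list", 2L * n)
  names(slides) <- as.vector(rbind(paste0(patient_id, "_pre"),
                                   paste0(patient_id, "_post")))
  for (i in seq_len(n)) {
    pre_cfg <- cfg$baseline
    pre_cfg$seed <- substream_seed(cfg$seed, 2L * i - 1L)
    post_cfg <- cfg$baseline
    post_cfg$lambda_target <- cfg$baseline$lambda_target * 2^pars$fc[i]
    post_cfg$seed <- substream_seed(cfg$seed, 2L * i)
    slides[[paste0(patient_id[i], "_pre")]] <-
      simulate_slide(pre_cfg, paste0(patient_id[i], "_pre"))
    slides[[paste0(patient_id[i], "_post")]] <-
      simulate_slide(post_cfg, paste0(patient_id[i], "_post"))
  }
  clinical <- data.frame(
    patient_id = patient_id,
    pre_slide_id = paste0(patient_id, "_pre"),
    post_slide_id = paste0(patient_id, "_post"),
    pfs_months = pars$pfs,
    progression_event = TRUE,
    prior_immunotherapy = FALSE,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(patient_id = patient_id, pfs_months = pars$pfs,
                      log2_fc_programmed = pars$fc, stringsAsFactors = FALSE)
  list(slides = slides, clinical = clinical, truth = truth)
}

#' Configuration for a simulated survival cohort
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_k * x_k))`; censoring times are
#' independent exponential with rate `censor_rate` (0 disables censoring).
#'
#' @param n Number of patients (>= 10).
#' @param betas Named numeric vector of log-hazard coefficients per covariate
#'   unit; names must refer to declared covariates.
#' @param baseline_hazard Baseline event rate per month (> 0).
#' @param censor_rate Censoring rate per month (>= 0).
#' @param covariates Named list declaring each covariate's marginal
#'   distribution, entries like `list(dist = "normal", mean = 0, sd = 1)`,
#'   `list(dist = "lognormal", meanlog = , sdlog = )`, or
#'   `list(dist = "binary", p = )`.
#' @param stage_mix Fraction of patients labelled early stage.
#' @param interaction Optional named numeric vector of product-term
#'   coefficients, names like `"sox10_z:immune_score"`.
#' @param gene_models Optional named list programming downstream expression
#'   columns `expr_<GENE>` as
#'   `2^(b0 + b_sox10*sox10_z + b_log2cd8*log2(cd8a_expr) +
#'   b_inter*sox10_z*log2(cd8a_expr) + N(0,sd))`.
#' @param seed Integer seed.
#' @return A `surv_sim_config` list.
#' @export
surv_sim_config <- function(n = 400,
                            betas = c(sox10_z = 0.3, immune_score = -0.4),
                            baseline_hazard = 0.01, censor_rate = 0.005,
                            covariates = default_covariates(),
                            stage_mix = 0.5, interaction = NULL,
                            gene_models = default_gene_models(), seed = 1L) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (censor_rate < 0) stop("censor_rate must be >= 0", call. = FALSE)
  undeclared <- setdiff(names(betas), names(covariates))
  if (length(undeclared) > 0L) {
    stop("betas name undeclared covariate(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  if (!is.null(interaction)) {
    parts <- unique(unlist(strsplit(names(interaction), ":", fixed = TRUE)))
    bad <- setdiff(parts, names(covariates))
    if (length(bad) > 0L) {
      stop("interaction terms name undeclared covariate(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(stage_mix >= 0, stage_mix <= 1)
  structure(list(n = as.integer(n), betas = betas,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, covariates = covariates,
                 stage_mix = stage_mix, interaction = interaction,
                 gene_models = gene_models, seed = as.integer(seed)),
            class = "surv_sim_config")
}

#' Default covariate distributions for the survival simulator
#' @return Named list of distribution declarations.
#' @export
default_covariates <- function() {
  list(
    sox10_z = list(dist = "normal", mean = 0, sd = 1),
    mlana_z = list(dist = "normal", mean = 0, sd = 1),
    immune_score = list(dist = "normal", mean = 0, sd = 1),
    cd8a_expr = list(dist = "lognormal", meanlog = 3, sdlog = 1),
    sex_male = list(dist = "binary", p = 0.6)
  )
}

#' Default downstream expression models (CD8-effector genes)
#' @return Named list of gene model declarations.
#' @export
default_gene_models <- function() {
  list(
    IFNG = list(b0 = 1, b_sox10 = 0, b_log2cd8 = 0.8, b_inter = 0, sd = 0.5),
    GZMB = list(b0 = 2, b_sox10 = 0, b_log2cd8 = 0.9, b_inter = 0, sd = 0.5),
    PDCD1 = list(b0 = 1, b_sox10 = 0, b_log2cd8 = 0.7, b_inter = 0, sd = 0.5),
    CD274 = list(b0 = 2, b_sox10 = 0.2, b_log2cd8 = 0.4, b_inter = 0,
                 sd = 0.5)
  )
}

draw_covariate <- function(spec, n) {
  switch(spec$dist,
    normal = stats::rnorm(n, spec$mean, spec$sd),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    uniform = stats::runif(n, spec$min, spec$max),
    binary = stats::rbinom(n, 1L, spec$p),
    stop("unknown covariate distribution: ", spec$dist, call. = FALSE)
  )
}

#' Simulate a survival cohort from a proportional-hazards model
#'
#' @param cfg A [surv_sim_config()].
#' @return A cohort data.frame (same columns as [read_tcga_cohort()]) with
#'   attribute `"truth"` holding the programmed coefficients.
#' @export
simulate_survival_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "surv_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    X <- as.data.frame(lapply(cfg$covariates, draw_covariate, n = n))
    lp <- rep(0, n)
    for (nm in names(cfg$betas)) lp <- lp + cfg$betas[[nm]] * X[[nm]]
    if (!is.null(cfg$interaction)) {
      for (nm in names(cfg$interaction)) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        lp <- lp + cfg$interaction[[nm]] * X[[parts[1]]] * X[[parts[2]]]
      }
    }
    t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(lp))
    t_cens <- if (cfg$censor_rate > 0) {
      stats::rexp(n, rate = cfg$censor_rate)
    } else rep(Inf, n)
    os_months <- pmin(t_event, t_cens)
    os_event <- t_event <= t_cens

    out <- data.frame(
      patient_id = sprintf("S%04d", seq_len(n)),
      os_months = os_months,
      os_event = os_event,
      stage_group = ifelse(stats::runif(n) < cfg$stage_mix, "early", "late"),
      sex = ifelse((X$sex_male %||% stats::rbinom(n, 1, 0.5)) == 1,
                   "male", "female"),
      stringsAsFactors = FALSE
    )
    for (nm in setdiff(names(X), "sex_male")) out[[nm]] <- X[[nm]]
    if (!is.null(cfg$gene_models) && !is.null(out$cd8a_expr)) {
      l2cd8 <- log2(out$cd8a_expr)
      sox <- out$sox10_z %||% rep(0, n)
      for (g in names(cfg$gene_models)) {
        m <- cfg$gene_models[[g]]
        out[[paste0("expr_", g)]] <-
          2^(m$b0 + m$b_sox10 * sox + m$b_log2cd8 * l2cd8 +
             m$b_inter * sox * l2cd8 + stats::rnorm(n, 0, m$sd))
      }
    }
    attr(out, "truth") <- list(betas = cfg$betas,
                               interaction = cfg$interaction,
                               baseline_hazard = cfg$baseline_hazard,
                               censor_rate = cfg$censor_rate,
                               seed = cfg$seed)
    out
  })
}
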