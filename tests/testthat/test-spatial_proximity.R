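test_that("density and frequency follow their definitions", {
  # 250 marker+ cells in 0.5 mm^2 -> 500 per mm^2
  set.seed(1)
  s <- make_slide(tx = runif(250, 0, 707), ty = runif(250, 0, 707),
                  rx = numeric(0), ry = numeric(0), area_mm2 = 0.5)
  expect_equal(cell_density(s, "SOX10"), 500)
  expect_equal(cell_density(s, "CD8"), 0)
  # density * area reconstructs the integer count exactly
  expect_identical(cell_density(s, "SOX10") * s$region_area_mm2, 250)

  # 30 marker+ of 120 nucleated -> 25%
  s2 <- make_slide(tx = runif(30), ty = runif(30),
                   rx = numeric(0), ry = numeric(0),
                   other_x = runif(90), other_y = runif(90))
  expect_equal(marker_frequency(s2, "SOX10"), 25)
  # marker on every nucleated cell -> 100%
  s3 <- make_slide(tx = runif(10), ty = runif(10),
                   rx = numeric(0), ry = numeric(0))
  expect_equal(marker_frequency(s3, "SOX10"), 100)
  expect_error(cell_density(s2, "CD40"), "not in the slide panel")
})

test_that("simulated density sits in the Poisson band", {
  # lambda 3e-4 / um^2 = 300 per mm^2 on a 1 mm^2 slide
  s <- simulate_slide(slide_sim_config(lambda_target = 3e-4, seed = 21), "D")
  expect_lt(abs(cell_density(s, "SOX10") - 300), 4 * sqrt(300))
})

test_that("paired-cell counting honors the inclusive 45 um boundary", {
  # d = 44 <= 45 -> paired
  expect_equal(count_paired_cells(make_slide(0, 0, 0, 44), "SOX10", "CD8", 45),
               1L)
  # d = 50 -> not paired
  expect_equal(count_paired_cells(make_slide(0, 0, 30, 40), "SOX10", "CD8", 45),
               0L)
  # exactly d = r counts as paired (boundary inclusive)
  expect_equal(count_paired_cells(make_slide(0, 0, 0, 45), "SOX10", "CD8", 45),
               1L)
  # a target near several references still counts once in cells mode
  s <- make_slide(0, 0, c(10, 20, 30), c(0, 0, 0))
  expect_equal(count_paired_cells(s, "SOX10", "CD8", 45), 1L)
  expect_equal(count_paired_cells(s, "SOX10", "CD8", 45, mode = "edges"), 3L)
  expect_error(count_paired_cells(s, "SOX10", "SOX10", 45), "must differ")
  expect_error(count_paired_cells(s, "SOX10", "CD8", -3), "radius_um")
})

test_that("grid-accelerated counting equals the brute-force oracle", {
  for (i in 1:25) {
    set.seed(i)
    n_t <- sample(0:120, 1); n_r <- sample(0:120, 1)
    tx <- runif(n_t, 0, 1000); ty <- runif(n_t, 0, 1000)
    rx <- runif(n_r, 0, 1000); ry <- runif(n_r, 0, 1000)
    s <- make_slide(tx, ty, rx, ry)
    for (r in c(10, 45, 200)) {
      expect_identical(count_paired_cells(s, "SOX10", "CD8", r),
                       as.integer(brute_force_paired_cells(tx, ty, rx, ry, r)),
                       info = sprintf("seed %d radius %g (cells)", i, r))
      expect_identical(count_paired_cells(s, "SOX10", "CD8", r,
                                          mode = "edges"),
                       as.integer(brute_force_paired_edges(tx, ty, rx, ry, r)),
                       info = sprintf("seed %d radius %g (edges)", i, r))
    }
  }
  # engineered ties at exactly d = r across grid-cell boundaries
  s <- make_slide(c(0, 100), c(0, 100), c(45, 100 + 45 / sqrt(2)),
                  c(0, 100 + 45 / sqrt(2)))
  expect_identical(count_paired_cells(s, "SOX10", "CD8", 45),
                   as.integer(brute_force_paired_cells(
                     c(0, 100), c(0, 100), c(45, 100 + 45 / sqrt(2)),
                     c(0, 100 + 45 / sqrt(2)), 45)))
})

test_that("torus counting matches a 9-image brute force and is translation-invariant", {
  set.seed(55)
  w <- 600; h <- 400
  tx <- runif(50, 0, w); ty <- runif(50, 0, h)
  rx <- runif(40, 0, w); ry <- runif(40, 0, h)
  # oracle: minimum distance over the nine periodic images
  torus_oracle <- function(tx, ty, rx, ry, r) {
    sh <- expand.grid(dx = c(-w, 0, w), dy = c(-h, 0, h))
    rx9 <- as.vector(outer(rx, sh$dx, "+"))
    ry9 <- as.vector(outer(ry, sh$dy, "+"))
    brute_force_paired_cells(tx, ty, rx9, ry9, r)
  }
  s <- make_slide(tx, ty, rx, ry)
  got <- count_paired_cells(s, "SOX10", "CD8", 45,
                            torus_dims_um = c(w, h))
  expect_identical(got, as.integer(torus_oracle(tx, ty, rx, ry, 45)))
  # translation invariance on the torus
  shift <- c(123.4, 77.7)
  s2 <- make_slide((tx + shift[1]) %% w, (ty + shift[2]) %% h,
                   (rx + shift[1]) %% w, (ry + shift[2]) %% h)
  expect_identical(count_paired_cells(s2, "SOX10", "CD8", 45,
                                      torus_dims_um = c(w, h)), got)
  expect_error(count_paired_cells(s, "SOX10", "CD8", 250,
                                  torus_dims_um = c(w, h)),
               "torus metric requires")
})

test_that("paired count is nondecreasing in radius and attains target count at any", {
  set.seed(99)
  tx <- runif(80, 0, 500); ty <- runif(80, 0, 500)
  rx <- runif(60, 0, 500); ry <- runif(60, 0, 500)
  s <- make_slide(tx, ty, rx, ry)
  radii <- c(5, 15, 45, 100, 400)
  counts <- vapply(radii, function(r)
    count_paired_cells(s, "SOX10", "CD8", r), integer(1))
  expect_true(all(diff(counts) >= 0L))
  expect_equal(count_paired_cells(s, "SOX10", "CD8", "any"), 80L)
  expect_equal(count_paired_cells(s, "SOX10", "CD8", Inf), 80L)
  # pair existence is symmetric even though counts need not be
  exists_ab <- count_paired_cells(s, "SOX10", "CD8", 45) > 0L
  exists_ba <- count_paired_cells(s, "CD8", "SOX10", 45) > 0L
  expect_identical(exists_ab, exists_ba)
})

test_that("pair statistic normalizes to the reference count and flags zero references", {
  # paired 30 of 60 references -> 0.5: 30 targets each on top of a reference
  set.seed(3)
  rx <- runif(60, 0, 2000); ry <- runif(60, 0, 2000)
  s <- make_slide(rx[1:30], ry[1:30], rx, ry)
  expect_equal(pair_statistic(s, "SOX10", "CD8", 1e-9), 0.5)
  # radius any: statistic = target_count / reference_count
  expect_equal(pair_statistic(s, "SOX10", "CD8", "any"), 30 / 60)
  # zero reference cells -> flagged undefined
  s0 <- make_slide(c(1, 2), c(1, 2), numeric(0), numeric(0))
  expect_true(is.na(quiet(pair_statistic(s0, "SOX10", "CD8", 45))))
})

test_that("log2 fold-change handles zeros, pseudocounts, and bad input", {
  expect_equal(log2_fold_change(100, 400), 2)
  expect_equal(log2_fold_change(7, 7), 0)
  expect_true(is.na(quiet(log2_fold_change(0, 5))))
  expect_true(is.na(quiet(log2_fold_change(5, 0))))
  expect_error(log2_fold_change(-1, 5), ">= 0")
  # explicit pseudocount makes the zero case defined (and is logged)
  expect_message(v <- log2_fold_change(0, 5, pseudocount = 1),
                 "pseudocount")
  expect_equal(v, log2(6 / 1))
  expect_equal(log2_fold_change(c(1, 2), c(2, 8)), c(1, 2))
})

test_that("proximity metrics and fold-change table assemble per slide/patient", {
  s_pre <- simulate_slide(slide_sim_config(seed = 31), "P1_pre")
  s_post <- simulate_slide(slide_sim_config(lambda_target = 4e-4, seed = 32),
                           "P1_post")
  m <- rbind(proximity_metrics(s_pre), proximity_metrics(s_post))
  expect_equal(m$radius_um, rep(c("45", "any"), 2))
  clin <- data.frame(patient_id = "P1", pre_slide_id = "P1_pre",
                     post_slide_id = "P1_post", pfs_months = 12,
                     progression_event = TRUE, prior_immunotherapy = FALSE)
  fc <- quiet(fold_change_table(m, clin))
  dens <- fc[fc$metric == "density_SOX10", ]
  expect_equal(nrow(dens), 1L)   # radius-free metric reported once
  expect_equal(dens$log2_fc,
               log2(cell_density(s_post, "SOX10") /
                    cell_density(s_pre, "SOX10")))
  expect_equal(sum(fc$metric == "pair_statistic"), 2L)  # one per radius
  clin_bad <- clin; clin_bad$post_slide_id <- "NOPE"
  expect_error(fold_change_table(m, clin_bad), "not found")
})
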