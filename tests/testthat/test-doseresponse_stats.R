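test_that("dose correlations reproduce the printed coefficients", {
  doses5 <- c(0, 0.075, 2.25, 11.25, 22.50)
  ure90 <- c(0.136, 0.132, 0.129, 0.109, 0.092)
  ct <- dose_correlation(doses5, ure90)
  expect_equal(round(ct$r, 3), -0.993)
  expect_true(ct$significant)  # flagged at p = 0.01
  rl_deh <- c(-0.467, -0.467, -0.508, -0.551)
  ct2 <- dose_correlation(doses5[-1], rl_deh)
  expect_equal(round(ct2$r, 3), -0.996)
  expect_equal(dose_correlation(doses5, 3 * doses5 + 1)$r, 1)
  expect_error(dose_correlation(doses5, rep(2, 5)),
               class = "soilecotox_degenerate_correlation")
})

test_that("Pearson r is affine-invariant and sign-flips with the values", {
  withr::local_seed(11)
  for (i in 1:25) {
    d <- sort(runif(5, 0, 30))
    v <- rnorm(5)
    r0 <- dose_correlation(d, v)$r
    expect_equal(dose_correlation(d, 2.5 * v + 3)$r, r0)
    expect_equal(dose_correlation(d, -v)$r, -r0)
  }
})

test_that("eta-squared partition matches the brute-force decomposition", {
  ea <- load_fixture("enzyme_activity")
  pal <- ea[ea$variable == "alkaline_phosphatase", ]
  vp <- eta_squared(pal)
  m <- matrix(NA_real_, 5, 3,
              dimnames = list(sort(unique(pal$dose)), sort(unique(pal$time))))
  for (i in seq_len(nrow(pal))) {
    m[as.character(pal$dose[i]), as.character(pal$time[i])] <- pal$value[i]
  }
  oracle <- oracle_ss_decomposition(m)
  expect_equal(vp$sum_sq[vp$term == "dose"], oracle$ss_dose, tolerance = 1e-9)
  expect_equal(vp$sum_sq[vp$term == "time"], oracle$ss_time, tolerance = 1e-9)
  expect_equal(vp$sum_sq[vp$term == "dose:time"], oracle$ss_interaction,
               tolerance = 1e-8)
  # frozen brute-force values for the alkaline phosphatase grid
  expect_equal(oracle$ss_dose, 0.04733, tolerance = 1e-4)
  expect_equal(oracle$ss_total, 7.80033, tolerance = 1e-5)
  # components sum to the total and shares to 100%
  expect_equal(sum(vp$sum_sq[vp$term != "total"]),
               vp$sum_sq[vp$term == "total"], tolerance = 1e-9)
  expect_equal(sum(vp$eta_sq_percent[vp$term != "total"]), 100, tolerance = 1e-9)
})

test_that("eta-squared handles additive, degenerate and invalid layouts", {
  g <- expand.grid(dose = c(0, 1, 2), time = c(30, 60, 90))
  additive <- tibble::tibble(dose = g$dose, time = g$time,
                             value = 2 * g$dose + 0.1 * g$time)
  vp <- eta_squared(additive)
  expect_equal(vp$eta_sq_percent[vp$term == "dose:time"], 0, tolerance = 1e-9)
  time_only <- tibble::tibble(dose = g$dose, time = g$time, value = g$time^2)
  vp2 <- eta_squared(time_only)
  expect_equal(vp2$eta_sq_percent[vp2$term == "time"], 100, tolerance = 1e-9)
  expect_error(eta_squared(additive[-1, ]), class = "soilecotox_layout_error")
  # swapping the factor labels swaps the dose and time components exactly
  withr::local_seed(5)
  rnd <- tibble::tibble(dose = g$dose, time = g$time, value = rnorm(9))
  swapped <- tibble::tibble(dose = rnd$time, time = rnd$dose, value = rnd$value)
  expect_equal(eta_squared(rnd)$sum_sq[1:2],
               eta_squared(swapped)$sum_sq[2:1])
  # replicated observations add an error stratum
  reps <- dplyr::bind_rows(rnd, rnd)
  reps$value <- reps$value + rnorm(18, 0, 0.1)
  vp3 <- eta_squared(reps)
  expect_gt(vp3$sum_sq[vp3$term == "error"], 0)
  expect_equal(sum(vp3$eta_sq_percent[vp3$term != "total"]), 100,
               tolerance = 1e-9)
})

test_that("compact letter display separates groups as Tukey's test does", {
  spread <- c(-1, -0.5, 0.5, 1)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  # identical distributions: one shared letter
  same <- tukey_letters(rep(spread, 3), g)
  expect_true(all(same == "a"))
  # three groups separated by far more than the HSD: distinct letters
  far <- tukey_letters(c(spread, spread + 10, spread + 20), g)
  expect_equal(as.character(far), c("a", "b", "c"))
  # shift chosen between HSD/2 and HSD: only the extremes differ -> a, ab, b
  mid <- tukey_letters(c(spread, spread + 1.8, spread + 3.6), g)
  expect_equal(as.character(mid), c("a", "ab", "b"))
  pm <- attr(mid, "p_matrix")
  expect_gt(pm["g1", "g2"], 0.01)
  expect_lt(pm["g1", "g3"], 0.01)
  expect_error(tukey_letters(1:3, c("a", "a", "b")),
               class = "soilecotox_df_error")
})

test_that("letter display is consistent with the pairwise oracle on random layouts", {
  withr::local_seed(202)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    n <- sample(3:6, 1)
    means <- runif(k, 0, 6)
    x <- rnorm(k * n, rep(means, each = n), 0.8)
    g <- rep(paste0("g", seq_len(k)), each = n)
    lt <- tukey_letters(x, g, alpha = 0.05)
    pm <- attr(lt, "p_matrix")
    sig <- pm < 0.05
    expect_true(oracle_cld_consistent(lt, sig),
                label = sprintf("CLD consistency, case %d (k=%d)", i, k))
  }
})

test_that("Ward clustering isolates fungi from the bacterial groups", {
  mc <- load_fixture("microbial_counts")
  wide <- tidyr::pivot_wider(mc, names_from = c("dose", "time"),
                             values_from = "value")
  m <- as.data.frame(wide[, -1])
  rownames(m) <- wide$variable
  h <- ward_cluster(m)
  # first merge joins the two bacterial groups; fungi attach last
  expect_equal(sort(h$merge[1, ]),
               sort(-match(c("organotrophic_bacteria", "actinomycetes"), h$labels)))
  expect_true(all(diff(h$height) >= -1e-12))
})

test_that("Ward linkage behaves on degenerate geometries", {
  x <- rbind(p1 = c(0, 0), p2 = c(0, 0), p3 = c(3, 4))
  h <- ward_cluster(x, standardize = FALSE)
  expect_equal(h$height[1], 0)            # identical profiles merge at 0
  expect_equal(sort(h$merge[1, ]), c(-2, -1))
  # coincident pair merges first, matching the exhaustive merge-cost oracle
  y <- rbind(a = c(1, 1), b = c(5, 5), c = c(5, 5))
  hy <- ward_cluster(y, standardize = FALSE)
  expect_equal(sort(-hy$merge[1, ]), sort(oracle_first_ward_merge(y)$pair))
  # input order invariance of merge heights
  withr::local_seed(8)
  z <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("r", 1:6), NULL))
  perm <- sample(6)
  expect_equal(sort(ward_cluster(z)$height), sort(ward_cluster(z[perm, ])$height))
  # constant features are dropped with a warning
  zc <- cbind(z, const = 1)
  expect_warning(ward_cluster(zc), class = "soilecotox_constant_feature")
  # both Ward dialects agree on the merge order
  expect_equal(ward_cluster(z, dialect = "squared")$merge,
               ward_cluster(z, dialect = "euclidean")$merge)
})

test_that("PCA explained variance is a proper decomposition", {
  rank1 <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  pv <- pca_variance(rank1, scale = FALSE)
  expect_equal(pv$variance_percent[1], 100, tolerance = 1e-9)
  # exactly orthogonal zero-mean columns: identity correlation, 20% each
  ortho <- stats::contr.helmert(6)  # 6 cases x 5 orthogonal contrasts
  expect_equal(unname(cor(ortho)), diag(5), tolerance = 1e-12)
  pv2 <- pca_variance(ortho)
  expect_equal(pv2$variance_percent, rep(20, 5), tolerance = 1e-9)
  # shares sum to 100 and are case-order invariant
  withr::local_seed(13)
  x <- matrix(rnorm(60), 12, 5)
  pv3 <- pca_variance(x)
  expect_equal(sum(pv3$variance_percent), 100, tolerance = 1e-9)
  expect_true(all(diff(pv3$variance_percent) <= 1e-9))
  expect_equal(pca_variance(x[sample(12), ])$variance_percent,
               pv3$variance_percent)
  expect_error(pca_variance(cbind(x, 0)), class = "soilecotox_domain_error")
  expect_error(pca_variance(x[, 1, drop = FALSE]),
               class = "soilecotox_validation_error")
})
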