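test_that("generators are pure functions of the configuration", {
  cfg <- synthetic_config(seed = 17)
  expect_identical(generate_experiment(cfg), generate_experiment(cfg))
  expect_identical(generate_emergence(cfg, 2.25), generate_emergence(cfg, 2.25))
  cfg2 <- synthetic_config(seed = 18)
  expect_false(identical(generate_experiment(cfg), generate_experiment(cfg2)))
})

test_that("experiment layout and deterministic means follow the model", {
  cfg <- synthetic_config(seed = 1)
  x <- generate_experiment(cfg)
  enzymes <- names(cfg$enzyme_baselines)
  expect_equal(sum(x$variable %in% enzymes), 5 * 3 * 5 * 9)   # 675 enzyme rows
  expect_equal(sum(!x$variable %in% enzymes), 5 * 3 * 3 * 3)  # count rows
  # half-saturation: at d = K50 and sigma = 0 activity is exactly
  # A0(t) * (1 - Imax/2)
  cfg0 <- synthetic_config(
    doses = 5, times = 30, sigma = 0, sigma_counts = 0,
    imax = setNames(rep(0.3, 5), names(cfg$enzyme_baselines)), k50 = 5, seed = 2)
  x0 <- generate_experiment(cfg0)
  deh <- x0$value[x0$variable == "dehydrogenases"]
  expect_equal(deh, rep(5.310 * 0.85, 9), tolerance = 1e-12)
  # d = 0: mean activity is the lognormal mean A0 * exp(sigma^2 / 2)
  cfgmc <- synthetic_config(doses = 0, times = 30, n_replicates = 20000,
                            sigma = 0.3, seed = 9)
  xm <- generate_experiment(cfgmc)
  ure <- xm$value[xm$variable == "urease"]
  expect_equal(mean(ure), 0.175 * exp(0.3^2 / 2), tolerance = 0.01)
  expect_error(synthetic_config(doses = numeric(0)),
               class = "soilecotox_config_error")
})

test_that("emergence profiles follow the fast/slow mixture", {
  cfg <- synthetic_config(n_colonies = 200, seed = 4)
  prof <- generate_emergence(cfg, 0)
  expect_length(prof, 10)
  expect_equal(sum(prof), 200)
  # all-fast point mass on day 1 gives CD = 100
  cfg_fast <- synthetic_config(w0 = 1, fast = c(1, rep(0, 9)), seed = 4)
  expect_equal(colony_development_index(generate_emergence(cfg_fast, 0)), 100)
  # all-slow uniform mixture: EP tends to 1 (law of large numbers)
  cfg_unif <- synthetic_config(w0 = 0, slow = rep(0.1, 10),
                               n_colonies = 1e5, seed = 4)
  expect_equal(ecophysiological_index(generate_emergence(cfg_unif, 0)), 1,
               tolerance = 0.01)
  expect_error(synthetic_config(w0 = 1.2), class = "soilecotox_config_error")
})

test_that("expected CD decreases as the mixture shifts toward slow growers", {
  ws <- seq(1, 0, by = -0.25)
  cds <- vapply(ws, function(w) {
    cfg <- synthetic_config(w0 = w, n_colonies = 1e4, seed = 12)
    colony_development_index(generate_emergence(cfg, 0))
  }, numeric(1))
  expect_true(all(diff(cds) < 0))
})

test_that("inhibition parameters are recovered from synthetic data", {
  # noiseless: exact recovery
  cfg0 <- synthetic_config(sigma = 0, seed = 5)
  x0 <- generate_experiment(cfg0)
  fit0 <- recover_parameters(x0, variable = "urease")
  expect_equal(fit0$imax, 0.32, tolerance = 1e-6)
  expect_equal(fit0$k50, 5, tolerance = 1e-6)
  # noisy: within 0.05 of truth at the stated replication
  cfg <- synthetic_config(sigma = 0.05, n_replicates = 9, seed = 6)
  fit <- recover_parameters(generate_experiment(cfg), variable = "urease")
  expect_lt(abs(fit$imax - 0.32), 0.05)
  # grid-search oracle agrees with the optimizer on a 3-dose instance
  cfg3 <- synthetic_config(doses = c(0, 1, 5, 20), sigma = 0.02, seed = 7)
  x3 <- generate_experiment(cfg3)
  fit3 <- recover_parameters(x3, variable = "catalase")
  obj <- function(imax, k50) {
    d <- x3[x3$variable == "catalase", ]
    lin <- log(1 - imax * d$dose / (d$dose + k50))
    r <- log(d$value) - lin
    at <- tapply(r, factor(d$time), mean)
    sum((r - at[factor(d$time)])^2)
  }
  im_grid <- seq(0.01, 0.9, length.out = 120)
  k_grid <- exp(seq(log(0.1), log(100), length.out = 120))
  sse <- outer(im_grid, k_grid, Vectorize(obj))
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_lt(obj(fit3$imax, fit3$k50),
            sse[best[1], best[2]] + 1e-4)
  expect_lt(abs(fit3$imax - im_grid[best[1]]), 0.05)
  # degenerate inputs
  expect_error(recover_parameters(x0), class = "soilecotox_validation_error")
  d0 <- x0[x0$variable == "urease" & x0$dose == 0, ]
  expect_error(recover_parameters(d0), class = "soilecotox_unidentifiable_error")
})

test_that("strong inhibition propagates through the full pipeline", {
  cfg <- synthetic_config(
    imax = setNames(rep(0.5, 5), c("dehydrogenases", "catalase", "urease",
                                   "acid_phosphatase", "alkaline_phosphatase")),
    sigma = 0.02, seed = 21)
  x <- generate_experiment(cfg)
  # correlation over replicate-level observations (n = 45 per enzyme-time),
  # as the assessment does; the 5 dose means alone cannot reach p < 0.01
  # for a saturating response
  for (v in names(cfg$enzyme_baselines)) {
    for (t in cfg$times) {
      sl <- x[x$variable == v & x$time == t, ]
      ct <- dose_correlation(sl$dose, sl$value)
      expect_lt(ct$r, 0)
      expect_true(ct$significant)
    }
  }
  # RS from noiseless means decreases monotonically with dose
  cfg0 <- synthetic_config(
    imax = cfg$imax, sigma = 0, seed = 22)
  m0 <- generate_experiment(cfg0)
  m0 <- m0[m0$variable == "urease" & m0$time == 30 & m0$replicate == "e1", ]
  ctrl <- m0$value[m0$dose == 0]
  rs <- resistance_index(ctrl, m0$value[m0$dose > 0])
  expect_true(all(diff(rs[order(m0$dose[m0$dose > 0])]) < 0))
})

test_that("configurations round-trip through the key-value text format", {
  cfg <- synthetic_config(seed = 33, sigma = 0.07, w0 = 0.8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$doses, cfg$doses)
  expect_equal(back$imax, cfg$imax)
  expect_equal(back$sigma, 0.07)
  expect_equal(back$seed, 33L)
  expect_identical(generate_experiment(back), generate_experiment(cfg))
  # offending keys are named
  writeLines(c("doses = 0,1", "bogus_key = 3"), path)
  expect_error(read_synthetic_config(path), class = "soilecotox_config_error",
               regexp = "bogus_key")
})
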