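# Independent oracles used to cross-check the implementations. These are
# deliberately naive (enumeration / grid refinement / direct sums) and do
# not share code with the package.

# Brute-force fit of PEC(d, t) = f * d * exp(-k t) by iterative grid
# refinement of the sum of squared log residuals.
oracle_pec_grid_search <- function(table, rounds = 14) {
  d <- table[table$dose > 0, ]
  sse <- function(f, k) {
    sum((log(d$value) - log(f * d$dose) + k * d$time)^2)
  }
  f_range <- c(1e-4, 1)
  k_range <- c(1e-5, 0.2)
  for (r in seq_len(rounds)) {
    fs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = 41))
    ks <- seq(k_range[1], k_range[2], length.out = 41)
    grid <- expand.grid(f = fs, k = ks)
    grid$sse <- mapply(sse, grid$f, grid$k)
    best <- grid[which.min(grid$sse), ]
    # a wide (+-4 cell) re-bracketing absorbs drift along the f-k ridge
    fi <- which.min(abs(fs - best$f))
    ki <- which.min(abs(ks - best$k))
    f_range <- c(fs[max(1, fi - 4)], fs[min(41, fi + 4)])
    k_range <- c(ks[max(1, ki - 4)], ks[min(41, ki + 4)])
  }
  list(f = best$f, k = best$k)
}

# Direct two-way sum-of-squares decomposition of a complete dose x time
# grid (matrix doses x times), one observation per cell.
oracle_ss_decomposition <- function(m) {
  grand <- mean(m)
  ss_dose <- ncol(m) * sum((rowMeans(m) - grand)^2)
  ss_time <- nrow(m) * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  list(ss_dose = ss_dose, ss_time = ss_time,
       ss_interaction = ss_total - ss_dose - ss_time, ss_total = ss_total)
}

# Exhaustive pairwise check of a compact letter display: two groups must
# share at least one letter iff their pairwise comparison is
# non-significant.
oracle_cld_consistent <- function(letters_vec, sig) {
  lev <- names(letters_vec)
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i) next
      shared <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                 strsplit(letters_vec[j], "")[[1]])) > 0
      if (shared == sig[lev[i], lev[j]]) return(FALSE)
    }
  }
  TRUE
}

# Ward merge cost between two singleton points: half the squared distance.
oracle_first_ward_merge <- function(x) {
  n <- nrow(x)
  best <- c(NA, NA); best_d <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- sum((x[i, ] - x[j, ])^2)
      if (dij < best_d) {
        best_d <- dij
        best <- c(i, j)
      }
    }
  }
  list(pair = best, cost = best_d)
}

random_emergence_profile <- function() {
  n_days <- 10
  counts <- rpois(n_days, lambda = sample(c(0.5, 2, 10, 50), 1))
  if (sum(counts) == 0) counts[sample(n_days, 1)] <- 1L
  counts
}
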