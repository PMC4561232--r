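# Assessment statistics: dose correlation with significance flags,
# two-way eta-squared variance partitioning, compact letter display over
# Tukey's range test, Ward clustering of response profiles, and PCA of
# resistance matrices.

#' Pearson correlation between dose and a response
#'
#' Standard Pearson correlation on the raw dose scale (no log transform),
#' with a two-sided t test significance flag at the conventional
#' assessment level of p = 0.01. For tables that include an untreated
#' control, the control (dose 0) is part of the sequence; resistance and
#' resilience indices are undefined at dose 0, so those correlations use
#' the treated doses only.
#'
#' @param doses Numeric dose sequence (length >= 3).
#' @param values Response values, same length.
#' @param alpha Significance level for the flag (default 0.01).
#' @return List of class `"dose_correlation"`: `r`, `n`, `p_value`,
#'   `alpha`, `significant`.
#' @examples
#' dose_correlation(c(0, 0.075, 2.25, 11.25, 22.50),
#'                  c(0.136, 0.132, 0.129, 0.109, 0.092))
#' @export
dose_correlation <- function(doses, values, alpha = 0.01) {
  if (length(doses) != length(values)) {
    stop_soilx("validation_error", "doses and values must have equal length")
  }
  if (length(doses) < 3) stop_soilx("validation_error", "need at least 3 points")
  if (sd(values) == 0) {
    stop_soilx("degenerate_correlation", "values have zero variance")
  }
  ct <- cor.test(doses, values, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(doses),
                 p_value = ct$p.value, alpha = alpha,
                 significant = ct$p.value < alpha),
            class = "dose_correlation")
}

#' @export
print.dose_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.4g)%s\n",
              x$r, x$n, x$p_value,
              if (x$significant) paste0(" * significant at p = ", x$alpha) else ""))
  invisible(x)
}

#' Two-way eta-squared variance partition
#'
#' Decomposes the total sum of squares of a complete dose x time factorial
#' into dose, time, interaction and (with replicated observations) error
#' components, and reports each share as `eta^2 = SS / SS_total` on the
#' percent scale. On a means grid (one value per cell) the error SS is 0
#' and the interaction is the residual of the additive fit; shares from a
#' means grid approximate, but do not equal, the replicate-level partition.
#'
#' @param data Tibble with columns `dose`, `time`, `value` for a single
#'   variable; one row per cell (means grid) or several (replicates).
#' @return Tibble of class `"variance_partition"` with columns `term`
#'   (`dose`, `time`, `dose:time`, `error`, `total`), `df`, `sum_sq`,
#'   `eta_sq_percent`.
#' @examples
#' ea <- load_fixture("enzyme_activity")
#' eta_squared(ea[ea$variable == "alkaline_phosphatase", ])
#' @export
eta_squared <- function(data) {
  fd <- factor(data$dose)
  ft <- factor(data$time)
  counts <- table(fd, ft)
  if (any(counts == 0)) {
    stop_soilx("layout_error",
               "incomplete dose x time layout: every cell needs at least one value")
  }
  if (length(unique(as.vector(counts))) != 1L) {
    stop_soilx("layout_error", "unbalanced layout: cells have unequal replication")
  }
  # suppress the 0-df F-test warning on saturated (means-grid) fits;
  # only the sums of squares are used
  a <- suppressWarnings(anova(lm(data$value ~ fd * ft)))
  ss <- a[["Sum Sq"]]
  df <- a[["Df"]]
  terms <- rownames(a)  # "fd", "ft", "fd:ft", "Residuals"
  get <- function(nm) ss[match(nm, terms)]
  ss_err <- get("Residuals")
  out <- tibble::tibble(
    term = c("dose", "time", "dose:time", "error"),
    df = c(df[match(c("fd", "ft", "fd:ft"), terms)], df[match("Residuals", terms)]),
    sum_sq = c(get("fd"), get("ft"), get("fd:ft"), ss_err))
  total <- sum(out$sum_sq)
  out$eta_sq_percent <- 100 * out$sum_sq / total
  out <- dplyr::bind_rows(out, tibble::tibble(term = "total", df = sum(out$df),
                                              sum_sq = total, eta_sq_percent = 100))
  class(out) <- c("variance_partition", class(out))
  out
}

#' Compact letter display for Tukey's range test
#'
#' Groups whose means are not significantly different under Tukey's HSD at
#' level `alpha` share at least one letter; significantly different groups
#' share none. Letters are assigned by the insert-and-absorb algorithm:
#' start from one letter covering all groups, split it for each significant
#' pair, then absorb redundant (subset) letters. Letter order follows
#' group order.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor; level order = first
#'   appearance order for character input).
#' @param alpha Significance level (default 0.01, the conventional
#'   assessment level).
#' @return Named character vector mapping each group to its letters, e.g.
#'   `c(a = "a", b = "ab", c = "b")`; attribute `p_matrix` holds the
#'   Tukey-adjusted pairwise p-values.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(5, 0), rnorm(5, 0.2), rnorm(5, 8))
#' g <- rep(c("ctl", "low", "high"), each = 5)
#' tukey_letters(x, g)
#' @export
tukey_letters <- function(values, groups, alpha = 0.01) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop_soilx("validation_error", "need at least 2 groups")
  n_per <- table(groups)
  if (any(n_per < 2)) {
    stop_soilx("df_error",
               paste0("group(s) with fewer than 2 replicates: ",
                      paste(names(n_per)[n_per < 2], collapse = ", ")))
  }
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  # pairwise significance matrix in level order
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  pmat <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    g1 <- pairs[[i]][1]; g2 <- pairs[[i]][2]
    pmat[g1, g2] <- pmat[g2, g1] <- tk[i, "p adj"]
    sig[g1, g2] <- sig[g2, g1] <- tk[i, "p adj"] < alpha
  }
  cols <- cld_insert_absorb(sig, lev)
  letters_out <- vapply(lev, function(g) {
    paste0(letters[which(vapply(cols, function(cl) g %in% cl, logical(1)))],
           collapse = "")
  }, character(1))
  attr(letters_out, "p_matrix") <- pmat
  letters_out
}

# Insert-and-absorb (Piepho-style) letter construction from a logical
# pairwise significance matrix. Returns a list of letter columns, each a
# character vector of member groups.
cld_insert_absorb <- function(sig, lev) {
  cols <- list(lev)
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i || !sig[i, j]) next
      gi <- lev[i]; gj <- lev[j]
      k <- 1L
      while (k <= length(cols)) {
        cl <- cols[[k]]
        if (gi %in% cl && gj %in% cl) {
          # split the offending column into two, one without each member
          cols[[k]] <- setdiff(cl, gi)
          cols[[length(cols) + 1L]] <- setdiff(cl, gj)
          # absorb: drop columns that are subsets of another column
          keep <- rep(TRUE, length(cols))
          for (a in seq_along(cols)) {
            for (b in seq_along(cols)) {
              if (a != b && keep[a] && keep[b] &&
                  all(cols[[a]] %in% cols[[b]]) &&
                  !(all(cols[[b]] %in% cols[[a]]) && a < b)) {
                keep[a] <- FALSE
              }
            }
          }
          cols <- cols[keep]
          k <- 0L
        }
        k <- k + 1L
      }
    }
  }
  # stable ordering: by first member's level index
  first <- vapply(cols, function(cl) min(match(cl, lev)), numeric(1))
  cols[order(first)]
}

#' Ward hierarchical clustering of response profiles
#'
#' Standardizes each feature (z-score), computes Euclidean distances
#' between profiles and applies Ward's minimum-variance linkage. The
#' classic dialect runs the Ward update on squared Euclidean distances
#' (`hclust` method `"ward.D"` on `d^2`, merge heights in squared units);
#' the alternative `"ward.D2"` dialect operates on unsquared distances.
#' Both produce the same merge order.
#'
#' @param x Numeric matrix or data frame, one row per profile (rownames
#'   are used as labels), columns are features.
#' @param standardize Z-score each feature first (default `TRUE`).
#' @param dialect `"squared"` (classic Ward, default) or `"euclidean"`
#'   (`ward.D2`).
#' @return An [stats::hclust] tree; merge heights are non-decreasing.
#' @examples
#' mc <- load_fixture("microbial_counts")
#' m <- tidyr::pivot_wider(mc, names_from = c(dose, time), values_from = value)
#' ward_cluster(tibble::column_to_rownames(m, "variable"))
#' @export
ward_cluster <- function(x, standardize = TRUE, dialect = c("squared", "euclidean")) {
  dialect <- match.arg(dialect)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_soilx("validation_error", "need at least 2 profiles")
  sds <- apply(x, 2, sd)
  if (standardize && any(sds == 0)) {
    dropped <- colnames(x)[sds == 0]
    warn(paste0("dropping constant feature(s) before standardization: ",
                paste(dropped, collapse = ", ")),
         class = "soilecotox_constant_feature")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (standardize) x <- scale(x)
  d <- dist(x)
  if (dialect == "squared") hclust(d^2, method = "ward.D")
  else hclust(d, method = "ward.D2")
}

#' Explained variance of principal components
#'
#' PCA of a cases x variables matrix with variables standardized
#' (correlation-matrix PCA, the convention for multi-variable resistance
#' profiles), reporting the percentage of total variance carried by each
#' component.
#'
#' @param x Numeric matrix or data frame, cases in rows.
#' @param scale Standardize variables (default `TRUE`; `FALSE` gives
#'   covariance-matrix PCA).
#' @return Tibble of class `"pca_variance"` with columns `component`,
#'   `variance_percent` (non-increasing, summing to 100) and
#'   `cumulative_percent`; the component scores and loadings are attached
#'   as attributes `scores` and `loadings`.
#' @examples
#' rs <- load_fixture("resistance")
#' m <- tidyr::pivot_wider(rs, names_from = variable, values_from = value)
#' pca_variance(m[, -(1:2)])
#' @export
pca_variance <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop_soilx("validation_error", "need at least 2 cases and 2 variables")
  }
  if (any(is.na(x))) stop_soilx("validation_error", "missing entries not allowed")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop_soilx("domain_error",
               paste0("zero-variance variable(s): ", paste(nm, collapse = ", ")))
  }
  p <- prcomp(x, center = TRUE, scale. = scale)
  ev <- p$sdev^2
  pct <- 100 * ev / sum(ev)
  out <- tibble::tibble(component = seq_along(pct),
                        variance_percent = pct,
                        cumulative_percent = cumsum(pct))
  attr(out, "scores") <- p$x
  attr(out, "loadings") <- p$rotation
  class(out) <- c("pca_variance", class(out))
  out
}
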