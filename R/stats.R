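.vgs_cache <- new.env(parent = emptyenv())

# all permutations of 1:n as an integer matrix (n! x n); cached, n <= 10
perm_matrix <- function(n) {
  stopifnot(n >= 1, n <= 10)
  key <- paste0("perm", n)
  if (!is.null(.vgs_cache[[key]])) return(.vgs_cache[[key]])
  p <- matrix(1L, 1, 1)
  for (m in seq_len(n)[-1]) {
    sz <- nrow(p)
    out <- matrix(0L, sz * m, m)
    for (k in seq_len(m)) {
      rows <- ((k - 1) * sz + 1):(k * sz)
      if (k > 1) out[rows, 1:(k - 1)] <- p[, 1:(k - 1), drop = FALSE]
      out[rows, k] <- m
      if (k < m) out[rows, (k + 1):m] <- p[, k:(m - 1), drop = FALSE]
    }
    p <- out
  }
  .vgs_cache[[key]] <- p
  p
}

# sorted |rho| of the exact null permutation distribution for untied ranks;
# universal given n, so cached
spearman_abs_null <- function(n) {
  key <- paste0("null", n)
  if (!is.null(.vgs_cache[[key]])) return(.vgs_cache[[key]])
  p <- perm_matrix(n)
  base <- seq_len(n)
  nr <- nrow(p)
  rho <- numeric(nr)
  chunk <- 500000L
  for (lo in seq(1L, nr, by = chunk)) {
    hi <- min(lo + chunk - 1L, nr)
    d2 <- rowSums((p[lo:hi, , drop = FALSE] -
                     matrix(base, hi - lo + 1L, n, byrow = TRUE))^2)
    rho[lo:hi] <- 1 - 6 * d2 / (n * (n^2 - 1))
  }
  out <- sort(abs(rho))
  .vgs_cache[[key]] <- out
  out
}

# exact two-sided permutation p-value for Spearman's rho at small n.
# Untied data uses the universal null; ties fall back to conditional
# enumeration over the observed rank multisets.
exact_spearman_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  eps <- 1e-9
  thr <- abs(rho_obs) - eps
  no_ties <- !anyDuplicated(rx) && !anyDuplicated(ry)
  if (no_ties) {
    null_abs <- spearman_abs_null(n)
    return((length(null_abs) - findInterval(thr, null_abs)) /
             length(null_abs))
  }
  p <- perm_matrix(n)
  nr <- nrow(p)
  mx <- mean(rx); my <- mean(ry)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  count <- 0
  chunk <- 200000L
  for (lo in seq(1L, nr, by = chunk)) {
    hi <- min(lo + chunk - 1L, nr)
    m <- matrix(ry[p[lo:hi, , drop = FALSE]], hi - lo + 1L, n)
    s <- as.vector(m %*% rx)
    rho <- (s - n * mx * my) / ((n - 1) * sx * sy)
    count <- count + sum(abs(rho) >= thr)
  }
  count / nr
}

correlation_result <- function(method, rho, p, n, status = "ok") {
  data.frame(method = method, rho = rho, p_value = p, n = n,
             status = status, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' Computes Spearman's rho using average ranks for ties.  The two-sided
#' p-value comes from the exact permutation distribution when the number
#' of complete pairs is at most `exact_max_n` (all `n!` pairings
#' enumerated; with ties, conditionally on the observed rank multisets)
#' and from the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom otherwise.  Pairs with a missing value in
#' either vector are removed first.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_max_n Largest n for which the exact permutation p-value is
#'   computed (at most 10); set to 0 to force the t-approximation.
#' @return A one-row data frame with columns `method`, `rho`, `p_value`,
#'   `n` and `status` (`"ok"`, `"insufficient_data"` with fewer than 3
#'   complete pairs, or `"zero_variance"`).
#' @export
rank_correlation <- function(x, y, exact_max_n = 10) {
  stopifnot(length(x) == length(y), exact_max_n <= 10)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(correlation_result("spearman", NA_real_, NA_real_, n,
                              "insufficient_data"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(correlation_result("spearman", NA_real_, NA_real_, n,
                              "zero_variance"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    p <- exact_spearman_p(rx, ry, rho)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  correlation_result("spearman", rho, p, n)
}

#' Pearson product-moment correlation
#'
#' Pearson's r with the two-sided t-test p-value on `n - 2` degrees of
#' freedom, after pairwise removal of missing values.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row data frame as in [rank_correlation()], with
#'   `method = "pearson"`.
#' @export
product_moment_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(correlation_result("pearson", NA_real_, NA_real_, n,
                              "insufficient_data"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(correlation_result("pearson", NA_real_, NA_real_, n,
                              "zero_variance"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  correlation_result("pearson", r, p, n)
}

#' Correlate oculomotor metrics against clinical covariates
#'
#' One correlation per metric x covariate pair over pairwise-complete
#' observations, flagged significant at `p < alpha`.  No multiple-testing
#' correction is applied (the companion report states the number of tests
#' and the uncorrected-p caveat).  Spearman is the default, appropriate
#' for ordinal covariates such as the Hoehn & Yahr stage.
#'
#' @param records Subject-level data frame (e.g. the `records` element of
#'   [simulate_cohort()] or a joined clinical/metrics table).
#' @param metrics Character vector of metric column names.
#' @param covariates Character vector of covariate column names.
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha Significance threshold.
#' @param exact_max_n Passed to [rank_correlation()].
#' @return A data frame with one row per pair: `metric`, `covariate`,
#'   `method`, `rho`, `p_value`, `n`, `status`, `significant`, plus
#'   attribute `n_tests`.
#' @export
correlation_grid <- function(records, metrics, covariates,
                             method = c("spearman", "pearson"),
                             alpha = 0.05, exact_max_n = 10) {
  method <- match.arg(method)
  if (!length(metrics) || !length(covariates)) {
    stop("metrics and covariates must be non-empty")
  }
  missing_cols <- setdiff(c(metrics, covariates), names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) < 3) stop("at least 3 subjects required")
  grid <- expand.grid(metric = metrics, covariate = covariates,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- records[[grid$metric[i]]]
    y <- records[[grid$covariate[i]]]
    res <- if (method == "spearman") {
      rank_correlation(x, y, exact_max_n = exact_max_n)
    } else {
      product_moment_correlation(x, y)
    }
    cbind(grid[i, , drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  attr(out, "alpha") <- alpha
  out
}

#' Verbal effect-size label for a correlation coefficient
#'
#' Bands on `|rho|`: below the first bound negligible, then weak,
#' moderate, and high at or above the last bound.
#'
#' @param rho Correlation coefficient(s).
#' @param bands Increasing band bounds.
#' @return Character vector of labels.
#' @export
effect_size_label <- function(rho, bands = c(0.1, 0.3, 0.5)) {
  stopifnot(length(bands) == 3, !is.unsorted(bands))
  cut(abs(rho), breaks = c(-Inf, bands, Inf),
      labels = c("negligible", "weak", "moderate", "high"),
      right = FALSE)
}

round2 <- function(x) round(x, 2)

#' Descriptive summary of a clinical cohort
#'
#' Counts and percentages by sex, age statistics overall and by sex,
#' Hoehn & Yahr stage counts/percentages (of the whole cohort) overall and
#' by sex with the count-weighted mean stage per sex, and MMSE / CANTAB
#' means and sample SDs (n-1 denominator).  Percentages are reported to
#' two decimals.  Columns absent from `records` are skipped.
#'
#' @param records Subject-level data frame with at least a `sex` column;
#'   optionally `age`, `hy_stage`, `mmse` and `cantab_*` columns.
#' @return An object of class `cohort_summary` (a list).
#' @export
cohort_summary <- function(records) {
  stopifnot(nrow(records) > 0, "sex" %in% names(records))
  n <- nrow(records)
  out <- list(n_total = n)
  sexes <- c("male", "female")
  sex_n <- vapply(sexes, function(s) sum(records$sex == s), numeric(1))
  out$sex <- data.frame(sex = sexes, n = sex_n,
                        pct = round2(100 * sex_n / n),
                        stringsAsFactors = FALSE)
  if ("age" %in% names(records) && any(!is.na(records$age))) {
    grp <- function(sel, label) {
      a <- records$age[sel]
      data.frame(group = label, mean = mean(a, na.rm = TRUE),
                 median = stats::median(a, na.rm = TRUE),
                 sd = stats::sd(a[!is.na(a)]), stringsAsFactors = FALSE)
    }
    out$age <- rbind(grp(rep(TRUE, n), "all"),
                     grp(records$sex == "female", "female"),
                     grp(records$sex == "male", "male"))
  }
  if ("hy_stage" %in% names(records)) {
    stages <- sort(unique(records$hy_stage))
    cnt <- function(sel) vapply(stages, function(s) {
      sum(records$hy_stage[sel] == s)
    }, numeric(1))
    tot <- cnt(rep(TRUE, n)); m <- cnt(records$sex == "male")
    f <- cnt(records$sex == "female")
    out$hy <- data.frame(stage = stages,
                         n_total = tot, pct_total = round2(100 * tot / n),
                         n_male = m, pct_male = round2(100 * m / n),
                         n_female = f, pct_female = round2(100 * f / n))
    wmean <- function(sel) {
      hy <- records$hy_stage[sel]
      if (!length(hy)) return(NA_real_)
      mean(hy)
    }
    out$hy_weighted_mean <- c(
      male = wmean(records$sex == "male"),
      female = wmean(records$sex == "female"),
      all = wmean(rep(TRUE, n)))
  }
  num_block <- function(cols) {
    cols <- intersect(cols, names(records))
    cols <- cols[vapply(cols, function(cl) any(!is.na(records[[cl]])),
                        logical(1))]
    if (!length(cols)) return(NULL)
    do.call(rbind, lapply(cols, function(cl) {
      v <- records[[cl]][!is.na(records[[cl]])]
      data.frame(variable = cl, mean = mean(v), sd = stats::sd(v),
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }
  out$mmse <- num_block("mmse")
  out$cantab <- num_block(c("cantab_prmcd", "cantab_prmmcld",
                            "cantab_prmpci", "cantab_prmmcli",
                            "cantab_swm_te"))
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n_total, "\n")
  print(x$sex, row.names = FALSE)
  if (!is.null(x$hy)) {
    cat("Hoehn & Yahr stages (% of cohort):\n")
    print(x$hy, row.names = FALSE)
    cat(sprintf("count-weighted mean stage: male %.2f, female %.2f\n",
                x$hy_weighted_mean[["male"]], x$hy_weighted_mean[["female"]]))
  }
  invisible(x)
}

#' Plain-text correlation report
#'
#' Formats a [correlation_grid()] result as a markdown-style report,
#' stating the number of uncorrected tests performed.
#'
#' @param grid A [correlation_grid()] result.
#' @param bands Effect-size bands passed to [effect_size_label()].
#' @return Character vector of report lines.
#' @export
format_correlation_report <- function(grid, bands = c(0.1, 0.3, 0.5)) {
  alpha <- attr(grid, "alpha")
  lines <- c(
    sprintf("# Correlation report (%d tests, alpha = %g)",
            nrow(grid), alpha),
    paste("NOTE: p-values are uncorrected for multiple testing;",
          sprintf("%d tests were performed.", nrow(grid))),
    "")
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    lines <- c(lines, if (g$status != "ok") {
      sprintf("- %s vs %s: %s (n = %d)", g$metric, g$covariate, g$status,
              g$n)
    } else {
      sprintf("- %s vs %s (%s): rho = %.3f (%s), P = %.4g, n = %d%s",
              g$metric, g$covariate, g$method, g$rho,
              as.character(effect_size_label(g$rho, bands)), g$p_value,
              g$n, if (g$significant) " *" else "")
    })
  }
  lines
}
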