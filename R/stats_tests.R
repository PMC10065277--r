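# Nonparametric group comparisons, chi-square, and FDR-screened Spearman
# correlation matrices.

#' Mann-Whitney test with rank-biserial effect size
#'
#' U is computed from rank sums with midranks for ties as the number of pairs
#' in which `x` exceeds `y` (ties counting one half), so complete separation
#' with `x` below `y` gives `U = 0` and `r = 1 - 2U/(n1*n2) = 1`; positive `r`
#' therefore means the first sample tends to be the smaller one. The p value
#' is obtained by exact enumeration of group assignments when feasible and by
#' the normal approximation with tie correction otherwise. The confidence
#' interval applies a Fisher-z transform to `r` with standard error
#' `sqrt((n1 + n2 + 1) / (3 * n1 * n2))` -- the convention that reproduces
#' published rank-biserial intervals; the true sampling method behind any
#' given report is rarely stated, so treat the CI as descriptive.
#'
#' @param x,y numeric samples (non-empty).
#' @param conf_level confidence level for the rank-biserial interval.
#' @param exact_max exact enumeration is used while `choose(n1+n2, n1)` does
#'   not exceed this bound.
#' @return A list of class `effect_size_result`: `U`, `rank_biserial_r`,
#'   `ci_low`, `ci_high`, `p`, `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_rb(c(1, 2, 3), c(10, 11, 12))$rank_biserial_r  # 1
#' @export
mann_whitney_rb <- function(x, y, conf_level = 0.95, exact_max = 2e5) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_user("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_user("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs x > y (+ ties/2)
  r <- rank_biserial_from_u(u, n1, n2)

  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (choose(n1 + n2, n1) <= exact_max) {
    method <- "exact enumeration"
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    method <- "normal approximation (tie-corrected)"
    n <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }

  se_z <- sqrt((n1 + n2 + 1) / (3 * n1 * n2))
  zr <- atanh(max(-1 + 1e-12, min(1 - 1e-12, r)))
  half <- stats::qnorm(1 - (1 - conf_level) / 2) * se_z
  structure(list(U = u, rank_biserial_r = r,
                 ci_low = tanh(zr - half), ci_high = tanh(zr + half),
                 p = min(1, p), n1 = n1, n2 = n2, method = method),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.2f (n1 = %d, n2 = %d), p = %.4g\n",
              x$U, x$n1, x$n2, x$p))
  cat(sprintf("rank-biserial r = %.3f, 95%% CI [%.3f, %.3f]  (%s)\n",
              x$rank_biserial_r, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Without Yates continuity correction by default (the convention matching
#' typical report tables); the corrected variant sits behind `correct = TRUE`.
#'
#' @param tab a matrix (or table) of counts, at least 2x2.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return A list of class `chi_square_result`: `statistic`, `df`, `p`,
#'   `expected`.
#' @examples
#' chi_square_test(matrix(c(18, 14, 4, 7), 2))$statistic  # 1.296
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2L)) stop_user("contingency table must be at least 2x2")
  if (any(tab < 0) || anyNA(tab)) stop_user("counts must be non-negative and complete")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop_user("table has an expected cell count of 0")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, expected = expected),
            class = "chi_square_result")
}

#' Spearman correlation matrix with Benjamini-Hochberg screening
#'
#' Spearman's rho with midranks over pairwise-complete observations; p values
#' from the t approximation; BH step-up correction over the family of unique
#' off-diagonal cells; significance mask at the configured level. Variables
#' that are constant (rho undefined) are flagged and their cells left `NA`.
#'
#' @param variables data frame of numeric variables (>= 2 columns).
#' @param level FDR level for the significance mask.
#' @param min_n minimum number of complete observations required per pair.
#' @return A list of class `correlation_report`: matrices `rho`, `p`, `q`,
#'   `significant`, `n`, plus `flagged_constant` and `level`.
#' @export
spearman_fdr <- function(variables, level = 0.05, min_n = 3) {
  stopifnot(is.data.frame(variables) || is.matrix(variables))
  X <- as.matrix(variables)
  if (!is.numeric(X)) stop_user("all variables must be numeric")
  p_var <- ncol(X)
  if (p_var < 2L) stop_user("need at least 2 variables")
  vn <- colnames(X)
  if (is.null(vn)) vn <- colnames(X) <- paste0("V", seq_len(p_var))

  flagged <- vn[apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || stats::sd(v) == 0
  })]
  rho <- p <- nmat <- matrix(NA_real_, p_var, p_var, dimnames = list(vn, vn))
  diag(rho) <- 1
  for (i in seq_len(p_var - 1)) {
    for (j in (i + 1):p_var) {
      ok <- stats::complete.cases(X[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < min_n || vn[i] %in% flagged || vn[j] %in% flagged) next
      xi <- X[ok, i]; xj <- X[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      r <- stats::cor(xi, xj, method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- if (abs(r) >= 1) 0 else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(tt), n - 2)
      }
    }
  }
  q <- matrix(NA_real_, p_var, p_var, dimnames = list(vn, vn))
  lower <- which(lower.tri(p) & !is.na(p))
  if (length(lower)) {
    q[lower] <- stats::p.adjust(p[lower], method = "BH")
    q[upper.tri(q)] <- t(q)[upper.tri(q)]
  }
  structure(list(rho = rho, p = p, q = q,
                 significant = !is.na(q) & q <= level,
                 n = nmat, flagged_constant = flagged, level = level),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> ", ncol(x$rho), " variables, FDR level ",
      x$level, "\n", sep = "")
  cat("  significant pairs:", sum(x$significant[lower.tri(x$significant)]), "\n")
  if (length(x$flagged_constant)) {
    cat("  constant (rho undefined):",
        paste(x$flagged_constant, collapse = ", "), "\n")
  }
  invisible(x)
}
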