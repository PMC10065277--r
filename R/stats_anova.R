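# Mixed-design (split-plot) ANOVA/ANCOVA with partial eta squared, and
# Bonferroni-corrected post hoc comparisons.
#
# With every factor at 2 levels the split-plot decomposition is exact via
# per-subject contrast scores: each within effect (and its interaction with
# the group) is a t test on the subjects' contrast scores, which under sum
# coding reproduces Type III (unweighted-means) F tests -- the convention of
# the common point-and-click packages. No sphericity machinery is needed
# (1-df effects are always spherical).

#' Mixed-design ANOVA / ANCOVA with partial eta squared
#'
#' One between-subject factor (2 levels) crossed with up to two within-subject
#' factors (2 levels each), Type III sums of squares, each effect tested
#' against its own error stratum: the between effect against the
#' subject-level error, within effects and their interactions with the group
#' against the corresponding subject-by-factor stratum. Covariates (constant
#' per participant) enter the between stratum, turning the analysis into an
#' ANCOVA for the group effect. Participants with incomplete within cells are
#' dropped listwise and logged in the `dropped` attribute; duplicate
#' observations per cell are averaged.
#'
#' @param data long-format data frame.
#' @param dependent name of the dependent-variable column.
#' @param between name of the 2-level between-subject factor column.
#' @param within character vector (length 0--2) of within-subject factor
#'   columns, each with 2 levels.
#' @param covariates optional character vector of participant-constant
#'   covariate columns.
#' @param participant name of the participant id column.
#' @return A data frame of class `anova_table`: `effect`, `sum_sq`, `df1`,
#'   `df2`, `f`, `p`, `partial_eta_sq`; attributes `dropped` (ids excluded
#'   listwise) and `levene_p` (diagnostic Brown-Forsythe test of equal group
#'   variances on the subject means -- a flag, not a gate).
#' @examples
#' d <- expand.grid(participant = paste0("P", 1:8), eye = c("yes", "no"))
#' d$group <- rep(c("A", "B"), each = 4)[match(d$participant, paste0("P", 1:8))]
#' set.seed(1); d$y <- rnorm(nrow(d), 100, 10)
#' mixed_anova(d, "y", between = "group", within = "eye")
#' @export
mixed_anova <- function(data, dependent, between, within = character(0),
                        covariates = NULL, participant = "participant") {
  cols <- c(dependent, between, within, covariates, participant)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop_user("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (f in c(between, within)) {
    lev <- unique(stats::na.omit(as.character(data[[f]])))
    if (length(lev) != 2L) {
      stop_user("factor '%s' has %d levels; only 2-level designs are supported",
                f, length(lev))
    }
  }

  # one row per participant x within-cell (average duplicates)
  cell_levels <- if (length(within)) {
    do.call(expand.grid, c(lapply(within, function(f)
      sort(unique(as.character(data[[f]])))), list(stringsAsFactors = FALSE)))
  } else data.frame(row.names = 1)
  n_cells <- max(1L, nrow(cell_levels))
  cell_of <- function(d) {
    if (!length(within)) return(rep("all", nrow(d)))
    do.call(paste, c(lapply(within, function(f) as.character(d[[f]])), sep = "."))
  }
  cell_names <- if (length(within)) {
    do.call(paste, c(cell_levels, sep = "."))
  } else "all"

  data <- data[!is.na(data[[dependent]]), , drop = FALSE]
  ids <- unique(as.character(data[[participant]]))
  Y <- matrix(NA_real_, length(ids), n_cells, dimnames = list(ids, cell_names))
  agg <- stats::aggregate(data[[dependent]],
                          by = list(id = as.character(data[[participant]]),
                                    cell = cell_of(data)), FUN = mean)
  Y[cbind(match(agg$id, ids), match(agg$cell, cell_names))] <- agg$x

  complete <- !apply(is.na(Y), 1, any)
  dropped <- ids[!complete]
  Y <- Y[complete, , drop = FALSE]
  ids <- ids[complete]
  if (length(dropped)) {
    message(length(dropped), " participant(s) dropped listwise: ",
            paste(dropped, collapse = ", "))
  }

  first_of <- function(col) {
    data[[col]][match(ids, as.character(data[[participant]]))]
  }
  grp <- factor(first_of(between))
  if (any(table(grp) < 2L)) {
    stop_user("need at least 2 participants per '%s' group", between)
  }
  gs <- ifelse(grp == levels(grp)[1], 1, -1)  # sum coding: Type III

  cov_df <- NULL
  if (length(covariates)) {
    cov_df <- as.data.frame(lapply(covariates, first_of),
                            col.names = covariates)
  }

  one_df_test <- function(response, X, term_col) {
    # F test of a single column of a full-rank design, via its t statistic
    fit <- stats::lm.fit(X, response)
    df2 <- length(response) - fit$rank
    rss <- sum(fit$residuals^2)
    mse <- rss / df2
    xtxi <- chol2inv(chol(crossprod(X)))
    est <- fit$coefficients[term_col]
    se <- sqrt(mse * xtxi[term_col, term_col])
    f <- (est / se)^2
    c(sum_sq = unname(f * mse), df1 = 1, df2 = df2, f = unname(f),
      p = stats::pf(unname(f), 1, df2, lower.tail = FALSE))
  }

  Xb <- cbind(`(Intercept)` = 1, group = gs)
  if (!is.null(cov_df)) {
    mm <- stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
    Xb <- cbind(Xb, mm)
  }

  rows <- list()
  m <- rowMeans(Y)
  rows[[between]] <- one_df_test(m, Xb, 2L)

  if (length(within)) {
    codes <- lapply(within, function(f) {
      lev <- sort(unique(as.character(data[[f]])))
      ifelse(cell_levels[[match(f, within)]] == lev[1], 1, -1)
    })
    names(codes) <- within
    subsets <- unlist(lapply(seq_along(within), function(k)
      utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
    Xw <- cbind(`(Intercept)` = 1, group = gs)
    for (S in subsets) {
      cs <- Reduce(`*`, codes[S])
      score <- as.numeric(Y %*% cs) / n_cells
      rows[[paste(S, collapse = ":")]] <- one_df_test(score, Xw, 1L)
      rows[[paste(c(S, between), collapse = ":")]] <- one_df_test(score, Xw, 2L)
    }
  }

  tab <- do.call(rbind, rows)
  out <- data.frame(effect = names(rows), tab, row.names = NULL)
  out$partial_eta_sq <- partial_eta_sq(out$f, out$df1, out$df2)

  # Brown-Forsythe (median-centred Levene) diagnostic on the subject means
  admd <- abs(m - stats::ave(m, grp, FUN = stats::median))
  lev_p <- tryCatch(
    suppressWarnings(stats::anova(stats::lm(admd ~ grp))$`Pr(>F)`[1]),
    error = function(e) NA_real_)
  structure(out, dropped = dropped, levene_p = lev_p,
            class = c("anova_table", "data.frame"))
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All pairwise t comparisons among the cells of `effect` (paired t tests when
#' every participant contributes to both cells, two-sample otherwise), with
#' each p value multiplied by the family size and capped at 1.
#'
#' @param data long-format data frame.
#' @param dependent name of the dependent-variable column.
#' @param effect character vector of factor column(s) whose cell combinations
#'   form the comparison family.
#' @param participant name of the participant id column.
#' @param family_size family size used for the correction; defaults to the
#'   number of comparisons performed.
#' @return A data frame of class `posthoc_table`: `comparison`, `estimate`,
#'   `t`, `df`, `p_raw`, `p_adj`, `ci_low`, `ci_high`, `paired`.
#' @export
bonferroni_posthoc <- function(data, dependent, effect,
                               participant = "participant",
                               family_size = NULL) {
  missing_cols <- setdiff(c(dependent, effect, participant), names(data))
  if (length(missing_cols)) {
    stop_user("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  cell <- do.call(paste, c(lapply(effect, function(f) as.character(data[[f]])),
                           sep = "."))
  levels <- unique(cell)
  if (length(levels) < 2L) stop_user("post hoc family is empty: '%s' has %d cell(s)",
                                     paste(effect, collapse = ":"), length(levels))
  agg <- stats::aggregate(data[[dependent]],
                          by = list(id = as.character(data[[participant]]),
                                    cell = cell), FUN = mean)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  m <- if (is.null(family_size)) length(pairs) else family_size
  rows <- lapply(pairs, function(pr) {
    a <- agg[agg$cell == pr[1], ]
    b <- agg[agg$cell == pr[2], ]
    common <- intersect(a$id, b$id)
    paired <- length(common) == length(union(a$id, b$id)) && length(common) >= 2
    tt <- if (paired) {
      stats::t.test(a$x[match(common, a$id)], b$x[match(common, b$id)],
                    paired = TRUE)
    } else {
      stats::t.test(a$x, b$x, var.equal = TRUE)
    }
    data.frame(comparison = paste(pr[1], "-", pr[2]),
               estimate = unname(if (paired) tt$estimate else diff(rev(tt$estimate))),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, tt$p.value * m),
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               paired = paired)
  })
  structure(do.call(rbind, rows), family_size = m,
            class = c("posthoc_table", "data.frame"))
}
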