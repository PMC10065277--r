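# Closed-form effect-size identities. These recover the effect sizes that a
# report prints alongside F/U statistics, and double as internal invariants.

#' Partial eta squared from an F statistic
#'
#' `eta2_p = F*df1 / (F*df1 + df2)`, the share of effect variance in effect
#' plus error variance, recoverable from any printed F test.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(8.999, 1, 41)  # 0.180
#' @export
partial_eta_sq <- function(f, df1, df2) {
  stopifnot(f >= 0, df1 > 0, df2 > 0)
  (f * df1) / (f * df1 + df2)
}

#' R squared from a regression F statistic
#'
#' Same identity as [partial_eta_sq()]: for the overall model test of a linear
#' regression, `R^2 = F*df1 / (F*df1 + df2)`.
#'
#' @inheritParams partial_eta_sq
#' @return R squared in `[0, 1]`.
#' @examples
#' r_squared_from_f(4.210, 3, 138)  # 0.084
#' @export
r_squared_from_f <- function(f, df1, df2) partial_eta_sq(f, df1, df2)

#' Rank-biserial correlation from a Mann-Whitney U
#'
#' `r = 1 - 2U / (n1 * n2)`: the difference between the proportions of
#' favourable and unfavourable pairs.
#'
#' @param u Mann-Whitney U statistic.
#' @param n1,n2 group sizes.
#' @return Rank-biserial correlation in `[-1, 1]`.
#' @examples
#' rank_biserial_from_u(18.50, 22, 21)  # 0.920
#' @export
rank_biserial_from_u <- function(u, n1, n2) {
  stopifnot(u >= 0, u <= n1 * n2, n1 >= 1, n2 >= 1)
  1 - 2 * u / (n1 * n2)
}
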