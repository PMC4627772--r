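# Dunnett's many-to-one comparison with two-sided adjusted p-values.
#
# No multiple-comparison package exists in the target environment, so the
# joint null distribution of the max |T_j| statistic is integrated directly.
# Conditioning on the control group's z-score z and the pooled scale
# s = S/sigma makes the treatment statistics independent:
#   |T_j| <= q  <=>  |Z_j/sqrt(n_j) - z/sqrt(n_0)| <= q s se_j,
# with se_j = sqrt(1/n_j + 1/n_0), Z_j iid N(0,1). Hence
#   P(max |T_j| <= q) =
#     E_s E_z prod_j [ Phi(sqrt(n_j)(z/sqrt(n_0) + q s se_j))
#                    - Phi(sqrt(n_j)(z/sqrt(n_0) - q s se_j)) ],
# with z ~ N(0,1) and nu * s^2 ~ chi-square(nu). Valid for unbalanced
# designs. Quadrature accuracy ~1e-6; cross-checked against
# scipy.stats.dunnett during development (frozen values in the tests).

# P(max_j |T_j| <= q) under the joint Dunnett null.
dunnett_pmax_le <- function(q, n_treat, n0, nu) {
  if (q <= 0) return(0)
  se <- sqrt(1 / n_treat + 1 / n0)
  inner_z <- function(zv, s) {
    vapply(zv, function(z) {
      lo <- sqrt(n_treat) * (z / sqrt(n0) - q * s * se)
      hi <- sqrt(n_treat) * (z / sqrt(n0) + q * s * se)
      prod(stats::pnorm(hi) - stats::pnorm(lo)) * stats::dnorm(z)
    }, numeric(1))
  }
  outer_s <- function(sv) {
    vapply(sv, function(s) {
      dens <- 2 * nu * s * stats::dchisq(nu * s^2, nu)
      if (dens == 0) return(0)
      dens * stats::integrate(inner_z, -9, 9, s = s,
                              rel.tol = 1e-9)$value
    }, numeric(1))
  }
  # s concentrates around 1 with SD ~ 1/sqrt(2 nu); generous bounds.
  hi <- 1 + 12 / sqrt(2 * nu) + 2
  val <- stats::integrate(outer_s, 1e-8, hi, rel.tol = 1e-8)$value
  min(max(val, 0), 1)
}

#' Dunnett's test: each treatment versus a shared control
#'
#' Pooled-variance many-to-one comparisons with two-sided p-values adjusted
#' for the family of contrasts (the distribution of the maximum absolute
#' Dunnett statistic), computed by direct numerical integration and valid
#' for unbalanced group sizes.
#'
#' @param values numeric response vector.
#' @param labels group label per value.
#' @param control the control group's label.
#' @return data.frame, one row per non-control group: `label`, `n`,
#'   `diff` (treatment mean - control mean), `se`, `statistic`, `df`,
#'   `p_adj`.
#' @export
dunnett_test <- function(values, labels, control) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values)
  values <- values[ok]; labels <- labels[ok]
  if (!control %in% labels) abort("control label not found")
  groups <- unique(labels)
  treat <- setdiff(groups, control)
  if (length(treat) == 0L) abort("no treatment groups")
  ns <- vapply(groups, function(g) sum(labels == g), numeric(1))
  if (any(ns < 2L)) abort("every group needs n >= 2")
  means <- vapply(groups, function(g) mean(values[labels == g]), numeric(1))
  nu <- length(values) - length(groups)
  s2 <- sum(vapply(groups, function(g) {
    v <- values[labels == g]
    sum((v - mean(v))^2)
  }, numeric(1))) / nu
  n0 <- ns[[control]]
  n_t <- ns[treat]
  se <- sqrt(s2 * (1 / n_t + 1 / n0))
  tstat <- (means[treat] - means[[control]]) / se
  p_adj <- vapply(abs(tstat), function(q) {
    1 - dunnett_pmax_le(q, n_t, n0, nu)
  }, numeric(1))
  data.frame(label = treat, n = as.integer(n_t),
             diff = unname(means[treat] - means[[control]]),
             se = unname(se), statistic = unname(tstat), df = nu,
             p_adj = unname(pmin(pmax(p_adj, 0), 1)),
             row.names = NULL)
}
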