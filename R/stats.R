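# Statistical helpers used by the imaging analysis and study design: the
# two-tailed two-sample t comparison and the normal-approximation group-size
# formula.

#' Two-tailed two-sample t comparison
#'
#' Classical Student's (pooled-variance) t by default; Welch available. Two
#' identical constant groups are reported as t = 0, p = 1 with a flag rather
#' than an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (Student's) or `"welch"`.
#' @return Object of class `group_comparison`: `t_stat`, `df`,
#'   `p_two_tailed`, `group_means`, `group_sds`, `n_per_group`,
#'   `degenerate` flag.
#' @export
two_sample_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  degenerate <- stats::var(group_a) == 0 && stats::var(group_b) == 0
  if (degenerate && mean(group_a) == mean(group_b)) {
    res <- list(statistic = 0, parameter = length(group_a) + length(group_b) - 2,
                p.value = 1)
  } else if (degenerate) {
    # zero variance, different means: infinitely significant under the model
    res <- list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                parameter = length(group_a) + length(group_b) - 2, p.value = 0)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"))
    res <- list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
                p.value = tt$p.value)
  }
  structure(list(
    t_stat = res$statistic,
    df = res$parameter,
    p_two_tailed = res$p.value,
    group_means = c(mean(group_a), mean(group_b)),
    group_sds = c(stats::sd(group_a), stats::sd(group_b)),
    n_per_group = c(length(group_a), length(group_b)),
    variant = variant,
    degenerate = degenerate
  ), class = "group_comparison")
}

#' Per-group sample size from the two-sample normal approximation
#'
#' \deqn{n = \lceil (\sigma_1^2 + \sigma_2^2)\,(z_{1-\alpha/2} + z_{1-\beta})^2
#'   / \Delta^2 \rceil}
#'
#' where \eqn{\Delta} is the minimum effect size (difference between means),
#' \eqn{\sigma_1, \sigma_2} the per-group standard deviations, \eqn{\alpha}
#' the two-sided type-I error and \eqn{1 - \beta} the power. All of
#' \eqn{\Delta} and \eqn{\sigma} are on the same (e.g. percent) scale.
#'
#' @param delta Minimum effect size, > 0.
#' @param sigma1,sigma2 Per-group SDs, > 0 (`sigma2` defaults to `sigma1`).
#' @param alpha Two-sided type-I error, in (0, 1).
#' @param power Target power 1 - beta, in (0, 1).
#' @return Integer n per group (ceiling), with attribute `n_raw` holding the
#'   pre-ceiling value.
#' @export
group_size <- function(delta, sigma1, sigma2 = sigma1, alpha = 0.05, power = 0.80) {
  if (delta <= 0 || sigma1 <= 0 || sigma2 <= 0) {
    stop("delta and sigmas must be > 0", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n_raw <- (sigma1^2 + sigma2^2) * (z_a + z_b)^2 / delta^2
  structure(as.integer(ceiling(n_raw)), n_raw = n_raw)
}
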