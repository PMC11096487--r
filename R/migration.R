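#' Mixture chi-square likelihood-ratio test for post-split migration
#'
#' Tests a migration rate against zero in an isolation-with-migration model.
#' Because the null (zero migration) lies on the boundary of the parameter
#' space, the statistic `-2 log(Lambda)` is compared to a 50:50 mixture of a
#' point mass at zero (chi-square with 0 df) and a chi-square with 1 df:
#' `p = 0.5 * P(chisq_1 >= statistic)` for a positive statistic, and `p = 1`
#' at zero.
#'
#' @param statistic the likelihood-ratio statistic `-2 log(Lambda)`, >= 0.
#' @param alpha significance level used for the decision (default 0.05).
#' @return object of class `lrt_result`: list with `statistic`, `p_value`,
#'   `alpha`, `critical_value` and logical `decision`
#'   (`statistic > critical_value`).
#' @export
mixture_lrt_pvalue <- function(statistic, alpha = 0.05) {
  if (statistic < 0) stop("the likelihood-ratio statistic must be >= 0")
  p <- if (statistic == 0) 1 else
    0.5 * stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  cv <- mixture_critical_value(alpha)
  out <- list(statistic = statistic, p_value = p, alpha = alpha,
              critical_value = cv, decision = statistic > cv)
  class(out) <- "lrt_result"
  out
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("-2log(Lambda) = %.4g, p = %.3f (mixture chi-square null), %s at alpha = %g (critical value %.2f)\n",
              x$statistic, x$p_value,
              if (x$decision) "migration supported" else "no migration detected",
              x$alpha, x$critical_value))
  invisible(x)
}

#' Critical value of the 50:50 chi-square mixture
#'
#' `P(mixture >= c) = 0.5 * P(chisq_1 >= c) = alpha` gives the
#' `(1 - 2 alpha)` quantile of a chi-square with 1 df; at `alpha = 0.05`
#' this is the 90% quantile, 2.71.
#'
#' @param alpha significance level in (0, 0.5).
#' @return the critical value.
#' @export
mixture_critical_value <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 0.5)
    stop("alpha must lie in (0, 0.5): the mixture places mass 0.5 at zero")
  stats::qchisq(1 - 2 * alpha, df = 1)
}

#' Mutation-rate scaling for IM parameter conversion
#'
#' Locus-wide mutation rates per year for the chloroplast and ITS markers,
#' the generation time, and the inheritance scalars of the two marker
#' classes. The geometric mean of the per-locus yearly rates is used as the
#' composite rate `u_year` (the convention of the IM software family), and
#' `u_gen = u_year * generation_time`.
#'
#' @param mu_cp,mu_its locus-wide mutation rates per year.
#' @param generation_time generation time in years.
#' @return list of class `im_scaling` with the rates, `u_year`, `u_gen` and
#'   the inheritance scalars.
#' @export
im_scaling <- function(mu_cp = 1.67e-6, mu_its = 1.24e-6,
                       generation_time = 25) {
  stopifnot(mu_cp > 0, mu_its > 0, generation_time > 0)
  u_year <- sqrt(mu_cp * mu_its)
  out <- list(mu_cp = mu_cp, mu_its = mu_its,
              generation_time = generation_time,
              u_year = u_year, u_gen = u_year * generation_time,
              scalar_cp = inheritance_scalar("haploid", "uniparental"),
              scalar_nuclear = inheritance_scalar("diploid", "biparental"))
  class(out) <- "im_scaling"
  out
}

#' Convert scaled IM estimates to demographic units
#'
#' Converts composite population-size parameters `q = 4 Ne u_gen` to
#' effective population sizes in individuals and scaled split times
#' `t = T u_year` to years:
#' `Ne = q / (4 u_gen)` and `T_years = t / u_year`.
#'
#' @param q_values numeric vector of scaled population-size estimates.
#' @param t_values numeric vector of scaled split-time estimates.
#' @param scaling an [im_scaling()] object.
#' @return list with `Ne` (individuals), `T_years` and the `scaling` used.
#' @export
convert_im_estimates <- function(q_values = numeric(0),
                                 t_values = numeric(0),
                                 scaling = im_scaling()) {
  if (any(q_values < 0) || any(t_values < 0))
    stop("q and t estimates must be non-negative")
  list(Ne = q_values / (4 * scaling$u_gen),
       T_years = t_values / scaling$u_year,
       scaling = scaling)
}

#' Back-convert demographic units to IM scaled parameters
#'
#' Inverse of [convert_im_estimates()], provided so conversions round-trip.
#'
#' @param Ne effective sizes in individuals.
#' @param T_years split times in years.
#' @param scaling an [im_scaling()] object.
#' @return list with `q` and `t`.
#' @export
deconvert_im_estimates <- function(Ne = numeric(0), T_years = numeric(0),
                                   scaling = im_scaling()) {
  list(q = Ne * 4 * scaling$u_gen, t = T_years * scaling$u_year)
}

#' Inheritance scalar of a locus
#'
#' Relative effective population size of a locus given its ploidy and
#' transmission mode in a dioecious species with an equal sex ratio: the
#' product of a ploidy factor (1 for diploid, 1/2 for haploid) and a
#' transmitting-sex factor (1 for biparental, 1/2 for uniparental). A
#' paternally inherited haploid chloroplast therefore has scalar
#' `1/2 * 1/2 = 0.25`; a biparental diploid nuclear locus has scalar 1.
#'
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param transmission `"biparental"` or `"uniparental"`.
#' @return the scalar.
#' @export
inheritance_scalar <- function(ploidy = c("haploid", "diploid"),
                               transmission = c("uniparental", "biparental")) {
  ploidy <- match.arg(ploidy)
  transmission <- match.arg(transmission)
  pf <- switch(ploidy, haploid = 0.5, diploid = 1)
  tf <- switch(transmission, uniparental = 0.5, biparental = 1)
  pf * tf
}

#' Likelihood-ratio test report for a set of migration statistics
#'
#' Applies [mixture_lrt_pvalue()] to each statistic and assembles a table.
#'
#' @param statistics named numeric vector of `-2 log(Lambda)` statistics.
#' @param alpha significance level.
#' @return data.frame with `migration`, `statistic`, `p_value` (3 decimals in
#'   the printed report; full precision retained), `critical_value`,
#'   `significant`.
#' @export
lrt_table <- function(statistics, alpha = 0.05) {
  res <- lapply(statistics, mixture_lrt_pvalue, alpha = alpha)
  data.frame(migration = if (is.null(names(statistics)))
    paste0("m", seq_along(statistics)) else names(statistics),
    statistic = statistics,
    p_value = vapply(res, function(r) r$p_value, numeric(1)),
    critical_value = vapply(res, function(r) r$critical_value, numeric(1)),
    significant = vapply(res, function(r) r$decision, logical(1)),
    row.names = NULL)
}
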