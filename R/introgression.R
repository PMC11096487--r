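#' Parameters of the cytonuclear introgression model
#'
#' A deterministic, discrete-generation model of introgression levels at a
#' paternally inherited haploid (chloroplast) locus versus a biparentally
#' inherited nuclear locus in a dioecious recipient population receiving
#' exotic genes either as pollen or as seeds.
#'
#' In pollen mode, a fraction `rate` of each generation's seeds is sired by
#' exotic pollen: such a recruit carries an exotic chloroplast (cpDNA is
#' paternal) but only half an exotic nuclear genome, so the instantaneous
#' cp introgression rate is exactly double the nuclear one. In seed mode, a
#' fraction `rate` of recruits are exotic seeds carrying exotic states at
#' both loci; a sex-ratio-adjusting mechanism can make exotic-origin recruits
#' female with probability `phi_e` different from the local `phi_l`, which
#' depresses cp (male-transmitted) introgression relative to nuclear
#' introgression.
#'
#' @param mode `"pollen"` or `"seed"`.
#' @param rate per-generation flow rate: fraction of seeds sired by exotic
#'   pollen (pollen mode) or fraction of recruits that are exotic seeds
#'   (seed mode).
#' @param phi_e probability an exotic-origin recruit is female (seed mode).
#' @param phi_l probability a local-origin recruit is female (default 0.5).
#' @param generations number of generations to iterate.
#' @return list of class `introgression_params`.
#' @export
introgression_params <- function(mode = c("pollen", "seed"), rate,
                                 phi_e = 0.5, phi_l = 0.5, generations = 1L) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, rate <= 1, phi_e >= 0, phi_e <= 1,
            phi_l >= 0, phi_l <= 1, generations >= 1)
  out <- list(mode = mode, rate = rate, phi_e = phi_e, phi_l = phi_l,
              generations = as.integer(generations))
  class(out) <- "introgression_params"
  out
}

#' All-zero introgression state
#'
#' State variables: `x_M`, `x_F` exotic chloroplast-haplotype frequencies
#' among males and females; `y_M`, `y_F` exotic nuclear allele frequencies
#' among males and females.
#'
#' @return named numeric vector of zeros.
#' @export
introgression_state0 <- function() {
  c(x_M = 0, x_F = 0, y_M = 0, y_F = 0)
}

#' One generation of the introgression recursions
#'
#' Pollen mode: every recruit has a local mother; its father is exotic with
#' probability `p = rate` (cp exotic, one exotic nuclear allele), otherwise a
#' local male. Hence for both sexes
#' `x' = p + (1 - p) x_M` and `y' = (y_F + p + (1 - p) y_M) / 2`.
#'
#' Seed mode: recruits are a mixture of exotic seeds (weight `s = rate`;
#' cp frequency 1, nuclear frequency 1) and local offspring (weight `1 - s`;
#' cp frequency `x_M`, nuclear `(y_M + y_F)/2`). Recruits enter the female
#' pool with probability `phi_e` (exotic origin) or `phi_l` (local origin),
#' and each sex pool is conditioned on its own recruitment mass, e.g.
#' `x'_M = [s (1-phi_e) + (1-s)(1-phi_l) x_M] / [s (1-phi_e) + (1-s)(1-phi_l)]`.
#'
#' @param state named vector as from [introgression_state0()].
#' @param params an [introgression_params()] object.
#' @return updated state vector.
#' @export
introgression_step <- function(state, params) {
  x_M <- state[["x_M"]]; x_F <- state[["x_F"]]
  y_M <- state[["y_M"]]; y_F <- state[["y_F"]]
  if (params$mode == "pollen") {
    p <- params$rate
    x_new <- p + (1 - p) * x_M
    y_new <- (y_F + p + (1 - p) * y_M) / 2
    return(c(x_M = x_new, x_F = x_new, y_M = y_new, y_F = y_new))
  }
  s <- params$rate
  phi_e <- params$phi_e; phi_l <- params$phi_l
  y_loc <- (y_M + y_F) / 2
  w_eM <- s * (1 - phi_e); w_lM <- (1 - s) * (1 - phi_l)
  w_eF <- s * phi_e;       w_lF <- (1 - s) * phi_l
  if (w_eM + w_lM <= 0) stop("no males recruited (phi_e and phi_l both 1)")
  if (w_eF + w_lF <= 0) stop("no females recruited (phi_e and phi_l both 0)")
  c(x_M = (w_eM * 1 + w_lM * x_M) / (w_eM + w_lM),
    x_F = (w_eF * 1 + w_lF * x_M) / (w_eF + w_lF),
    y_M = (w_eM * 1 + w_lM * y_loc) / (w_eM + w_lM),
    y_F = (w_eF * 1 + w_lF * y_loc) / (w_eF + w_lF))
}

#' Introgression-level trajectory
#'
#' Iterates [introgression_step()] from the all-zero state. Population-level
#' introgression levels weight the two adult sex pools equally:
#' `L_cp = (x_M + x_F)/2`, `L_nuc = (y_M + y_F)/2`.
#'
#' @param params an [introgression_params()] object.
#' @return data.frame of class `introgression_trajectory` with columns
#'   `generation` (0..T), `x_M`, `x_F`, `y_M`, `y_F`, `L_cp`, `L_nuc`.
#' @export
introgression_trajectory <- function(params) {
  T <- params$generations
  states <- matrix(0, nrow = T + 1L, ncol = 4,
                   dimnames = list(NULL, c("x_M", "x_F", "y_M", "y_F")))
  st <- introgression_state0()
  for (t in seq_len(T)) {
    st <- introgression_step(st, params)
    states[t + 1L, ] <- st
  }
  out <- data.frame(generation = 0:T, states,
                    L_cp = (states[, "x_M"] + states[, "x_F"]) / 2,
                    L_nuc = (states[, "y_M"] + states[, "y_F"]) / 2)
  class(out) <- c("introgression_trajectory", "data.frame")
  out
}

#' Individual-based forward simulation of introgression
#'
#' Independent validation of the deterministic recursions: a dioecious
#' population of `N` individuals with non-overlapping generations, paternal
#' chloroplast inheritance and biparental nuclear inheritance. Each
#' generation, `N` recruits are drawn: in seed mode a recruit is an exotic
#' seed with probability `rate` (cp = 1, nuclear genotype 1/1, female with
#' probability `phi_e`), otherwise the offspring of a local mother and
#' father (female with probability `phi_l`); in pollen mode every recruit
#' has a local mother and an exotic father with probability `rate`. Levels
#' average the two sex pools equally; replicates where a sex class goes
#' extinct are discarded with a warning.
#'
#' @param params an [introgression_params()] object.
#' @param N population size per generation (>= 50).
#' @param seed integer seed.
#' @param replicates number of independent replicates.
#' @return list with `L_cp`, `L_nuc` (means across replicates), `se_cp`,
#'   `se_nuc` (Monte-Carlo standard errors), `replicates_used`.
#' @export
introgression_forward <- function(params, N = 2000, seed = 1L,
                                  replicates = 50) {
  if (N < 50) stop("N must be at least 50")
  set.seed(seed)
  res_cp <- numeric(0); res_nuc <- numeric(0)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    sex <- stats::runif(N) < 0.5           # TRUE = female
    cp <- integer(N)
    nuc <- matrix(0L, N, 2)
    ok <- TRUE
    for (t in seq_len(params$generations)) {
      males <- which(!sex); females <- which(sex)
      if (length(males) == 0L || length(females) == 0L) { ok <- FALSE; break }
      exotic <- stats::runif(N) < params$rate
      mothers <- sample(females, N, replace = TRUE)
      fathers <- sample(males, N, replace = TRUE)
      mat_allele <- nuc[cbind(mothers, sample.int(2L, N, replace = TRUE))]
      pat_allele <- nuc[cbind(fathers, sample.int(2L, N, replace = TRUE))]
      if (params$mode == "pollen") {
        new_cp <- ifelse(exotic, 1L, cp[fathers])
        new_nuc <- cbind(mat_allele, ifelse(exotic, 1L, pat_allele))
        new_sex <- stats::runif(N) < params$phi_l
      } else {
        new_cp <- ifelse(exotic, 1L, cp[fathers])
        new_nuc <- cbind(ifelse(exotic, 1L, mat_allele),
                         ifelse(exotic, 1L, pat_allele))
        new_sex <- stats::runif(N) < ifelse(exotic, params$phi_e, params$phi_l)
      }
      cp <- new_cp; nuc <- new_nuc; sex <- new_sex
    }
    if (!ok || !any(sex) || !any(!sex)) { dropped <- dropped + 1L; next }
    lf <- mean(cp[sex]); lm <- mean(cp[!sex])
    yf <- mean(nuc[sex, ]); ym <- mean(nuc[!sex, ])
    res_cp <- c(res_cp, (lf + lm) / 2)
    res_nuc <- c(res_nuc, (yf + ym) / 2)
  }
  if (dropped > 0L)
    warning(dropped, " replicate(s) discarded after sex-class extinction")
  n <- length(res_cp)
  if (n == 0L) stop("all replicates lost a sex class")
  list(L_cp = mean(res_cp), L_nuc = mean(res_nuc),
       se_cp = stats::sd(res_cp) / sqrt(n),
       se_nuc = stats::sd(res_nuc) / sqrt(n),
       replicates_used = n)
}

#' Calibrate the introgression model to observed levels
#'
#' Grid search minimising the squared error between the trajectory endpoint
#' `(L_cp, L_nuc)` after `generations` generations and the observed levels.
#' Pollen mode keeps `L_cp >= L_nuc` at every generation, so an observation
#' with `L_nuc > L_cp` is flagged infeasible rather than silently fitted.
#'
#' @param observed list or named vector with `L_cp` and `L_nuc` in (0, 1).
#' @param mode `"pollen"` or `"seed"`.
#' @param generations generations of flow assumed.
#' @param rate_grid candidate flow rates.
#' @param phi_e_grid candidate exotic female fractions (seed mode only).
#' @param phi_l local female fraction (default 0.5).
#' @return list with `feasible`, `rate`, `phi_e`, `objective` (squared
#'   error at the optimum), `fit` (endpoint levels) and `grid` (the full
#'   objective surface as a data.frame).
#' @export
introgression_calibrate <- function(observed, mode = c("pollen", "seed"),
                                    generations,
                                    rate_grid = seq(0.0005, 0.05, by = 0.0005),
                                    phi_e_grid = seq(0.5, 0.995, by = 0.005),
                                    phi_l = 0.5) {
  mode <- match.arg(mode)
  L_cp <- observed[["L_cp"]]; L_nuc <- observed[["L_nuc"]]
  stopifnot(L_cp > 0, L_cp < 1, L_nuc > 0, L_nuc < 1)
  if (mode == "pollen" && L_nuc > L_cp) {
    return(list(feasible = FALSE, rate = NA_real_, phi_e = NA_real_,
                objective = NA_real_, fit = NULL, grid = NULL,
                reason = paste("pollen-mediated flow cannot produce a nuclear",
                               "introgression level above the chloroplast level")))
  }
  if (mode == "pollen") phi_e_grid <- 0.5
  grid <- expand.grid(rate = rate_grid, phi_e = phi_e_grid)
  obj <- numeric(nrow(grid))
  fits <- matrix(0, nrow(grid), 2)
  for (i in seq_len(nrow(grid))) {
    pr <- introgression_params(mode, grid$rate[i], phi_e = grid$phi_e[i],
                               phi_l = phi_l, generations = generations)
    tr <- introgression_trajectory(pr)
    endp <- tr[nrow(tr), c("L_cp", "L_nuc")]
    fits[i, ] <- as.numeric(endp)
    obj[i] <- (endp$L_cp - L_cp)^2 + (endp$L_nuc - L_nuc)^2
  }
  best <- which.min(obj)
  list(feasible = TRUE, rate = grid$rate[best],
       phi_e = if (mode == "seed") grid$phi_e[best] else NA_real_,
       objective = obj[best],
       fit = c(L_cp = fits[best, 1L], L_nuc = fits[best, 2L]),
       grid = data.frame(grid, objective = obj))
}
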