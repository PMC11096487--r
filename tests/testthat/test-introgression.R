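test_that("pollen flow doubles the instantaneous cp introgression rate", {
  for (p in c(0.01, 0.1, 0.37, 0.9)) {
    st <- introgression_step(introgression_state0(),
                             introgression_params("pollen", p))
    L_cp <- (st[["x_M"]] + st[["x_F"]]) / 2
    L_nuc <- (st[["y_M"]] + st[["y_F"]]) / 2
    expect_equal(L_cp / L_nuc, 2)
  }
})

test_that("pollen-mode trajectories follow the closed-form solution", {
  tr <- introgression_trajectory(introgression_params("pollen", 0.1,
                                                      generations = 10))
  expect_equal(tr$L_cp[11], 1 - 0.9^10)
  expect_equal(tr$L_nuc[11], 1 - 0.95^10)
  expect_equal(tr$L_cp, 1 - 0.9^(0:10))
  expect_equal(tr$L_nuc, 1 - 0.95^(0:10))
})

test_that("seed mode is symmetric when sex ratios are equal", {
  for (s in c(0.01, 0.1, 0.5)) {
    for (phi in c(0.3, 0.5, 0.8)) {
      tr <- introgression_trajectory(
        introgression_params("seed", s, phi_e = phi, phi_l = phi,
                             generations = 15))
      expect_equal(tr$L_cp, tr$L_nuc, tolerance = 1e-12)
    }
  }
})

test_that("all-female exotic recruits never feed the male cp pool", {
  tr <- introgression_trajectory(
    introgression_params("seed", 0.05, phi_e = 1, phi_l = 0.5,
                         generations = 20))
  expect_equal(tr$x_M, rep(0, 21))
  expect_gt(tr$L_nuc[21], 0)
  # degenerate sex pools error out
  expect_error(introgression_step(introgression_state0(),
                                  introgression_params("seed", 0.1,
                                                       phi_e = 1, phi_l = 1)),
               "no males")
})

test_that("zero flow leaves a flat zero trajectory", {
  for (mode in c("pollen", "seed")) {
    tr <- introgression_trajectory(introgression_params(mode, 0,
                                                        generations = 8))
    expect_equal(tr$L_cp, rep(0, 9))
    expect_equal(tr$L_nuc, rep(0, 9))
  }
})

test_that("frequencies stay in [0,1] and levels are monotone in generation", {
  set.seed(17)
  for (i in 1:20) {
    mode <- sample(c("pollen", "seed"), 1)
    pr <- introgression_params(mode, runif(1, 0, 0.5),
                               phi_e = runif(1, 0.05, 0.95),
                               phi_l = runif(1, 0.05, 0.95),
                               generations = 25)
    tr <- introgression_trajectory(pr)
    vals <- unlist(tr[, c("x_M", "x_F", "y_M", "y_F", "L_cp", "L_nuc")])
    expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
    expect_true(all(diff(tr$L_cp) >= -1e-12))
    expect_true(all(diff(tr$L_nuc) >= -1e-12))
  }
})

test_that("mode dictates the cp/nuclear ordering of introgression levels", {
  # pollen: cp leads at every generation
  tr_p <- introgression_trajectory(introgression_params("pollen", 0.07,
                                                        generations = 30))
  expect_true(all(tr_p$L_cp >= tr_p$L_nuc - 1e-12))
  # seed with female-biased exotic recruits: nuclear leads, strictly after
  # the second generation
  tr_s <- introgression_trajectory(
    introgression_params("seed", 0.03, phi_e = 0.9, phi_l = 0.5,
                         generations = 30))
  expect_true(all(tr_s$L_nuc >= tr_s$L_cp - 1e-12))
  expect_true(all(tr_s$L_nuc[-(1:2)] > tr_s$L_cp[-(1:2)]))
})

test_that("the individual-based simulation reproduces the recursions", {
  pr <- introgression_params("seed", 0.05, phi_e = 0.8, phi_l = 0.5,
                             generations = 10)
  fw <- introgression_forward(pr, N = 600, seed = 21, replicates = 40)
  tr <- introgression_trajectory(pr)
  endp <- tr[nrow(tr), ]
  expect_lt(abs(fw$L_cp - endp$L_cp), 3 * fw$se_cp + 0.01)
  expect_lt(abs(fw$L_nuc - endp$L_nuc), 3 * fw$se_nuc + 0.01)
  # determinism and exact zero at zero flow
  fw2 <- introgression_forward(pr, N = 600, seed = 21, replicates = 5)
  fw3 <- introgression_forward(pr, N = 600, seed = 21, replicates = 5)
  expect_identical(fw2, fw3)
  fw0 <- introgression_forward(introgression_params("pollen", 0,
                                                    generations = 5),
                               N = 100, seed = 3, replicates = 3)
  expect_equal(fw0$L_cp, 0)
  expect_equal(fw0$L_nuc, 0)
})

test_that("calibration recovers self-generated targets and flags infeasibility", {
  target_pr <- introgression_params("seed", 0.01, phi_e = 0.9, phi_l = 0.5,
                                    generations = 40)
  tr <- introgression_trajectory(target_pr)
  obs <- as.list(tr[nrow(tr), c("L_cp", "L_nuc")])
  fit <- introgression_calibrate(obs, "seed", generations = 40,
                                 rate_grid = seq(0.002, 0.03, by = 0.002),
                                 phi_e_grid = seq(0.5, 0.95, by = 0.05))
  expect_true(fit$feasible)
  expect_lt(abs(fit$rate - 0.01), 0.002 + 1e-12)   # within one grid cell
  expect_lt(abs(fit$phi_e - 0.9), 0.05 + 1e-12)
  # the observed continental-to-Taiwan pattern cannot arise from pollen flow
  inf <- introgression_calibrate(list(L_cp = 0.014, L_nuc = 0.057), "pollen",
                                 generations = 40)
  expect_false(inf$feasible)
  expect_match(inf$reason, "pollen")
  # one-generation pollen fit recovers p = L_cp
  fit1 <- introgression_calibrate(list(L_cp = 0.03, L_nuc = 0.015), "pollen",
                                  generations = 1,
                                  rate_grid = seq(0.005, 0.06, by = 0.005))
  expect_equal(fit1$rate, 0.03)
})
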