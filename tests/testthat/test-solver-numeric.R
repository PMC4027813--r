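test_that("with no enzymes, pumps or conversion the state is uniform", {
  dead <- dead_enzymes()
  p <- ccm_params(membrane = membrane_params(jc = 0, alpha = 0),
                  ca = dead$ca, rubisco = dead$rubisco)
  s <- fast_solve(p)
  expect_lt(max(abs(s$C - p$external$Cout)), 1e-9)
  expect_lt(max(abs(s$H - p$external$Hout)), 1e-9)
})

test_that("cytosolic HCO3- matches the transport-leakage balance", {
  p <- default_params()           # jc = 0.6, kc = 1e-3, alpha = 0
  s <- fast_solve(p)
  HR <- membrane_conc(s, "H")
  ## balance oracle before consumption correction: Hout*(1 + jc/kmH)
  expect_equal(HR, 14 * (1 + 0.6 / 3e-4), tolerance = 0.01)
  ## the published 30 mM pool, within 10%
  expect_equal(HR / 1000, 30, tolerance = 0.10)
  ## flat across the cytosol (spread below 1% of the mean)
  cyt <- s$r > p$geometry$Rc
  expect_lt(diff(range(s$H[cyt])) / mean(s$H[cyt]), 0.01)
})

test_that("carboxysomal H/C sits at equilibrium shifted by the loss rate", {
  ## well-mixed balance oracle: the steady carboxysomal ratio exceeds Keq
  ## by (shell loss + RuBisCO consumption per unit CO2) over the linear CA
  ## dehydration rate a = Vba/Kba
  p <- default_params(jc = 0.01)
  s <- fast_solve(p)
  Cc <- region_mean(s, "C", "carboxysome")
  ratio <- region_mean(s, "H", "carboxysome") / Cc
  a <- p$ca$Vba / p$ca$Kba
  loss_per_C <- 3 * p$shell$kc / p$geometry$Rc +
    p$rubisco$Vmax / (Cc + km_effective(p$rubisco, p$external$O))
  expect_equal(ratio, equilibrium_ratio(p$ca) + loss_per_C / a,
               tolerance = 0.02)
  ## and converges to the bare equilibrium ratio as losses vanish
  p2 <- default_params(jc = 0.01, kc = 1e-6)
  p2$rubisco$Vmax <- p$rubisco$Vmax / 100
  p2$rubisco$VmaxO <- p$rubisco$VmaxO / 100
  s2 <- fast_solve(p2)
  expect_equal(region_mean(s2, "H", "carboxysome") /
                 region_mean(s2, "C", "carboxysome"),
               equilibrium_ratio(p$ca), tolerance = 0.01)
})

test_that("steady-state mass balance closes at every operating point", {
  for (ops in list(c(0.6, 1e-3), c(0.06, 1e-3), c(1, 1e-5), c(0.01, 1))) {
    s <- fast_solve(default_params(jc = ops[1], kc = ops[2]))
    b <- flux_budget(s)
    expect_lt(b$conservation_residual, 1e-3)
  }
})

test_that("solutions are grid-converged", {
  p <- default_params()
  c1 <- region_mean(solve_ccm_numeric(p, n = 200), "C", "carboxysome")
  c2 <- region_mean(solve_ccm_numeric(p, n = 400), "C", "carboxysome")
  expect_lt(abs(c1 / c2 - 1), 0.005)
})

test_that("radial profiles have the documented shapes", {
  p <- default_params()
  s <- fast_solve(p)
  ## flat inside the carboxysome
  carb <- s$grid$vin > 0
  expect_lt(diff(range(s$C[carb])) / mean(s$C[carb]), 0.01)
  ## outward-decreasing cytosolic CO2 gradient at kc at/above optimal
  for (kc in c(1e-3, 1)) {
    sk <- fast_solve(default_params(kc = kc))
    Ccyt <- sk$C[sk$r > p$geometry$Rc]
    expect_true(all(diff(Ccyt) <= 1e-12))
  }
})

test_that("interface flux continuity holds at the shell", {
  p <- default_params()
  s <- fast_solve(p)
  g <- s$grid
  m <- g$iface[1]
  jump <- p$shell$kc * 4 * pi * p$geometry$Rc^2 * (s$C[m + 1] - s$C[m])
  ## discrete flux on the cytosol side of the interface
  flux_out <- g$g[m + 1] * (s$C[m + 2] - s$C[m + 1])
  ## at steady state with no cytosolic reactions these differ only by the
  ## (tiny) control-volume imbalance
  expect_equal(jump, flux_out, tolerance = 1e-6)
})

test_that("warm starts reproduce the cold-start solution", {
  p <- default_params()
  s1 <- fast_solve(p)
  s2 <- fast_solve(p, init = s1)
  expect_equal(s1$C, s2$C, tolerance = 1e-8)
})

test_that("shell-localized carbonic anhydrase matches the volumetric case", {
  p <- default_params()
  sv <- fast_solve(p)
  ss <- solve_ccm_shell_ca(p, n = 200)
  expect_equal(region_mean(ss, "C", "carboxysome"),
               region_mean(sv, "C", "carboxysome"), tolerance = 0.02)
  ## crowded interior (sucrose-like diffusivity): still within a few percent
  p2 <- p; p2$diffusion$D_carb <- 1e-7
  sv2 <- fast_solve(p2)
  ss2 <- solve_ccm_shell_ca(p2, n = 200)
  expect_equal(region_mean(ss2, "C", "carboxysome"),
               region_mean(sv2, "C", "carboxysome"), tolerance = 0.05)
  ## degenerate source: zero CA activity gives the volumetric zero-CA state
  dead <- dead_enzymes()
  p3 <- ccm_params(ca = dead$ca)
  expect_equal(solve_ccm_shell_ca(p3, n = 200)$C, fast_solve(p3)$C,
               tolerance = 1e-6)
})
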