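test_that("closed form reduces to uniform state without enzymes or pumps", {
  dead <- dead_enzymes()
  p <- ccm_params(membrane = membrane_params(jc = 0, alpha = 0),
                  ca = dead$ca, rubisco = dead$rubisco)
  s <- solve_ccm_analytic(p, n = 200)
  expect_lt(max(abs(s$C - p$external$Cout)), 1e-6)
  expect_lt(max(abs(s$H - p$external$Hout)), 1e-6)
})

test_that("closed form agrees with the numeric solver at the reference point", {
  p <- default_params()
  sn <- fast_solve(p)
  sa <- solve_ccm_analytic(p, n = 200)
  expect_equal(region_mean(sa, "C", "carboxysome"),
               region_mean(sn, "C", "carboxysome"), tolerance = 0.02)
  expect_equal(membrane_conc(sa, "H"), membrane_conc(sn, "H"),
               tolerance = 0.02)
})

test_that("interior closed form satisfies the linearized ODE", {
  p <- default_params(jc = 0.01)
  sa <- solve_ccm_analytic(p, branch = "unsaturated", n = 400,
                           linearization = "limit")
  ## collocation check: D ((rC)'' / r) + R_CA_lin - R_Rub_lin ~ 0 via
  ## high-order finite differences of the returned closed-form profile
  co <- sa$internals$co
  r <- sa$r; C <- sa$C; H <- sa$H
  idx <- which(r > 0.2 * p$geometry$Rc & r < 0.9 * p$geometry$Rc)
  idx <- idx[seq(2, length(idx) - 1)]
  h <- diff(r)[idx]  # uniform inside
  u <- r * C; v <- r * H
  upp <- (u[idx + 1] - 2 * u[idx] + u[idx - 1]) / h^2
  resC <- p$diffusion$D_carb * upp / r[idx] +
    (co$p0 + co$a * H[idx] - co$b * C[idx]) -
    (co$q0 + co$g * C[idx])
  scale <- max(abs(co$b * C[idx]) + co$q0 + co$g * C[idx])
  expect_lt(max(abs(resC)) / scale, 1e-4)
})

test_that("analytic and numeric solvers agree in self-consistent regimes", {
  p <- default_params()
  jcs <- 10^seq(-3, 0, length.out = 5)
  kcs <- 10^seq(-5, 0, length.out = 5)
  n_checked <- 0
  for (jc in jcs) for (kc in kcs) {
    q <- default_params(jc = jc, kc = kc)
    sa <- tryCatch(solve_ccm_analytic(q, n = 200),
                   ccm_regime_error = function(e) NULL)
    if (is.null(sa) || !isTRUE(sa$regime$valid)) next
    sn <- fast_solve(q)
    expect_equal(region_mean(sa, "C", "carboxysome"),
                 region_mean(sn, "C", "carboxysome"), tolerance = 0.02)
    expect_equal(membrane_conc(sa, "H"), membrane_conc(sn, "H"),
                 tolerance = 0.02)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)  # the oracle covers most of the grid
})

test_that("regime classification follows the stated thresholds", {
  p <- default_params(jc = 1e-3)
  expect_identical(classify_regime(p)$ca_state, "unsaturated")
  expect_identical(classify_regime(default_params(jc = 10))$ca_state,
                   "saturated")
  ## tie-break: carboxysomal H exactly at Kba labels saturated
  s <- fast_solve(p)
  s$H <- s$H * (p$ca$Kba / region_mean(s, "H", "carboxysome"))
  expect_identical(classify_regime(s)$ca_state, "saturated")
})

test_that("deep CA saturation decouples carboxysomal CO2 from transport", {
  ## log-slope of C_carb vs jc flattens strongly across the saturation
  ## transition (the Fig-3 shape)
  cc <- vapply(c(0.01, 0.03, 10, 30), function(jc)
    region_mean(fast_solve(default_params(jc = jc)), "C", "carboxysome"),
    numeric(1))
  slope_unsat <- log(cc[2] / cc[1]) / log(3)
  slope_sat <- log(cc[4] / cc[3]) / log(3)
  expect_gt(slope_unsat, 0.8)
  expect_lt(slope_sat, 0.2)
})

test_that("the two limit branches meet continuously at the CA transition", {
  ## near the jc where carboxysomal H crosses Kba the branch solutions agree
  p <- default_params(jc = 0.25)
  su <- solve_ccm_analytic(p, branch = "unsaturated", linearization = "limit")
  ss <- solve_ccm_analytic(p, branch = "saturated", linearization = "limit")
  expect_equal(region_mean(su, "C", "carboxysome"),
               region_mean(ss, "C", "carboxysome"), tolerance = 0.1)
})

test_that("cytosolic HCO3- closed form inverts the transport balance", {
  p <- default_params()
  expect_equal(hcyt_closed_form(default_params(jc = 0)), 14)
  h1 <- hcyt_closed_form(default_params(jc = 0.3))
  h2 <- hcyt_closed_form(p)  # jc = 0.6
  expect_equal((h2 - 14) / (h1 - 14), 2, tolerance = 1e-12)
  ## inverse consistency with jc = kmH*(Hcyt - Hout)/Hout
  jc_back <- p$membrane$kmH * (h2 - 14) / 14
  expect_equal(jc_back, 0.6, tolerance = 1e-12)
  expect_equal(h2, 14 * (1 + 0.6 / 3e-4), tolerance = 1e-12)
})
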