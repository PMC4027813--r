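test_that("flux budget percentages close under conservation", {
  s <- fast_solve(default_params())
  b <- flux_budget(s)
  pct <- b$table$pct_of_transport
  ## leakage% + CO2-leak% + carboxylation% (+ negligible oxygenation)
  expect_equal(sum(pct[2:4]), 100, tolerance = 0.002)
  expect_lt(b$conservation_residual, 1e-3)
  expect_equal(b$net_hco3, b$gross_transport - b$hco3_leakage)
  s$converged <- FALSE
  expect_error(flux_budget(s), "not converged")
})

test_that("carboxysomal CO2 is unimodal in shell permeability", {
  kcs <- 10^seq(-6, 1, length.out = 9)
  cc <- vapply(kcs, function(kc)
    region_mean(ccmsim:::ccm_point(default_params(), kc = kc, n = 200),
                "C", "carboxysome"), numeric(1))
  ## rises to an interior maximum, then falls: exactly one sign change
  s <- sign(diff(cc))
  expect_equal(sum(diff(s) != 0), 1)
  expect_true(which.max(cc) > 1 && which.max(cc) < length(cc))
})

test_that("carboxysomal CO2 grows monotonically with transport below
           saturation", {
  jcs <- 10^seq(-3, -1, length.out = 6)
  cc <- vapply(jcs, function(jc)
    region_mean(fast_solve(default_params(jc = jc)), "C", "carboxysome"),
    numeric(1))
  expect_true(all(diff(cc) > 0))
})

test_that("facilitated conversion never lowers carboxysomal CO2", {
  cc <- vapply(c(0, 0.1, 1), function(am) {
    p <- default_params()
    p$membrane$alpha <- am * 1e6; p$membrane$Kalpha <- 1e6
    region_mean(fast_solve(p), "C", "carboxysome")
  }, numeric(1))
  expect_true(all(diff(cc) >= 0))
})

test_that("phase scan extracts coherent contours", {
  p <- default_params()
  jcs <- 10^seq(-3, 1, length.out = 10)
  kcs <- 10^seq(-5, 0, length.out = 8)
  sc <- phase_scan(jcs, kcs, p, n = 150)
  expect_equal(dim(sc$C_carb), c(10, 8))
  expect_length(sc$failures, 0)
  km_line <- subset(sc$contours, target == "Km")
  expect_gt(nrow(km_line), 3)
  ## contour points interpolate the level set: re-solving at a contour
  ## point recovers the target concentration
  i <- which.min(abs(km_line$kc - 1e-3))
  sol <- fast_solve(default_params(jc = km_line$jc[i], kc = km_line$kc[i]))
  expect_equal(region_mean(sol, "C", "carboxysome"),
               km_effective(p$rubisco, p$external$O), tolerance = 0.1)
  ## the 30 mM cytosolic line is nearly vertical: jc varies weakly with kc
  h_line <- subset(sc$contours, target == "Hcyt_level")
  expect_gt(nrow(h_line), 3)
  expect_lt(diff(range(h_line$jc)) / mean(h_line$jc), 0.1)
  expect_equal(mean(h_line$jc), 0.643, tolerance = 0.05)
})

test_that("a crowded carboxysome interior does not aid the CCM", {
  ## when the shell is rate limiting (kc well below D_carb/Rc), slowing
  ## interior diffusion a hundredfold leaves the transport required for a
  ## given carboxysomal CO2 essentially unchanged -- CO2 trapping by a
  ## viscous interior is no substitute for a tight shell
  p <- default_params()
  p2 <- p; p2$diffusion$D_carb <- 1e-7
  Km <- km_effective(p$rubisco, p$external$O)
  for (kc in c(1e-5, 1e-4, 1e-3)) {
    j1 <- jc_needed(Km, p, kc = kc, n = 150)
    j2 <- jc_needed(Km, p2, kc = kc, n = 150)
    expect_equal(j2 / j1, 1, tolerance = 0.05)
  }
})

test_that("uptake partition: transport dominates unless CO2 is the bulk of
           the pool", {
  p <- ccm_params(membrane = membrane_params(jc = 1, alpha = 1e6,
                                             Kalpha = 1e6))
  pt <- uptake_partition_scan(seq(0, 1, 0.05), total_Ci = 15, p = p,
                              n = 150)
  tab <- pt$table
  ## no external CO2: nothing to facilitate
  expect_equal(tab$facilitated[1], 0, tolerance = 1e-12)
  expect_gt(tab$transport[1], 100 * tab$conversion_total[1])
  ## crossover near 80% external CO2
  expect_gt(pt$crossover_fraction, 0.72)
  expect_lt(pt$crossover_fraction, 0.9)
  ## scavenging is negligible at the optimal shell permeability
  expect_true(all(tab$scavenging < 0.01 * tab$transport[1]))
  expect_error(uptake_partition_scan(c(-0.1, 0.5), p = p), "\\[0, 1\\]")
})

test_that("pore geometry bounds the shell permeability linearly", {
  sh <- shell_params(Npores = 4800, rpore = 0.35e-7, lshell = 1.8e-7)
  b <- kc_upper_bound(sh, D = 1e-5, Rc = 5e-6)
  ## direct arithmetic of the pore-fraction formula
  expect_equal(b, 4800 * (pi * (0.35e-7)^2) / (4 * pi * (5e-6)^2) *
                 1e-5 / 1.8e-7, tolerance = 1e-12)
  sh2 <- sh; sh2$Npores <- 9600
  expect_equal(kc_upper_bound(sh2, 1e-5, 5e-6), 2 * b)
  sh0 <- sh; sh0$Npores <- 0
  expect_equal(kc_upper_bound(sh0, 1e-5, 5e-6), 0)
  expect_error(kc_upper_bound(shell_params(Npores = NULL)), "pore geometry")
})

test_that("organization: co-localization then encapsulation raise central
           CO2", {
  oc <- organization_compare(ccm_params(), n = 150)
  tb <- oc$table
  rownames(tb) <- tb$scenario
  expect_lt(tb["whole_cell", "C_central"], tb["scaffold", "C_central"])
  expect_lt(tb["scaffold", "C_central"],
            tb["carboxysome_optimal_kc", "C_central"])
  ## scaffolding alone gains roughly an order of magnitude (at least 5x)
  expect_gt(tb["scaffold", "C_central"] / tb["whole_cell", "C_central"], 5)
  ## every scenario hits the cytosolic HCO3- target
  expect_equal(unname(tb$H_cytosol), rep(3e4, 4), tolerance = 1e-6)
  ## error rates fall as CO2 is concentrated
  expect_true(all(diff(tb$oxygenation_error_pct) < 0))
  ## a very permeable shell converges to the scaffold limit
  oc2 <- organization_compare(ccm_params(), kc_high = 100, n = 150)
  tb2 <- oc2$table; rownames(tb2) <- tb2$scenario
  expect_equal(tb2["carboxysome_high_kc", "C_central"],
               tb2["scaffold", "C_central"], tolerance = 0.25)
})

test_that("physiology estimates implement the stated arithmetic", {
  b <- flux_budget(fast_solve(default_params()))
  est <- physiology_estimates(b, per_transporter_rate = 1e3,
                              carbon_per_cell_pg = c(0.1, 0.3))
  ## ~1e4-1e5 transporters per um^2 at the reference operating point
  expect_gt(est$transporter_density_per_um2, 1e4)
  expect_lt(est$transporter_density_per_um2, 1e5)
  ## division time = carbon needed / fixation rate
  expect_equal(unname(est$division_time_h),
               c(0.1, 0.3) / est$fixation_pg_per_h, tolerance = 1e-12)
  ## fixation mass rate from the carboxylation flux via 12 g/mol
  expect_equal(est$fixation_pg_per_h,
               b$carboxylation * 1e-12 * 12 * 3600 * 1e12,
               tolerance = 1e-12)
  b0 <- b; b0$carboxylation <- 0
  expect_error(physiology_estimates(b0), "zero")
})
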