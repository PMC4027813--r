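## Analysis drivers: flux budgets, phase scans, optima, uptake partitioning,
## organization comparison, and order-of-magnitude physiology.

## solve one (jc, kc) point, preferring the closed form where its
## linearization is self-consistent
ccm_point <- function(p, jc = NULL, kc = NULL, n = 200,
                      prefer = c("analytic", "numeric"), init = NULL) {
  prefer <- match.arg(prefer)
  if (!is.null(jc)) p$membrane$jc <- jc
  if (!is.null(kc)) p$shell$kc <- kc
  if (prefer == "analytic" && p$ca_placement == "volumetric") {
    sol <- tryCatch(solve_ccm_analytic(p, n = n), error = function(e) NULL)
    if (!is.null(sol) && isTRUE(sol$regime$valid)) return(sol)
  }
  solve_ccm_numeric(p, n = n, init = init)
}

#' Membrane flux budget (fate of transported carbon)
#'
#' Gross fluxes across the cell membrane and total reaction fluxes, in
#' pmol/(cell s), with each entry also expressed as a percentage of gross
#' active HCO3- transport.
#'
#' @param sol a converged `ccm_solution`
#' @param p parameters (defaults to those stored in the solution)
#' @return object of class `ccm_flux_budget`: a data.frame of budget rows
#'   plus fields `gross_transport`, `net_hco3`, `facilitated`,
#'   `conservation_residual`
#' @export
flux_budget <- function(sol, p = sol$params) {
  if (!isTRUE(sol$converged)) .stopf("solution is not converged")
  mem <- p$membrane; ext <- p$external
  SA <- p$geometry$SAcell
  CN <- membrane_conc(sol, "C"); HN <- membrane_conc(sol, "H")

  gross <- mem$jc * ext$Hout * SA * UM_CM3_TO_PMOL
  h_leak <- mem$kmH * (HN - ext$Hout) * SA * UM_CM3_TO_PMOL
  c_leak <- mem$kmC * (CN - ext$Cout) * SA * UM_CM3_TO_PMOL
  facil <- mem$alpha * CN / (mem$Kalpha + CN) * SA * UM_CM3_TO_PMOL

  rr <- rubisco_rates(pmax(sol$C, 0), ext$O, p$rubisco)
  carbox <- sum(sol$grid$vol_rub * rr$carboxylation) * UM_CM3_TO_PMOL
  oxy <- sum(sol$grid$vol_rub * rr$oxygenation) * UM_CM3_TO_PMOL

  resid <- abs(gross - h_leak - c_leak - carbox) / max(gross, 1e-300)
  rows <- data.frame(
    quantity = c("HCO3- transport", "HCO3- leakage", "CO2 leakage",
                 "carboxylation", "oxygenation"),
    formula = c("jc*Hout", "kmH*(Hcyt(Rb)-Hout)", "kmC*(Ccyt(Rb)-Cout)",
                "Vmax*C/(C+Km0*(1+O/KO))", "VmaxO*O/(O+KmO*(1+C/KC))"),
    flux_pmol_per_s = c(gross, h_leak, c_leak, carbox, oxy),
    pct_of_transport = 100 * c(gross, h_leak, c_leak, carbox, oxy) / gross)
  structure(list(table = rows, gross_transport = gross,
                 hco3_leakage = h_leak, co2_leakage = c_leak,
                 carboxylation = carbox, oxygenation = oxy,
                 facilitated = facil, net_hco3 = gross - h_leak,
                 conservation_residual = resid, params = p),
            class = "ccm_flux_budget")
}

#' @export
print.ccm_flux_budget <- function(x, ...) {
  cat("Fate of carbon brought into the cell\n")
  tb <- x$table
  tb$flux_pmol_per_s <- signif(tb$flux_pmol_per_s, 3)
  tb$pct_of_transport <- round(tb$pct_of_transport, 1)
  print(tb[, c("quantity", "flux_pmol_per_s", "pct_of_transport")],
        row.names = FALSE)
  cat(sprintf("net HCO3- flux: %.3g pmol/(cell s); conservation residual %.2e\n",
              x$net_hco3, x$conservation_residual))
  invisible(x)
}

#' Phase-space scan over HCO3- transport and shell permeability
#'
#' Solves the steady state on a (jc, kc) grid and extracts
#' iso-concentration contours: carboxysomal CO2 equal to the effective Km
#' and to the 1%-oxygenation level C99, the carbonic anhydrase saturation
#' boundary (carboxysomal HCO3- = Kba), and the 30 mM cytosolic HCO3- line.
#'
#' @param jc_values,kc_values monotone positive grids, cm/s
#' @param p base parameters
#' @param targets named vector of carboxysomal CO2 contour levels, uM;
#'   defaults to `c(Km = ..., C99 = ...)` computed from `p`
#' @param hcyt_level cytosolic HCO3- contour level, uM (default 30000)
#' @param n radial nodes per solve
#' @return object of class `ccm_phase_scan` with matrices `C_carb`,
#'   `H_carb`, `H_cyt` (rows = jc, cols = kc), a tidy `grid` data.frame and
#'   a `contours` data.frame with columns target, kc, jc
#' @export
phase_scan <- function(jc_values, kc_values, p, targets = NULL,
                       hcyt_level = 3e4, n = 200) {
  if (any(diff(jc_values) <= 0) || any(diff(kc_values) <= 0) ||
      any(jc_values <= 0) || any(kc_values <= 0))
    .stopf("jc_values and kc_values must be positive and increasing")
  Km <- km_effective(p$rubisco, p$external$O)
  if (is.null(targets))
    targets <- c(Km = Km, C99 = c99_concentration(p$external$O, p$rubisco))
  nj <- length(jc_values); nk <- length(kc_values)
  C_carb <- H_carb <- H_cyt <- matrix(NA_real_, nj, nk,
                                      dimnames = list(NULL, NULL))
  failures <- list()
  for (k in seq_len(nk)) {
    for (j in seq_len(nj)) {
      sol <- tryCatch(
        ccm_point(p, jc = jc_values[j], kc = kc_values[k], n = n),
        error = function(e) e)
      if (inherits(sol, "error")) {
        failures[[length(failures) + 1]] <-
          list(jc = jc_values[j], kc = kc_values[k],
               message = conditionMessage(sol))
        next
      }
      C_carb[j, k] <- region_mean(sol, "C", "carboxysome")
      H_carb[j, k] <- region_mean(sol, "H", "carboxysome")
      H_cyt[j, k] <- membrane_conc(sol, "H")
    }
  }
  ## contour extraction: for each kc column, interpolate the jc at which a
  ## quantity crosses the target level (log-log bilinear in spirit)
  xing <- function(M, level) {
    out <- data.frame(kc = numeric(0), jc = numeric(0))
    if (!is.finite(level)) return(out)
    for (k in seq_len(nk)) {
      v <- M[, k]
      ok <- is.finite(v) & v > 0
      if (sum(ok) < 2) next
      lv <- log(v[ok]); lj <- log(jc_values[ok])
      s <- sign(lv - log(level))
      idx <- which(diff(s) != 0)
      if (!length(idx)) next
      i <- idx[1]
      f <- (log(level) - lv[i]) / (lv[i + 1] - lv[i])
      out <- rbind(out, data.frame(kc = kc_values[k],
                                   jc = exp(lj[i] + f * (lj[i + 1] - lj[i]))))
    }
    out
  }
  named_xing <- function(nm, M, level) {
    x <- xing(M, level)
    if (!nrow(x)) data.frame(target = character(0), kc = numeric(0),
                             jc = numeric(0))
    else cbind(target = nm, x)
  }
  contours <- do.call(rbind, c(
    lapply(names(targets), function(nm) named_xing(nm, C_carb,
                                                   targets[[nm]])),
    list(named_xing("CA_saturation", H_carb, p$ca$Kba),
         named_xing("Hcyt_level", H_cyt, hcyt_level))))
  grid_df <- data.frame(jc = rep(jc_values, nk),
                        kc = rep(kc_values, each = nj),
                        C_carb = as.vector(C_carb),
                        H_carb = as.vector(H_carb),
                        H_cyt = as.vector(H_cyt))
  structure(list(jc = jc_values, kc = kc_values, C_carb = C_carb,
                 H_carb = H_carb, H_cyt = H_cyt, targets = targets,
                 hcyt_level = hcyt_level, contours = contours,
                 grid = grid_df, failures = failures, params = p),
            class = "ccm_phase_scan")
}

#' @export
print.ccm_phase_scan <- function(x, ...) {
  cat(sprintf("CCM phase scan: %d x %d (jc, kc) grid, %d failures\n",
              length(x$jc), length(x$kc), length(x$failures)))
  cat(sprintf("  contour targets: %s; Hcyt level %g uM\n",
              paste(sprintf("%s=%.4g uM", names(x$targets), x$targets),
                    collapse = ", "), x$hcyt_level))
  invisible(x)
}

#' Transport velocity needed to reach a carboxysomal CO2 target
#'
#' Root-finds, at a fixed shell permeability, the HCO3- transport velocity
#' at which carboxysomal CO2 reaches `target_C`.
#'
#' @param target_C carboxysomal CO2 target, uM
#' @param p base parameters
#' @param kc shell permeability, cm/s (defaults to `p$shell$kc`)
#' @param jc_range search interval, cm/s
#' @param n radial nodes per solve
#' @return jc, cm/s (NA if the target is unreachable in `jc_range`)
#' @export
jc_needed <- function(target_C, p, kc = NULL, jc_range = c(1e-4, 50),
                      n = 200) {
  f <- function(lj) {
    sol <- ccm_point(p, jc = 10^lj, kc = kc, n = n)
    log(region_mean(sol, "C", "carboxysome") / target_C)
  }
  lo <- log10(jc_range[1]); hi <- log10(jc_range[2])
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  10^uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Optimal carboxysome shell permeability
#'
#' The kc at which the least HCO3- transport is required to reach a target
#' carboxysomal CO2 concentration: a 1-D minimization over log kc of the
#' root jc(kc).
#'
#' @param target_C carboxysomal CO2 target, uM
#' @param p base parameters
#' @param kc_range search interval, cm/s
#' @param jc_range transport search interval passed to [jc_needed()]
#' @param n radial nodes per solve
#' @return list with `kc_opt`, `jc_min`, and the evaluated points
#' @export
optimal_kc <- function(target_C, p, kc_range = c(1e-6, 1),
                       jc_range = c(1e-4, 50), n = 200) {
  evals <- new.env(); evals$pts <- data.frame()
  f <- function(lk) {
    jc <- jc_needed(target_C, p, kc = 10^lk, jc_range = jc_range, n = n)
    val <- if (is.na(jc)) 1e6 else log(jc)
    evals$pts <- rbind(evals$pts, data.frame(kc = 10^lk, jc = ifelse(
      is.na(jc), NA, jc)))
    val
  }
  opt <- optimize(f, log10(kc_range), tol = 0.02)
  if (opt$objective >= 1e6)
    .stopf("target carboxysomal CO2 %g uM unreachable for any kc in range",
           target_C)
  list(kc_opt = 10^opt$minimum, jc_min = exp(opt$objective),
       evaluations = evals$pts)
}

#' Carboxysomal CO2 amplification factor
#'
#' Carboxysomal CO2 divided by total external inorganic carbon
#' (Cout + Hout).
#'
#' @param sol a converged `ccm_solution`
#' @param external external conditions (defaults to the solution's)
#' @return dimensionless amplification
#' @export
amplification_factor <- function(sol, external = sol$params$external) {
  region_mean(sol, "C", "carboxysome") / (external$Cout + external$Hout)
}

#' Diffusive upper bound on the shell permeability from pore geometry
#'
#' `Npores * (pore cross-section / shell surface) * (D / l)`: the
#' probability that a molecule meets a pore times its diffusive speed
#' through the pore length.
#'
#' @param shell a [shell_params()] list with pore geometry
#' @param D diffusion constant, cm^2/s
#' @param Rc carboxysome radius, cm
#' @return velocity bound, cm/s
#' @export
kc_upper_bound <- function(shell, D = 1e-5, Rc = 5e-6) {
  if (is.null(shell$Npores) || is.null(shell$rpore) || is.null(shell$lshell))
    .stopf("pore geometry (Npores, rpore, lshell) is required")
  shell$Npores * (pi * shell$rpore^2) / (4 * pi * Rc^2) * D / shell$lshell
}

#' Partition of HCO3- supply between transport, facilitated uptake and
#' scavenging
#'
#' Scans the external CO2 fraction of a fixed total inorganic carbon pool.
#' At each fraction the full model is solved and the alpha-conversion flux
#' at the membrane is attributed: the component sustained by externally
#' sourced CO2 (the cytosolic CO2 field that would obtain with the shell
#' flux switched off, which is the uniform level `Cout*kmC/(kmC + alpha/
#' Kalpha)`) counts as facilitated uptake; the remainder, sustained by CO2
#' escaping the carboxysome, counts as scavenging.
#'
#' @param co2_fraction vector of external CO2 fractions in `[0, 1]`
#' @param total_Ci total external inorganic carbon, uM
#' @param p base parameters; `jc`, `alpha`, `Kalpha`, `kc` are honored
#' @param n radial nodes per solve
#' @return object of class `ccm_partition`: data.frame of fluxes
#'   (pmol/(cell s)) per fraction plus the interpolated crossover fraction
#'   at which facilitated uptake first exceeds active transport
#' @export
uptake_partition_scan <- function(co2_fraction, total_Ci = 15, p = ccm_params(),
                                  n = 200) {
  if (any(co2_fraction < 0 | co2_fraction > 1))
    .stopf("co2_fraction must lie in [0, 1]")
  mem <- p$membrane
  SA <- p$geometry$SAcell
  am <- mem$alpha / mem$Kalpha
  rows <- lapply(co2_fraction, function(f) {
    p2 <- p
    p2$external$Cout <- f * total_Ci
    p2$external$Hout <- (1 - f) * total_Ci
    sol <- solve_ccm_numeric(p2, n = n)
    CN <- membrane_conc(sol, "C")
    total_alpha <- mem$alpha * CN / (mem$Kalpha + CN) * SA * UM_CM3_TO_PMOL
    C_ext <- p2$external$Cout * mem$kmC / (mem$kmC + am)
    facil <- mem$alpha * C_ext / (mem$Kalpha + C_ext) * SA * UM_CM3_TO_PMOL
    facil <- min(facil, total_alpha)
    data.frame(co2_fraction = f,
               transport = mem$jc * p2$external$Hout * SA * UM_CM3_TO_PMOL,
               facilitated = facil,
               scavenging = total_alpha - facil,
               conversion_total = total_alpha)
  })
  tab <- do.call(rbind, rows)
  ## crossover: first fraction where facilitated exceeds transport
  dfx <- tab$facilitated - tab$transport
  cross <- NA_real_
  idx <- which(diff(sign(dfx)) > 0)
  if (length(idx)) {
    i <- idx[1]
    cross <- tab$co2_fraction[i] +
      (0 - dfx[i]) / (dfx[i + 1] - dfx[i]) *
      (tab$co2_fraction[i + 1] - tab$co2_fraction[i])
  } else if (all(dfx > 0)) cross <- 0
  structure(list(table = tab, crossover_fraction = cross,
                 total_Ci = total_Ci, params = p),
            class = "ccm_partition")
}

#' @export
print.ccm_partition <- function(x, ...) {
  cat(sprintf("Uptake partition scan (total Ci = %g uM, %d fractions)\n",
              x$total_Ci, nrow(x$table)))
  cat(sprintf("  facilitated uptake exceeds transport above CO2 fraction %.3f\n",
              x$crossover_fraction))
  invisible(x)
}

#' Compare cellular organizations of the CCM enzymes
#'
#' Solves the model for enzymes distributed through the cytosol
#' (`whole_cell`), co-localized at the cell center without a shell
#' (`scaffold`), and encapsulated in a carboxysome with high and with the
#' preset (optimal) shell permeability. All scenarios carry the same total
#' enzyme; in each, the HCO3- transport velocity is tuned so the cytosolic
#' HCO3- pool reaches `target_Hcyt`.
#'
#' @param p base parameters (carboxysome-scenario kinetics)
#' @param target_Hcyt cytosolic HCO3- target, uM (default 30 mM)
#' @param kc_high the "high permeability" shell value, cm/s
#' @param n radial nodes per solve
#' @param jc_range search interval for the transport tuning, cm/s
#' @return object of class `ccm_organization`: data.frame with per-scenario
#'   jc, central CO2 (mean over r <= Rc), cytosolic HCO3-, and oxygenation
#'   error rate (% of RuBisCO reactions)
#' @export
organization_compare <- function(p, target_Hcyt = 3e4, kc_high = 1,
                                 n = 200, jc_range = c(1e-3, 1e3)) {
  scen <- list(
    whole_cell = function(q) rescale_for_scenario(q, "whole_cell"),
    scaffold = function(q) rescale_for_scenario(q, "scaffold"),
    carboxysome_high_kc = function(q) { q$shell$kc <- kc_high; q },
    carboxysome_optimal_kc = function(q) q)
  rows <- lapply(names(scen), function(nm) {
    q <- scen[[nm]](p)
    f <- function(lj) {
      q$membrane$jc <- 10^lj
      sol <- solve_ccm_numeric(q, n = n)
      log(region_mean(sol, "H", "cytosol") / target_Hcyt)
    }
    lo <- log10(jc_range[1]); hi <- log10(jc_range[2])
    if (f(lo) * f(hi) > 0)
      .stopf("cannot tune jc to reach Hcyt = %g uM for scenario %s",
             target_Hcyt, nm)
    lj <- uniroot(f, c(lo, hi), tol = 1e-9)$root
    q$membrane$jc <- 10^lj
    sol <- solve_ccm_numeric(q, n = n)
    rr <- rubisco_rates(pmax(sol$C, 0), q$external$O, q$rubisco)
    carb <- sum(sol$grid$vol_rub * rr$carboxylation)
    oxy <- sum(sol$grid$vol_rub * rr$oxygenation)
    data.frame(scenario = nm, jc = 10^lj,
               C_central = region_mean(sol, "C", "carboxysome"),
               H_cytosol = region_mean(sol, "H", "cytosol"),
               oxygenation_error_pct = 100 * oxy / (oxy + carb))
  })
  structure(list(table = do.call(rbind, rows), target_Hcyt = target_Hcyt,
                 params = p),
            class = "ccm_organization")
}

#' @export
print.ccm_organization <- function(x, ...) {
  cat(sprintf("Cellular organization comparison (Hcyt tuned to %g uM)\n",
              x$target_Hcyt))
  tb <- x$table
  tb$jc <- signif(tb$jc, 3)
  tb$C_central <- signif(tb$C_central, 4)
  tb$H_cytosol <- signif(tb$H_cytosol, 4)
  tb$oxygenation_error_pct <- signif(tb$oxygenation_error_pct, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Back-of-envelope physiological estimates from a flux budget
#'
#' Transporter surface density, carbon-fixation mass rate, and the time to
#' accumulate the carbon for one division.
#'
#' @param budget a `ccm_flux_budget`
#' @param per_transporter_rate molecules/s moved by one transporter
#' @param carbon_per_cell_pg carbon needed for a new cell, pg (range)
#' @return list with `transport_molecules_per_s`,
#'   `transporter_density_per_um2`, `fixation_pg_per_h`,
#'   `division_time_h` (one value per element of `carbon_per_cell_pg`)
#' @export
physiology_estimates <- function(budget, per_transporter_rate = 1e3,
                                 carbon_per_cell_pg = c(0.1, 0.3)) {
  SA_um2 <- budget$params$geometry$SAcell * 1e8   # cm^2 -> um^2
  molecules <- budget$gross_transport * 1e-12 * AVOGADRO
  fix_pg_h <- budget$carboxylation * 1e-12 * 12 * 3600 * 1e12
  if (fix_pg_h <= 0) .stopf("carboxylation flux is zero; no division time")
  list(transport_molecules_per_s = molecules,
       transporter_density_per_um2 = molecules / per_transporter_rate / SA_um2,
       fixation_pg_per_h = fix_pg_h,
       division_time_h = setNames(carbon_per_cell_pg / fix_pg_h,
                                  paste0(carbon_per_cell_pg, "_pg")))
}
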