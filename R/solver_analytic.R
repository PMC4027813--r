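## Closed-form steady states in the linearizable kinetic regimes.
##
## Outside the enzyme-bearing region both species are harmonic (a + b/r).
## Inside, an affine rate law R_CA ~ p0 + a*H - b*C, R_Rub ~ q0 + g*C turns
## the coupled system for (u, v) = (r*C, r*H) into w'' = M w + s*r with a
## constant 2x2 matrix M; its eigen-decomposition gives sinh(kappa*r)
## interior modes (modified Helmholtz) for positive eigenvalues and
## polynomial modes for zero eigenvalues. Matching flux-jump conditions at
## the shell and Robin conditions at the membrane closes a small linear
## system.

## eigen-decomposition of M = [[b+g, -a], [-b, a]] / Dc (always real);
## rates too slow to matter over the domain size Ra collapse to the
## reaction-free polynomial modes
interior_modes <- function(a, b, g, Dc, Ra) {
  if ((a + b + g) / Dc * Ra^2 < 1e-12) {
    return(list(lambda = c(0, 0), P = diag(2)))
  }
  TT <- a + b + g
  Delta <- a * g
  if (abs(TT^2 - 4 * Delta) < 1e-24 * TT^2) g <- g * (1 + 1e-9) + 1e-12 * TT
  TT <- a + b + g; Delta <- a * g
  disc <- sqrt(max(TT^2 - 4 * Delta, 0))
  lam <- c((TT + disc) / 2, (TT - disc) / 2) / Dc
  P <- matrix(0, 2, 2)
  for (k in 1:2) {
    lk <- lam[k] * Dc
    w1 <- c(a, b + g - lk)          # from row 1 of (M*Dc - lk I)
    w2 <- c(a - lk, b)              # from row 2
    w <- if (sum(w1^2) >= sum(w2^2)) w1 else w2
    P[, k] <- w / sqrt(sum(w^2))
  }
  list(lambda = lam, P = P)
}

## linear forms (over unknown mode amplitudes A1, A2 plus a constant) for
## C, H and their radial derivatives at radius r
interior_eval <- function(modes, shat, r) {
  lam <- modes$lambda; P <- modes$P
  phi <- dphi <- psi <- dpsi <- numeric(2)
  for (k in 1:2) {
    if (lam[k] * r^2 > 1e-12) {
      kap <- sqrt(lam[k])
      phi[k] <- sinh(kap * r); dphi[k] <- kap * cosh(kap * r)
      psi[k] <- -shat[k] / lam[k] * r; dpsi[k] <- -shat[k] / lam[k]
    } else {
      phi[k] <- r; dphi[k] <- 1
      psi[k] <- shat[k] * r^3 / 6; dpsi[k] <- shat[k] * r^2 / 2
    }
  }
  ## u(r) = P[1,] %*% z, v(r) = P[2,] %*% z with z_k = A_k phi_k + psi_k
  ## C = u/r, dC/dr = (u' r - u)/r^2
  uA <- P[1, ] * phi; uc <- sum(P[1, ] * psi)
  vA <- P[2, ] * phi; vc <- sum(P[2, ] * psi)
  duA <- P[1, ] * dphi; duc <- sum(P[1, ] * dpsi)
  dvA <- P[2, ] * dphi; dvc <- sum(P[2, ] * dpsi)
  list(C = list(A = uA / r, const = uc / r),
       H = list(A = vA / r, const = vc / r),
       dC = list(A = (duA * r - uA) / r^2, const = (duc * r - uc) / r^2),
       dH = list(A = (dvA * r - vA) / r^2, const = (dvc * r - vc) / r^2))
}

## affine kinetic coefficients R_CA ~ p0 + a*H - b*C, R_Rub ~ q0 + g*C.
## linearization "limit": the textbook branch forms (low-occupancy /
## dehydration-at-capacity). linearization "operating_point": first-order
## Taylor expansion of the full rate laws about the self-consistent
## carboxysomal operating point (Hbar, Cbar) -- same sinh-family solutions,
## reducing to the limit forms in their respective asymptotic regimes, but
## uniformly accurate in between.
branch_coefficients <- function(p, branch, rub_state, Hbar, Cbar,
                                linearization = "operating_point") {
  ca <- p$ca; rub <- p$rubisco
  Keq <- equilibrium_ratio(ca)
  Km <- km_effective(rub, p$external$O)
  if (linearization == "operating_point") {
    jac <- ca_rate_jac(Hbar, Cbar, ca)
    R0 <- ca_rate(Hbar, Cbar, ca)
    a <- max(jac$dH, 0)
    b <- max(-jac$dC, 0)
    p0 <- R0 - a * Hbar + b * Cbar
    g <- rubisco_carbox_dC(Cbar, p$external$O, rub)
    q0 <- rub$Vmax * Cbar / (Cbar + Km) - g * Cbar
  } else if (branch == "unsaturated") {
    a <- ca$Vba / ca$Kba
    b <- ca$Vca / ca$Kca
    p0 <- 0
    if (rub_state == "saturated") { g <- 0; q0 <- rub$Vmax }
    else { g <- rub$Vmax / Km; q0 <- 0 }
  } else {
    ## saturated dehydration: R_CA ~ Vba*(1 - Keq*C/Hbar); retaining the
    ## linearized reverse flux keeps the branch continuous with the
    ## equilibrium-limited regime
    a <- 0
    b <- ca$Vba * Keq / max(Hbar, 1e-12)
    p0 <- ca$Vba
    if (rub_state == "saturated") { g <- 0; q0 <- rub$Vmax }
    else { g <- rub$Vmax / Km; q0 <- 0 }
  }
  list(a = a, b = b, p0 = p0, g = g, q0 = q0, Keq = Keq, Km = Km)
}

solve_analytic_once <- function(p, branch, rub_state, Hbar, Cbar,
                                linearization = "operating_point") {
  geo <- p$geometry; mem <- p$membrane; ext <- p$external
  D <- p$diffusion$D; Dc <- p$diffusion$D_carb
  Ra <- if (p$scenario == "whole_cell") geo$Rb else geo$Rc
  co <- branch_coefficients(p, branch, rub_state, Hbar, Cbar, linearization)
  modes <- interior_modes(co$a, co$b, co$g, Dc, Ra)
  ## source vector s = ((q0 - p0), p0)/Dc in (u, v); shat = P^-1 s
  s <- c(co$q0 - co$p0, co$p0) / Dc
  shat <- solve(modes$P, s)
  am <- if (mem$alpha > 0) mem$alpha / mem$Kalpha else 0

  if (p$scenario == "whole_cell") {
    ev <- interior_eval(modes, shat, geo$Rb)
    ## rows: membrane conditions for C and H; unknowns A1, A2
    Amat <- rbind(D * ev$dC$A + (am + mem$kmC) * ev$C$A,
                  D * ev$dH$A - am * ev$C$A + mem$kmH * ev$H$A)
    bvec <- c(mem$kmC * ext$Cout - (D * ev$dC$const +
                                      (am + mem$kmC) * ev$C$const),
              mem$jc * ext$Hout + mem$kmH * ext$Hout -
                (D * ev$dH$const - am * ev$C$const + mem$kmH * ev$H$const))
    theta <- solve(Amat, bvec)
    coefs <- list(A = theta, cyt = NULL)
  } else {
    ev <- interior_eval(modes, shat, geo$Rc)
    kc <- p$shell$kc
    ## unknowns: A1, A2, aC, bC, aH, bH
    Z <- function(A, aC = 0, bC = 0, aH = 0, bH = 0)
      c(A, aC, bC, aH, bH)
    rows <- list(); rhs <- numeric(0)
    Rc <- geo$Rc; Rb <- geo$Rb
    if (p$scenario == "carboxysome") {
      ## flux-jump matching: Dc dC_in = kc (C_cyt - C_in) = D dC_cyt
      rows[[1]] <- Z(Dc * ev$dC$A + kc * ev$C$A, aC = -kc, bC = -kc / Rc)
      rhs[1] <- -(Dc * ev$dC$const + kc * ev$C$const)
      rows[[2]] <- Z(kc * ev$C$A, aC = -kc, bC = -kc / Rc - D / Rc^2)
      rhs[2] <- -kc * ev$C$const
      rows[[3]] <- Z(Dc * ev$dH$A + kc * ev$H$A, aH = -kc, bH = -kc / Rc)
      rhs[3] <- -(Dc * ev$dH$const + kc * ev$H$const)
      rows[[4]] <- Z(kc * ev$H$A, aH = -kc, bH = -kc / Rc - D / Rc^2)
      rhs[4] <- -kc * ev$H$const
    } else {  # scaffold: continuity of value and flux
      rows[[1]] <- Z(ev$C$A, aC = -1, bC = -1 / Rc)
      rhs[1] <- -ev$C$const
      rows[[2]] <- Z(Dc * ev$dC$A, bC = D / Rc^2)
      rhs[2] <- -Dc * ev$dC$const
      rows[[3]] <- Z(ev$H$A, aH = -1, bH = -1 / Rc)
      rhs[3] <- -ev$H$const
      rows[[4]] <- Z(Dc * ev$dH$A, bH = D / Rc^2)
      rhs[4] <- -Dc * ev$dH$const
    }
    ## membrane: D dC_cyt(Rb) + am C_cyt(Rb) + kmC (C_cyt(Rb) - Cout) = 0
    rows[[5]] <- Z(c(0, 0), aC = am + mem$kmC,
                   bC = -D / Rb^2 + (am + mem$kmC) / Rb)
    rhs[5] <- mem$kmC * ext$Cout
    ## membrane H: D dH_cyt(Rb) - jc Hout - am C_cyt(Rb) - kmH (Hout - H_cyt(Rb)) = 0
    rows[[6]] <- Z(c(0, 0), aC = -am, bC = -am / Rb,
                   aH = mem$kmH, bH = -D / Rb^2 + mem$kmH / Rb)
    rhs[6] <- (mem$jc + mem$kmH) * ext$Hout
    Amat <- do.call(rbind, rows)
    theta <- solve(Amat, rhs)
    coefs <- list(A = theta[1:2],
                  cyt = list(aC = theta[3], bC = theta[4],
                             aH = theta[5], bH = theta[6]))
  }
  list(coefs = coefs, modes = modes, shat = shat, co = co, Ra = Ra)
}

## evaluate an analytic solution on the standard radial grid
analytic_profiles <- function(p, fit, n) {
  grid <- make_grid(p, n)
  r <- grid$r
  C <- H <- numeric(grid$N)
  Ra <- fit$Ra
  inner <- if (p$scenario == "carboxysome")
    seq_len(grid$iface[1]) else which(r <= Ra + 1e-300)
  if (p$scenario == "whole_cell") inner <- seq_len(grid$N)
  for (i in inner) {
    ri <- max(r[i], r[2] / 2)  # r = 0: use the regular limit at small r
    ev <- interior_eval(fit$modes, fit$shat, ri)
    C[i] <- sum(ev$C$A * fit$coefs$A) + ev$C$const
    H[i] <- sum(ev$H$A * fit$coefs$A) + ev$H$const
  }
  if (!is.null(fit$coefs$cyt)) {
    outer_idx <- setdiff(seq_len(grid$N), inner)
    cy <- fit$coefs$cyt
    C[outer_idx] <- cy$aC + cy$bC / r[outer_idx]
    H[outer_idx] <- cy$aH + cy$bH / r[outer_idx]
  }
  list(grid = grid, C = C, H = H)
}

#' Closed-form steady-state solution in a linearizable regime
#'
#' Piecewise closed forms: harmonic `a + b/r` profiles in the
#' enzyme-free cytosol matched through the shell flux-jump conditions to
#' modified-Helmholtz (`sinh(kappa*r)/r`) interior solutions of the
#' linearized kinetics. Two carbonic anhydrase branches are available:
#' `"unsaturated"` (low-occupancy linearization of the reversible rate law)
#' and `"saturated"` (dehydration at capacity with the linearized reverse
#' flux, iterated to self-consistency in the carboxysomal HCO3- level).
#' The facilitated-uptake term is linearized as `alpha/Kalpha * C`.
#'
#' @param p a [ccm_params()] object (volumetric CA placement only)
#' @param branch `"auto"` (classify, then verify self-consistency),
#'   `"unsaturated"`, or `"saturated"`
#' @param n nodes of the output grid
#' @param linearization `"operating_point"` (default; first-order expansion
#'   of the rate laws about the self-consistent carboxysomal operating
#'   point, uniformly accurate) or `"limit"` (the asymptotic branch forms:
#'   low-occupancy and dehydration-at-capacity)
#' @return a `ccm_solution` (method `"analytic"`) whose `regime` field
#'   carries the branch labels, self-consistency and linearization-validity
#'   diagnostics
#' @export
solve_ccm_analytic <- function(p, branch = c("auto", "unsaturated",
                                             "saturated"), n = 400,
                               linearization = c("operating_point",
                                                 "limit")) {
  p <- validate_ccm_params(p)
  branch <- match.arg(branch)
  linearization <- match.arg(linearization)
  if (p$ca_placement != "volumetric")
    .stopf("analytic solver supports volumetric CA placement only")
  Keq <- equilibrium_ratio(p$ca)
  Km <- km_effective(p$rubisco, p$external$O)

  run_branch <- function(br) {
    ## initial operating-point estimate from the transport-leakage balance
    Hbar <- hcyt_closed_form(p)
    Cbar <- min(Hbar / Keq, Hbar)
    rub_state <- if (Cbar >= Km) "saturated" else "linear"
    prof <- NULL
    fp_converged <- FALSE
    for (iter in 1:200) {
      fit <- solve_analytic_once(p, br, rub_state, Hbar, Cbar,
                                 linearization)
      prof <- analytic_profiles(p, fit, n)
      w <- prof$grid$vin
      Hnew <- sum(w * prof$H) / sum(w)
      Cnew <- sum(w * prof$C) / sum(w)
      rub_state <- if (Cnew >= Km) "saturated" else "linear"
      done <- abs(Hnew - Hbar) <= 1e-10 * max(abs(Hbar), 1) &&
        abs(Cnew - Cbar) <= 1e-10 * max(abs(Cbar), 1)
      ## damped update guards against oscillation of the fixed point
      Hbar <- max(0.5 * Hbar + 0.5 * Hnew, 0)
      Cbar <- max(0.5 * Cbar + 0.5 * Cnew, 0)
      if (linearization == "limit" && br == "unsaturated" && iter >= 3)
        break  # only rub_state iterates in that mode
      if (done) { fp_converged <- TRUE; break }
    }
    occ <- (p$ca$Kca * Hbar + p$ca$Kba * Cbar) / (p$ca$Kba * p$ca$Kca)
    dom <- p$ca$Kca * Hbar /
      (p$ca$Kba * p$ca$Kca + p$ca$Kca * Hbar + p$ca$Kba * Cbar)
    ca_state <- if (Hbar >= p$ca$Kba) "saturated" else "unsaturated"
    consistent <- (br == "saturated") == (ca_state == "saturated")
    valid <- if (linearization == "operating_point") fp_converged
    else if (br == "unsaturated") occ <= 0.25 else dom >= 0.75
    list(fit = fit, prof = prof, Hbar = Hbar, Cbar = Cbar,
         regime = list(ca_state = ca_state,
                       rubisco_state = rub_state,
                       branch = br, consistent = consistent,
                       valid = consistent && valid,
                       occupancy = occ, dominance = dom))
  }

  tried <- list()
  order <- if (branch == "auto") {
    H0 <- hcyt_closed_form(p)
    if (H0 >= p$ca$Kba) c("saturated", "unsaturated")
    else c("unsaturated", "saturated")
  } else branch
  sol <- NULL
  for (br in order) {
    res <- run_branch(br)
    tried[[br]] <- res
    if (res$regime$consistent || branch != "auto") { sol <- res; break }
  }
  if (is.null(sol)) {
    err <- simpleError(paste0(
      "parameters outside both linearizable regimes ",
      "(self-inconsistent classification); use solve_ccm_numeric()"))
    class(err) <- c("ccm_regime_error", class(err))
    stop(err)
  }
  grid <- sol$prof$grid
  structure(list(r = grid$r, C = pmax(sol$prof$C, 0),
                 H = pmax(sol$prof$H, 0),
                 converged = TRUE, residual = NA_real_,
                 iterations = NA_integer_,
                 scenario = p$scenario, ca_placement = p$ca_placement,
                 method = "analytic", params = p, grid = grid,
                 regime = sol$regime,
                 internals = sol$fit),
            class = "ccm_solution")
}

#' Kinetic regime labels of a parameter set or solution
#'
#' Carbonic anhydrase counts as saturated when the carboxysomal HCO3-
#' concentration reaches the dehydration half-max `Kba` (ties label
#' saturated); RuBisCO counts as saturated when carboxysomal CO2 reaches the
#' effective Km.
#'
#' @param x a `ccm_solution` or a [ccm_params()] object (then a solve is
#'   performed: analytic if self-consistent, numeric fallback)
#' @param ... passed on to the solver when `x` is a parameter set
#' @return list with `ca_state` and `rubisco_state` labels
#' @export
classify_regime <- function(x, ...) {
  if (inherits(x, "ccm_params")) {
    x <- tryCatch(solve_ccm_analytic(x, ...),
                  ccm_regime_error = function(e)
                    solve_ccm_numeric(validate_ccm_params(x), n = 200))
  }
  if (!inherits(x, "ccm_solution")) .stopf("need ccm_params or ccm_solution")
  Hb <- region_mean(x, "H", "carboxysome")
  Cb <- region_mean(x, "C", "carboxysome")
  p <- x$params
  list(ca_state = if (Hb >= p$ca$Kba) "saturated" else "unsaturated",
       rubisco_state = if (Cb >= km_effective(p$rubisco, p$external$O))
         "saturated" else "linear",
       H_carb = Hb, C_carb = Cb)
}

#' Cytosolic HCO3- from the transport-leakage balance
#'
#' Away from saturation of the transporters, nearly all actively imported
#' HCO3- leaks back out across the membrane, giving the closed form
#' `Hcyt = Hout*(1 + jc/kmH)` minus a correction for the flux actually
#' consumed (converted to CO2 and fixed or lost). Inverting the balance
#' recovers the transport velocity needed for a target cytosolic pool.
#'
#' @param p a [ccm_params()] object
#' @param consumed total consumed flux (conversion + fixation),
#'   pmol/(cell s); default 0
#' @return cytosolic HCO3-, uM
#' @export
hcyt_closed_form <- function(p, consumed = 0) {
  mem <- p$membrane; ext <- p$external
  phi <- consumed / UM_CM3_TO_PMOL / p$geometry$SAcell  # uM cm/s
  ext$Hout + (mem$jc * ext$Hout - phi) / mem$kmH
}
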