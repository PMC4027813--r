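## Radial finite-volume machinery.
##
## Vertex-centred control volumes on [0, Rb]. Rc always coincides with a
## node; in the "carboxysome" scenario the node is duplicated (inner/outer
## faces of a zero-thickness shell) and the face between the twins carries
## the shell conductance kc*4*pi*Rc^2. Face conductances elsewhere use the
## exact spherical-shell diffusive resistance, which reproduces a + b/r
## profiles exactly in source-free regions.

make_grid <- function(p, n = 400) {
  Rb <- p$geometry$Rb; Rc <- p$geometry$Rc
  interface <- p$scenario == "carboxysome"
  n_in <- max(12L, round(n * 0.25))
  n_out <- max(24L, n - n_in)
  r_in <- Rc * seq(0, 1, length.out = n_in)
  u <- seq(0, 1, length.out = n_out)
  x <- 0.7 * (1 - cos(pi * u)) / 2 + 0.3 * u  # cluster towards Rc and Rb
  r_out <- Rc + (Rb - Rc) * x
  if (interface) {
    r <- c(r_in, r_out)
    iface <- c(n_in, n_in + 1L)      # twin nodes at Rc
  } else {
    r <- c(r_in, r_out[-1])
    iface <- c(n_in, n_in)
  }
  N <- length(r)

  ## control-volume bounds: midpoints, pinned to Rc around the interface
  rL <- c(0, (r[-N] + r[-1]) / 2)
  rR <- c((r[-N] + r[-1]) / 2, Rb)
  rR[iface[1]] <- Rc
  rL[iface[2]] <- Rc
  vol <- 4 / 3 * pi * (rR^3 - rL^3)

  ## per-node volume lying inside the carboxysome (active enzyme volume)
  vin <- 4 / 3 * pi * (pmin(rR, Rc)^3 - pmin(rL, Rc)^3)
  vin[r > Rc] <- 0
  if (interface) vin[iface[2]] <- 0

  ## face conductances g[i]: flux from node i+1 into node i is
  ## g[i]*(x[i+1]-x[i]); cm^3/s
  D <- p$diffusion$D; Dc <- p$diffusion$D_carb
  g <- numeric(N - 1)
  for (i in seq_len(N - 1)) {
    if (interface && i == iface[1]) {
      g[i] <- p$shell$kc * 4 * pi * Rc^2
    } else {
      Dseg <- if (r[i + 1] <= Rc + 1e-300) Dc else D
      if (r[i] <= 0) {
        rf <- (r[i] + r[i + 1]) / 2
        g[i] <- 4 * pi * rf^2 * Dseg / (r[i + 1] - r[i])
      } else {
        g[i] <- 4 * pi * Dseg / (1 / r[i] - 1 / r[i + 1])
      }
    }
  }

  ## enzyme-volume vectors
  vol_rub <- if (p$scenario == "whole_cell") vol else vin
  if (p$ca_placement == "inner_shell") {
    vol_ca <- numeric(N)
    m <- iface[1]
    vol_ca[m] <- sum(vin)   # all CA activity on the inner shell face node
  } else {
    vol_ca <- vol_rub
  }

  list(r = r, N = N, iface = iface, interface = interface,
       vol = vol, vin = vin, vol_ca = vol_ca, vol_rub = vol_rub,
       g = g, SAb = 4 * pi * Rb^2)
}

## residual and sparse Jacobian of the discrete steady-state system;
## x = c(C, H), residuals in uM*cm^3/s
ccm_residual <- function(x, grid, p, want_jac = FALSE) {
  N <- grid$N
  C <- x[1:N]; H <- x[N + 1:N]
  g <- grid$g
  mem <- p$membrane; ext <- p$external

  Cc <- pmax(C, 0); Hc <- pmax(H, 0)
  rca <- ca_rate(Hc, Cc, p$ca)
  rub <- p$rubisco$Vmax * Cc / (Cc + km_effective(p$rubisco, ext$O))

  dif <- function(u) {
    f <- g * (u[-1] - u[-N])          # flux from i+1 into i across face i
    c(f, 0) - c(0, f)                 # net inflow per node
  }
  Fc <- dif(C) + grid$vol_ca * rca - grid$vol_rub * rub
  Fh <- dif(H) - grid$vol_ca * rca

  afac <- mem$alpha * C[N] / (mem$Kalpha + Cc[N])
  bC <- grid$SAb * (mem$kmC * (ext$Cout - C[N]) - afac)
  bH <- grid$SAb * (mem$jc * ext$Hout + afac + mem$kmH * (ext$Hout - H[N]))
  Fc[N] <- Fc[N] + bC
  Fh[N] <- Fh[N] + bH

  ## global magnitude scale: total turnover of all residual terms; the
  ## relative residual is the summed imbalance against it (a mass-balance
  ## closure metric)
  fl <- abs(g * (C[-1] - C[-N]))
  flh <- abs(g * (H[-1] - H[-N]))
  scale_tot <- 2 * sum(fl) + 2 * sum(flh) +
    2 * sum(grid$vol_ca * abs(rca)) + sum(grid$vol_rub * abs(rub)) +
    grid$SAb * (mem$kmC * (abs(ext$Cout) + abs(C[N])) + 2 * abs(afac) +
                  mem$jc * ext$Hout +
                  mem$kmH * (abs(ext$Hout) + abs(H[N]))) +
    grid$SAb * (mem$kmC + mem$kmH) * max(ext$Cout + ext$Hout, 1) * 1e-3
  res <- list(F = c(Fc, Fh),
              rel = sum(abs(c(Fc, Fh))) / scale_tot)
  if (!want_jac) return(res)

  jc_ca <- ca_rate_jac(Hc, Cc, p$ca)
  drub <- rubisco_carbox_dC(Cc, ext$O, p$rubisco)
  dafac <- mem$alpha * mem$Kalpha / (mem$Kalpha + Cc[N])^2

  ## triplets: diffusion stencil (same for both species)
  i_idx <- j_idx <- vals <- list()
  add <- function(i, j, v) {
    k <- length(i_idx) + 1L
    i_idx[[k]] <<- i; j_idx[[k]] <<- j; vals[[k]] <<- v
  }
  ii <- seq_len(N - 1)
  for (off in c(0L, N)) {
    add(off + ii, off + ii + 1L, g)          # dF_i/dx_{i+1}
    add(off + ii + 1L, off + ii, g)          # dF_{i+1}/dx_i
    diag_d <- -(c(g, 0) + c(0, g))
    add(off + 1:N, off + 1:N, diag_d)
  }
  ## reaction coupling
  add(1:N, 1:N, grid$vol_ca * jc_ca$dC - grid$vol_rub * drub)  # dFc/dC
  add(1:N, N + 1:N, grid$vol_ca * jc_ca$dH)                    # dFc/dH
  add(N + 1:N, 1:N, -grid$vol_ca * jc_ca$dC)                   # dFh/dC
  add(N + 1:N, N + 1:N, -grid$vol_ca * jc_ca$dH)               # dFh/dH
  ## membrane terms
  add(N, N, -grid$SAb * (mem$kmC + dafac))
  add(2L * N, N, grid$SAb * dafac)
  add(2L * N, 2L * N, -grid$SAb * mem$kmH)

  res$J <- Matrix::sparseMatrix(i = unlist(i_idx), j = unlist(j_idx),
                                x = unlist(vals), dims = c(2L * N, 2L * N))
  res
}

#' Numeric steady-state solution of the two-species CCM model
#'
#' Conservative finite-volume discretization of the spherical
#' diffusion-reaction system with a flux-jump shell interface (scenario
#' `"carboxysome"`) and Robin active-transport conditions at the cell
#' membrane, solved by damped Newton iteration with an analytic Jacobian.
#' The scheme is deterministic (no randomness).
#'
#' @param p a [ccm_params()] object
#' @param n number of radial nodes (default 400)
#' @param init optional warm start: a previous `ccm_solution` on the same
#'   grid, or a list with components `C` and `H`
#' @param tol relative residual tolerance
#' @param max_iter maximum Newton iterations
#' @return object of class `ccm_solution` with fields `r`, `C`, `H`,
#'   `converged`, `residual`, `iterations`, `scenario`, `params`, `grid`
#' @export
solve_ccm_numeric <- function(p, n = 400, init = NULL, tol = 1e-9,
                              max_iter = 200) {
  p <- validate_ccm_params(p)
  grid <- make_grid(p, n)
  N <- grid$N
  if (is.null(init)) {
    x <- c(rep(p$external$Cout, N), rep(p$external$Hout, N))
  } else if (inherits(init, "ccm_solution") && length(init$C) == N) {
    x <- c(init$C, init$H)
  } else if (is.list(init) && length(init$C) == N) {
    x <- c(init$C, init$H)
  } else {
    x <- c(rep(p$external$Cout, N), rep(p$external$Hout, N))
  }

  hist <- numeric(0)
  cur <- ccm_residual(x, grid, p, want_jac = TRUE)
  relax <- 1
  for (it in seq_len(max_iter)) {
    hist <- c(hist, cur$rel)
    if (cur$rel < tol) break
    dx <- tryCatch(as.numeric(Matrix::solve(cur$J, -cur$F)),
                   error = function(e) NULL)
    if (is.null(dx) || anyNA(dx)) {
      err <- simpleError("linear solve failed in Newton iteration")
      err$residual_history <- hist
      stop(err)
    }
    lam <- relax
    accepted <- FALSE
    for (half in 1:30) {
      xt <- pmax(x + lam * dx, 0)   # concentration floor
      nxt <- ccm_residual(xt, grid, p, want_jac = TRUE)
      if (is.finite(nxt$rel) && (nxt$rel < cur$rel * (1 - 1e-4 * lam) ||
                                 nxt$rel < tol)) {
        x <- xt; cur <- nxt; accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted) {
      if (relax > 0.5) {
        relax <- 0.5            # fall back to under-relaxed iteration
        next
      }
      ## line search exhausted: either we are at the rounding floor of the
      ## residual evaluation (accept: the imbalance is noise-level), or the
      ## iteration genuinely failed
      if (cur$rel < 1e3 * tol) break
      err <- simpleError(sprintf(
        "no convergence after %d iterations (relative residual %.3g)",
        it, cur$rel))
      err$residual_history <- hist
      stop(err)
    }
  }
  if (cur$rel >= 1e3 * tol) {
    err <- simpleError(sprintf(
      "no convergence after %d iterations (relative residual %.3g)",
      max_iter, cur$rel))
    err$residual_history <- hist
    stop(err)
  }
  C <- x[1:N]; H <- x[N + 1:N]
  if (any(C < -1e-12) || any(H < -1e-12))
    .stopf("negative concentrations in converged solution")
  structure(list(r = grid$r, C = pmax(C, 0), H = pmax(H, 0),
                 converged = TRUE, residual = cur$rel,
                 iterations = length(hist), residual_history = hist,
                 scenario = p$scenario, ca_placement = p$ca_placement,
                 method = "numeric", params = p, grid = grid),
            class = "ccm_solution")
}

#' Numeric solution with carbonic anhydrase localized to the shell
#'
#' Same total CA activity as the volumetric case, applied as a surface
#' source on the inner face of the carboxysome shell.
#'
#' @inheritParams solve_ccm_numeric
#' @export
solve_ccm_shell_ca <- function(p, n = 400, init = NULL, tol = 1e-9,
                               max_iter = 200) {
  p$ca_placement <- "inner_shell"
  solve_ccm_numeric(p, n = n, init = init, tol = tol, max_iter = max_iter)
}

#' @export
print.ccm_solution <- function(x, ...) {
  cat(sprintf("CCM steady state (%s, %s): %d nodes, residual %.2e (%d iter)\n",
              x$method, x$scenario, length(x$r), x$residual, x$iterations))
  cat(sprintf("  carboxysome: C = %.4g uM, H = %.4g uM\n",
              region_mean(x, "C", "carboxysome"),
              region_mean(x, "H", "carboxysome")))
  cat(sprintf("  cytosol:     C = %.4g uM, H = %.4g uM\n",
              region_mean(x, "C", "cytosol"),
              region_mean(x, "H", "cytosol")))
  invisible(x)
}

#' Volume-weighted mean concentration over a region of the cell
#'
#' @param sol a `ccm_solution`
#' @param species `"C"` (CO2) or `"H"` (HCO3-)
#' @param region `"carboxysome"` (r <= Rc), `"cytosol"` (r > Rc), `"cell"`,
#'   or `"active"` (the enzyme-bearing region of the scenario)
#' @return concentration, uM
#' @export
region_mean <- function(sol, species = c("C", "H"),
                        region = c("carboxysome", "cytosol", "cell",
                                   "active")) {
  species <- match.arg(species)
  region <- match.arg(region)
  u <- sol[[species]]
  g <- sol$grid
  w <- switch(region,
              carboxysome = g$vin,
              cytosol = g$vol - g$vin,
              cell = g$vol,
              active = g$vol_rub)
  sum(w * u) / sum(w)
}

#' Concentration at the inner face of the cell membrane
#' @param sol a `ccm_solution`
#' @param species `"C"` or `"H"`
#' @export
membrane_conc <- function(sol, species = c("C", "H")) {
  species <- match.arg(species)
  sol[[species]][length(sol$r)]
}
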