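#' Carbonic anhydrase equilibrium ratio Keq = H/C
#'
#' The HCO3-/CO2 ratio at which the net carbonic anhydrase rate vanishes:
#' `Keq = Kba*Vca/(Kca*Vba)` (about 5 near pH 7).
#'
#' @param ca a [ca_kinetics()] list
#' @return dimensionless ratio
#' @export
equilibrium_ratio <- function(ca) {
  for (nm in c("Vca", "Vba", "Kca", "Kba"))
    .check_num(ca[[nm]], nm, positive = TRUE)
  ca$Kba * ca$Vca / (ca$Kca * ca$Vba)
}

#' Net carbonic anhydrase dehydration rate
#'
#' Reversible Michaelis-Menten interconversion; positive values produce CO2
#' (dehydration of HCO3-), matching the `+R_CA` term of the CO2 equation and
#' `-R_CA` of the HCO3- equation. Bounded by `-Vca` and `+Vba`; zero on the
#' equilibrium manifold `H = Keq*C`.
#'
#' @param H HCO3- concentration, uM (vectorized)
#' @param C CO2 concentration, uM (vectorized)
#' @param ca a [ca_kinetics()] list
#' @return net dehydration rate, uM/s
#' @export
ca_rate <- function(H, C, ca) {
  if (any(H < 0) || any(C < 0)) .stopf("concentrations must be >= 0")
  (ca$Vba * ca$Kca * H - ca$Vca * ca$Kba * C) /
    (ca$Kba * ca$Kca + ca$Kca * H + ca$Kba * C)
}

## partial derivatives of ca_rate, used by the Newton solver
ca_rate_jac <- function(H, C, ca) {
  num <- ca$Vba * ca$Kca * H - ca$Vca * ca$Kba * C
  den <- ca$Kba * ca$Kca + ca$Kca * H + ca$Kba * C
  list(dH = (ca$Vba * ca$Kca * den - num * ca$Kca) / den^2,
       dC = (-ca$Vca * ca$Kba * den - num * ca$Kba) / den^2)
}

#' Effective carboxylation half-max in the presence of O2
#' @param rub a [rubisco_kinetics()] list
#' @param O O2 concentration, uM
#' @return `Km0*(1 + O/KO)`, uM
#' @export
km_effective <- function(rub, O) rub$Km0 * (1 + O / rub$KO)

#' RuBisCO carboxylation and oxygenation rates
#'
#' Carboxylation `Vmax*C/(C + Km0*(1+O/KO))` and oxygenation
#' `VmaxO*O/(O + KmO*(1+C/KC))`: competitive binding makes carboxylation
#' increasing in C and decreasing in O, and vice versa for oxygenation.
#'
#' @param C CO2, uM (vectorized)
#' @param O O2, uM
#' @param rub a [rubisco_kinetics()] list
#' @return list with components `carboxylation` and `oxygenation`, uM/s
#' @export
rubisco_rates <- function(C, O, rub) {
  if (any(C < 0) || any(O < 0)) .stopf("concentrations must be >= 0")
  list(carboxylation = rub$Vmax * C / (C + km_effective(rub, O)),
       oxygenation = rub$VmaxO * O / (O + rub$KmO * (1 + C / rub$KC)))
}

## d(carboxylation)/dC, used by the Newton solver
rubisco_carbox_dC <- function(C, O, rub) {
  Km <- km_effective(rub, O)
  rub$Vmax * Km / (C + Km)^2
}

#' Oxygenation error rate
#'
#' Fraction of all RuBisCO reactions that are oxygenations at concentrations
#' (C, O).
#'
#' @inheritParams rubisco_rates
#' @return dimensionless fraction in (0, 1)
#' @export
oxygenation_fraction <- function(C, O, rub) {
  r <- rubisco_rates(C, O, rub)
  r$oxygenation / (r$oxygenation + r$carboxylation)
}

#' CO2 concentration giving a 1% oxygenation error rate
#'
#' Root-finds the CO2 concentration `C*` at which oxygenation reactions are
#' the fraction `frac` (default 1%) of all RuBisCO reactions, for a given O2
#' concentration.
#'
#' @param O O2 concentration, uM (> 0)
#' @param rub a [rubisco_kinetics()] list
#' @param frac target oxygenation fraction (default 0.01)
#' @param C_max upper search bound, uM
#' @return CO2 concentration, uM
#' @export
c99_concentration <- function(O, rub, frac = 0.01, C_max = 1e7) {
  .check_num(O, "O", positive = TRUE)
  .check_num(frac, "frac", positive = TRUE)
  f <- function(C) oxygenation_fraction(C, O, rub) - frac
  lo <- 1e-8
  if (f(lo) < 0 || f(C_max) > 0)
    .stopf("no oxygenation fraction %g root in (0, %g]", frac, C_max)
  uniroot(f, c(lo, C_max), tol = 1e-12)$root
}
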