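#' ccmsim: steady-state model of the cyanobacterial CO2-concentrating mechanism
#'
#' Reaction-diffusion model of CO2 and bicarbonate in a spherical cell with a
#' central carboxysome. Units used throughout: concentrations in uM, lengths
#' in cm, times in s, membrane/shell velocities in cm/s, volumetric enzyme
#' rates in uM/s, and whole-cell fluxes in pmol/(cell s)
#' (1 uM = 1e-9 mol/cm^3, so uM * cm/s * cm^2 * 1000 = pmol/s).
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx optimize setNames uniroot
#' @importFrom utils modifyList read.csv write.csv
NULL

## Avogadro's number, molecules per mole
AVOGADRO <- 6.02214076e23

## pmol/(cell s) per (uM * cm^3 / s): 1 uM = 1e-9 mol/cm^3 = 1e3 pmol/cm^3
UM_CM3_TO_PMOL <- 1e3

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                       len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    .stopf("'%s' must be a finite numeric of length %d", name, len)
  x <- as.numeric(x)
  if (positive && any(x <= 0)) .stopf("'%s' must be > 0", name)
  if (nonneg && any(x < 0)) .stopf("'%s' must be >= 0", name)
  invisible(x)
}

#' Cell and carboxysome geometry
#'
#' @param Rb cell radius, cm
#' @param Rc carboxysome (compartment) radius, cm; must satisfy 0 < Rc < Rb
#' @return list with `Rb`, `Rc`, and derived quantities: cell volume
#'   `Vcell_L` (L), surface area `SAcell` (cm^2), compartment volume
#'   `Vcarb_L` (L), plus the cm^3 volumes `Vcell`, `Vcarb` and shell area
#'   `SAcarb` used internally.
#' @export
geometry <- function(Rb = 5e-5, Rc = 5e-6) {
  .check_num(Rb, "Rb", positive = TRUE)
  .check_num(Rc, "Rc", positive = TRUE)
  if (Rc >= Rb) .stopf("need 0 < Rc < Rb (got Rc = %g, Rb = %g)", Rc, Rb)
  Vcell <- 4 / 3 * pi * Rb^3   # cm^3
  Vcarb <- 4 / 3 * pi * Rc^3
  Rb <- as.numeric(Rb); Rc <- as.numeric(Rc)
  list(Rb = Rb, Rc = Rc,
       Vcell = Vcell, Vcarb = Vcarb,
       Vcell_L = Vcell * 1e-3, Vcarb_L = Vcarb * 1e-3,
       SAcell = 4 * pi * Rb^2, SAcarb = 4 * pi * Rc^2)
}

#' Diffusion constants
#'
#' @param D cytosolic diffusion constant of small molecules, cm^2/s
#' @param D_carb diffusion constant inside the carboxysome, cm^2/s
#'   (defaults to `D`; 1e-7 emulates a 60% sucrose-like crowded interior)
#' @export
diffusion_params <- function(D = 1e-5, D_carb = D) {
  .check_num(D, "D", positive = TRUE)
  .check_num(D_carb, "D_carb", positive = TRUE)
  list(D = as.numeric(D), D_carb = as.numeric(D_carb))
}

#' Cell-membrane transport parameters
#'
#' `alpha` is the maximal CO2->HCO3- conversion velocity-scale (cm/s * uM);
#' the conversion flux density is `alpha*C/(Kalpha + C)` so in the linear
#' regime (C << Kalpha) the uptake velocity is `alpha/Kalpha` cm/s.
#'
#' @param kmC membrane velocity for CO2, cm/s
#' @param kmH membrane velocity for HCO3-, cm/s
#' @param jc active HCO3- uptake velocity, cm/s
#' @param alpha maximal facilitated-uptake conversion scale, cm/s * uM
#' @param Kalpha half-max CO2 concentration of the conversion, uM
#' @export
membrane_params <- function(kmC = 0.3, kmH = 3e-4, jc = 0.6,
                            alpha = 0, Kalpha = 1) {
  .check_num(kmC, "kmC", nonneg = TRUE)
  .check_num(kmH, "kmH", nonneg = TRUE)
  .check_num(jc, "jc", nonneg = TRUE)
  .check_num(alpha, "alpha", nonneg = TRUE)
  .check_num(Kalpha, "Kalpha", positive = TRUE)
  list(kmC = as.numeric(kmC), kmH = as.numeric(kmH),
       jc = as.numeric(jc), alpha = as.numeric(alpha),
       Kalpha = as.numeric(Kalpha))
}

#' Carboxysome shell parameters
#'
#' The shell is non-selective: `kc` applies to both CO2 and HCO3-.
#' Pore geometry is optional and only used by [kc_upper_bound()].
#'
#' @param kc shell diffusive velocity, cm/s
#' @param Npores number of shell pores (optional)
#' @param rpore pore radius, cm (optional)
#' @param lshell shell thickness, cm (optional)
#' @export
shell_params <- function(kc = 1e-3, Npores = 4800, rpore = 0.35e-7,
                         lshell = 1.8e-7) {
  .check_num(kc, "kc", nonneg = TRUE)
  if (!is.null(Npores)) .check_num(Npores, "Npores", nonneg = TRUE)
  if (!is.null(rpore)) .check_num(rpore, "rpore", positive = TRUE)
  if (!is.null(lshell)) .check_num(lshell, "lshell", positive = TRUE)
  list(kc = as.numeric(kc),
       Npores = if (!is.null(Npores)) as.numeric(Npores),
       rpore = if (!is.null(rpore)) as.numeric(rpore),
       lshell = if (!is.null(lshell)) as.numeric(lshell))
}

#' Carbonic anhydrase kinetic constants (reversible Michaelis-Menten)
#'
#' Net dehydration rate (positive = HCO3- -> CO2):
#' `R_CA = (Vba*Kca*H - Vca*Kba*C) / (Kba*Kca + Kca*H + Kba*C)`.
#' Defaults are the carboxysome-column volumetric rates.
#'
#' @param Vca max hydration rate (CO2 -> HCO3-), uM/s in the active volume
#' @param Vba max dehydration rate (HCO3- -> CO2), uM/s
#' @param Kca hydration half-max (CO2), uM
#' @param Kba dehydration half-max (HCO3-), uM
#' @export
ca_kinetics <- function(Vca = 1.5e7, Vba = 8.8e6, Kca = 3.2e3, Kba = 9.3e3) {
  for (nm in c("Vca", "Vba", "Kca", "Kba"))
    .check_num(get(nm), nm, positive = TRUE)
  list(Vca = as.numeric(Vca), Vba = as.numeric(Vba),
       Kca = as.numeric(Kca), Kba = as.numeric(Kba))
}

#' RuBisCO kinetic constants (competitive CO2/O2 binding)
#'
#' Carboxylation: `Vmax*C/(C + Km0*(1 + O/KO))`.
#' Oxygenation:   `VmaxO*O/(O + KmO*(1 + C/KC))`.
#' In the standard paired competitive form `KC = Km0` and `KmO = KO`
#' (one O2 constant; `KO` and the literature's `Ki` are the same quantity).
#' `VmaxO` and `KO` defaults come from a one-time calibration against the
#' model's own operating point (see the calibration script shipped under
#' `scripts/`); headline budget quantities are insensitive to them.
#'
#' @param Vmax max carboxylation rate, uM/s in the active volume
#' @param Km0 carboxylation half-max without O2, uM
#' @param KO O2 inhibition constant of carboxylation, uM (alias `Ki`)
#' @param VmaxO max oxygenation rate, uM/s
#' @param KmO oxygenation half-max for O2, uM (defaults to `KO`)
#' @param KC CO2 inhibition constant of oxygenation, uM (defaults to `Km0`)
#' @export
rubisco_kinetics <- function(Vmax = 1.8e5, Km0 = 270, KO = 900,
                             VmaxO = 5.71185e4, KmO = KO, KC = Km0) {
  for (nm in c("Vmax", "Km0", "KO", "VmaxO", "KmO", "KC"))
    .check_num(get(nm), nm, positive = TRUE)
  list(Vmax = as.numeric(Vmax), Km0 = as.numeric(Km0),
       KO = as.numeric(KO), VmaxO = as.numeric(VmaxO),
       KmO = as.numeric(KmO), KC = as.numeric(KC))
}

#' External (boundary) conditions
#'
#' @param Cout external CO2, uM
#' @param Hout external HCO3-, uM
#' @param O intracellular O2, uM (treated as a constant field)
#' @export
external_conditions <- function(Cout = 0.14, Hout = 14, O = 260) {
  .check_num(Cout, "Cout", nonneg = TRUE)
  .check_num(Hout, "Hout", nonneg = TRUE)
  .check_num(O, "O", nonneg = TRUE)
  list(Cout = as.numeric(Cout), Hout = as.numeric(Hout),
       O = as.numeric(O))
}

CCM_SCENARIOS <- c("carboxysome", "scaffold", "whole_cell")
CA_PLACEMENTS <- c("volumetric", "inner_shell")

#' Full model parameterization
#'
#' Bundles geometry, diffusion, membrane, shell, enzyme kinetics and external
#' conditions. Kinetic rates (`ca`, `rubisco`) are volumetric rates in the
#' scenario's active volume: the carboxysome for `"carboxysome"` and
#' `"scaffold"`, the whole cell for `"whole_cell"`. Use
#' [rescale_for_scenario()] to move a parameter set between scenarios while
#' conserving total enzyme.
#'
#' @param geometry see [geometry()]
#' @param diffusion see [diffusion_params()]
#' @param membrane see [membrane_params()]
#' @param shell see [shell_params()]
#' @param ca see [ca_kinetics()]
#' @param rubisco see [rubisco_kinetics()]
#' @param external see [external_conditions()]
#' @param scenario one of `"carboxysome"` (enzymes behind a kc shell),
#'   `"scaffold"` (enzymes in the central sphere, no shell resistance),
#'   `"whole_cell"` (enzymes everywhere)
#' @param ca_placement `"volumetric"` or `"inner_shell"` (carbonic anhydrase
#'   as a surface source on the inner face of the shell, total activity
#'   conserved)
#' @return object of class `ccm_params`
#' @export
ccm_params <- function(geometry = ccmsim::geometry(),
                       diffusion = diffusion_params(),
                       membrane = membrane_params(),
                       shell = shell_params(),
                       ca = ca_kinetics(),
                       rubisco = rubisco_kinetics(),
                       external = external_conditions(),
                       scenario = "carboxysome",
                       ca_placement = "volumetric") {
  scenario <- match.arg(scenario, CCM_SCENARIOS)
  ca_placement <- match.arg(ca_placement, CA_PLACEMENTS)
  p <- structure(list(geometry = geometry, diffusion = diffusion,
                      membrane = membrane, shell = shell, ca = ca,
                      rubisco = rubisco, external = external,
                      scenario = scenario, ca_placement = ca_placement),
                 class = "ccm_params")
  validate_ccm_params(p)
}

#' Validate a `ccm_params` object
#' @param p a `ccm_params` object
#' @return `p`, invisibly reconstructed through the component constructors
#' @export
validate_ccm_params <- function(p) {
  if (!inherits(p, "ccm_params")) .stopf("not a ccm_params object")
  p$geometry <- do.call(geometry, p$geometry[c("Rb", "Rc")])
  p$diffusion <- do.call(diffusion_params, p$diffusion[c("D", "D_carb")])
  p$membrane <- do.call(membrane_params,
                        p$membrane[c("kmC", "kmH", "jc", "alpha", "Kalpha")])
  p$shell <- do.call(shell_params,
                     p$shell[c("kc", "Npores", "rpore", "lshell")])
  p$ca <- do.call(ca_kinetics, p$ca[c("Vca", "Vba", "Kca", "Kba")])
  p$rubisco <- do.call(rubisco_kinetics,
                       p$rubisco[c("Vmax", "Km0", "KO", "VmaxO", "KmO", "KC")])
  p$external <- do.call(external_conditions,
                        p$external[c("Cout", "Hout", "O")])
  p$scenario <- match.arg(p$scenario, CCM_SCENARIOS)
  p$ca_placement <- match.arg(p$ca_placement, CA_PLACEMENTS)
  p
}

#' Active enzyme volume of a scenario, cm^3
#' @param p a `ccm_params` object
#' @export
active_volume <- function(p) {
  if (p$scenario == "whole_cell") p$geometry$Vcell else p$geometry$Vcarb
}

#' Rescale kinetics to another scenario, conserving total enzyme
#'
#' Volumetric Vmax values scale inversely with the active volume so that
#' `Vmax * V_active` is invariant; half-max constants are unchanged.
#'
#' @param p a `ccm_params` object
#' @param scenario target scenario
#' @return a `ccm_params` object for the target scenario
#' @export
rescale_for_scenario <- function(p, scenario) {
  scenario <- match.arg(scenario, CCM_SCENARIOS)
  f <- active_volume(p)
  p$scenario <- scenario
  f <- f / active_volume(p)   # old volume / new volume
  p$ca$Vca <- p$ca$Vca * f
  p$ca$Vba <- p$ca$Vba * f
  p$rubisco$Vmax <- p$rubisco$Vmax * f
  p$rubisco$VmaxO <- p$rubisco$VmaxO * f
  validate_ccm_params(p)
}

#' Literal enzymatic-rate table (volumetric rates)
#'
#' The published whole-cell and carboxysome volumetric rate columns, kept
#' verbatim. Note the cell:carboxysome ratios are mutually inconsistent with
#' a single volume ratio (hydration x1704, dehydration x587, carboxylation
#' x1011 vs (Rb/Rc)^3 = 1000); [rescale_for_scenario()] therefore conserves
#' enzyme from the carboxysome column instead of using this table's cell
#' column.
#'
#' @return data.frame with columns reaction, Vmax_cell, Vmax_carboxysome,
#'   K_half (uM/s, uM/s, uM)
#' @export
table2_cell_column <- function() {
  data.frame(
    reaction = c("ca_hydration", "ca_dehydration", "rubisco_carboxylation"),
    Vmax_cell = c(8.8e3, 1.5e4, 178),
    Vmax_carboxysome = c(1.5e7, 8.8e6, 1.8e5),
    K_half = c(3.2e3, 9.3e3, 270))
}

#' @export
print.ccm_params <- function(x, ...) {
  cat("CCM model parameters\n")
  cat(sprintf("  scenario: %s (CA placement: %s)\n", x$scenario,
              x$ca_placement))
  cat(sprintf("  geometry: Rb = %g cm, Rc = %g cm\n",
              x$geometry$Rb, x$geometry$Rc))
  cat(sprintf("  diffusion: D = %g, D_carb = %g cm^2/s\n",
              x$diffusion$D, x$diffusion$D_carb))
  cat(sprintf("  membrane: jc = %g, kmC = %g, kmH = %g cm/s; alpha = %g, Kalpha = %g\n",
              x$membrane$jc, x$membrane$kmC, x$membrane$kmH,
              x$membrane$alpha, x$membrane$Kalpha))
  cat(sprintf("  shell: kc = %g cm/s\n", x$shell$kc))
  cat(sprintf("  CA: Vca = %g, Vba = %g uM/s; Kca = %g, Kba = %g uM\n",
              x$ca$Vca, x$ca$Vba, x$ca$Kca, x$ca$Kba))
  cat(sprintf("  RuBisCO: Vmax = %g, Km0 = %g, KO = %g; VmaxO = %g uM/s\n",
              x$rubisco$Vmax, x$rubisco$Km0, x$rubisco$KO, x$rubisco$VmaxO))
  cat(sprintf("  external: Cout = %g, Hout = %g, O = %g uM\n",
              x$external$Cout, x$external$Hout, x$external$O))
  invisible(x)
}
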