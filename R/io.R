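## Configuration files, presets, and result serialization.
##
## Configs are JSON (YAML accepted when the yaml package is available),
## with sections mirroring the parameter constructors; all values in
## canonical units (cm, s, uM). Unknown keys are rejected.

CONFIG_SCHEMA <- list(
  geometry = c("Rb", "Rc"),
  diffusion = c("D", "D_carb"),
  membrane = c("kmC", "kmH", "jc", "alpha", "Kalpha"),
  shell = c("kc", "Npores", "rpore", "lshell"),
  ca = c("Vca", "Vba", "Kca", "Kba"),
  rubisco = c("Vmax", "Km0", "KO", "VmaxO", "KmO", "KC"),
  external = c("Cout", "Hout", "O"))

#' Load model parameters from a config file or named preset
#'
#' Shipped presets: `"table1_table2_defaults"` (the standard
#' parameterization) and `"sucrose_carboxysome"` (identical except for a
#' crowded carboxysome interior, D_carb = 1e-7 cm^2/s).
#'
#' @param source path to a JSON/YAML config, or a preset name
#' @return a validated [ccm_params()] object
#' @export
load_config <- function(source) {
  path <- source
  if (!file.exists(path)) {
    path <- system.file("extdata", paste0(source, ".json"),
                        package = "ccmsim")
    if (!nzchar(path))
      .stopf("'%s' is neither a readable file nor a known preset", source)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  config_to_params(raw)
}

config_to_params <- function(raw) {
  known_top <- c(names(CONFIG_SCHEMA), "scenario", "ca_placement")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    .stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  for (sec in names(CONFIG_SCHEMA)) {
    extra <- setdiff(names(raw[[sec]]), CONFIG_SCHEMA[[sec]])
    if (length(extra))
      .stopf("unknown keys in section '%s': %s", sec,
             paste(extra, collapse = ", "))
  }
  build <- function(sec, fun) {
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    do.call(fun, args)
  }
  ccm_params(geometry = build("geometry", geometry),
             diffusion = build("diffusion", diffusion_params),
             membrane = build("membrane", membrane_params),
             shell = build("shell", shell_params),
             ca = build("ca", ca_kinetics),
             rubisco = build("rubisco", rubisco_kinetics),
             external = build("external", external_conditions),
             scenario = raw$scenario %||% "carboxysome",
             ca_placement = raw$ca_placement %||% "volumetric")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save model parameters as a JSON config
#'
#' @param p a [ccm_params()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
save_config <- function(p, path) {
  p <- validate_ccm_params(p)
  out <- list()
  for (sec in names(CONFIG_SCHEMA))
    out[[sec]] <- p[[if (sec == "geometry") "geometry" else sec]][
      CONFIG_SCHEMA[[sec]]]
  out$geometry <- p$geometry[c("Rb", "Rc")]
  out$scenario <- p$scenario
  out$ca_placement <- p$ca_placement
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write analysis results to deterministic CSV/JSON files
#'
#' Writes one or more CSV files (plus a JSON summary) into `outdir`;
#' re-running with an identical configuration reproduces identical numeric
#' fields.
#'
#' @param x a `ccm_solution`, `ccm_flux_budget`, `ccm_phase_scan`,
#'   `ccm_partition`, or `ccm_organization`
#' @param outdir output directory (created if missing)
#' @param prefix file-name prefix
#' @return character vector of files written, invisibly
#' @export
write_results <- function(x, outdir, prefix = NULL) UseMethod("write_results")

.res_file <- function(outdir, prefix, name) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  file.path(outdir, paste0(if (!is.null(prefix)) paste0(prefix, "_"), name))
}

.write_csv <- function(df, path) {
  write.csv(format(df, digits = 15, scientific = NA, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  path
}

#' @export
write_results.ccm_solution <- function(x, outdir, prefix = "solution") {
  f1 <- .res_file(outdir, NULL, paste0(prefix, "_profile.csv"))
  .write_csv(data.frame(r_cm = x$r, CO2_uM = x$C, HCO3_uM = x$H), f1)
  f2 <- .res_file(outdir, NULL, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(
    method = x$method, scenario = x$scenario, converged = x$converged,
    residual = x$residual, iterations = x$iterations,
    C_carboxysome_uM = region_mean(x, "C", "carboxysome"),
    H_carboxysome_uM = region_mean(x, "H", "carboxysome"),
    C_cytosol_uM = region_mean(x, "C", "cytosol"),
    H_cytosol_uM = region_mean(x, "H", "cytosol")),
    f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' @export
write_results.ccm_flux_budget <- function(x, outdir, prefix = "budget") {
  f1 <- .res_file(outdir, NULL, paste0(prefix, ".csv"))
  .write_csv(x$table, f1)
  f2 <- .res_file(outdir, NULL, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(
    gross_transport = x$gross_transport, hco3_leakage = x$hco3_leakage,
    co2_leakage = x$co2_leakage, carboxylation = x$carboxylation,
    oxygenation = x$oxygenation, facilitated = x$facilitated,
    net_hco3 = x$net_hco3,
    conservation_residual = x$conservation_residual),
    f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' @export
write_results.ccm_phase_scan <- function(x, outdir, prefix = "scan") {
  f1 <- .res_file(outdir, NULL, paste0(prefix, "_grid.csv"))
  .write_csv(x$grid, f1)
  f2 <- .res_file(outdir, NULL, paste0(prefix, "_contours.csv"))
  .write_csv(x$contours, f2)
  invisible(c(f1, f2))
}

#' @export
write_results.ccm_partition <- function(x, outdir, prefix = "partition") {
  f1 <- .res_file(outdir, NULL, paste0(prefix, ".csv"))
  .write_csv(x$table, f1)
  f2 <- .res_file(outdir, NULL, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(crossover_fraction = x$crossover_fraction,
                            total_Ci = x$total_Ci),
                       f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' @export
write_results.ccm_organization <- function(x, outdir, prefix = "organization") {
  f1 <- .res_file(outdir, NULL, paste0(prefix, ".csv"))
  .write_csv(x$table, f1)
  invisible(f1)
}
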