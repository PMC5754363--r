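#' Parse a concentration with explicit units
#'
#' Accepts a bare number (interpreted as mol/L) or a string with a unit
#' suffix: `"M"`, `"mM"`, `"uM"` (or the micro sign), `"nM"`, `"pM"`.
#' `"0.5 uM"` and `5e-7` parse identically.
#'
#' @param x Numeric scalar or unit-suffixed string.
#' @param name Field name used in error messages.
#' @return Concentration in mol/L.
#' @export
parse_concentration <- function(x, name = "concentration") {
  if (is.numeric(x)) {
    check_scalar(x, name)
    return(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    stop_invalid("'%s' must be a number (mol/L) or a string with units", name)
  }
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*(M|mM|uM|µM|μM|nM|pM)\\s*$", x))[[1L]]
  if (length(m) != 3L) {
    stop_invalid("cannot parse '%s' for '%s': use e.g. '0.5 uM' or a molar number",
                 x, name)
  }
  value <- as.numeric(m[[2L]])
  if (!is.finite(value)) stop_invalid("non-numeric value in '%s' for '%s'", x, name)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
             "µM" = 1e-6, "μM" = 1e-6)[[m[[3L]]]]
  value * scale
}

config_keys <- list(
  top = c("fiber", "composition", "species", "inhibition", "kinetics",
          "noise", "output", "seed"),
  fiber = c("radius_nm", "axial_rise_nm"),
  composition = c("conc_btadna", "conc_bta3oh"),
  species = c("name", "recruiter_total", "protein_total", "duplex_kd",
              "has_toehold"),
  inhibition = c("ki_solution"),
  kinetics = c("kcat_over_km", "substrate_conc", "fluorescence_per_product",
               "duplex_koff"),
  noise = c("sd_activity", "sd_fluorescence", "n_replicates", "seed")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    stop_invalid("unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", "))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) configuration describing the fiber
#' geometry, assembly composition, recruited species, inhibition constant,
#' kinetic constants and noise model, fills in the package defaults for
#' anything omitted, and returns fully validated domain objects. Unknown
#' keys are rejected by name; concentrations may be given as molar numbers
#' or unit-suffixed strings (see [parse_concentration()]). Every applied
#' default is recorded and reported via [message()].
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the applied-defaults message?
#' @return An object of class `run_config`: `fiber`, `composition`,
#'   `species` (named list of [recruited_species()]), `inhibition`,
#'   `kinetics`, `noise` (or `NULL`), `output`, `seed` and
#'   `defaults_applied` (character vector).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_keys$top, "config")
  used_default <- character(0)
  note_default <- function(what) used_default <<- c(used_default, what)

  fb <- raw$fiber
  if (is.null(fb)) fb <- list()
  check_keys(fb, config_keys$fiber, "fiber")
  if (is.null(fb$radius_nm)) note_default("fiber.radius_nm = 15")
  if (is.null(fb$axial_rise_nm)) note_default("fiber.axial_rise_nm = 0.452")
  fiber <- fiber_model(
    radius = fb$radius_nm %||% bta_defaults$radius_nm,
    axial_rise = fb$axial_rise_nm %||% bta_defaults$axial_rise_nm)

  cm <- raw$composition
  if (is.null(cm) || is.null(cm$conc_btadna) || is.null(cm$conc_bta3oh)) {
    stop_invalid("config must provide composition.conc_btadna and composition.conc_bta3oh")
  }
  check_keys(cm, config_keys$composition, "composition")
  composition <- assembly_composition(
    parse_concentration(cm$conc_btadna, "composition.conc_btadna"),
    parse_concentration(cm$conc_bta3oh, "composition.conc_bta3oh"))

  species <- list()
  for (sp in raw$species %||% list()) {
    check_keys(sp, config_keys$species, "species entry")
    if (is.null(sp$name) || is.null(sp$recruiter_total)) {
      stop_invalid("each species needs 'name' and 'recruiter_total'")
    }
    if (is.null(sp$duplex_kd)) {
      note_default(sprintf("species.%s.duplex_kd = 0.162 uM", sp$name))
    }
    species[[sp$name]] <- recruited_species(
      name = sp$name,
      recruiter_total = parse_concentration(sp$recruiter_total,
                                            paste0(sp$name, ".recruiter_total")),
      protein_total = if (is.null(sp$protein_total)) 0 else {
        parse_concentration(sp$protein_total, paste0(sp$name, ".protein_total"))
      },
      duplex_kd = if (is.null(sp$duplex_kd)) bta_defaults$duplex_kd_M else {
        parse_concentration(sp$duplex_kd, paste0(sp$name, ".duplex_kd"))
      },
      has_toehold = isTRUE(sp$has_toehold))
  }

  ih <- raw$inhibition
  if (is.null(ih)) ih <- list()
  check_keys(ih, config_keys$inhibition, "inhibition")
  if (is.null(ih$ki_solution)) note_default("inhibition.ki_solution = 1.5 uM")
  inhibition <- inhibition_model(
    if (is.null(ih$ki_solution)) bta_defaults$ki_solution_M else {
      parse_concentration(ih$ki_solution, "inhibition.ki_solution")
    })

  kn <- raw$kinetics
  if (is.null(kn)) kn <- list()
  check_keys(kn, config_keys$kinetics, "kinetics")
  kinetics <- enzyme_kinetics(
    kcat_over_km = kn$kcat_over_km %||% 1e3,
    substrate_conc = if (is.null(kn$substrate_conc)) 2e-6 else {
      parse_concentration(kn$substrate_conc, "kinetics.substrate_conc")
    },
    fluorescence_per_product = kn$fluorescence_per_product %||% 1e9,
    duplex_koff = kn$duplex_koff %||% bta_defaults$duplex_koff_s)

  noise <- NULL
  if (!is.null(raw$noise)) {
    check_keys(raw$noise, config_keys$noise, "noise")
    noise <- noise_model(
      sd_activity = raw$noise$sd_activity %||% 0.03,
      sd_fluorescence = raw$noise$sd_fluorescence %||% 0,
      n_replicates = raw$noise$n_replicates %||% 3L,
      seed = raw$noise$seed %||% raw$seed %||%
        stop_invalid("noise model requires a seed (noise.seed or top-level seed)"))
  }

  if (!quiet && length(used_default) > 0) {
    message("defaults applied: ", paste(used_default, collapse = "; "))
  }
  structure(list(fiber = fiber, composition = composition, species = species,
                 inhibition = inhibition, kinetics = kinetics, noise = noise,
                 output = raw$output, seed = raw$seed,
                 defaults_applied = used_default),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table_schemas <- list(
  titration = c("inhibitor_conc_M", "activity"),
  trace = c("time_s", "fluorescence_au"),
  exchange = c("time_h", "activity")
)

#' Read a schema-validated CSV table
#'
#' @param path CSV path with a header row.
#' @param schema One of `"titration"` (`inhibitor_conc_M`, `activity`, with
#'   optional `sd`, `n`), `"trace"` (`time_s`, `fluorescence_au`) or
#'   `"exchange"` (`time_h`, `activity`). Extra columns are preserved.
#' @return A `data.frame`; required columns are validated to be numeric,
#'   with malformed cells reported by row number.
#' @export
read_table <- function(path, schema = c("titration", "trace", "exchange")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- table_schemas[[schema]]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_invalid("missing column%s in %s: %s",
                 if (length(missing_cols) > 1) "s" else "", path,
                 paste(missing_cols, collapse = ", "))
  }
  numeric_cols <- intersect(c(required, "sd", "n"), names(df))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0) {
      stop_invalid("malformed numeric value in column '%s', row %d of %s: '%s'",
                   col, bad[[1L]], path, df[[col]][[bad[[1L]]]])
    }
    df[[col]] <- vals
  }
  for (col in setdiff(names(df), numeric_cols)) {
    conv <- utils::type.convert(df[[col]], as.is = TRUE)
    df[[col]] <- conv
  }
  df
}

#' Write a table as CSV, optionally with a provenance sidecar
#'
#' Writes `rows` as a plain CSV. When `provenance` is given (any named
#' list, e.g. seed, parameter defaults, package version), it is written to
#' `<path>.provenance.json` alongside, so every output records how it was
#' produced. Round-trips through [read_table()] are stable to float
#' formatting at 1e-12.
#'
#' @param rows A `data.frame`.
#' @param path Output CSV path.
#' @param provenance Optional named list recorded next to the table
#'   (requires the jsonlite package).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, provenance = NULL) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(format(rows, digits = 15, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(provenance)) {
    stopifnot(is.list(provenance))
    provenance$package_version <- as.character(utils::packageVersion("btarecruit"))
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop_invalid("writing provenance requires the 'jsonlite' package")
    }
    jsonlite::write_json(provenance, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
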