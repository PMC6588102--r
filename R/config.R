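# Configuration schema, validation, and output writing.
#
# A run configuration is a nested YAML (or JSON) document with one section
# per model component. load_config() fills defaults, rejects unknown keys,
# enforces every constructor invariant, and returns both the raw
# (round-trippable) document and the built parameter objects.

#' @noRd
config_defaults <- function() {
  list(
    schema_version = 1L,
    root_seed = 1L,
    cohort = list(
      n_persons = 100000L, entry_age_min = 40L, entry_age_max = 70L,
      age_weights = NULL, seed = NULL, cohort_csv = NULL
    ),
    mortality = list(
      makeham_c = 0.002, gompertz_a = 5e-5, gompertz_b = 0.092,
      max_age = 100L, life_table_csv = NULL
    ),
    natural_history = list(
      provenance = "uncalibrated placeholder",
      onset_hazard_scale = 0.006, onset_age_shape = 0.025,
      frac_onset_dcis = 0.80,
      progression = list(
        dcis_to_local = 0.35, local_to_regional = 0.32, regional_to_distant = 0.30
      ),
      symptomatic_detection_prob = list(
        DCIS = 0.04, LOCAL = 0.12, REGIONAL = 0.30, DISTANT = 0.60
      ),
      excess_bc_mortality = list(
        DCIS = 0.002, LOCAL = 0.015, REGIONAL = 0.06, DISTANT = 0.30
      )
    ),
    screening = list(
      status_quo = list(
        three_year_uptake = 0.60, program_window_years = 3L,
        background_uptake = 0.60, screening_interval_years = 2L,
        sensitivity_by_stage = list(
          DCIS = 0.75, LOCAL = 0.85, REGIONAL = 0.90, DISTANT = 0.95
        ),
        specificity = 0.92, program_flag = FALSE
      ),
      program = list(
        three_year_uptake = 0.80, program_window_years = 3L,
        background_uptake = 0.60, screening_interval_years = 2L,
        sensitivity_by_stage = list(
          DCIS = 0.75, LOCAL = 0.85, REGIONAL = 0.90, DISTANT = 0.95
        ),
        specificity = 0.92, program_flag = TRUE
      )
    ),
    economics = list(
      discount_rate = 0.03, program_cost_per_participant = 500,
      mammogram_cost = 100, false_positive_workup_cost = 250,
      treatment_cost_by_stage = list(
        DCIS = 12000, LOCAL = 22000, REGIONAL = 45000, DISTANT = 80000
      ),
      terminal_care_cost = 40000, utility_healthy = 0.92,
      utility_decrement_by_stage = list(
        DCIS = 0.05, LOCAL = 0.10, REGIONAL = 0.20, DISTANT = 0.40
      )
    ),
    cea = list(threshold = 50000),
    sensitivity = list(
      rate_from = 0.60, rate_to = 0.80, rate_by = 0.01,
      cost_from = 0, cost_to = 6000, cost_by = 50,
      n_persons = 20000L
    ),
    calibration = list(
      free_parameters = c(
        "onset_hazard_scale", "symptomatic_detection_scale",
        "excess_bc_mortality_scale", "treatment_cost_scale",
        "utility_decrement_scale", "program_cost_per_participant"
      ),
      bounds = NULL,
      targets = NULL, # default_calibration_targets()
      n_eval = 20000L, n_confirm = 100000L, max_evaluations = 150L
    )
  )
}

# Fill defaults recursively and reject unknown keys, tracking provenance.
#' @noRd
merge_config <- function(user, defaults, path = "", defaulted = character(0)) {
  if (!is.list(defaults)) {
    return(list(value = user, defaulted = defaulted))
  }
  if (is.null(user)) {
    return(list(value = defaults, defaulted = c(defaulted, path)))
  }
  if (!is.list(user)) stop_field(path, "must be a mapping")
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop_field(paste0(path, ".", extra[1]), "unknown configuration key")
  }
  out <- defaults
  for (nm in names(defaults)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (nm %in% names(user)) {
      if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]])) {
        m <- merge_config(user[[nm]], defaults[[nm]], key, defaulted)
        out[[nm]] <- m$value
        defaulted <- m$defaulted
      } else {
        out[[nm]] <- user[[nm]]
      }
    } else {
      defaulted <- c(defaulted, key)
    }
  }
  list(value = out, defaulted = defaulted)
}

# Remove NULL-valued keys recursively so explicit `~` in a file and an
# absent key normalise to the same structure (round-trip stability).
#' @noRd
drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' @noRd
num4 <- function(x, field) {
  v <- unlist(x)
  if (length(v) != 4L) stop_field(field, "needs 4 stage values")
  as.numeric(v)
}

# Build validated parameter objects from the raw (defaults-filled) document.
#' @noRd
build_config <- function(raw, source = "<list>") {
  wrap <- function(field, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: in `%s`: %s", source, field, conditionMessage(e)), call. = FALSE)
    })
  }
  co <- raw$cohort
  cohort_seed <- if (is.null(co$seed)) raw$root_seed else co$seed
  cspec <- wrap("cohort", cohort_spec(
    co$n_persons, co$entry_age_min, co$entry_age_max,
    if (is.null(co$age_weights)) NULL else as.numeric(unlist(co$age_weights)),
    seed = cohort_seed
  ))
  mo <- raw$mortality
  law <- wrap("mortality", if (!is.null(mo$life_table_csv)) {
    read_life_table(mo$life_table_csv, max_age = mo$max_age)
  } else {
    mortality_law(mo$makeham_c, mo$gompertz_a, mo$gompertz_b, mo$max_age)
  })
  nhs <- raw$natural_history
  nh <- wrap("natural_history", nh_params(
    onset_hazard_scale = nhs$onset_hazard_scale,
    onset_age_shape = nhs$onset_age_shape,
    frac_onset_dcis = nhs$frac_onset_dcis,
    progression = as.numeric(unlist(nhs$progression)),
    symptomatic_detection_prob = num4(nhs$symptomatic_detection_prob,
                                      "natural_history.symptomatic_detection_prob"),
    excess_bc_mortality = num4(nhs$excess_bc_mortality,
                               "natural_history.excess_bc_mortality"),
    provenance = nhs$provenance
  ))
  mk_policy <- function(block, field) {
    wrap(field, screening_policy(
      three_year_uptake = block$three_year_uptake,
      program_window_years = block$program_window_years,
      background_uptake = block$background_uptake,
      screening_interval_years = block$screening_interval_years,
      sensitivity_by_stage = num4(block$sensitivity_by_stage,
                                  paste0(field, ".sensitivity_by_stage")),
      specificity = block$specificity,
      program_flag = block$program_flag
    ))
  }
  policies <- list(
    status_quo = mk_policy(raw$screening$status_quo, "screening.status_quo"),
    program = mk_policy(raw$screening$program, "screening.program")
  )
  ec <- raw$economics
  econ <- wrap("economics", econ_params(
    discount_rate = ec$discount_rate,
    program_cost_per_participant = ec$program_cost_per_participant,
    mammogram_cost = ec$mammogram_cost,
    false_positive_workup_cost = ec$false_positive_workup_cost,
    treatment_cost_by_stage = num4(ec$treatment_cost_by_stage,
                                   "economics.treatment_cost_by_stage"),
    terminal_care_cost = ec$terminal_care_cost,
    utility_healthy = ec$utility_healthy,
    utility_decrement_by_stage = num4(ec$utility_decrement_by_stage,
                                      "economics.utility_decrement_by_stage")
  ))
  if (raw$cea$threshold <= 0) stop_field("cea.threshold", "must be > 0")
  ca <- raw$calibration
  cal_spec <- wrap("calibration", calibration_spec(
    free_parameters = unlist(ca$free_parameters),
    bounds = ca$bounds,
    targets = if (is.null(ca$targets)) {
      default_calibration_targets()
    } else {
      do.call(rbind, lapply(ca$targets, as.data.frame))
    },
    n_eval = ca$n_eval, n_confirm = ca$n_confirm,
    root_seed = raw$root_seed, max_evaluations = ca$max_evaluations
  ))
  se <- raw$sensitivity
  structure(
    list(
      raw = raw,
      schema_version = raw$schema_version,
      root_seed = as.integer(raw$root_seed),
      cohort_spec = cspec,
      cohort_csv = co$cohort_csv,
      law = law,
      nh = nh,
      policies = policies,
      econ = econ,
      cea = list(threshold = raw$cea$threshold),
      sensitivity = list(
        rate_grid = seq(se$rate_from, se$rate_to, by = se$rate_by),
        cost_grid = seq(se$cost_from, se$cost_to, by = se$cost_by),
        n_persons = as.integer(se$n_persons)
      ),
      calibration_spec = cal_spec
    ),
    class = "navsim_config"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, fills defaults (recorded in
#' `$defaulted_keys`), rejects unknown keys, enforces every parameter
#' invariant, and builds the parameter objects used by the simulation
#' functions.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`); alternatively a
#'   raw list via `config_list`.
#' @param config_list optional already-parsed configuration list (overrides
#'   `path`).
#' @param verbose message each defaulted key?
#' @return An object of class `navsim_config`.
#' @export
load_config <- function(path = NULL, config_list = NULL, verbose = FALSE) {
  source <- if (is.null(path)) "<list>" else path
  if (is.null(config_list)) {
    if (is.null(path) || !file.exists(path)) {
      stop(sprintf("configuration file not found: %s", source), call. = FALSE)
    }
    config_list <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }
  if (!is.null(config_list$schema_version) && config_list$schema_version != 1L) {
    stop_field("schema_version", "this package reads schema_version 1")
  }
  m <- merge_config(config_list, config_defaults())
  m$value <- drop_nulls(m$value)
  cfg <- build_config(m$value, source = source)
  cfg$defaulted_keys <- m$defaulted
  if (verbose && length(m$defaulted)) {
    message(
      "defaulted keys: ",
      paste(m$defaulted, collapse = ", ")
    )
  }
  cfg
}

#' The packaged default configuration
#'
#' @inheritParams load_config
#' @return A `navsim_config` built from the YAML shipped in
#'   `inst/extdata/default_config.yaml`.
#' @export
default_config <- function(verbose = FALSE) {
  load_config(
    system.file("extdata", "default_config.yaml", package = "navsim", mustWork = TRUE),
    verbose = verbose
  )
}

#' Write a configuration back to YAML
#'
#' Writes the defaults-filled raw document, so `load -> save -> load`
#' round-trips to an identical structure.
#'
#' @param config a `navsim_config`.
#' @param path output path (`.yaml`).
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "navsim_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Write result files and a run manifest
#'
#' Writes `scenario_results.csv` (one row per arm), `cea_comparison.csv`,
#' optionally `frontier.csv` and `calibration_report.csv`, a defaults-filled
#' `config.yaml` copy, and `manifest.json` carrying the config's MD5 hash,
#' the root seed, the package version, and the headline settings (discount
#' rate, threshold). Numeric CSV fields are written at full precision with
#' display-rounded companion columns where a published table defines the
#' display convention.
#'
#' @param bundle a named list with elements `comparison`
#'   (`cea_comparison`), optionally `frontier` (`frontier_result`) and
#'   `calibration` (`calibration_result`).
#' @param config the `navsim_config` of the run.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(bundle, config, out_dir) {
  stopifnot(inherits(config, "navsim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  cmp <- bundle$comparison
  if (!is.null(cmp)) {
    arms <- list(cmp$program, cmp$status_quo)
    wcsv(data.frame(
      arm = vapply(arms, `[[`, character(1), "arm"),
      mean_cost = vapply(arms, `[[`, numeric(1), "mean_cost"),
      mean_life_expectancy = vapply(arms, `[[`, numeric(1), "mean_life_expectancy"),
      mean_qaly = vapply(arms, `[[`, numeric(1), "mean_qaly"),
      se_cost = vapply(arms, function(a) a$se[["cost"]], numeric(1)),
      se_life_expectancy = vapply(arms, function(a) a$se[["life_expectancy"]], numeric(1)),
      se_qaly = vapply(arms, function(a) a$se[["qaly"]], numeric(1)),
      n_persons = vapply(arms, `[[`, integer(1), "n_persons"),
      display_cost = round(vapply(arms, `[[`, numeric(1), "mean_cost"), 2),
      display_life_expectancy = round(vapply(arms, `[[`, numeric(1), "mean_life_expectancy"), 2),
      display_qaly = round(vapply(arms, `[[`, numeric(1), "mean_qaly"), 2)
    ), "scenario_results.csv")
    wcsv(data.frame(
      delta_cost = cmp$delta_cost,
      delta_life_expectancy = cmp$delta_life_expectancy,
      delta_qaly = cmp$delta_qaly,
      icer = cmp$icer,
      flag = cmp$flag,
      threshold = cmp$threshold,
      cost_effective = cmp$cost_effective,
      display_delta_cost = round(cmp$delta_cost, 2),
      display_delta_qaly = round(cmp$delta_qaly, 2),
      display_icer = if (is.na(cmp$icer)) NA_real_ else round(cmp$icer, 2)
    ), "cea_comparison.csv")
  }
  if (!is.null(bundle$frontier)) {
    wcsv(bundle$frontier$frontier, "frontier.csv")
  }
  if (!is.null(bundle$calibration)) {
    wcsv(bundle$calibration$achieved, "calibration_report.csv")
    cal <- bundle$calibration$best_parameters
    wcsv(data.frame(parameter = names(cal), value = as.numeric(cal)),
         "calibrated_parameters.csv")
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  paths <- c(paths, cfg_path)
  manifest <- list(
    package = "navsim",
    package_version = as.character(utils::packageVersion("navsim")),
    root_seed = config$root_seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    discount_rate = config$econ$discount_rate,
    threshold = config$cea$threshold,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(paths)
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mpath))
}
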