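#' Read a pipeline run configuration
#'
#' Configurations are flat JSON or YAML documents (chosen by extension)
#' mirroring the arguments of [run_pipeline()]. Unknown keys are rejected so
#' typos fail loudly; missing keys fall back to package defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)",
         call. = FALSE)
  )
  known <- c("records", "smiles", "unit_target", "mode", "tce_homo_ref",
             "kid_tolerance", "pka_intercept", "pka_slope", "radar_ranges",
             "out_dir", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Run the full reporting pipeline
#'
#' Orchestrates record loading, KID validation, global and local descriptor
#' computation, pKa prediction and SMILES screening, and writes one CSV/JSON
#' report per stage. All arithmetic happens in the module functions
#' ([compute_kid()], [compute_global()], [local_site_table()],
#' [predict_pka()], [compute_profile()]); the pipeline only routes data, so
#' report values equal direct module-level calls on the same records. Given
#' the same configuration the outputs are byte-identical across runs.
#'
#' eV quantities in the CSV reports are formatted to 4 decimals; the JSON
#' sidecars retain full precision. A structured log of every configuration
#' value used is written alongside the reports.
#'
#' @param config A named list, or a path to a JSON/YAML file readable by
#'   [read_run_config()]. Recognised keys: `records` (character vector of
#'   record JSON paths), `smiles` (character vector of SMILES, or a path to
#'   a one-per-line file), `unit_target` (`"eV"`), `mode`
#'   (`"orbital"`/`"finite_difference"`), `tce_homo_ref`, `kid_tolerance`,
#'   `pka_intercept`/`pka_slope` (omit both to refit the packaged
#'   benchmark), `radar_ranges` (data frame like
#'   [default_radar_ranges()]), `out_dir`, `seed`.
#' @return Invisibly, a list of the report data frames (`kid`, `global`,
#'   `pka`, `local` (list), `profiles`, `radar` (list)) and `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  cfg <- list(
    records = config$records %||% character(0),
    smiles = config$smiles %||% character(0),
    unit_target = config$unit_target %||% "eV",
    mode = config$mode %||% "orbital",
    tce_homo_ref = config$tce_homo_ref %||% tce_homo_default,
    kid_tolerance = config$kid_tolerance %||% 0.10,
    pka_intercept = config$pka_intercept,
    pka_slope = config$pka_slope,
    out_dir = config$out_dir %||% ".",
    seed = config$seed %||% 1L
  )
  radar_ranges <- config$radar_ranges %||% default_radar_ranges()
  if (length(cfg$smiles) == 1L && file.exists(cfg$smiles)) {
    cfg$smiles <- readLines(cfg$smiles, warn = FALSE)
    cfg$smiles <- cfg$smiles[nzchar(trimws(cfg$smiles))]
  }
  if (length(cfg$records) == 0L && length(cfg$smiles) == 0L) {
    warning("no inputs configured; writing empty reports")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(name) file.path(cfg$out_dir, name)

  records <- lapply(cfg$records, function(p) {
    tryCatch(convert_units(load_record(p), cfg$unit_target),
             error = function(e) {
               stop("record '", p, "': ", conditionMessage(e), call. = FALSE)
             })
  })

  reports <- list(config = cfg)

  # KID report (records lacking any KID input are flagged, not dropped)
  kid_ok <- vapply(records, function(r) {
    !is.null(r$eps_somo_anion) || !is.null(r$e_n)
  }, logical(1))
  if (any(!kid_ok)) {
    warning("records without KID inputs skipped in the KID report: ",
            paste(vapply(records[!kid_ok], `[[`, "", "molecule_id"),
                  collapse = ", "))
  }
  reports$kid <- if (any(kid_ok)) {
    kid_table(records[kid_ok], tolerance = cfg$kid_tolerance)
  } else .empty_df(c("molecule_id", "homo", "lumo", "somo", "gap",
                     "j_i", "j_a", "j_hl", "delta_sl", "compliant"))
  .write_report_csv(reports$kid, out_path("kid.csv"))

  # global descriptors
  reports$global <- if (length(records) > 0) {
    global_table(records, mode = cfg$mode, tce_homo_ref = cfg$tce_homo_ref)
  } else .empty_df(c("molecule_id", "chi", "eta", "omega", "softness",
                     "nucleophilicity_n", "omega_minus", "omega_plus",
                     "net_electrophilicity"))
  .write_report_csv(reports$global, out_path("global.csv"))
  jsonlite::write_json(reports$global, out_path("global.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)

  # local site tables, one CSV per record that supports them
  reports$local <- list()
  for (r in records) {
    tab <- tryCatch(local_site_table(r), error = function(e) NULL)
    if (!is.null(tab)) {
      reports$local[[r$molecule_id]] <- tab
      write_site_table(tab, out_path(paste0(
        "local_", gsub("[^A-Za-z0-9._-]", "_", r$molecule_id), ".csv")))
    }
  }

  # pKa from hardness
  pmodel <- if (!is.null(cfg$pka_intercept) && !is.null(cfg$pka_slope)) {
    structure(list(intercept = cfg$pka_intercept, slope = cfg$pka_slope,
                   residuals = numeric(0), max_abs_residual = NA_real_,
                   n = 0L, fit = NULL), class = "pka_model")
  } else pka_default_model()
  reports$pka <- if (nrow(reports$global) > 0) {
    data.frame(molecule_id = reports$global$molecule_id,
               eta = reports$global$eta,
               pka = predict_pka(pmodel, reports$global$eta),
               stringsAsFactors = FALSE)
  } else .empty_df(c("molecule_id", "eta", "pka"))
  .write_report_csv(reports$pka, out_path("pka.csv"), digits = 2)

  # drug-likeness screen
  reports$profiles <- if (length(cfg$smiles) > 0) {
    profile_table(cfg$smiles)
  } else .empty_df(c("molecule_id", "smiles", "molecular_weight",
                     "logp_estimate", "tpsa", "hbd", "hba",
                     "rotatable_bonds", "fraction_csp3",
                     "molar_refractivity", "logs_estimate",
                     "lipinski_violations", "veber_pass"))
  utils::write.csv(reports$profiles, out_path("profiles.csv"),
                   row.names = FALSE)
  reports$radar <- lapply(cfg$smiles, function(s) {
    radar_axes(compute_profile(s), ranges = radar_ranges)
  })
  names(reports$radar) <- cfg$smiles
  jsonlite::write_json(reports$radar, out_path("radar.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)

  # structured log of every configuration value used
  log_cfg <- cfg
  log_cfg$radar_ranges <- radar_ranges
  log_cfg$pka_model <- list(intercept = pmodel$intercept,
                            slope = pmodel$slope)
  jsonlite::write_json(log_cfg, out_path("config_used.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(reports)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_df <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                      cols))
  df
}

# CSV writer with fixed decimal formatting for numeric columns (eV report
# convention: 4 decimals); logical/character columns pass through.
.write_report_csv <- function(df, path, digits = 4) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), "",
                          formatC(out[[nm]], digits = digits, format = "f"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
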