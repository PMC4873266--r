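# Table schemas: required/optional columns, types, and row-level checks.
# Each check returns TRUE per valid row; failures are reported with row
# numbers so bad lines in a CSV can be located.

.schemas <- list(
  irms = list(
    required = c(sample_id = "character", tree_id = "character",
                 tissue = "character", group = "character",
                 delta15n_permil = "numeric"),
    optional = c(n_mass_fraction = "numeric"),
    checks = list(
      delta15n_permil = list(
        fun = function(d) is.na(d$delta15n_permil) |
          d$delta15n_permil > -1000,
        msg = "delta15n_permil must be > -1000 per mil"),
      n_mass_fraction = list(
        fun = function(d) {
          if (!"n_mass_fraction" %in% names(d)) return(TRUE)
          is.na(d$n_mass_fraction) |
            (d$n_mass_fraction > 0 & d$n_mass_fraction <= 0.1)
        },
        msg = "n_mass_fraction must lie in (0, 0.1]")
    )
  ),
  ara_standards = list(
    required = c(known_ethylene_amount = "numeric", peak_area = "numeric"),
    optional = character(),
    checks = list(
      nonneg = list(
        fun = function(d) d$known_ethylene_amount >= 0 & d$peak_area >= 0,
        msg = "standard amounts and areas must be >= 0")
    )
  ),
  ara_vials = list(
    required = c(vial_id = "character", dosed = "logical",
                 sample_mass_g = "numeric"),
    optional = c(branch_id = "character", peak_area = "numeric",
                 ethylene_per_g = "numeric"),
    checks = list(
      mass = list(fun = function(d) d$sample_mass_g > 0,
                  msg = "sample_mass_g must be positive")
    )
  ),
  plates = list(
    required = c(sample_id = "character", tissue = "character",
                 medium = "character", colonies = "numeric",
                 dilution_factor = "numeric", plated_volume_ml = "numeric",
                 extraction_ml_per_g = "numeric"),
    optional = c(tntc = "logical"),
    checks = list(
      colonies = list(
        fun = function(d) (!is.na(d$colonies) & d$colonies >= 0) |
          (is.na(d$colonies) & isTRUE_vec(d$tntc)),
        msg = "colonies must be >= 0 (NA allowed only for TNTC plates)"),
      dilution = list(
        fun = function(d) d$dilution_factor > 0 & d$dilution_factor <= 1,
        msg = "dilution_factor must lie in (0, 1]"),
      volumes = list(
        fun = function(d) d$plated_volume_ml > 0 & d$extraction_ml_per_g > 0,
        msg = "plated_volume_ml and extraction_ml_per_g must be positive")
    )
  )
)

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Validate a table against a named schema
#'
#' Checks column presence and types, coerces integer columns to numeric
#' where the schema expects numeric, and evaluates the schema's row-level
#' invariants, reporting offending row numbers.
#'
#' @param df A data frame.
#' @param schema_name One of `"irms"`, `"ara_standards"`, `"ara_vials"`,
#'   `"plates"`.
#' @return The validated tibble (invisibly coerced).
#' @export
validate_table <- function(df, schema_name) {
  if (!schema_name %in% names(.schemas)) {
    stop("Unknown schema: ", schema_name, call. = FALSE)
  }
  sch <- .schemas[[schema_name]]
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(names(sch$required), names(df))
  if (length(missing_cols) > 0L) {
    stop("Schema '", schema_name, "': missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  types <- c(sch$required, sch$optional)
  for (col in intersect(names(types), names(df))) {
    want <- types[[col]]
    x <- df[[col]]
    if (want == "numeric" && is.integer(x)) x <- as.numeric(x)
    if (want == "character" && is.factor(x)) x <- as.character(x)
    if (want == "logical" && is.numeric(x) && all(x %in% c(0, 1, NA))) {
      x <- as.logical(x)
    }
    ok <- switch(want, numeric = is.numeric(x), character = is.character(x),
                 logical = is.logical(x))
    if (!ok) {
      stop("Schema '", schema_name, "': column `", col, "` must be ",
           want, ".", call. = FALSE)
    }
    df[[col]] <- x
  }
  for (nm in names(sch$checks)) {
    chk <- sch$checks[[nm]]
    ok <- chk$fun(df)
    if (length(ok) == 1L) ok <- rep(ok, nrow(df))
    if (any(!ok)) {
      stop("Schema '", schema_name, "': ", chk$msg, " (row(s) ",
           paste(utils::head(which(!ok), 10), collapse = ", "), ").",
           call. = FALSE)
    }
  }
  df
}

#' Read a CSV table and validate it
#'
#' @param path Path to an RFC-4180 CSV file with a header row; blank
#'   optional fields become `NA`.
#' @param schema_name Schema to validate against (see [validate_table()]).
#' @return Validated tibble.
#' @export
read_table <- function(path, schema_name) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(df, schema_name)
}

#' Write a table as CSV
#'
#' Doubles are written with 15 significant digits, which makes a
#' write/read/write cycle byte-stable (a 15-digit decimal re-serialises to
#' itself after parsing).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    x <- df[[col]]
    if (is.double(x)) {
      df[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
    }
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write all tables of a simulated study to a directory
#'
#' Emits `irms.csv`, `ara_vials.csv`, `ara_standards.csv`, `plates.csv`,
#' `truth.csv`, and a `manifest.yaml` recording the seed and config; a
#' fixed seed and config give byte-identical files.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    irms = file.path(dir, "irms.csv"),
    ara_vials = file.path(dir, "ara_vials.csv"),
    ara_standards = file.path(dir, "ara_standards.csv"),
    plates = file.path(dir, "plates.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_table(study$irms, paths[["irms"]])
  write_table(study$ara_vials, paths[["ara_vials"]])
  write_table(study$ara_standards, paths[["ara_standards"]])
  write_table(study$plates, paths[["plates"]])
  write_table(study$truth, paths[["truth"]])
  manifest <- list(seed = study$config$seed,
                   config = unclass(study$config),
                   config_hash = hash_object(unclass(study$config)),
                   files = as.list(unname(tools::md5sum(paths))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(paths)
}

hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain dosing -> %Ndfa -> group comparison, plus ARA
#' and CFU quantification, on either a simulated study (default) or input
#' CSVs, writing every stage's output table and a run manifest to
#' `out_dir`. Identical config and inputs give identical output tables.
#' Any stage failure aborts with a stage-named error and removes partial
#' outputs.
#'
#' @param config List (or path to a YAML file) with optional entries:
#'   `seed` (integer, default 1), `sim` (overrides passed to
#'   [sim_config()]), `inputs` (named paths `irms`, `ara_vials`,
#'   `ara_standards`, `plates` to analyse instead of simulating),
#'   `regime` (`flask = c(total, liquid)` plus `events`, each
#'   `list(type = "dose"/"air_exchange", removed, added, label_atom_pct,
#'   duration_days)`), `atmosphere_excess_atom_pct` (used when no regime
#'   given; default 6.17), `exposure_days` (default 14), `bdl_threshold`,
#'   `fold_threshold` (default 2), `weighting` (default `"final_dose"`).
#' @param out_dir Output directory.
#' @return Named list of stage results (invisibly): `excess`, `ndfa`,
#'   `ara`, `cfu`, `comparison`, `recovery` (when truth is available), and
#'   the `manifest` path.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  written <- character()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    written <<- c(written, p)
    p
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  input_files <- character()
  if (is.null(config$inputs)) {
    study <- run_stage("simulate", {
      cfg <- do.call(sim_config, c(list(seed = as.integer(seed)),
                                   config$sim))
      simulate_study(cfg)
    })
    irms <- study$irms; ara_vials <- study$ara_vials
    ara_standards <- study$ara_standards; plates <- study$plates
    truth <- study$truth
    emit(irms, "irms.csv"); emit(truth, "truth.csv")
  } else {
    study <- NULL; truth <- NULL
    irms <- run_stage("read", read_table(config$inputs$irms, "irms"))
    ara_vials <- if (!is.null(config$inputs$ara_vials)) {
      run_stage("read", read_table(config$inputs$ara_vials, "ara_vials"))
    }
    ara_standards <- if (!is.null(config$inputs$ara_standards)) {
      run_stage("read",
                read_table(config$inputs$ara_standards, "ara_standards"))
    }
    plates <- if (!is.null(config$inputs$plates)) {
      run_stage("read", read_table(config$inputs$plates, "plates"))
    }
    input_files <- unlist(config$inputs)
  }

  excess <- run_stage("dosing", {
    if (!is.null(config$regime)) {
      fl <- do.call(flask_spec, as.list(config$regime$flask))
      evs <- lapply(config$regime$events, function(e) {
        if (identical(e$type, "air_exchange")) {
          air_exchange(duration_days = e$duration_days %||% 0,
                       efficiency = e$efficiency %||% 1)
        } else {
          dose_event(e$removed, e$added, e$label_atom_pct %||% 98,
                     e$duration_days %||% 0)
        }
      })
      regime_excess(fl, evs,
                    weighting = config$weighting %||% "final_dose")
    } else {
      config$atmosphere_excess_atom_pct %||% 6.17
    }
  })

  ndfa <- run_stage("ndfa", {
    ndfa_table(irms, atmosphere_excess_atom_pct = excess,
               exposure_days = config$exposure_days %||% 14,
               bdl_threshold = config$bdl_threshold)
  })
  emit(ndfa, "ndfa.csv")

  ara <- NULL
  if (!is.null(ara_vials)) {
    ara <- run_stage("ara", {
      ara_analysis(ara_vials, standards = ara_standards,
                   fold_threshold = config$fold_threshold %||% 2)
    })
    emit(ara, "ara.csv")
  }

  cfu <- NULL
  if (!is.null(plates)) {
    cfu <- run_stage("cfu", cfu_per_gram(plates))
    emit(cfu, "cfu.csv")
  }

  comparison <- run_stage("compare", {
    agg <- aggregate_subsamples(irms)
    group_compare(agg)
  })
  emit(comparison$contrasts, "contrasts.csv")
  emit(comparison$means, "group_means.csv")

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- run_stage("recovery", truth_recovery_report(ndfa, truth))
    emit(tibble::tibble(ndfa_bias = recovery$ndfa_bias,
                        ndfa_rmse = recovery$ndfa_rmse,
                        sensitivity = recovery$confusion$sensitivity,
                        specificity = recovery$confusion$specificity),
         "recovery.csv")
  }

  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    seed = seed,
    config_hash = hash_object(config),
    settings = list(
      atmosphere_excess_atom_pct = excess,
      exposure_days = config$exposure_days %||% 14,
      reference_atom_pct = attr(ndfa, "reference_atom_pct"),
      bdl_threshold = attr(ndfa, "bdl_threshold"),
      fold_threshold = config$fold_threshold %||% 2),
    inputs = as.list(if (length(input_files)) {
      unname(tools::md5sum(input_files))
    } else character()),
    outputs = as.list(unname(tools::md5sum(written))),
    package_version = as.character(utils::packageVersion("diazoquant")),
    timestamp = format(Sys.time(), tz = "UTC")
  ), manifest_path)

  invisible(list(excess = excess, ndfa = ndfa, ara = ara, cfu = cfu,
                 comparison = comparison, recovery = recovery,
                 manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
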