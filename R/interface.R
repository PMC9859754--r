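#' Read and write run configurations
#'
#' Configurations are YAML (or JSON) files whose `params` block mirrors
#' [model_params()] field names exactly, with optional `schedule`
#' (`t_equilibrate`, `n_samples`, `sample_interval`) and analysis settings.
#' Unknown fields are rejected to catch typos. `overrides` (e.g. parsed from
#' command-line flags) take precedence over the file, which takes precedence
#' over package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param overrides Named list applied on top of the file's `params`.
#' @return A list with `params` ([model_params()]), `schedule`
#'   ([run_schedule()]) and any further top-level blocks passed through.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  par_fields <- raw$params %||% list()
  known <- names(formals(model_params))
  bad <- setdiff(names(par_fields), c(known, "omega_a"))
  if (length(bad))
    stop("unknown parameter field(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  par_fields <- modifyList(par_fields, overrides)
  pars <- do.call(model_params, par_fields)
  sch <- do.call(run_schedule, raw$schedule %||% list())
  out <- raw
  out$params <- pars
  out$schedule <- sch
  out
}

#' @rdname read_run_config
#' @param config A list as returned by [read_run_config()] (or with plain
#'   lists in place of the classed objects).
#' @export
write_run_config <- function(config, path) {
  config$params <- unclass(config$params)
  config$schedule <- unclass(config$schedule)
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' Write a run manifest
#'
#' Every output directory gets exactly one manifest recording the full
#' configuration snapshot, seed(s), package version, timestamps and an MD5
#' digest of every output file, so any result file is regenerable from its
#' manifest alone and verifiable against it.
#'
#' @param dir Output directory.
#' @param config Configuration snapshot (lists / classed objects).
#' @param seeds Named or unnamed integer vector of seeds used.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, config, seeds) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  digests <- if (length(files))
    as.list(tools::md5sum(file.path(dir, files))) else list()
  names(digests) <- files
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  manifest <- list(
    package = "cometsim",
    version = as.character(packageVersion("cometsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.list(seeds),
    config = strip(config),
    files = digests)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Verify files against a manifest
#'
#' @param dir Directory containing `manifest.json`.
#' @return `TRUE` if all digests match; otherwise an error naming the first
#'   mismatching file.
#' @export
verify_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    have <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(have) || have != manifest$files[[f]])
      stop("digest mismatch for ", f)
  }
  TRUE
}

#' Scenario flag combinations of the end-accumulation study
#'
#' The five mechanism combinations compared against each other: motor
#' slowdown in the cap region only (`cap`), coherently moving cargo trains
#' without (`trains`) and with (`trains_cap`) the cap, and stabilized cargo
#' clusters (trains plus enhanced dwell time) without (`stabilized`) and
#' with (`stabilized_cap`) the cap.
#' @return Named list of flag lists.
#' @export
scenario_flags <- function() {
  list(
    cap = list(enable_cap = TRUE, enable_trains = FALSE,
               enable_stabilization = FALSE),
    trains = list(enable_cap = FALSE, enable_trains = TRUE,
                  enable_stabilization = FALSE),
    trains_cap = list(enable_cap = TRUE, enable_trains = TRUE,
                      enable_stabilization = FALSE),
    stabilized = list(enable_cap = FALSE, enable_trains = TRUE,
                      enable_stabilization = TRUE),
    stabilized_cap = list(enable_cap = TRUE, enable_trains = TRUE,
                          enable_stabilization = TRUE))
}

apply_flags <- function(pars, flags) {
  pars[names(flags)] <- flags
  pars
}

#' Run the full scenario suite
#'
#' Runs each of the five scenarios ([scenario_flags()]) on matched seeds at
#' the base concentration, sweeps motor concentration for the independent
#' (cap only) and stabilized-cluster (trains + stabilization + cap)
#' scenarios, and computes non-linearity indices. Emits per-scenario density
#' profile CSVs, a sweep CSV, a JSON summary and a manifest into `out_dir`.
#' A failure in one scenario is isolated: the others still complete and the
#' failure is recorded in the summary.
#'
#' @param pars Base [model_params()] (scenario flags are overridden per
#'   scenario; the seed is shared so scenarios are matched).
#' @param schedule A [run_schedule()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param concentrations Motor concentrations for the sweep, nM.
#' @param profile_window Sites from the tip kept in the profile CSVs.
#' @param tip,lattice Analysis windows in sites from the tip (length-2,
#'   inclusive); defaults are the ~200 nm tip window and the 300-600 site
#'   mid-lattice window.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-scenario `profiles`,
#'   tip/lattice `occupations`, `sweeps`, `indices` and `errors`.
#' @export
run_scenario_suite <- function(pars = model_params(),
                              schedule = run_schedule(),
                              out_dir = NULL,
                              concentrations = c(20, 60, 120, 180),
                              profile_window = 601L,
                              tip = tip_window(pars),
                              lattice = lattice_window(pars),
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  tipw <- tip
  latw <- lattice
  scenarios <- scenario_flags()
  profiles <- list(); occupations <- list(); errors <- list()
  for (nm in names(scenarios)) {
    res <- tryCatch({
      pi <- apply_flags(pars, scenarios[[nm]])
      t0 <- proc.time()[["elapsed"]]
      ser <- run_simulation(pi, schedule)
      prof <- tip_aligned_profile(ser, profile_window)
      say(sprintf("scenario %-14s %6.1f s, %.3g events, tip cargo %.4f",
                  nm, proc.time()[["elapsed"]] - t0,
                  unname(ser$counts["events"]),
                  region_occupation(prof, tipw)))
      list(profile = prof,
           occ = c(tip_cargo = region_occupation(prof, tipw, "cargo"),
                   lattice_cargo = region_occupation(prof, latw, "cargo"),
                   tip_motor = region_occupation(prof, tipw, "motor"),
                   lattice_motor = region_occupation(prof, latw, "motor")))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      say("scenario ", nm, " FAILED: ", errors[[nm]])
    } else {
      profiles[[nm]] <- res$profile
      occupations[[nm]] <- res$occ
    }
  }

  sweep_scen <- c(independent = "cap", stabilized = "stabilized_cap")
  sweeps <- list(); indices <- list()
  for (nm in names(sweep_scen)) {
    res <- tryCatch({
      pi <- apply_flags(pars, scenarios[[sweep_scen[[nm]]]])
      sw <- concentration_sweep(pi, concentrations, schedule,
                                tip = tipw, lattice = latw)
      idx <- nonlinearity_index(sw, min(concentrations), max(concentrations))
      say(sprintf("sweep %-12s nonlinearity index %.3f", nm, idx))
      list(sweep = sw, index = idx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[paste0("sweep_", nm)]] <- conditionMessage(res)
    } else {
      sweeps[[nm]] <- res$sweep
      indices[[nm]] <- res$index
    }
  }

  out <- list(profiles = profiles, occupations = occupations,
              sweeps = sweeps, indices = indices, errors = errors,
              windows = list(tip = tipw, lattice = latw))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(profiles))
      utils::write.csv(profiles[[nm]],
                       file.path(out_dir, paste0("profile_", nm, ".csv")),
                       row.names = FALSE)
    for (nm in names(sweeps))
      utils::write.csv(sweeps[[nm]],
                       file.path(out_dir, paste0("sweep_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(occupations = occupations, nonlinearity_indices = indices,
           errors = errors, windows = out$windows),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(out_dir,
                   list(params = pars, schedule = schedule,
                        concentrations = concentrations),
                   seeds = pars$seed)
  }
  invisible(out)
}
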