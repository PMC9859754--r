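#' Simulation schedule: equilibration and sampling
#'
#' The published protocol equilibrates the system and then records motor and
#' cargo distributions at intervals of one single-motor traversal time of the
#' initial lattice (`L0 / p` seconds, ~50 s at the defaults), so that
#' successive snapshots are close to independent. The package default is a
#' desk-scale schedule (2,000 s equilibration, 500 samples); the full
#' published schedule (1e5 s, 1e4 samples) is available by argument.
#'
#' @param t_equilibrate Equilibration time before the first sample, s.
#' @param n_samples Number of recorded snapshots.
#' @param sample_interval Time between snapshots, s. Default `NULL` means one
#'   single-motor traversal time of the initial lattice, `L0 / p`, resolved
#'   when the schedule is used with a parameter set.
#' @return An object of class `run_schedule`.
#' @export
run_schedule <- function(t_equilibrate = 2000, n_samples = 500,
                         sample_interval = NULL) {
  if (t_equilibrate <= 0) stop("'t_equilibrate' must be positive")
  if (n_samples < 1) stop("schedule must request at least one sample")
  if (!is.null(sample_interval) && sample_interval <= 0)
    stop("'sample_interval' must be positive")
  structure(list(t_equilibrate = t_equilibrate,
                 n_samples = as.integer(n_samples),
                 sample_interval = sample_interval),
            class = "run_schedule")
}

resolve_interval <- function(schedule, pars) {
  if (!is.null(schedule$sample_interval)) return(schedule$sample_interval)
  if (pars$p <= 0) stop("cannot derive the traversal-time sample interval with p = 0; ",
                        "give 'sample_interval' explicitly")
  pars$L0 / pars$p
}

#' Run the stochastic simulation
#'
#' Exact continuous-time simulation (Gillespie direct method, compiled
#' class-aggregated implementation) of the growing-lattice motor-cargo model.
#' Starts from an empty, fully hydrolysed (all-GDP) lattice of `L0` sites,
#' equilibrates for `t_equilibrate`, then records `n_samples` snapshots at
#' `sample_interval`. Snapshots are the piecewise-constant state at the
#' scheduled times. Identical `(params, schedule, seed)` give identical
#' output; the seed in `pars$seed` is applied via [set.seed()] unless
#' `reseed = FALSE`.
#'
#' @param pars A [model_params()] object.
#' @param schedule A [run_schedule()] object.
#' @param reseed Apply `pars$seed` before running (default `TRUE`).
#' @return An object of class `snapshot_series`: list with `times`, `states`
#'   (each a [lattice_state]), `counts` (event tallies), `final_motor_count`,
#'   and provenance (`params`, `schedule`, `seed`).
#' @examples
#' pars <- model_params(L0 = 50, gamma = 0.5, seed = 7)
#' ser <- run_simulation(pars, run_schedule(50, 10, 5))
#' length(ser$states)
#' @export
run_simulation <- function(pars, schedule = run_schedule(), reseed = TRUE) {
  validate_model_params(pars)
  stopifnot(inherits(schedule, "run_schedule"))
  interval <- resolve_interval(schedule, pars)
  if (reseed) set.seed(pars$seed)
  raw <- .engine_run(unclass(pars), pars$L0, schedule$t_equilibrate,
                     schedule$n_samples, interval)
  states <- lapply(raw$states, function(sn) {
    structure(list(length = sn$length,
                   motor = sn$motor,
                   cargo = sn$cargo,
                   nucleotide = NUCLEOTIDE_STATES[sn$nucleotide + 1L],
                   time = sn$time),
              class = "lattice_state")
  })
  structure(list(times = raw$times,
                 states = states,
                 counts = raw$counts,
                 final_motor_count = raw$final_motor_count,
                 final_length = raw$final_length,
                 params = pars,
                 schedule = list(t_equilibrate = schedule$t_equilibrate,
                                 n_samples = schedule$n_samples,
                                 sample_interval = interval),
                 seed = pars$seed),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf("snapshot_series: %d snapshots, t = %.1f .. %.1f s\n",
              length(x$states), min(x$times), max(x$times)))
  cat(sprintf("  lattice %d -> %d sites; final motors: %d; events: %.3g\n",
              x$params$L0, x$final_length, x$final_motor_count,
              unname(x$counts["events"])))
  invisible(x)
}

#' Serialize a snapshot series to disk
#'
#' Writes one gzip-compressed tabular file (one row per site per snapshot:
#' `time, site, motor, cargo, nucleotide`) plus a JSON provenance sidecar
#' holding parameters, schedule and seed.
#'
#' @param series A `snapshot_series`.
#' @param dir Output directory (created if missing).
#' @param name Basename for the two files.
#' @return Invisibly, the paths written.
#' @export
write_snapshots <- function(series, dir, name = "snapshots") {
  stopifnot(inherits(series, "snapshot_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.table::rbindlist(lapply(seq_along(series$states), function(i) {
    st <- series$states[[i]]
    data.table::data.table(time = st$time, site = seq_len(st$length),
                           motor = st$motor, cargo = st$cargo,
                           nucleotide = st$nucleotide)
  }))
  data_path <- file.path(dir, paste0(name, ".csv.gz"))
  side_path <- file.path(dir, paste0(name, ".provenance.json"))
  data.table::fwrite(tab, data_path)
  jsonlite::write_json(
    list(params = unclass(series$params), schedule = series$schedule,
         seed = series$seed, n_snapshots = length(series$states),
         counts = as.list(series$counts)),
    side_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(data = data_path, provenance = side_path))
}

#' Read back a serialized snapshot series
#'
#' @param dir Directory written by [write_snapshots()].
#' @param name Basename used when writing.
#' @return A `snapshot_series` (parameters restored from the sidecar).
#' @export
read_snapshots <- function(dir, name = "snapshots") {
  tab <- utils::read.csv(file.path(dir, paste0(name, ".csv.gz")))
  prov <- jsonlite::read_json(file.path(dir, paste0(name, ".provenance.json")),
                              simplifyVector = TRUE)
  states <- lapply(split(tab, factor(tab$time, levels = unique(tab$time))),
                   function(d) {
    structure(list(length = nrow(d), motor = d$motor, cargo = d$cargo,
                   nucleotide = d$nucleotide, time = d$time[1L]),
              class = "lattice_state")
  })
  pars <- prov$params
  class(pars) <- "model_params"
  structure(list(times = vapply(states, `[[`, numeric(1), "time"),
                 states = unname(states),
                 counts = unlist(prov$counts),
                 final_motor_count = NA_integer_,
                 final_length = states[[length(states)]]$length,
                 params = pars, schedule = prov$schedule, seed = prov$seed),
            class = "snapshot_series")
}
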