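#' Tip-aligned density profile
#'
#' Aligns the last `window_sites` sites of every snapshot at the growing
#' plus-end and averages motor occupancy and total cargo occupation (stack
#' heights, so multi-layer cargo counts with its multiplicity) across
#' snapshots. The distance axis starts at the tip (0) and increases towards
#' the minus-end.
#'
#' @param series A `snapshot_series` from [run_simulation()].
#' @param window_sites Number of sites from the tip to include; must not
#'   exceed the shortest lattice in the series.
#' @return A `density_profile`: data frame with columns `distance_sites`,
#'   `distance_nm`, `motor_density` (in \[0, 1\]) and `cargo_occupation`
#'   (>= 0), with attribute `n_snapshots`.
#' @examples
#' ser <- run_simulation(model_params(L0 = 50, gamma = 0, seed = 2),
#'                       run_schedule(20, 20, 2))
#' prof <- tip_aligned_profile(ser, 30)
#' head(prof)
#' @export
tip_aligned_profile <- function(series, window_sites) {
  stopifnot(inherits(series, "snapshot_series"))
  window_sites <- as.integer(window_sites)
  if (window_sites < 1L) stop("'window_sites' must be at least 1")
  lens <- vapply(series$states, `[[`, integer(1), "length")
  short <- which(lens < window_sites)
  if (length(short))
    stop(sprintf("window of %d sites exceeds snapshot %d (length %d sites)",
                 window_sites, short[1L], lens[short[1L]]))
  n <- length(series$states)
  motor_sum <- numeric(window_sites)
  cargo_sum <- numeric(window_sites)
  for (st in series$states) {
    idx <- seq.int(st$length, by = -1L, length.out = window_sites)
    motor_sum <- motor_sum + st$motor[idx]
    cargo_sum <- cargo_sum + st$cargo[idx]
  }
  prof <- data.frame(distance_sites = 0:(window_sites - 1L),
                     distance_nm = (0:(window_sites - 1L)) * series$params$a,
                     motor_density = motor_sum / n,
                     cargo_occupation = cargo_sum / n)
  attr(prof, "n_snapshots") <- n
  class(prof) <- c("density_profile", "data.frame")
  prof
}

#' Mean occupation over a profile region
#'
#' Arithmetic mean of the cargo occupation (or motor density) over a window
#' of distances from the tip, the construction used to summarise tip and
#' lattice regions of a density profile.
#'
#' @param profile A `density_profile`.
#' @param region Length-2 vector: first and last distance from the tip, in
#'   sites, inclusive.
#' @param what `"cargo"` (default) or `"motor"`.
#' @return The mean occupation per site over the region.
#' @export
region_occupation <- function(profile, region, what = c("cargo", "motor")) {
  what <- match.arg(what)
  stopifnot(inherits(profile, "density_profile"), length(region) == 2L)
  region <- as.integer(region)
  sel <- profile$distance_sites >= min(region) &
         profile$distance_sites <= max(region)
  if (!any(sel)) stop("empty region: no profile sites between ",
                      min(region), " and ", max(region), " sites from the tip")
  col <- if (what == "cargo") "cargo_occupation" else "motor_density"
  mean(profile[[col]][sel])
}

#' Default analysis windows, in sites from the tip
#'
#' The tip window is 24 sites, i.e. round(200 nm / 8.4 nm): the ~200 nm tip
#' region. The lattice window is 300-600 sites from the tip, far from both
#' the tip and the minus-end boundary.
#' @name analysis_windows
#' @export
tip_window <- function(pars = model_params()) {
  c(0L, as.integer(round(200 / pars$a)) - 1L)
}

#' @rdname analysis_windows
#' @param pars A `model_params` object (only the site length `a` is used).
#' @export
lattice_window <- function(pars = model_params()) c(300L, 600L)

#' Motor-concentration sweep
#'
#' Runs one simulation per motor concentration (attachment rate scaled
#' through `kappa_a`; independent seeds `base seed + index`, recorded in the
#' result) and summarises each by the mean cargo occupation and motor density
#' over the tip and lattice windows.
#'
#' @param base_params A [model_params()] object; its scenario flags and all
#'   non-attachment rates are shared across the sweep.
#' @param concentrations Strictly increasing motor concentrations, nM.
#' @param schedule A [run_schedule()].
#' @param tip,lattice Windows in sites from the tip (length-2, inclusive).
#' @return A `sweep_result`: data frame with columns `c_motor`, `seed`,
#'   `tip_cargo`, `lattice_cargo`, `tip_motor`, `lattice_motor`.
#' @export
concentration_sweep <- function(base_params, concentrations,
                                schedule = run_schedule(),
                                tip = tip_window(base_params),
                                lattice = lattice_window(base_params)) {
  stopifnot(inherits(base_params, "model_params"))
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  rows <- lapply(seq_along(concentrations), function(i) {
    pars_i <- at_concentration(base_params, concentrations[i],
                               seed = base_params$seed + i)
    ser <- run_simulation(pars_i, schedule)
    win <- max(lattice, tip) + 1L
    prof <- tip_aligned_profile(ser, win)
    data.frame(c_motor = concentrations[i],
               seed = pars_i$seed,
               tip_cargo = region_occupation(prof, tip, "cargo"),
               lattice_cargo = region_occupation(prof, lattice, "cargo"),
               tip_motor = region_occupation(prof, tip, "motor"),
               lattice_motor = region_occupation(prof, lattice, "motor"))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", "data.frame")
  attr(res, "params") <- base_params
  attr(res, "tip") <- tip
  attr(res, "lattice") <- lattice
  res
}

#' Non-linearity index of end accumulation
#'
#' Ratio of the tip cargo-occupation fold-change to the lattice cargo
#' occupation fold-change between two motor concentrations. A value of 1
#' means the tip signal follows the lattice signal proportionally; values
#' above 1 indicate super-linear (non-stoichiometric) end accumulation. As an
#' experimental illustration of the same construction: an end intensity
#' increasing roughly fourfold while the motor's own signal doubles gives an
#' index of 2.
#'
#' @param sweep A `sweep_result` from [concentration_sweep()].
#' @param c_low,c_high Two concentrations present in the sweep.
#' @return Dimensionless ratio (tip fold-change) / (lattice fold-change).
#' @export
nonlinearity_index <- function(sweep, c_low, c_high) {
  stopifnot(inherits(sweep, "sweep_result"))
  i_lo <- match(c_low, sweep$c_motor)
  i_hi <- match(c_high, sweep$c_motor)
  if (is.na(i_lo) || is.na(i_hi))
    stop("both concentrations must be present in the sweep")
  if (sweep$tip_cargo[i_lo] <= 0)
    stop("tip cargo occupation is zero at the low concentration; ",
         "fold-change undefined")
  if (sweep$lattice_cargo[i_lo] <= 0 || sweep$lattice_cargo[i_hi] <= 0)
    stop("lattice cargo occupation must be positive at both concentrations")
  tip_fold <- sweep$tip_cargo[i_hi] / sweep$tip_cargo[i_lo]
  lattice_fold <- sweep$lattice_cargo[i_hi] / sweep$lattice_cargo[i_lo]
  tip_fold / lattice_fold
}
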