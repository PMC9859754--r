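#' Model parameters for the growing-lattice motor-cargo model
#'
#' Collects every kinetic rate, geometric constant and scenario switch of the
#' lattice model: a microtubule is a one-dimensional lattice of tubulin-dimer
#' sized sites growing at its plus-end; motors attach, detach and hop towards
#' the plus-end under mutual exclusion (TASEP with Langmuir kinetics, operated
#' in the low-density phase); cargo binds to bound motors and can stack into
#' multiple layers; optional scenario modifiers add a hydrolysing GTP cap that
#' slows motors near the tip, coherently moving cargo trains, and dwell-time
#' stabilization of cargo clusters.
#'
#' The motor attachment rate is proportional to motor concentration,
#' `omega_a = kappa_a * c_motor`; passing `omega_a` explicitly overrides this.
#' Defaults put the system in the low-density (LD) phase: at 100 nM the
#' Langmuir occupancy `omega_a / (omega_a + omega_d)` is 0.05.
#'
#' @param a Site length in nm (size of one tubulin heterodimer).
#' @param L0 Initial lattice length in sites.
#' @param p Motor hop rate on GDP sites, 1/s.
#' @param p_slow Motor hop rate on GTP and GDP-Pi sites, 1/s (used when
#'   `enable_cap` is `TRUE`); must not exceed `p`.
#' @param c_motor Motor concentration in nM.
#' @param kappa_a Attachment rate constant per nM, 1/(nM s).
#' @param omega_a Motor attachment rate per empty site, 1/s. Defaults to
#'   `kappa_a * c_motor`.
#' @param omega_d Motor detachment rate per bound motor, 1/s.
#' @param gamma Lattice growth rate, sites/s.
#' @param k_h1 Hydrolysis rate GTP -> GDP-Pi per site, 1/s.
#' @param k_h2 Hydrolysis rate GDP-Pi -> GDP per site, 1/s.
#' @param k_c_on First-layer cargo binding rate per cargo-free bound motor, 1/s.
#' @param k_c_off First-layer cargo unbinding rate, 1/s.
#' @param k_m_on Multi-layer cargo adsorption rate per exposed cargo top, 1/s.
#' @param k_m_off Multi-layer cargo desorption rate per exposed cargo top, 1/s.
#' @param s Cluster stabilization factor (dwell-time multiplier for clustered
#'   motor-cargo), dimensionless, >= 1.
#' @param enable_cap Enable the GTP cap and nucleotide-dependent slowdown.
#' @param enable_trains Enable coherent movement of cargo trains.
#' @param enable_stabilization Enable dwell-time stabilization of cargo
#'   clusters (detachment rate divided by `s` for clustered motor-cargo).
#' @param seed Integer random-number seed used by [run_simulation()].
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' pars <- model_params(c_motor = 100, enable_cap = TRUE)
#' pars$omega_a / (pars$omega_a + pars$omega_d)  # LD-phase Langmuir density
#' @export
model_params <- function(a = 8.4,
                         L0 = 1000L,
                         p = 20,
                         p_slow = p / 3,
                         c_motor = 100,
                         kappa_a = 0.25 * 0.05 / 0.95 / 100,
                         omega_a = NULL,
                         omega_d = 0.25,
                         gamma = 3,
                         k_h1 = 0.35,
                         k_h2 = 0.35,
                         k_c_on = 1,
                         k_c_off = 1,
                         k_m_on = 0.5,
                         k_m_off = 0.5,
                         s = 3,
                         enable_cap = FALSE,
                         enable_trains = FALSE,
                         enable_stabilization = FALSE,
                         seed = 1L) {
  if (is.null(omega_a)) omega_a <- kappa_a * c_motor
  pars <- list(
    a = a, L0 = as.integer(L0), p = p, p_slow = p_slow,
    c_motor = c_motor, kappa_a = kappa_a,
    omega_a = omega_a, omega_d = omega_d, gamma = gamma,
    k_h1 = k_h1, k_h2 = k_h2,
    k_c_on = k_c_on, k_c_off = k_c_off,
    k_m_on = k_m_on, k_m_off = k_m_off,
    s = s,
    enable_cap = isTRUE(enable_cap),
    enable_trains = isTRUE(enable_trains),
    enable_stabilization = isTRUE(enable_stabilization),
    seed = as.integer(seed)
  )
  class(pars) <- "model_params"
  validate_model_params(pars)
  pars
}

#' Validate model parameters
#'
#' Checks the structural invariants of a [model_params()] object: all rates
#' non-negative, `a > 0`, `L0 >= 2`, `s >= 1`, `p_slow <= p`. Emits a warning
#' (not an error) when the Langmuir occupancy `omega_a / (omega_a + omega_d)`
#' is at or above 0.5, i.e. outside the low-density regime the model is
#' intended for.
#'
#' @param pars A `model_params` object.
#' @return `pars`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_model_params <- function(pars) {
  stopifnot(inherits(pars, "model_params"))
  rates <- c("p", "p_slow", "omega_a", "omega_d", "gamma", "k_h1", "k_h2",
             "k_c_on", "k_c_off", "k_m_on", "k_m_off")
  for (r in rates) {
    v <- pars[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite non-negative number", r))
  }
  if (pars$a <= 0) stop("site length 'a' must be positive")
  if (pars$L0 < 2L) stop("initial lattice length 'L0' must be at least 2 sites")
  if (pars$s < 1) stop("stabilization factor 's' must be >= 1")
  if (pars$p_slow > pars$p)
    stop("'p_slow' must not exceed the GDP-lattice hop rate 'p'")
  occ <- pars$omega_a / (pars$omega_a + pars$omega_d)
  if (is.finite(occ) && occ >= 0.5)
    warning("Langmuir occupancy omega_a/(omega_a+omega_d) >= 0.5: ",
            "outside the low-density (LD) regime the model targets")
  invisible(pars)
}

#' Derive a parameter set at a different motor concentration
#'
#' Rescales the attachment rate through `kappa_a` while keeping every other
#' rate and flag, as in a motor-concentration titration.
#'
#' @param pars A `model_params` object.
#' @param c_motor New motor concentration, nM.
#' @param seed Optional new seed.
#' @return A `model_params` object at the new concentration.
#' @export
at_concentration <- function(pars, c_motor, seed = pars$seed) {
  stopifnot(inherits(pars, "model_params"), c_motor >= 0)
  pars$c_motor <- c_motor
  pars$omega_a <- pars$kappa_a * c_motor
  pars$seed <- as.integer(seed)
  validate_model_params(pars)
  pars
}

#' @export
print.model_params <- function(x, ...) {
  cat("Growing-lattice motor-cargo model parameters\n")
  cat(sprintf("  lattice: L0 = %d sites x %.1f nm, growth gamma = %g sites/s\n",
              x$L0, x$a, x$gamma))
  cat(sprintf("  motors:  p = %g/s (GDP), p_slow = %g/s (GTP/GDP-Pi), omega_a = %.4g/s (%g nM), omega_d = %g/s\n",
              x$p, x$p_slow, x$omega_a, x$c_motor, x$omega_d))
  cat(sprintf("  cargo:   k_c_on/off = %g/%g /s, k_m_on/off = %g/%g /s, s = %g\n",
              x$k_c_on, x$k_c_off, x$k_m_on, x$k_m_off, x$s))
  cat(sprintf("  scenario: cap = %s, trains = %s, stabilization = %s, seed = %d\n",
              x$enable_cap, x$enable_trains, x$enable_stabilization, x$seed))
  invisible(x)
}
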