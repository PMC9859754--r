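#' Nucleotide state labels, in hydrolysis order
#'
#' Per-site nucleotide states. Transitions only ever run forwards:
#' GTP -> GDP_Pi -> GDP (two-step hydrolysis), never backwards.
#' @export
NUCLEOTIDE_STATES <- c("GTP", "GDP_Pi", "GDP")

#' Construct a lattice state
#'
#' A microtubule is represented as a one-dimensional lattice of `length`
#' sites. Site 1 is the minus-end, site `length` the growing plus-end; motors
#' hop towards increasing site index. Each site holds at most one motor
#' (`motor[i]` is 0/1), and a bound motor may carry a stack of cargo layers
#' (`cargo[i] >= 0`); cargo exists only on bound motors. Each site carries a
#' nucleotide state (GTP, GDP-Pi or GDP) used by the GTP-cap scenario.
#'
#' @param length Number of sites (>= 1).
#' @param motor Integer 0/1 vector of motor occupancy (default empty lattice).
#' @param cargo Integer vector of cargo stack heights (default all 0).
#' @param nucleotide Character vector of per-site nucleotide states, or a
#'   single state recycled to all sites (default "GDP", a fully hydrolysed
#'   lattice).
#' @param time Simulation clock, seconds.
#' @return An object of class `lattice_state`.
#' @examples
#' st <- lattice_state(10)
#' st$motor[3] <- 1L; st$cargo[3] <- 2L
#' validate_lattice_state(st)
#' @export
lattice_state <- function(length, motor = integer(length), cargo = integer(length),
                          nucleotide = "GDP", time = 0) {
  length <- as.integer(length)
  if (length(nucleotide) == 1L) nucleotide <- rep(nucleotide, length)
  st <- structure(
    list(length = length,
         motor = as.integer(motor),
         cargo = as.integer(cargo),
         nucleotide = nucleotide,
         time = time),
    class = "lattice_state")
  validate_lattice_state(st)
  st
}

#' Validate a lattice state
#'
#' Enforces the state-space invariants: motor occupancy is 0/1, cargo stack
#' heights are non-negative and vanish on motor-free sites, nucleotide states
#' are one of [NUCLEOTIDE_STATES], and all per-site vectors have length
#' `length`. A cargo stack on an empty site is a hard failure naming the site.
#'
#' @param state A `lattice_state`.
#' @return `state`, invisibly, if valid.
#' @export
validate_lattice_state <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  L <- state$length
  if (length(state$motor) != L || length(state$cargo) != L ||
      length(state$nucleotide) != L)
    stop("per-site vectors must all have length ", L)
  if (!all(state$motor %in% c(0L, 1L)))
    stop("motor occupancy must be 0/1: each lattice site holds at most one motor")
  if (any(state$cargo < 0L)) stop("cargo stack heights must be non-negative")
  bad <- which(state$cargo > 0L & state$motor == 0L)
  if (length(bad))
    stop("cargo on empty site ", bad[1L], ": cargo exists only on bound motors")
  if (!all(state$nucleotide %in% NUCLEOTIDE_STATES))
    stop("nucleotide states must be one of: ",
         paste(NUCLEOTIDE_STATES, collapse = ", "))
  invisible(state)
}

#' Identify cargo trains
#'
#' A cargo train is a maximal run of adjacent cargo-bearing motors
#' (neighbouring cargo particles). Cargo-free motors are never members and
#' break runs, as do empty sites.
#'
#' @param state A `lattice_state`.
#' @return A list of integer vectors, each the (1-based, ascending) site
#'   indices of one train. Singleton clusters are length-1 trains.
#' @examples
#' st <- lattice_state(8)
#' st$motor[3:5] <- 1L; st$cargo[3:5] <- 1L
#' identify_trains(st)  # one train: sites 3,4,5
#' @export
identify_trains <- function(state) {
  validate_lattice_state(state)
  cm <- state$motor == 1L & state$cargo > 0L
  r <- rle(cm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) seq.int(starts[k], ends[k]))
}

#' Sites in stabilized cargo clusters
#'
#' A motor-cargo neighbouring at least one other motor-cargo is part of a
#' cluster; in the stabilization scenario such motors get a dwell time
#' enhanced by the factor `s` (detachment rate divided by `s`).
#'
#' @param state A `lattice_state`.
#' @return Integer vector of site indices holding clustered cargo-bearing
#'   motors (empty if none).
#' @export
stabilized_sites <- function(state) {
  validate_lattice_state(state)
  cm <- state$motor == 1L & state$cargo > 0L
  L <- state$length
  left <- c(FALSE, cm[-L])
  right <- c(cm[-1L], FALSE)
  which(cm & (left | right))
}

#' Enumerate all currently possible reactions and their rates
#'
#' Builds the full propensity catalogue of the model for a given state:
#' motor attachment at every empty site (`omega_a`); motor detachment at every
#' occupied site (`omega_d`, divided by `s` at stabilized cluster sites when
#' `enable_stabilization`); a hop for every motor with an empty plus-neighbour
#' (at the hop rate of the destination site's nucleotide state when
#' `enable_cap`, else `p`), where with `enable_trains` a hop of a cargo-bearing
#' motor is a train hop that moves its whole train coherently; first-layer
#' cargo binding/unbinding; multi-layer adsorption/desorption on the topmost
#' cargo layer; both hydrolysis steps when `enable_cap`; and one lattice
#' growth event (`gamma`). The plus-boundary is open: a motor on the terminal
#' site walks off the lattice (with its cargo stack) at its hop rate —
#' `p_slow` when the tip site is still in the cap — so the growing end itself
#' retains no motors; its detachment rate stays `omega_d` like everywhere
#' else. Impossible events and zero-rate reactions are omitted, never listed
#' with rate zero.
#'
#' @param state A `lattice_state`.
#' @param pars A `model_params` object.
#' @return A data frame with columns `event` (character), `site` (integer,
#'   `NA` for lattice growth) and `rate` (positive, finite). For `train_hop`
#'   the site is the train's leading (plus-most) motor.
#' @examples
#' pars <- model_params(L0 = 5, gamma = 1)
#' cat_empty <- propensity_catalogue(lattice_state(5), pars)
#' table(cat_empty$event)  # 5 attachments + 1 growth
#' @export
propensity_catalogue <- function(state, pars) {
  validate_lattice_state(state)
  stopifnot(inherits(pars, "model_params"))
  L <- state$length
  motor <- state$motor
  cargo <- state$cargo
  ev <- character(0); site <- integer(0); rate <- numeric(0)
  add <- function(e, s, r) {  # scalar rate r applied to site vector s
    if (r > 0 && length(s)) {
      ev <<- c(ev, rep(e, length(s)))
      site <<- c(site, s)
      rate <<- c(rate, rep(r, length(s)))
    }
  }

  empty <- which(motor == 0L)
  add("attach", empty, pars$omega_a)

  occ <- which(motor == 1L)
  if (length(occ)) {
    r_det <- rep(pars$omega_d, length(occ))
    if (pars$enable_stabilization) {
      stab <- stabilized_sites(state)
      r_det[occ %in% stab] <- pars$omega_d / pars$s
    }
    keep <- r_det > 0
    ev <- c(ev, rep("detach", sum(keep)))
    site <- c(site, occ[keep]); rate <- c(rate, r_det[keep])
  }

  movers <- which(motor == 1L & c(motor[-1L], 1L) == 0L)  # empty plus-neighbour
  if (length(movers)) {
    dest <- movers + 1L
    r_hop <- if (pars$enable_cap)
      ifelse(state$nucleotide[dest] == "GDP", pars$p, pars$p_slow)
    else rep(pars$p, length(movers))
    is_train <- pars$enable_trains & cargo[movers] > 0L
    keep <- r_hop > 0
    ev <- c(ev, ifelse(is_train, "train_hop", "hop")[keep])
    site <- c(site, movers[keep]); rate <- c(rate, r_hop[keep])
  }

  if (motor[L] == 1L) {  # open plus-boundary: walk off the end
    r_exit <- if (pars$enable_cap && state$nucleotide[L] != "GDP")
      pars$p_slow else pars$p
    if (r_exit > 0) {
      ev <- c(ev, "end_exit"); site <- c(site, L); rate <- c(rate, r_exit)
    }
  }

  add("cargo_bind", which(motor == 1L & cargo == 0L), pars$k_c_on)
  add("cargo_unbind", which(cargo == 1L), pars$k_c_off)
  add("cargo_adsorb", which(cargo >= 1L), pars$k_m_on)
  add("cargo_desorb", which(cargo >= 2L), pars$k_m_off)

  if (pars$enable_cap) {
    add("hydrolysis1", which(state$nucleotide == "GTP"), pars$k_h1)
    add("hydrolysis2", which(state$nucleotide == "GDP_Pi"), pars$k_h2)
  }

  if (pars$gamma > 0) {
    ev <- c(ev, "grow"); site <- c(site, NA_integer_); rate <- c(rate, pars$gamma)
  }
  data.frame(event = ev, site = site, rate = rate, stringsAsFactors = FALSE)
}

#' Apply one reaction to a lattice state
#'
#' Executes the state change of a single catalogue event. Motor detachment
#' removes the motor's entire cargo stack; a hop moves the motor with its
#' stack; a train hop advances the whole maximal run of adjacent cargo-bearing
#' motors ending at `site` by one site (internal exclusion preserved by
#' construction); growth appends one empty site at the plus-end (GTP when the
#' cap scenario is on, GDP otherwise) regardless of tip occupancy.
#'
#' @param state A `lattice_state`.
#' @param event Event name as produced by [propensity_catalogue()].
#' @param site Site index (ignored for `grow`).
#' @param pars A `model_params` object.
#' @return The updated `lattice_state` (time unchanged; the caller advances
#'   the clock).
#' @export
apply_event <- function(state, event, site, pars) {
  L <- state$length
  switch(event,
    attach = {
      stopifnot(state$motor[site] == 0L)
      state$motor[site] <- 1L
    },
    detach = ,
    end_exit = {
      stopifnot(state$motor[site] == 1L)
      state$motor[site] <- 0L
      state$cargo[site] <- 0L
    },
    hop = {
      stopifnot(state$motor[site] == 1L, site < L, state$motor[site + 1L] == 0L)
      state$motor[site + 1L] <- 1L
      state$cargo[site + 1L] <- state$cargo[site]
      state$motor[site] <- 0L
      state$cargo[site] <- 0L
    },
    train_hop = {
      stopifnot(state$motor[site] == 1L, state$cargo[site] > 0L,
                site < L, state$motor[site + 1L] == 0L)
      j <- site
      while (j > 1L && state$motor[j - 1L] == 1L && state$cargo[j - 1L] > 0L)
        j <- j - 1L
      idx <- seq.int(j, site)
      state$motor[idx + 1L] <- 1L
      state$cargo[idx + 1L] <- state$cargo[idx]
      state$motor[j] <- 0L
      state$cargo[j] <- 0L
    },
    cargo_bind = {
      stopifnot(state$motor[site] == 1L, state$cargo[site] == 0L)
      state$cargo[site] <- 1L
    },
    cargo_unbind = {
      stopifnot(state$cargo[site] == 1L)
      state$cargo[site] <- 0L
    },
    cargo_adsorb = {
      stopifnot(state$cargo[site] >= 1L)
      state$cargo[site] <- state$cargo[site] + 1L
    },
    cargo_desorb = {
      stopifnot(state$cargo[site] >= 2L)
      state$cargo[site] <- state$cargo[site] - 1L
    },
    hydrolysis1 = {
      stopifnot(state$nucleotide[site] == "GTP")
      state$nucleotide[site] <- "GDP_Pi"
    },
    hydrolysis2 = {
      stopifnot(state$nucleotide[site] == "GDP_Pi")
      state$nucleotide[site] <- "GDP"
    },
    grow = {
      state$length <- L + 1L
      state$motor <- c(state$motor, 0L)
      state$cargo <- c(state$cargo, 0L)
      state$nucleotide <- c(state$nucleotide,
                            if (pars$enable_cap) "GTP" else "GDP")
    },
    stop("unknown event: ", event)
  )
  state
}

#' One Gillespie step (reference R implementation)
#'
#' Draws the waiting time to the next reaction exponentially with rate equal
#' to the total propensity, selects one reaction with probability proportional
#' to its rate, and executes it. This pure-R stepper over
#' [propensity_catalogue()] is the small-system reference implementation; use
#' [run_simulation()] (compiled engine, distributionally identical) for
#' production-size lattices. Uses the session RNG; seed with [set.seed()].
#'
#' @param state A `lattice_state`.
#' @param pars A `model_params` object.
#' @return A list with the updated `state` (clock advanced by `dt`), the
#'   waiting time `dt`, and the executed `event`/`site`.
#' @examples
#' set.seed(1)
#' pars <- model_params(L0 = 10, gamma = 0)
#' out <- step_gillespie(lattice_state(10), pars)
#' out$event
#' @export
step_gillespie <- function(state, pars) {
  cat <- propensity_catalogue(state, pars)
  if (nrow(cat) == 0L)
    stop("absorbing state: no reaction has positive rate, simulation cannot proceed")
  total <- sum(cat$rate)
  dt <- rexp(1L, total)
  k <- sample.int(nrow(cat), 1L, prob = cat$rate)
  state <- apply_event(state, cat$event[k], cat$site[k], pars)
  state$time <- state$time + dt
  list(state = state, dt = dt, event = cat$event[k], site = cat$site[k])
}
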