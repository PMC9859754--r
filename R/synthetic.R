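#' Rendering configuration for synthetic microscopy data
#'
#' Imaging constants used by all synthetic-data generators. Defaults are
#' typical TIRF values: 0.107 um pixels, 1 s frames, 0.3 um PSF FWHM.
#'
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @param frame_interval_s Time between frames, seconds.
#' @param psf_fwhm_um Full width at half maximum of the Gaussian point-spread
#'   function, micrometres; 0 means a delta PSF (no blur).
#' @param intensity_per_particle Counts contributed by one particle.
#' @param background Background level, counts.
#' @param noise `"none"`, `"poisson"` (shot noise on counts) or `"gaussian"`.
#' @param gaussian_sd Standard deviation for Gaussian noise, counts.
#' @param n_frames Number of frames when rendering a static scene.
#' @param seed Seed for the generator's randomness.
#' @return A `render_config` object.
#' @export
render_config <- function(pixel_size_um = 0.107, frame_interval_s = 1,
                          psf_fwhm_um = 0.3, intensity_per_particle = 100,
                          background = 10,
                          noise = c("none", "poisson", "gaussian"),
                          gaussian_sd = 5, n_frames = 1L, seed = 1L) {
  if (pixel_size_um <= 0 || frame_interval_s <= 0)
    stop("pixel size and frame interval must be positive")
  if (psf_fwhm_um < 0) stop("'psf_fwhm_um' must be non-negative")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 psf_fwhm_um = psf_fwhm_um,
                 intensity_per_particle = intensity_per_particle,
                 background = background,
                 noise = match.arg(noise),
                 gaussian_sd = gaussian_sd,
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "render_config")
}

psf_sigma_px <- function(cfg) cfg$psf_fwhm_um / 2.3548 / cfg$pixel_size_um

# 1D Gaussian convolution with reflected borders (no-op for sigma = 0)
gauss_blur_1d <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  as.numeric(stats::convolve(xp, rev(k), type = "filter"))
}

apply_noise <- function(img, cfg) {
  switch(cfg$noise,
         none = img,
         poisson = {
           v <- rpois(length(img), pmax(img, 0))
           array(as.numeric(v), dim = dim(img) %||% length(img))
         },
         gaussian = img + rnorm(length(img), 0, cfg$gaussian_sd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a kymograph from simulation output or a parametric comet profile
#'
#' Produces a space-time image in which each motor (channel 1) and each cargo
#' layer (channel 2) contributes `intensity_per_particle` counts, convolved
#' with a Gaussian PSF, on top of a flat background with optional noise. The
#' cargo channel is proportional to total stack height (multi-layer cargo is
#' brighter), the motor channel to motor count, mirroring a
#' cargo-versus-motor two-colour readout. Given a `snapshot_series`, each
#' snapshot is one frame, with the minus-end at pixel 1; lattices shorter
#' than the longest one are zero-padded at the plus side. Given a single
#' [intensity_profile()], a static scene of `cfg$n_frames` identical frames
#' is rendered (one channel).
#'
#' @param x A `snapshot_series` or an `intensity_profile`.
#' @param cfg A [render_config()]. Randomness (noise) is seeded from
#'   `cfg$seed`.
#' @return A `kymograph`: list with `image` (array frames x pixels x
#'   channels), `pixel_size_um`, `frame_interval_s`, `channels`, and
#'   `ground_truth` (the generating occupancy maps or profile).
#' @export
render_kymograph <- function(x, cfg = render_config()) {
  stopifnot(inherits(cfg, "render_config"))
  set.seed(cfg$seed)
  sig <- psf_sigma_px(cfg)
  if (inherits(x, "snapshot_series")) {
    a_um <- x$params$a / 1000
    max_len <- max(vapply(x$states, `[[`, integer(1), "length"))
    npix <- ceiling(max_len * a_um / cfg$pixel_size_um)
    bin_of_site <- pmin(npix, 1L + floor(((seq_len(max_len)) - 0.5) *
                                           a_um / cfg$pixel_size_um))
    nfr <- length(x$states)
    img <- array(0, dim = c(nfr, npix, 2))
    truth_m <- matrix(0L, nfr, max_len)
    truth_c <- matrix(0L, nfr, max_len)
    for (f in seq_len(nfr)) {
      st <- x$states[[f]]
      truth_m[f, seq_len(st$length)] <- st$motor
      truth_c[f, seq_len(st$length)] <- st$cargo
      m_px <- vapply(seq_len(npix), function(b)
        sum(st$motor[bin_of_site[seq_len(st$length)] == b]), numeric(1))
      c_px <- vapply(seq_len(npix), function(b)
        sum(st$cargo[bin_of_site[seq_len(st$length)] == b]), numeric(1))
      img[f, , 1] <- gauss_blur_1d(m_px, sig) * cfg$intensity_per_particle
      img[f, , 2] <- gauss_blur_1d(c_px, sig) * cfg$intensity_per_particle
    }
    img <- img + cfg$background
    img[] <- apply_noise(img, cfg)
    gt <- list(motor = truth_m, cargo = truth_c, site_um = a_um)
    channels <- c("motor", "cargo")
  } else if (inherits(x, "intensity_profile")) {
    base <- gauss_blur_1d(x$intensity, sig) + cfg$background
    img <- array(rep(base, each = cfg$n_frames),
                 dim = c(cfg$n_frames, length(base), 1))
    img[] <- apply_noise(img, cfg)
    gt <- list(profile = x$intensity)
    channels <- "intensity"
  } else stop("'x' must be a snapshot_series or an intensity_profile")
  structure(list(image = img, pixel_size_um = cfg$pixel_size_um,
                 frame_interval_s = cfg$frame_interval_s,
                 channels = channels, config = cfg, ground_truth = gt),
            class = "kymograph")
}

#' Parametric comet-shaped intensity profile
#'
#' The canonical average shape of an end-tracking comet along a microtubule:
#' a shallow smooth intensity rise over the seed region, a constant plateau
#' along the lattice, and an exponential peak at the plus-end. The tip pixel
#' has value `lattice_level + end_amplitude` by construction.
#'
#' @param length_um Microtubule length, micrometres (must exceed
#'   `seed_rise_um`).
#' @param lattice_level Plateau intensity on the lattice.
#' @param end_amplitude Amplitude of the plus-end peak above the plateau.
#' @param end_decay_um Exponential decay length of the end peak, micrometres.
#' @param seed_rise_um Length of the smooth rise at the seed, micrometres.
#' @param pixel_size_um Pixel size, micrometres.
#' @param condition Condition label passed through.
#' @return An [intensity_profile()] whose attribute `ground_truth` records
#'   the generating parameters.
#' @export
parametric_comet_profile <- function(length_um, lattice_level, end_amplitude,
                                     end_decay_um, seed_rise_um = 1,
                                     pixel_size_um = 0.107, condition = "") {
  if (min(length_um, lattice_level, end_decay_um, seed_rise_um) < 0 ||
      end_amplitude < 0)
    stop("all profile parameters must be non-negative")
  if (length_um <= seed_rise_um)
    stop("microtubule length (", length_um,
         " um) must exceed the seed rise region (", seed_rise_um, " um)")
  n <- max(2L, round(length_um / pixel_size_um))
  x_seed <- (seq_len(n) - 1L) * pixel_size_um     # distance from the seed
  d_tip <- (n - seq_len(n)) * pixel_size_um       # distance from the plus-end
  rise <- ifelse(x_seed < seed_rise_um,
                 sin(pi / 2 * x_seed / seed_rise_um)^2, 1)
  y <- lattice_level * rise + end_amplitude * exp(-d_tip / end_decay_um)
  prof <- intensity_profile(y, pixel_size_um, condition)
  attr(prof, "ground_truth") <- list(length_um = length_um,
                                     lattice_level = lattice_level,
                                     end_amplitude = end_amplitude,
                                     end_decay_um = end_decay_um,
                                     seed_rise_um = seed_rise_um)
  prof
}

#' Synthetic two-channel condensate image
#'
#' Places `n` non-overlapping disks (rejection sampling) of given radii and
#' tag intensities on a flat background, blurs with the PSF and adds noise.
#' The client channel carries `recruitment_factor` times the tag structure
#' inside the condensates, emulating client recruitment into scaffold
#' droplets. Intensities are on the normalized \[0, 1\] scale expected by
#' [detect_condensates()].
#'
#' @param n Number of condensates (0 gives pure background).
#' @param radii Disk radii in pixels (recycled to length `n`).
#' @param tag_intensities Tag-channel disk intensities in (0, 1\] (recycled).
#' @param recruitment_factor Client/tag intensity ratio inside condensates.
#' @param cfg A [render_config()]; `background` and `gaussian_sd` are on the
#'   normalized intensity scale here.
#' @param dim Image dimensions in pixels.
#' @param max_attempts Placement attempts before failing.
#' @return List with `tag`, `client` (matrices) and `ground_truth` (centres,
#'   radii, intensities, recruitment factor).
#' @export
synth_condensate_image <- function(n, radii = 6, tag_intensities = 0.5,
                                   recruitment_factor = 1,
                                   cfg = render_config(background = 0.01,
                                                       gaussian_sd = 0.01),
                                   dim = c(256L, 256L),
                                   max_attempts = 2000L) {
  stopifnot(n >= 0, recruitment_factor >= 0)
  set.seed(cfg$seed)
  radii <- rep_len(radii, max(n, 1L))
  tag_intensities <- rep_len(tag_intensities, max(n, 1L))
  centres <- matrix(numeric(0), 0, 2)
  margin <- max(radii) + 4
  attempts <- 0L
  while (nrow(centres) < n) {
    if ((attempts <- attempts + 1L) > max_attempts)
      stop("could not place ", n, " non-overlapping condensates in ",
           max_attempts, " attempts")
    cand <- c(runif(1, margin, dim[1] - margin),
              runif(1, margin, dim[2] - margin))
    k <- nrow(centres) + 1L
    ok <- TRUE
    if (k > 1L) {
      dists <- sqrt(colSums((t(centres) - cand)^2))
      ok <- all(dists > radii[seq_len(k - 1L)] + radii[k] + 4)
    }
    if (ok) centres <- rbind(centres, cand)
  }
  xs <- matrix(seq_len(dim[1]), dim[1], dim[2])
  ys <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  structure_img <- matrix(0, dim[1], dim[2])
  for (k in seq_len(n)) {
    inside <- (xs - centres[k, 1])^2 + (ys - centres[k, 2])^2 <= radii[k]^2
    structure_img[inside] <- tag_intensities[k]
  }
  sig <- psf_sigma_px(cfg)
  blurred <- if (sig > 0)
    EBImage::imageData(EBImage::gblur(structure_img, sigma = sig))
  else structure_img
  clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  tag <- clamp01(apply_noise(blurred + cfg$background, cfg))
  client <- clamp01(apply_noise(recruitment_factor * blurred +
                                  cfg$background, cfg))
  list(tag = tag, client = client,
       ground_truth = list(n = n, centres = centres, radii = radii[seq_len(n)],
                           tag_intensities = tag_intensities[seq_len(n)],
                           recruitment_factor = recruitment_factor,
                           seed = cfg$seed))
}

#' Synthetic motile traces
#'
#' Linear traces with velocities drawn from a stated distribution and
#' Gaussian positional noise per point. The default distribution is
#' lognormal with median 0.23 um/s and log-sd 1.148, i.e. sd about
#' 0.73 um/s — matching a trace population with median 0.23 um/s and a
#' standard error of the mean of 0.06 um/s at N = 148. Negative-velocity
#' (minus-end-directed) distributions are supported by passing any sampler.
#'
#' @param n Number of traces (>= 1).
#' @param velocity_sampler Function of `n` returning `n` velocities in um/s.
#' @param noise_sd Positional noise per point, micrometres.
#' @param duration Trace duration, seconds.
#' @param dt Time step between points, seconds.
#' @param seed Seed.
#' @return List with `traces` (a [trace_set()]) and `ground_truth`
#'   (the drawn velocities and the generator settings).
#' @export
synth_traces <- function(n, velocity_sampler = function(m)
                           rlnorm(m, meanlog = log(0.23), sdlog = 1.148),
                         noise_sd = 0.02, duration = 10, dt = 1, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  v <- velocity_sampler(n)
  times <- seq(0, duration, by = dt)
  traces <- lapply(seq_len(n), function(i)
    data.frame(time_s = times,
               position_um = v[i] * times + rnorm(length(times), 0, noise_sd)))
  list(traces = trace_set(traces),
       ground_truth = list(velocities = v, median_velocity = median(v),
                           noise_sd = noise_sd, duration = duration,
                           dt = dt, seed = seed))
}

#' Serialize ground truth alongside a synthetic dataset
#'
#' @param ground_truth A generator's `ground_truth` list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path)
  jsonlite::read_json(path, simplifyVector = TRUE)
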