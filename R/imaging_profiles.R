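#' Rolling-ball background subtraction
#'
#' Estimates the image background by grey-level morphological opening with a
#' ball (spherical cap) structuring element of the given radius — the
#' classical rolling-ball estimate — and subtracts it, clipping the result at
#' zero. Intensities are internally rescaled so that the image's dynamic
#' range spans the ball radius, reproducing the classical behaviour on raw
#' camera-count images for arbitrarily normalized input. The subtraction is
#' invariant under an additive constant offset, and features much smaller
#' than the ball radius are preserved.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param radius_px Ball radius in pixels (> 0 and smaller than both image
#'   dimensions).
#' @return Matrix of the same dimensions with the background removed.
#' @examples
#' img <- matrix(5, 64, 64); img[30:32, 30:32] <- 50
#' out <- subtract_background(img, 20)
#' max(abs(out[1:10, 1:10]))  # flat background maps to 0
#' @export
subtract_background <- function(image, radius_px) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius_px <= 0) stop("'radius_px' must be positive")
  if (radius_px >= nrow(image) || radius_px >= ncol(image))
    stop("ball radius (", radius_px, " px) must be smaller than the image (",
         nrow(image), " x ", ncol(image), " px)")
  rng <- diff(range(image))
  if (rng == 0) return(array(0, dim(image)))  # flat image: all background
  scale <- radius_px / rng
  eroded <- .ball_morph(image * scale, radius_px, TRUE)
  background <- .ball_morph(eroded, radius_px, FALSE) / scale
  out <- image - background
  out[out < 0] <- 0
  out
}

#' Construct an intensity profile
#'
#' Per-pixel fluorescence intensity along one microtubule, from the seed
#' (index 1) to the plus-end (last pixel).
#'
#' @param intensity Non-negative numeric vector, one value per pixel.
#' @param pixel_size_um Pixel size in micrometres.
#' @param condition Free-text condition label (e.g. a motor concentration).
#' @return An `intensity_profile` object; its microtubule length is
#'   `length(intensity) * pixel_size_um`.
#' @export
intensity_profile <- function(intensity, pixel_size_um = 0.107,
                              condition = "") {
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  structure(list(intensity = as.numeric(intensity),
                 pixel_size_um = pixel_size_um,
                 length_um = length(intensity) * pixel_size_um,
                 condition = condition),
            class = "intensity_profile")
}

# s.d. of the pointwise difference between profile `x` shifted by `shift`
# pixels and the reference, over the overlapping support; Inf if the overlap
# has fewer than 2 pixels
shift_sd <- function(x, ref, shift) {
  ix <- seq_along(x) + shift          # positions of x's pixels on ref's axis
  keep <- ix >= 1L & ix <= length(ref)
  if (sum(keep) < 2L) return(Inf)
  stats::sd(x[keep] - ref[ix[keep]])
}

#' Bin intensity profiles by length and align them
#'
#' Profiles are grouped into microtubule-length bins of +/- `bin_halfwidth_um`
#' around bin centres spaced `2 * bin_halfwidth_um` apart. Within each bin a
#' reference profile is chosen by a seeded random draw, and every other
#' profile is shifted by an integer number of pixels (searched over
#' `+/- max_shift_px`) to minimise the standard deviation of its pointwise
#' difference to the reference; offsets are recorded. Singleton bins get
#' offset 0. Aligning an already-aligned set yields zero additional offsets.
#'
#' @param profiles List of [intensity_profile()] objects (at least one).
#' @param bin_halfwidth_um Half-width of the length bins, micrometres.
#' @param max_shift_px Alignment search range, pixels.
#' @param seed Seed for the reference draw.
#' @return A `profile_set`: list with `profiles`, integer `bin` assignment,
#'   integer `offset` per profile (pixels), `reference` index per bin, and
#'   `bin_centre_um`.
#' @export
bin_and_align <- function(profiles, bin_halfwidth_um = 0.64,
                          max_shift_px = 20L, seed = 1L) {
  if (!length(profiles)) stop("at least one profile is required")
  stopifnot(all(vapply(profiles, inherits, logical(1), "intensity_profile")))
  lens <- vapply(profiles, `[[`, numeric(1), "length_um")
  width <- 2 * bin_halfwidth_um
  bin <- as.integer(round(lens / width))
  offset <- integer(length(profiles))
  reference <- integer(0)
  set.seed(seed)
  for (b in sort(unique(bin))) {
    members <- which(bin == b)
    ref_i <- members[sample.int(length(members), 1L)]
    reference[as.character(b)] <- ref_i
    ref <- profiles[[ref_i]]$intensity
    for (i in members) {
      if (i == ref_i) { offset[i] <- 0L; next }
      shifts <- seq.int(-max_shift_px, max_shift_px)
      shifts <- shifts[order(abs(shifts))]  # ties resolve to the smallest shift
      sds <- vapply(shifts, function(s)
        shift_sd(profiles[[i]]$intensity, ref, s), numeric(1))
      offset[i] <- shifts[which.min(sds)]
    }
  }
  structure(list(profiles = profiles, bin = bin, offset = offset,
                 reference = reference,
                 bin_centre_um = as.numeric(sort(unique(bin))) * width,
                 bin_halfwidth_um = bin_halfwidth_um, seed = seed),
            class = "profile_set")
}

#' Average aligned profiles per length bin
#'
#' Pointwise mean of the aligned profiles of each bin over the support where
#' all of the bin's profiles overlap after shifting.
#'
#' @param set A `profile_set` from [bin_and_align()].
#' @return A named list (one entry per bin, names are bin centres in um) of
#'   [intensity_profile()] objects carrying attributes `n_profiles` and
#'   `support` (pixel range on the reference axis).
#' @export
average_profiles <- function(set) {
  stopifnot(inherits(set, "profile_set"))
  out <- list()
  for (b in sort(unique(set$bin))) {
    members <- which(set$bin == b)
    # overlap on the reference pixel axis
    lo <- max(vapply(members, function(i) 1L + set$offset[i], integer(1)))
    hi <- min(vapply(members, function(i)
      length(set$profiles[[i]]$intensity) + set$offset[i], integer(1)))
    if (hi < lo) stop("aligned profiles of bin ", b, " have no common support")
    acc <- rowMeans(vapply(members, function(i) {
      set$profiles[[i]]$intensity[(lo:hi) - set$offset[i]]
    }, numeric(hi - lo + 1L)))
    avg <- intensity_profile(acc, set$profiles[[members[1L]]]$pixel_size_um,
                             condition = set$profiles[[members[1L]]]$condition)
    attr(avg, "n_profiles") <- length(members)
    attr(avg, "support") <- c(lo, hi)
    out[[as.character(round(b * 2 * set$bin_halfwidth_um, 3))]] <- avg
  }
  out
}

# mean intensity of one profile over a window given as distances from the
# plus-end (tip), in micrometres: region = c(nearest, farthest)
region_mean <- function(profile, region_um) {
  n <- length(profile$intensity)
  d <- (n:1 - 1L) * profile$pixel_size_um  # distance of each pixel from tip
  sel <- d >= min(region_um) & d <= max(region_um)
  if (!any(sel)) stop("region [", min(region_um), ", ", max(region_um),
                      "] um from the tip contains no pixels")
  mean(profile$intensity[sel])
}

#' Per-profile intensity ratio between two conditions
#'
#' For each profile of the high condition, its mean intensity over a region
#' is divided by the across-profile average of the low condition over the
#' same region — the construction used to compare e.g. 100 nM against 20 nM
#' motor, for the lattice and the comet regions separately.
#'
#' @param high_profiles,low_profiles Lists of [intensity_profile()] objects.
#' @param region Length-2 numeric: window of distances from the plus-end,
#'   micrometres (e.g. `c(0, 1)` for the comet, `c(2, 6)` for the lattice).
#' @return Numeric vector of one ratio per high-condition profile.
#' @export
condition_ratio <- function(high_profiles, low_profiles, region) {
  if (!length(low_profiles)) stop("low condition must be non-empty")
  low_means <- vapply(low_profiles, region_mean, numeric(1), region)
  denom <- mean(low_means)
  if (denom <= 0) stop("low-condition mean over the region is not positive")
  vapply(high_profiles, region_mean, numeric(1), region) / denom
}
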