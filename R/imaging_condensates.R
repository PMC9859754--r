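#' Detect condensates in a tag-channel image
#'
#' Mirrors the condensate (droplet) segmentation used for scaffold-client
#' colocalization assays: the tag-channel image, normalized to \[0, 1\], is
#' background-subtracted (rolling ball), converted to a binary mask at a
#' fixed threshold (~0.05), and connected components are labelled. For each
#' component the binary centroid, the major/minor axis lengths of the
#' second-moment ellipse and the mean tag intensity are computed. Components
#' touching the image border are kept.
#'
#' @param tag_image Numeric matrix in \[0, 1\].
#' @param threshold Binarization threshold in (0, 1); default 0.05.
#' @param background_radius Rolling-ball radius in pixels, or `NULL` to skip
#'   background subtraction.
#' @return A `condensate_records` data frame with columns `label`, `cx`,
#'   `cy` (centroid, pixels), `major`, `minor` (axis lengths, pixels) and
#'   `mean_tag`, with the label image as attribute `labels`. Empty when
#'   nothing crosses the threshold.
#' @export
detect_condensates <- function(tag_image, threshold = 0.05,
                               background_radius = 50) {
  stopifnot(is.matrix(tag_image))
  if (min(tag_image) < 0 || max(tag_image) > 1)
    stop("'tag_image' must be normalized to [0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  img <- if (is.null(background_radius)) tag_image
         else subtract_background(tag_image, background_radius)
  mask <- EBImage::bwlabel(img > threshold)
  n <- max(mask)
  empty <- data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
                      major = numeric(0), minor = numeric(0),
                      mean_tag = numeric(0))
  if (n == 0) {
    res <- empty
  } else {
    mom <- EBImage::computeFeatures.moment(mask)
    mom <- matrix(mom, ncol = ncol(mom),
                  dimnames = list(NULL, colnames(mom)))  # keep matrix at n=1
    means <- vapply(seq_len(n), function(k) mean(img[mask == k]), numeric(1))
    # minor axis from the ellipse eccentricity: minor = major * sqrt(1 - e^2)
    res <- data.frame(label = seq_len(n),
                      cx = mom[, "m.cx"], cy = mom[, "m.cy"],
                      major = mom[, "m.majoraxis"],
                      minor = mom[, "m.majoraxis"] *
                        sqrt(pmax(0, 1 - mom[, "m.eccentricity"]^2)),
                      mean_tag = means)
  }
  attr(res, "labels") <- mask
  class(res) <- c("condensate_records", "data.frame")
  res
}

#' Client recruitment into condensates
#'
#' Mean client-channel intensity within each condensate mask, quantifying
#' colocalization of a client protein with tagged scaffold droplets.
#'
#' @param records A `condensate_records` object from [detect_condensates()]
#'   (its label image provides the masks).
#' @param client_image Numeric matrix with the same dimensions as the tag
#'   image the records were detected in.
#' @param background_radius Rolling-ball radius applied to the client channel
#'   before averaging, or `NULL` to skip.
#' @return `records` with an added column `mean_client`.
#' @export
client_recruitment <- function(records, client_image,
                               background_radius = 50) {
  stopifnot(inherits(records, "condensate_records"), is.matrix(client_image))
  labels <- attr(records, "labels")
  if (!identical(dim(labels), dim(client_image)))
    stop("client image geometry (", paste(dim(client_image), collapse = "x"),
         ") does not match the tag image (",
         paste(dim(labels), collapse = "x"), ")")
  img <- if (is.null(background_radius)) client_image
         else subtract_background(client_image, background_radius)
  records$mean_client <- vapply(records$label, function(k)
    mean(img[labels == k]), numeric(1))
  records
}
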