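## Geometric primitives. Segments are length-7 numeric vectors
## c(x0,y0,z0, x1,y1,z1, r) or lists made by segment(); all units um.

#' Construct a segment (capsule) between two points
#'
#' The neurite piece between a front and its parent, collision-tested as a
#' line segment inflated by the child front's radius. A degenerate segment
#' (`p0 == p1`) is allowed only as a soma placeholder.
#'
#' @param p0 numeric length-3, proximal (parent) endpoint, um.
#' @param p1 numeric length-3, distal (child) endpoint, um.
#' @param r capsule radius (child front radius), um, > 0.
#' @return numeric vector `c(p0, p1, r)` of class `arbor_segment`.
#' @export
segment <- function(p0, p1, r) {
  v <- c(as.numeric(p0), as.numeric(p1), as.numeric(r))
  if (length(v) != 7L || !all(is.finite(v)))
    stop("invalid geometry: segment needs finite p0, p1 (length 3) and r")
  if (v[7L] <= 0) stop("invalid geometry: segment radius must be > 0")
  class(v) <- "arbor_segment"
  v
}

seg_ends <- function(s) as.numeric(unclass(s)[1:6])

check_seg <- function(s) {
  s <- unclass(s)
  if (length(s) < 6L || !all(is.finite(s[1:6])))
    stop("invalid geometry: non-finite segment coordinates")
  s
}

#' Minimal distance between two line segments
#'
#' Minimum Euclidean distance between the two closed segments, radii
#' ignored. Symmetric and non-negative; zero iff the segments intersect.
#'
#' @param a,b segments from [segment()] (or plain length-6/7 vectors).
#' @return distance in um.
#' @export
minimal_segment_distance <- function(a, b) {
  a <- check_seg(a); b <- check_seg(b)
  cpp_seg_dist(a[1:6], b[1:6])
}

#' Capsule overlap test
#'
#' Two segments overlap when the minimal distance between their axes is
#' strictly smaller than the sum of their radii. Excluding adjacent
#' (parent/sibling) segments is the caller's job.
#'
#' @param a,b segments from [segment()].
#' @return logical flag.
#' @export
capsules_overlap <- function(a, b) {
  a <- check_seg(a); b <- check_seg(b)
  if (length(a) < 7L || length(b) < 7L)
    stop("capsules_overlap needs segments with radii")
  cpp_seg_dist(a[1:6], b[1:6]) < a[7L] + b[7L]
}

#' Closest-approach point between two segments
#'
#' Midpoint of the two closest points of `a` and `b`; used to locate
#' putative synapses. When the closest-point pair is non-unique (parallel
#' overlap) the midpoint of the overlapping parameter intervals is used, so
#' the answer is deterministic.
#'
#' @param a,b segments.
#' @return numeric length-3 point, um.
#' @export
closest_approach_point <- function(a, b) {
  a <- check_seg(a); b <- check_seg(b)
  cp <- cpp_seg_closest(a[1:6], b[1:6])
  0.5 * (cp[4:6] + cp[7:9])
}

#' Compose a growth direction from weighted cue contributions
#'
#' Normalized weighted vector sum of the contributions. A degenerate sum
#' (norm below 1e-12, e.g. perfectly opposed cues) falls back to a uniformly
#' random unit vector so growth never stalls silently; supply a seeded RNG
#' state for reproducibility.
#'
#' @param contributions list of `list(v = length-3 vector, w = weight >= 0)`.
#' @return unit-length direction vector.
#' @export
compose_direction <- function(contributions) {
  if (length(contributions) == 0L)
    stop("compose_direction: at least one contribution is required")
  acc <- c(0, 0, 0)
  for (ct in contributions) {
    w <- if (is.null(ct$w)) 1 else ct$w
    if (w < 0) stop("compose_direction: weights must be >= 0")
    acc <- acc + w * as.numeric(ct$v)
  }
  nrm <- sqrt(sum(acc^2))
  if (!is.finite(nrm) || nrm < 1e-12) return(random_unit_vector())
  acc / nrm
}

#' Distance-dependent cue weight
#'
#' Exponential gradient `exp(-d / scale)`, mimicking the falloff of a
#' secreted guidance molecule. Bounded in (0, 1], monotone non-increasing.
#'
#' @param d distance, um, >= 0 (vectorized).
#' @param scale decay length, um, > 0.
#' @return weight(s) in (0, 1].
#' @export
distance_weight <- function(d, scale) {
  if (any(d < 0) || !all(is.finite(d))) stop("distance_weight: d must be >= 0")
  if (scale <= 0) stop("distance_weight: scale must be > 0")
  exp(-d / scale)
}

#' Uniformly random unit vector
#'
#' Gaussian-normalize method: a standard-normal triple scaled to unit norm
#' is uniform on the sphere. Draws from R's global RNG; seed the session for
#' reproducibility.
#'
#' @return unit-length direction vector.
#' @export
random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-12) return(v / nrm)
  }
}

normalize3 <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) random_unit_vector() else v / nrm
}

## Uniform point in the unit ball (for conflict-resolution perturbations).
runif_ball <- function(radius) {
  radius * runif(1)^(1 / 3) * random_unit_vector()
}
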