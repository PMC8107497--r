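#' Diagnostic parameters on the superpixel grid
#'
#' Three scalar parameters summarise an eye's adjusted superpixel
#' reflectance vector against the normative reference: the overall average
#' reflectance, the number of low-reflectance superpixels (below the
#' normative 5th-percentile cutoff), and the focal reflectance loss (the
#' summed deviation from the normative mean over low-reflectance
#' superpixels, divided by the total superpixel count). Focal loss
#' concentrates on regions whose loss is too deep to be measurement noise,
#' which is what makes it sensitive to early, localized glaucoma.
#'
#' @name diagnostics
NULL

#' Overall average reflectance
#'
#' Arithmetic mean of the (adjusted) superpixel values; missing superpixels
#' are excluded.
#'
#' @param values numeric vector of superpixel reflectance (dB).
#' @return Scalar dB.
#' @export
average_reflectance <- function(values) {
  if (all(is.na(values))) stop("all superpixel values missing")
  mean(values, na.rm = TRUE)
}

#' Count of low-reflectance superpixels
#'
#' Number of superpixels strictly below their percentile cutoff. Values
#' exactly at the cutoff are not counted.
#'
#' @param values superpixel vector (dB).
#' @param cutoffs matching vector of per-superpixel cutoffs (dB).
#' @return Integer count.
#' @export
low_reflectance_count <- function(values, cutoffs) {
  if (length(values) != length(cutoffs)) stop("length mismatch")
  sum(values < cutoffs, na.rm = TRUE)
}

#' Focal reflectance loss
#'
#' Sum of `value - normative mean` over the low-reflectance superpixels
#' (those strictly below the 5% cutoff), divided by the total number of
#' superpixels. Zero when no superpixel is low; otherwise negative, since
#' low superpixels sit below the normative mean.
#'
#' @param values superpixel vector (dB).
#' @param mu per-superpixel normative means (dB).
#' @param cutoffs per-superpixel 5% cutoffs (dB).
#' @return Scalar dB (<= 0).
#' @export
focal_reflectance_loss <- function(values, mu, cutoffs) {
  if (length(values) != length(mu) || length(values) != length(cutoffs))
    stop("length mismatch")
  low <- which(values < cutoffs)
  if (!length(low)) return(0)
  sum(values[low] - mu[low]) / length(values)
}

#' Per-superpixel significance labels
#'
#' Classifies each superpixel as `"abnormal"` (below the 1% cutoff),
#' `"borderline"` (at or above the 1% but below the 5% cutoff) or
#' `"normal"`.
#'
#' @param values superpixel vector (dB).
#' @param q5,q1 per-superpixel cutoffs (dB).
#' @return Character vector of labels (`NA` where the value is missing).
#' @export
significance_map <- function(values, q5, q1) {
  if (length(values) != length(q5) || length(values) != length(q1))
    stop("length mismatch")
  out <- ifelse(values < q1, "abnormal",
                ifelse(values < q5, "borderline", "normal"))
  out[is.na(values)] <- NA_character_
  out
}

#' Classify the reflectance-loss pattern
#'
#' Operationalizes the five-way defect-pattern taxonomy on the track-by-
#' segment lattice of low-reflectance superpixels. Connected components are
#' taken under 4-connectivity with the track dimension wrapping cyclically
#' (diagonal contact is not contiguity). Labels, in decreasing severity:
#' \describe{
#'   \item{diffuse}{full-width loss (all segments low in a track) over more
#'     than a quadrant, i.e. more than `n_tracks / 4` consecutive tracks;}
#'   \item{wedge}{a connected component touching both the innermost and the
#'     outermost segment ring;}
#'   \item{other_grouping}{a connected component of 3 or more superpixels
#'     that is not a wedge;}
#'   \item{isolated}{low superpixels present but none of the above;}
#'   \item{none}{no low superpixel.}
#' }
#' When several patterns coexist the most severe one is reported.
#'
#' @param low logical vector of length `n_tracks * n_segments` (the 5%
#'   low-reflectance mask), ordered (track, segment) with segment fastest.
#' @param n_tracks,n_segments lattice dimensions.
#' @return One of `"diffuse"`, `"wedge"`, `"other_grouping"`, `"isolated"`,
#'   `"none"`.
#' @export
classify_pattern <- function(low, n_tracks = 32, n_segments = 5) {
  low[is.na(low)] <- FALSE
  stopifnot(length(low) == n_tracks * n_segments)
  lat <- matrix(low, nrow = n_segments, ncol = n_tracks)  # [segment, track]
  if (!any(lat)) return("none")

  # diffuse: > n_tracks/4 consecutive full-width tracks (cyclic run)
  full <- apply(lat, 2, all)
  if (any(full)) {
    runs <- rle(c(full, full))                 # doubled for cyclic runs
    longest <- max(runs$lengths[runs$values])
    longest <- min(longest, n_tracks)
    if (longest > n_tracks / 4) return("diffuse")
  }

  comp <- lattice_components(lat)
  sizes <- tabulate(comp[lat])
  for (k in seq_along(sizes)) {
    segs <- row(lat)[which(comp == k)]
    if (any(segs == 1) && any(segs == n_segments)) return("wedge")
  }
  if (any(sizes >= 3)) return("other_grouping")
  "isolated"
}

# connected components of a [segment, track] logical lattice,
# 4-connectivity, cyclic in the track dimension; 0 where FALSE
lattice_components <- function(lat) {
  ns <- nrow(lat); nt <- ncol(lat)
  comp <- matrix(0L, ns, nt)
  k <- 0L
  for (start in which(lat)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      s <- (p - 1L) %% ns + 1L; t <- (p - 1L) %/% ns + 1L
      nbr <- c(if (s > 1L) p - 1L, if (s < ns) p + 1L,
               (s + (((t - 2L) %% nt)) * ns),       # track - 1, cyclic
               (s + ((t %% nt)) * ns))              # track + 1, cyclic
      for (q in nbr) if (lat[q] && comp[q] == 0L) {
        comp[q] <- k
        queue <- c(queue, q)
      }
    }
  }
  comp
}
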