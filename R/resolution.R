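#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized complex correlation of the Fourier coefficients,
#' `FSC(s) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)`, with a
#' shell width of one Fourier voxel up to Nyquist.
#'
#' @param v1,v2 [density_volume()]s on matching grids
#' @param shell_width shell width in Fourier voxels (default 1)
#' @return object of class `fsc_curve`: data.frame with `freq` (1/A, shell
#'   centers), `fsc`, `n` (voxels per shell); pixel size kept as attribute
#' @export
compute_fsc <- function(v1, v2, shell_width = 1) {
  if (!identical(dim(v1$data), dim(v2$data)) ||
      abs(v1$pixel_size - v2$pixel_size) > 1e-9)
    stop("compute_fsc: grid mismatch")
  d <- dim(v1$data)
  f1 <- fft(v1$data)
  f2 <- fft(v2$data)
  smag <- freq_magnitude_3d(d, v1$pixel_size)
  dv <- shell_width / (d[1] * v1$pixel_size)
  nyq <- 1 / (2 * v1$pixel_size)
  shell <- pmin(as.integer(floor(smag / dv)) + 1L, as.integer(ceiling(nyq / dv)) + 1L)
  keep <- smag <= nyq & smag > 0
  sh <- shell[keep]
  num <- tapply(Re(f1[keep] * Conj(f2[keep])), sh, sum)
  p1 <- tapply(abs(f1[keep])^2, sh, sum)
  p2 <- tapply(abs(f2[keep])^2, sh, sum)
  n <- tapply(rep(1, sum(keep)), sh, sum)
  denom <- sqrt(p1 * p2)
  fsc <- ifelse(denom > 0, num / denom, 1)
  idx <- as.integer(names(num))
  freq <- pmin((idx - 0.5) * dv, nyq)
  out <- data.frame(freq = freq, fsc = pmax(-1, pmin(1, fsc)), n = as.integer(n))
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  attr(out, "pixel_size") <- v1$pixel_size
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the first linearly interpolated crossing of the curve below
#' the threshold (0.143 by default, the gold-standard criterion). If the
#' curve never drops below the threshold the estimate is Nyquist-limited and
#' flagged.
#'
#' @param fsc an `fsc_curve` from [compute_fsc()]
#' @param threshold FSC threshold (default 0.143)
#' @return list with `resolution` (A), `threshold`, `nyquist_limited`,
#'   `crossing_freq` (1/A)
#' @export
resolution_at <- function(fsc, threshold = 0.143) {
  stopifnot(nrow(fsc) > 0)
  px <- attr(fsc, "pixel_size")
  below <- which(fsc$fsc < threshold)
  if (!length(below)) {
    nyq_res <- if (!is.null(px)) 2 * px else 1 / max(fsc$freq)
    return(list(resolution = nyq_res, threshold = threshold,
                nyquist_limited = TRUE, crossing_freq = 1 / nyq_res))
  }
  i <- below[1]
  if (i == 1) {
    s <- fsc$freq[1]
  } else {
    f0 <- fsc$fsc[i - 1]; f1 <- fsc$fsc[i]
    s0 <- fsc$freq[i - 1]; s1 <- fsc$freq[i]
    s <- s0 + (f0 - threshold) / (f0 - f1) * (s1 - s0)
  }
  list(resolution = 1 / s, threshold = threshold,
       nyquist_limited = FALSE, crossing_freq = s)
}

#' B-factor sharpen a volume
#'
#' Fourier amplitudes are scaled by `exp(-B * s^2 / 4)` (so a negative B
#' amplifies high frequencies), followed by a cosine-edge low-pass at
#' `lowpass` so that the amplification peaks near the nominal resolution.
#'
#' @param vol a [density_volume()]
#' @param bfactor B in Angstrom^2 (negative sharpens); -150 is typical for a
#'   ~4.6 A map
#' @param lowpass resolution of the terminating low-pass, A (`Inf` = none)
#' @return sharpened [density_volume()]
#' @export
sharpen <- function(vol, bfactor, lowpass = Inf) {
  d <- dim(vol$data)
  smag <- freq_magnitude_3d(d, vol$pixel_size)
  tf <- exp(-bfactor * smag^2 / 4)
  if (is.finite(lowpass)) {
    dv <- 1 / (d[1] * vol$pixel_size)
    tf <- tf * cosine_lowpass_tf(smag, 1 / lowpass, 1.5 * dv)
  }
  apply_transfer_3d(vol, tf)
}

#' Apply a soft cylindrical mask
#'
#' Voxels beyond `radius + soft_edge` from the z axis are zeroed, with a
#' cosine roll-off across the edge. Used to restrict FSC estimation to
#' radial zones of a helical map (full filament, motor-excluded,
#' interface-only). Idempotent up to the soft edge.
#'
#' @param vol a [density_volume()]
#' @param radius mask radius, A
#' @param soft_edge cosine edge width, A (default 5 voxels)
#' @return masked [density_volume()]
#' @export
cylindrical_mask <- function(vol, radius, soft_edge = 5 * vol$pixel_size) {
  stopifnot(radius > 0)
  d <- dim(vol$data)
  half <- d[1] * vol$pixel_size / 2
  if (radius > sqrt(2) * half) {
    warning("cylindrical_mask: radius exceeds the box; clipping")
    radius <- sqrt(2) * half
  }
  cx <- axis_coords(d[1], vol$pixel_size)
  cy <- axis_coords(d[2], vol$pixel_size)
  r <- sqrt(outer(cx^2, cy^2, `+`))
  m2 <- matrix(1, d[1], d[2])
  m2[r >= radius + soft_edge] <- 0
  band <- r > radius & r < radius + soft_edge
  m2[band] <- 0.5 * (1 + cos(pi * (r[band] - radius) / soft_edge))
  out <- vol$data * array(rep(m2, d[3]), dim = d)
  density_volume(out, vol$pixel_size, vol$origin)
}

#' Cylindrically masked resolution series
#'
#' The local-resolution proxy for helical maps: FSC resolution recomputed
#' after applying identical cylindrical masks of decreasing radius to both
#' half-maps (e.g. full filament, converter/lever excluded, interface only).
#'
#' @param half1,half2 half-map [density_volume()]s
#' @param radii vector of mask radii, A
#' @param threshold FSC threshold (default 0.143)
#' @param soft_edge mask edge width, A
#' @return data.frame with columns `radius`, `resolution`, `nyquist_limited`
#' @export
masked_resolution_series <- function(half1, half2, radii, threshold = 0.143,
                                     soft_edge = 5 * half1$pixel_size) {
  rows <- lapply(radii, function(r) {
    m1 <- cylindrical_mask(half1, r, soft_edge)
    m2 <- cylindrical_mask(half2, r, soft_edge)
    res <- resolution_at(compute_fsc(m1, m2), threshold)
    data.frame(radius = r, resolution = res$resolution,
               nyquist_limited = res$nyquist_limited)
  })
  do.call(rbind, rows)
}
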