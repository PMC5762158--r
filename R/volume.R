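#' Density volume on a cubic voxel grid
#'
#' A 3D scalar field with a physical pixel size. The array is indexed
#' `[x, y, z]` and the helix axis is the z (third) index by convention.
#' Physical coordinates are measured from the box center: voxel `(i, j, k)`
#' sits at `(i - 1 - n/2) * pixel_size` etc., so the center of the grid is
#' the physical origin used by rotations and symmetry operators. The `origin`
#' field records the physical position of the first voxel (header-style
#' corner origin, used by the MRC writer).
#'
#' @param data numeric 3D array (cubic, even edge length recommended for FFTs)
#' @param pixel_size voxel edge, Angstrom (> 0)
#' @param origin physical position of voxel (1,1,1); default centers the box
#' @return object of class `density_volume`
#' @export
density_volume <- function(data, pixel_size, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  d <- dim(data)
  if (is.null(origin)) origin <- -(d / 2) * pixel_size
  structure(list(data = data, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Density volume: %d x %d x %d voxels at %.3f A/px (%.1f A box)\n",
              d[1], d[2], d[3], x$pixel_size, d[1] * x$pixel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

# physical coordinates (A, box-centered) of voxel centers along one axis
axis_coords <- function(n, pixel_size) ((seq_len(n) - 1) - n / 2) * pixel_size

# physical (A) -> fractional voxel index for box-centered coordinates
phys_to_index <- function(x, n, pixel_size) x / pixel_size + n / 2 + 1

#' Trilinear interpolation of a volume at arbitrary points
#'
#' @param vol a [density_volume()]
#' @param points n x 3 matrix of physical coordinates (A, box-centered)
#' @param outside value returned outside the grid (default 0)
#' @return numeric vector of interpolated densities
#' @export
interp_volume <- function(vol, points, outside = 0) {
  d <- dim(vol$data)
  p <- as.matrix(points)
  ix <- phys_to_index(p[, 1], d[1], vol$pixel_size)
  iy <- phys_to_index(p[, 2], d[2], vol$pixel_size)
  iz <- phys_to_index(p[, 3], d[3], vol$pixel_size)
  trilinear_at(vol$data, ix, iy, iz, outside)
}

# trilinear interpolation at fractional 1-based voxel indices
trilinear_at <- function(a, ix, iy, iz, outside = 0) {
  d <- dim(a)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  ok <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1 &
        z0 >= 1 & z0 <= d[3] - 1
  out <- rep(outside, length(ix))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  g <- function(dx, dy, dz) a[cbind(x0 + dx, y0 + dy, z0 + dz)]
  v <-
    g(0L, 0L, 0L) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1L, 0L, 0L) * fx       * (1 - fy) * (1 - fz) +
    g(0L, 1L, 0L) * (1 - fx) * fy       * (1 - fz) +
    g(1L, 1L, 0L) * fx       * fy       * (1 - fz) +
    g(0L, 0L, 1L) * (1 - fx) * (1 - fy) * fz +
    g(1L, 0L, 1L) * fx       * (1 - fy) * fz +
    g(0L, 1L, 1L) * (1 - fx) * fy       * fz +
    g(1L, 1L, 1L) * fx       * fy       * fz
  out[ok] <- v
  out
}

# bilinear interpolation on an image at fractional 1-based indices
bilinear_at <- function(img, ix, iy, outside = 0) {
  d <- dim(img)
  x0 <- floor(ix); y0 <- floor(iy)
  fx <- ix - x0; fy <- iy - y0
  ok <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1
  out <- rep(outside, length(ix))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; fx <- fx[ok]; fy <- fy[ok]
  v <- img[cbind(x0, y0)]         * (1 - fx) * (1 - fy) +
       img[cbind(x0 + 1L, y0)]    * fx       * (1 - fy) +
       img[cbind(x0, y0 + 1L)]    * (1 - fx) * fy +
       img[cbind(x0 + 1L, y0 + 1L)] * fx     * fy
  out[ok] <- v
  out
}

# FFT-friendly frequency coordinates (cycles per A) along one axis
freq_coords <- function(n, pixel_size) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # 0,1,...,n/2,-(n/2-1),...,-1
  k / (n * pixel_size)
}

# |s| grid (1/A) matching the layout of stats::fft output for a 3D array
freq_magnitude_3d <- function(d, pixel_size) {
  fx <- freq_coords(d[1], pixel_size)
  fy <- freq_coords(d[2], pixel_size)
  fz <- freq_coords(d[3], pixel_size)
  sq <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  sqrt(sq)
}

# |s| grid for a 2D image
freq_magnitude_2d <- function(d, pixel_size) {
  fx <- freq_coords(d[1], pixel_size)
  fy <- freq_coords(d[2], pixel_size)
  sqrt(outer(fx^2, fy^2, `+`))
}

# raised-cosine low-pass transfer function on a frequency-magnitude grid:
# 1 below s_cut - half-width, 0 above s_cut + half-width
cosine_lowpass_tf <- function(smag, s_cut, edge_halfwidth) {
  tf <- array(0, dim = dim(smag))
  tf[smag <= s_cut - edge_halfwidth] <- 1
  band <- smag > s_cut - edge_halfwidth & smag < s_cut + edge_halfwidth
  tf[band] <- 0.5 * (1 + cos(pi * (smag[band] - (s_cut - edge_halfwidth)) /
                               (2 * edge_halfwidth)))
  tf
}

#' Low-pass filter a volume with a soft cosine edge
#'
#' Fourier amplitudes beyond `1/lowpass` are attenuated through a raised
#' cosine edge; `lowpass = Inf` returns the volume unchanged.
#'
#' @param vol a [density_volume()]
#' @param lowpass target resolution, Angstrom; must be coarser than 2 px
#' @param edge_width soft-edge full width in reciprocal voxels (default 3)
#' @return filtered [density_volume()]
#' @export
lowpass_volume <- function(vol, lowpass, edge_width = 3) {
  if (!is.finite(lowpass)) return(vol)
  if (lowpass < 2 * vol$pixel_size)
    stop("lowpass_volume: requested resolution finer than Nyquist")
  d <- dim(vol$data)
  smag <- freq_magnitude_3d(d, vol$pixel_size)
  dv <- 1 / (d[1] * vol$pixel_size) # one reciprocal voxel
  tf <- cosine_lowpass_tf(smag, 1 / lowpass, edge_width * dv / 2)
  out <- Re(fft(fft(vol$data) * tf, inverse = TRUE)) / prod(d)
  density_volume(out, vol$pixel_size, vol$origin)
}

# apply an arbitrary real transfer function (same dims as fft layout)
apply_transfer_3d <- function(vol, tf) {
  d <- dim(vol$data)
  out <- Re(fft(fft(vol$data) * tf, inverse = TRUE)) / prod(d)
  density_volume(out, vol$pixel_size, vol$origin)
}

#' Rotate/transform a volume by resampling
#'
#' Returns the volume whose value at x is `vol(T^-1 x)` (the volume moved by
#' transform `t`), using trilinear interpolation about the box center.
#'
#' @param vol a [density_volume()]
#' @param t a [rigid_transform()]
#' @return transformed [density_volume()]
#' @export
resample_volume <- function(vol, t) {
  d <- dim(vol$data)
  cx <- axis_coords(d[1], vol$pixel_size)
  cy <- axis_coords(d[2], vol$pixel_size)
  cz <- axis_coords(d[3], vol$pixel_size)
  pts <- cbind(rep(cx, times = d[2] * d[3]),
               rep(rep(cy, each = d[1]), times = d[3]),
               rep(cz, each = d[1] * d[2]))
  inv <- invert_transform(t)
  src <- transform_points(pts, inv)
  vals <- interp_volume(vol, src)
  density_volume(array(vals, dim = d), vol$pixel_size, vol$origin)
}

# Pearson correlation between two volumes inside a logical mask
masked_correlation <- function(a, b, mask) {
  va <- a$data[mask]; vb <- b$data[mask]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

# logical cylindrical mask (axis = z) with radius (A) and z half-extent (A)
cylinder_logical <- function(d, pixel_size, radius, z_half = Inf) {
  cx <- axis_coords(d[1], pixel_size)
  cy <- axis_coords(d[2], pixel_size)
  cz <- axis_coords(d[3], pixel_size)
  r2 <- outer(cx^2, cy^2, `+`)
  inplane <- r2 <= radius^2
  zok <- abs(cz) <= z_half
  outer(inplane, zok, `&`)
}
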