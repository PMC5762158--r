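#' Pseudo-atomic subunit
#'
#' A coarse stand-in for one actin protomer (optionally carrying a bound
#' myosin motor domain): a handful of isotropic Gaussians with individual
#' scattering weights and widths. At least 3 non-collinear atoms are required
#' so that the subunit orientation (and hence the helical twist) is
#' determinable from its density.
#'
#' @param positions n x 3 matrix of atom positions, Angstrom
#' @param weight scattering weights (recycled)
#' @param width Gaussian sigma per atom, Angstrom (> 0, recycled)
#' @param label free-text label
#' @return object of class `pseudo_atom_subunit`
#' @export
pseudo_atom_subunit <- function(positions, weight = 1, width = 4,
                                label = "subunit") {
  p <- as.matrix(positions)
  stopifnot(ncol(p) == 3L, nrow(p) >= 3L, all(is.finite(p)))
  w <- rep_len(weight, nrow(p))
  s <- rep_len(width, nrow(p))
  stopifnot(all(s > 0), all(w != 0) || TRUE)
  # collinearity check: rank of centered coordinates must be >= 2
  ctr <- sweep(p, 2, colMeans(p))
  if (sum(svd(ctr)$d > 1e-8) < 2)
    stop("pseudo_atom_subunit: atoms are collinear; orientation undetermined")
  structure(list(positions = p, weight = w, width = s, label = label),
            class = "pseudo_atom_subunit")
}

#' Default actin-like decorated subunit
#'
#' A deterministic pseudo-atomic protomer: an inner blob representing the
#' actin subunit (centroid ~12 A off-axis) and, if `decorated`, an outer
#' blob representing a bound motor domain reaching ~45 A from the axis.
#' Deliberately azimuthally asymmetric so the helical twist is identifiable.
#'
#' @param decorated add the motor-domain blob (default TRUE)
#' @return a [pseudo_atom_subunit()]
#' @export
default_subunit <- function(decorated = TRUE) {
  actin <- rbind(
    c(10,  3,  6), c(14, -4,  2), c( 8,  8, -5), c(16,  2, -8),
    c( 6, -7, -2), c(12,  6, 10), c(18, -2,  7), c( 9,  0,  0))
  w <- c(1, 1, 0.8, 0.9, 0.7, 0.8, 0.6, 1.2)
  s <- c(5, 5, 4.5, 4.5, 4, 4.5, 4, 6)
  if (decorated) {
    # motor domain slanting toward the filament minus end as it extends
    # radially outward: the arrowhead pattern of decorated actin, which
    # makes filament polarity identifiable in projections
    motor <- rbind(c(26, 6, -2), c(34, 0, -9), c(42, 4, -16),
                   c(30, 11, -12), c(38, -6, -20))
    actin <- rbind(actin, motor)
    w <- c(w, c(1.2, 1.1, 0.9, 0.8, 0.8))
    s <- c(s, c(6, 6, 5.5, 5, 5))
  }
  pseudo_atom_subunit(actin, w, s,
                      label = if (decorated) "actin+motor" else "actin")
}

#' Build a helical filament from a subunit
#'
#' Subunit `k` (k = 0..n-1) is placed by the helical symmetry operator; the
#' assembly is then recentred along z so the filament midpoint sits at the
#' origin. Centroid z of subunit k minus subunit 0 equals `k * rise` by
#' construction.
#'
#' @param subunit a [pseudo_atom_subunit()]
#' @param sym a [helical_symmetry()]
#' @param n_subunits number of asymmetric units (>= 1)
#' @return list with `positions` (n_total x 3), `weight`, `width`,
#'   `subunit_index` (0-based), `sym`, `n_subunits`
#' @export
build_filament <- function(subunit, sym, n_subunits) {
  stopifnot(inherits(subunit, "pseudo_atom_subunit"),
            inherits(sym, "helical_symmetry"))
  if (n_subunits < 1) stop("build_filament: n_subunits must be >= 1")
  n_subunits <- as.integer(n_subunits)
  parts <- lapply(0:(n_subunits - 1L), function(k)
    transform_points(subunit$positions, symmetry_operator(sym, k)))
  pos <- do.call(rbind, parts)
  pos[, 3] <- pos[, 3] - (n_subunits - 1L) * sym$rise / 2
  list(positions = pos,
       weight = rep(subunit$weight, n_subunits),
       width = rep(subunit$width, n_subunits),
       subunit_index = rep(0:(n_subunits - 1L), each = nrow(subunit$positions)),
       sym = sym, n_subunits = n_subunits)
}

#' Rasterize pseudo-atoms into a density volume
#'
#' Sum of isotropic Gaussians, amplitude proportional to weight. The grid
#' integral equals `sum(weight * (2*pi*width^2)^(3/2)) / pixel_size^3` up to
#' truncation (Gaussians are evaluated within 4 sigma).
#'
#' @param atoms list with `positions`, `weight`, `width` (as from
#'   [build_filament()]) or a [pseudo_atom_subunit()]
#' @param box cubic box edge, voxels
#' @param pixel_size Angstrom per voxel
#' @param clip drop atoms whose centers fall outside the (centered) box
#'   instead of raising an error; intended for filaments longer than the box
#' @return a [density_volume()]
#' @export
rasterize <- function(atoms, box, pixel_size, clip = FALSE) {
  pos <- as.matrix(atoms$positions)
  w <- atoms$weight
  sg <- atoms$width
  half <- box * pixel_size / 2
  inside <- apply(abs(pos) < half, 1, all)
  if (!all(inside)) {
    if (!clip) stop("rasterize: atoms outside the box (use clip = TRUE for long filaments)")
    pos <- pos[inside, , drop = FALSE]; w <- w[inside]; sg <- sg[inside]
  }
  a <- array(0, dim = c(box, box, box))
  cx <- axis_coords(box, pixel_size)
  for (i in seq_len(nrow(pos))) {
    s <- sg[i]
    reach <- 4 * s
    ix <- which(abs(cx - pos[i, 1]) <= reach)
    iy <- which(abs(cx - pos[i, 2]) <= reach)
    iz <- which(abs(cx - pos[i, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(cx[ix] - pos[i, 1])^2 / (2 * s^2))
    gy <- exp(-(cx[iy] - pos[i, 2])^2 / (2 * s^2))
    gz <- exp(-(cx[iz] - pos[i, 3])^2 / (2 * s^2))
    blk <- (w[i] * outer(outer(gx, gy), gz))
    a[ix, iy, iz] <- a[ix, iy, iz] + blk
  }
  density_volume(a, pixel_size)
}

#' Microscope contrast-transfer-function parameters
#'
#' @param voltage accelerating voltage, kV
#' @param defocus underfocus, micrometres (positive = underfocus)
#' @param spherical_aberration Cs, mm
#' @param amplitude_contrast fraction in 0..1
#' @param pixel_size Angstrom per pixel
#' @return object of class `ctf_params`
#' @export
ctf_params <- function(voltage = 200, defocus = 2.25,
                       spherical_aberration = 2.0,
                       amplitude_contrast = 0.07, pixel_size = 2.5) {
  stopifnot(pixel_size > 0, amplitude_contrast >= 0, amplitude_contrast <= 1,
            voltage > 0)
  structure(list(voltage = voltage, defocus = defocus,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#' @param voltage_kv accelerating voltage in kV
#' @return wavelength in Angstrom
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Contrast transfer function value
#'
#' Standard phase-contrast CTF,
#' `-(sqrt(1 - w^2) * sin(chi) + w * cos(chi))` with phase
#' `chi(s) = pi * lambda * dz * s^2 - pi/2 * Cs * lambda^3 * s^4`
#' (underfocus positive). Bounded in \[-1, 1\]; at s = 0 the value is `-w`.
#'
#' @param ctf a [ctf_params()]
#' @param s spatial frequency, 1/Angstrom (vectorized, >= 0)
#' @return CTF value(s)
#' @export
ctf_value <- function(ctf, s) {
  lambda <- electron_wavelength(ctf$voltage)
  dz <- ctf$defocus * 1e4        # um -> A
  cs <- ctf$spherical_aberration * 1e7 # mm -> A
  chi <- pi * lambda * dz * s^2 - (pi / 2) * cs * lambda^3 * s^4
  w <- ctf$amplitude_contrast
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

# CTF evaluated on the 2D Fourier grid of a box x box image
ctf_grid <- function(ctf, box, pixel_size) {
  smag <- freq_magnitude_2d(c(box, box), pixel_size)
  matrix(ctf_value(ctf, as.vector(smag)), box, box)
}

# apply a transfer function (e.g. CTF or its sign) to an image
apply_transfer_2d <- function(img, tf) {
  Re(fft(fft(img) * tf, inverse = TRUE)) / length(img)
}

#' Project a density volume
#'
#' Line integrals of the rotated volume along the viewing axis. The volume
#' is rotated by the ZYZ Euler matrix `Rz(psi) Ry(theta) Rz(phi)` and
#' integrated along lab z; `phi` is azimuth about the helix axis, `theta`
#' the out-of-plane angle (90 deg puts the axis in the image plane), `psi`
#' the in-plane rotation. The image sum equals the volume sum times the
#' pixel size (line integrals carry units of density x Angstrom).
#'
#' @param vol a [density_volume()]
#' @param orientation numeric (phi, theta, psi), degrees
#' @param shift in-plane (x, y) shift of the projected image, Angstrom
#' @return `box x box` numeric matrix
#' @export
project_volume <- function(vol, orientation = c(0, 0, 0), shift = c(0, 0)) {
  stopifnot(all(is.finite(orientation)), all(is.finite(shift)))
  d <- dim(vol$data)
  R <- euler_matrix(orientation[1], orientation[2], orientation[3])
  cx <- axis_coords(d[1], vol$pixel_size)
  cz <- axis_coords(d[3], vol$pixel_size)
  # view-grid points (u - sx, v - sy, w), mapped back into the volume by R^T
  u <- rep(cx - shift[1], times = d[2])
  v <- rep(cx - shift[2], each = d[1])
  img <- matrix(0, d[1], d[2])
  Rt <- t(R)
  for (k in seq_along(cz)) {
    src <- cbind(u, v, cz[k]) %*% t(Rt)
    img <- img + matrix(interp_volume(vol, src), d[1], d[2])
  }
  img * vol$pixel_size
}

# analytic projection of Gaussian atoms onto an image grid:
# atoms already expressed in view coordinates (x, y = image, z = viewing axis)
project_atoms_2d <- function(pos_xy, weight, width, box, pixel_size) {
  cx <- axis_coords(box, pixel_size)
  img <- matrix(0, box, box)
  for (i in seq_len(nrow(pos_xy))) {
    s <- width[i]
    reach <- 4 * s
    ix <- which(abs(cx - pos_xy[i, 1]) <= reach)
    iy <- which(abs(cx - pos_xy[i, 2]) <= reach)
    if (!length(ix) || !length(iy)) next
    gx <- exp(-(cx[ix] - pos_xy[i, 1])^2 / (2 * s^2))
    gy <- exp(-(cx[iy] - pos_xy[i, 2])^2 / (2 * s^2))
    # integral of the 3D Gaussian along the viewing axis: w * sqrt(2 pi) s
    img[ix, iy] <- img[ix, iy] + weight[i] * sqrt(2 * pi) * s * outer(gx, gy)
  }
  img
}

#' Rotate an image in-plane
#' @param img square matrix
#' @param deg rotation angle, degrees (right-handed about the viewing axis)
#' @return rotated image (bilinear interpolation, zeros outside)
#' @export
rotate_image <- function(img, deg) {
  d <- dim(img)
  c1 <- (seq_len(d[1]) - 1) - d[1] / 2
  c2 <- (seq_len(d[2]) - 1) - d[2] / 2
  r <- -deg * pi / 180 # sample source = inverse rotation
  u <- rep(c1, times = d[2]); v <- rep(c2, each = d[1])
  sx <- cos(r) * u - sin(r) * v + d[1] / 2 + 1
  sy <- sin(r) * u + cos(r) * v + d[2] / 2 + 1
  matrix(bilinear_at(img, sx, sy), d[1], d[2])
}

#' Shift an image
#' @param img matrix
#' @param dx,dy shift in pixels (the content moves by +dx, +dy)
#' @return shifted image (bilinear, zeros outside)
#' @export
shift_image <- function(img, dx, dy) {
  d <- dim(img)
  sx <- rep(seq_len(d[1]), times = d[2]) - dx
  sy <- rep(seq_len(d[2]), each = d[1]) - dy
  matrix(bilinear_at(img, sx, sy), d[1], d[2])
}

#' Normalize a segment image against a background annulus
#'
#' Affine rescaling so the background annulus has mean 0 and standard
#' deviation 1. Idempotent, and invariant to affine transforms of the input.
#'
#' @param image numeric matrix
#' @param annulus logical matrix of background pixels (same dim)
#' @return normalized image
#' @export
normalize_segment <- function(image, annulus) {
  stopifnot(identical(dim(image), dim(annulus)), any(annulus))
  bg <- image[annulus]
  s <- sd(bg)
  if (s == 0) stop("normalize_segment: zero-variance background")
  (image - mean(bg)) / s
}

#' Annulus mask helper
#' @param box image edge in pixels
#' @param inner,outer annulus radii in pixels
#' @return logical `box x box` matrix
#' @export
annulus_mask <- function(box, inner, outer = box / 2) {
  c1 <- (seq_len(box) - 1) - box / 2
  r <- sqrt(outer(c1^2, c1^2, `+`))
  r >= inner & r <= outer
}

#' Number of windowed segments along a filament
#'
#' `floor((projected_length - box_A) / step) + 1`, zero when the filament is
#' shorter than one box.
#'
#' @param length_proj projected filament length, Angstrom
#' @param box_a box edge, Angstrom
#' @param step window step, Angstrom
#' @return integer segment count
#' @export
segment_count <- function(length_proj, box_a, step) {
  if (length_proj < box_a) return(0L)
  as.integer(floor((length_proj - box_a) / step) + 1)
}

#' Simulate windowed filament segments with ground truth
#'
#' Generates pseudo-atomic filaments, projects them at random orientations
#' (azimuth uniform, out-of-plane angle uniform in `theta_range`, in-plane
#' angle uniform, random sub-pixel shifts), applies the CTF by Fourier
#' multiplication, adds white Gaussian noise at the target SNR (signal
#' variance over noise variance inside the filament support), and windows
#' overlapping segments every `step` Angstrom along the filament axis.
#' Each segment spans several protomers; `asu_per_segment` records the
#' bookkeeping ratio of asymmetric units per segment (3 by default, the
#' windowing convention for actin).
#'
#' The ground-truth orientation of every segment is expressed relative to a
#' one-box helical reference volume: stepping along the filament by one rise
#' equals an azimuth change of one twist, so the recorded `phi` folds the
#' axial position into the reference frame and the sub-rise remainder
#' appears as an in-plane shift along the projected axis.
#'
#' @param subunit a [pseudo_atom_subunit()]
#' @param sym a [helical_symmetry()]
#' @param ctf a [ctf_params()] (its `pixel_size` is used for the images);
#'   `NULL` disables CTF modulation
#' @param box segment box edge, pixels
#' @param step windowing step, Angstrom
#' @param n_filaments number of filaments
#' @param snr target signal-to-noise ratio; `Inf` for noise-free
#' @param seed integer RNG seed (bit-reproducible output)
#' @param n_subunits subunits per filament (default 24, several boxes long)
#' @param pixel_size Angstrom per pixel (overrides `ctf$pixel_size` if given)
#' @param theta_range out-of-plane angle range, degrees
#' @param shift_sd sd of random in-plane jitter, Angstrom
#' @param asu_per_segment asymmetric units per segment (bookkeeping)
#' @return list with `stack` (a `segment_stack`) and `truth` (data.frame of
#'   per-segment true phi/theta/psi/shifts and the generating symmetry)
#' @export
simulate_segments <- function(subunit, sym, ctf = ctf_params(), box = 64,
                              step = 81, n_filaments = 20, snr = 5,
                              seed = 1, n_subunits = 24,
                              pixel_size = if (is.null(ctf)) 2.5 else ctf$pixel_size,
                              theta_range = c(84, 96), shift_sd = 1.0,
                              asu_per_segment = 3L) {
  stopifnot(step > 0, snr > 0, n_filaments >= 1)
  set.seed(as.integer(seed))
  box_a <- box * pixel_size
  fil <- build_filament(subunit, sym, n_subunits)
  fil_len <- (n_subunits - 1) * sym$rise
  images <- list(); meta <- list(); truth <- list()
  n_tot <- 0L
  for (f in seq_len(n_filaments)) {
    phi0 <- runif(1, 0, 360)
    theta <- runif(1, theta_range[1], theta_range[2])
    psi <- runif(1, 0, 360)
    defocus <- if (is.null(ctf)) NA_real_ else runif(1, 1.5, 3.0)
    ctf_f <- if (is.null(ctf)) NULL else
      ctf_params(ctf$voltage, defocus, ctf$spherical_aberration,
                 ctf$amplitude_contrast, pixel_size)
    R <- euler_matrix(phi0, theta, psi)
    rot <- fil$positions %*% t(R)
    # projected axis direction in the image plane
    axis_img <- as.numeric(R %*% c(0, 0, 1))[1:2]
    sin_th <- sqrt(sum(axis_img^2)) # = |sin(theta)| for this geometry
    u_axis <- axis_img / sin_th
    l_proj <- fil_len * sin_th
    n_seg <- segment_count(l_proj, box_a, step)
    if (n_seg < 1)
      stop("simulate_segments: filament projects shorter than one box")
    # segment centers along the projected axis, filament centered at 0
    d_proj <- -l_proj / 2 + box_a / 2 + (seq_len(n_seg) - 1) * step
    for (i in seq_len(n_seg)) {
      jit <- rnorm(2, 0, shift_sd)
      # move the filament so segment center lands at the image center
      offset <- -d_proj[i] * u_axis + jit
      pos_xy <- cbind(rot[, 1] + offset[1], rot[, 2] + offset[2])
      keep <- abs(pos_xy[, 1]) < box_a / 2 + 4 * max(fil$width) &
              abs(pos_xy[, 2]) < box_a / 2 + 4 * max(fil$width)
      img <- project_atoms_2d(pos_xy[keep, , drop = FALSE], fil$weight[keep],
                              fil$width[keep], box, pixel_size)
      if (!is.null(ctf_f))
        img <- apply_transfer_2d(img, ctf_grid(ctf_f, box, pixel_size))
      if (is.finite(snr)) {
        mask <- abs(img) > 0.05 * max(abs(img))
        sig_var <- stats::var(img[mask])
        img <- img + matrix(rnorm(box * box, 0, sqrt(sig_var / snr)), box, box)
      }
      # ground truth relative to a one-box helical reference:
      # axial offset of the segment center along the 3D filament axis
      a_off <- d_proj[i] / sin_th
      m <- round(a_off / sym$rise)
      delta <- a_off - m * sym$rise # residual axial shift, A
      phi_true <- wrap_twist(phi0 + m * sym$twist)
      shift_true <- -delta * sin_th * u_axis + jit
      n_tot <- n_tot + 1L
      images[[n_tot]] <- img
      meta[[n_tot]] <- data.frame(
        segment = n_tot, filament = f, index = i, defocus = defocus,
        half_set = NA_integer_, included = TRUE)
      truth[[n_tot]] <- data.frame(
        segment = n_tot, filament = f, index = i,
        phi = phi_true, theta = theta, psi = psi,
        shift_x = shift_true[1], shift_y = shift_true[2])
    }
  }
  arr <- array(unlist(images), dim = c(box, box, n_tot))
  stack <- structure(list(images = arr,
                          meta = do.call(rbind, meta),
                          pixel_size = pixel_size, box = box, step = step,
                          ctf = ctf, asu_per_segment = asu_per_segment,
                          seed = seed),
                     class = "segment_stack")
  truth <- do.call(rbind, truth)
  attr(truth, "sym") <- sym
  attr(truth, "seed") <- seed
  list(stack = stack, truth = truth)
}

#' @export
print.segment_stack <- function(x, ...) {
  cat(sprintf("Segment stack: %d segments, %d px boxes at %.2f A/px, step %.1f A\n",
              dim(x$images)[3], x$box, x$pixel_size, x$step))
  cat(sprintf("  %d filament(s); %d asymmetric units per segment\n",
              length(unique(x$meta$filament)), x$asu_per_segment))
  invisible(x)
}

#' Reference projection of a helical volume at a ground-truth record
#'
#' Reprojects a one-box reference volume at a segment's true orientation and
#' shift; used for self-consistency checks of the simulator and for
#' projection matching oracles.
#'
#' @param vol one-box reference [density_volume()]
#' @param rec single-row data.frame with phi/theta/psi/shift_x/shift_y
#' @return projection image matrix
#' @export
reproject_truth <- function(vol, rec) {
  project_volume(vol, c(rec$phi, rec$theta, rec$psi),
                 c(rec$shift_x, rec$shift_y))
}
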