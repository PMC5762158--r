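#' Refinement configuration for helical reconstruction
#'
#' Bundles every tunable of the iterative refinement: angular and shift
#' search grids, helical-symmetry search bounds, the cross-correlation
#' exclusion threshold (1.5 sigma by default), reference filtering policy
#' (the initial model is filtered to 35 A; between iterations references are
#' filtered at the half-map FSC 0.143 crossing; the polishing pass uses a
#' strict 10 A filter), and the RNG seed controlling half-set assignment.
#'
#' @param n_iterations refinement iterations of the half-set loop
#' @param phi_step azimuth grid step, degrees
#' @param theta_range out-of-plane search range, degrees
#' @param theta_step out-of-plane grid step, degrees
#' @param psi_step in-plane grid step, degrees
#' @param shift_range in-plane shift search half-range, Angstrom
#' @param shift_step shift grid step, Angstrom (`NULL` = one pixel)
#' @param sym_bounds helical search half-widths `c(rise, twist)` (A, deg)
#' @param sym_grid coarse search steps `c(rise, twist)` (A, deg)
#' @param exclusion_sigma cross-correlation cutoff in standard deviations
#' @param exclusion_after iteration after which the cutoff is applied once
#' @param initial_lowpass initial-model low-pass, A
#' @param polish_lowpass strict low-pass of the polishing pass, A
#' @param ctf_policy `"phase_flip"` or `"none"`
#' @param half_assignment `"segment"` (random per segment, as in the
#'   original protocol) or `"filament"` (independence-preserving alternative)
#' @param seed integer RNG seed
#' @return object of class `refinement_config`
#' @export
refinement_config <- function(n_iterations = 3, phi_step = 6,
                              theta_range = c(84, 96), theta_step = 6,
                              psi_step = 6, shift_range = 5,
                              shift_step = NULL,
                              sym_bounds = c(1.5, 3),
                              sym_grid = c(0.1, 0.25),
                              exclusion_sigma = 1.5, exclusion_after = 2,
                              initial_lowpass = 35, polish_lowpass = 10,
                              ctf_policy = c("phase_flip", "none"),
                              half_assignment = c("segment", "filament"),
                              seed = 1) {
  stopifnot(n_iterations >= 1, phi_step > 0, theta_step > 0, psi_step > 0,
            shift_range >= 0, exclusion_sigma > 0, all(sym_grid > 0))
  structure(list(n_iterations = as.integer(n_iterations), phi_step = phi_step,
                 theta_range = theta_range, theta_step = theta_step,
                 psi_step = psi_step, shift_range = shift_range,
                 shift_step = shift_step, sym_bounds = sym_bounds,
                 sym_grid = sym_grid, exclusion_sigma = exclusion_sigma,
                 exclusion_after = as.integer(exclusion_after),
                 initial_lowpass = initial_lowpass,
                 polish_lowpass = polish_lowpass,
                 ctf_policy = match.arg(ctf_policy),
                 half_assignment = match.arg(half_assignment),
                 seed = as.integer(seed)),
            class = "refinement_config")
}

#' Low-pass filtered initial model
#'
#' The reference for the first refinement round: an existing (actin)
#' reconstruction filtered to a coarse resolution (35 A by default) so that
#' high-resolution features cannot bias the alignment.
#'
#' @param volume a [density_volume()]
#' @param lowpass filter resolution, A (must be coarser than 2 px)
#' @return filtered [density_volume()]
#' @export
make_initial_model <- function(volume, lowpass = 35) {
  lowpass_volume(volume, lowpass)
}

#' Reference projections of a volume over an angular grid
#'
#' @param volume reference [density_volume()]
#' @param config a [refinement_config()] (phi/theta grids)
#' @return object of class `reference_projections` holding the projection
#'   images, their (phi, theta) angles, and a cache for in-plane-rotated
#'   expansions used by the aligner
#' @export
make_reference_projections <- function(volume, config) {
  phis <- seq(0, 360 - config$phi_step, by = config$phi_step)
  thetas <- seq(config$theta_range[1], config$theta_range[2],
                by = config$theta_step)
  ang <- expand.grid(phi = phis, theta = thetas)
  d <- dim(volume$data)
  imgs <- array(0, dim = c(d[1], d[2], nrow(ang)))
  for (i in seq_len(nrow(ang)))
    imgs[, , i] <- project_volume(volume, c(ang$phi[i], ang$theta[i], 0))
  obj <- new.env(parent = emptyenv())
  obj$images <- imgs
  obj$angles <- ang
  obj$pixel_size <- volume$pixel_size
  obj$cache <- NULL
  class(obj) <- "reference_projections"
  obj
}

# normalized reference matrix (one row per (phi, theta) projection),
# cached on the reference object
reference_matrix <- function(refs) {
  if (!is.null(refs$cache)) return(refs$cache)
  d <- dim(refs$images)
  mat <- matrix(0, d[3], d[1] * d[2])
  for (i in seq_len(d[3])) {
    v <- as.numeric(refs$images[, , i])
    v <- v - mean(v)
    nrm <- sqrt(sum(v^2))
    mat[i, ] <- if (nrm > 0) v / nrm else v
  }
  refs$cache <- mat
  mat
}

# integer-pixel shift of an image (content moves by +dx, +dy), zero-padded
shift_image_int <- function(img, dx, dy) {
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  if (!length(xs) || !length(ys)) return(out)
  out[xs, ys] <- img[xs - dx, ys - dy]
  out
}

shift_grid_px <- function(config, pixel_size) {
  step_px <- if (is.null(config$shift_step)) 1 else
    max(0.25, config$shift_step / pixel_size)
  r <- floor(config$shift_range / pixel_size / step_px) * step_px
  s <- seq(-r, r, by = step_px)
  expand.grid(dx = s, dy = s)
}

#' Align one segment against reference projections
#'
#' Exhaustive grid search over reference (phi, theta), in-plane rotation psi
#' and integer-pixel shifts, maximizing the normalized cross-correlation.
#' Deterministic: ties resolve to the lowest grid index.
#'
#' @param segment image matrix
#' @param reference_projections from [make_reference_projections()]
#' @param config a [refinement_config()]
#' @return one-row data.frame: phi, theta, psi, shift_x, shift_y (A),
#'   cross_correlation
#' @export
align_segment <- function(segment, reference_projections, config) {
  rmat <- reference_matrix(reference_projections)
  if (nrow(rmat) == 0) stop("align_segment: empty reference set")
  px <- reference_projections$pixel_size
  sg <- shift_grid_px(config, px)
  psis <- seq(0, 360 - config$psi_step, by = config$psi_step)
  d <- dim(segment)
  ncand <- length(psis) * nrow(sg)
  cand <- matrix(0, d[1] * d[2], ncand)
  tab_psi <- integer(ncand); tab_shift <- integer(ncand)
  col <- 0L
  for (ip in seq_along(psis)) {
    # undo the candidate in-plane rotation of the segment
    rot <- if (psis[ip] == 0) segment else rotate_image(segment, -psis[ip])
    for (j in seq_len(nrow(sg))) {
      col <- col + 1L
      v <- if (sg$dx[j] == round(sg$dx[j]) && sg$dy[j] == round(sg$dy[j]))
        as.numeric(shift_image_int(rot, sg$dx[j], sg$dy[j]))
      else as.numeric(shift_image(rot, sg$dx[j], sg$dy[j]))
      v <- v - mean(v)
      nrm <- sqrt(sum(v^2))
      cand[, col] <- if (nrm > 0) v / nrm else v
      tab_psi[col] <- ip; tab_shift[col] <- j
    }
  }
  cc <- rmat %*% cand # n_refs x n_candidates
  best <- arrayInd(which.max(cc), dim(cc))
  i <- best[1]; j <- best[2]
  psi <- psis[tab_psi[j]]
  # candidate applied shift s'' to the de-rotated segment; the segment's
  # own shift is -R(psi) s''
  spp <- c(sg$dx[tab_shift[j]], sg$dy[tab_shift[j]]) * px
  rp <- psi * pi / 180
  shift <- -c(cos(rp) * spp[1] - sin(rp) * spp[2],
              sin(rp) * spp[1] + cos(rp) * spp[2])
  data.frame(phi = reference_projections$angles$phi[i],
             theta = reference_projections$angles$theta[i],
             psi = psi, shift_x = shift[1], shift_y = shift[2],
             cross_correlation = cc[i, j])
}

# align every included segment of a stack; returns the params data.frame
align_stack <- function(stack, refs, config, subset = NULL) {
  n <- dim(stack$images)[3]
  idx <- if (is.null(subset)) seq_len(n) else subset
  rows <- vector("list", length(idx))
  for (ii in seq_along(idx)) {
    s <- idx[ii]
    rows[[ii]] <- cbind(segment = s,
                        align_segment(stack$images[, , s], refs, config))
  }
  do.call(rbind, rows)
}

#' Phase-flip a segment stack
#'
#' Multiplies each segment by the sign of its CTF in Fourier space (the
#' phase-flipping CTF correction used throughout the refinement).
#'
#' @param stack a `segment_stack`
#' @return stack with corrected images
#' @export
phase_flip_stack <- function(stack) {
  if (is.null(stack$ctf)) return(stack)
  n <- dim(stack$images)[3]
  for (s in seq_len(n)) {
    df <- stack$meta$defocus[s]
    if (!is.finite(df)) next
    ctf_s <- ctf_params(stack$ctf$voltage, df, stack$ctf$spherical_aberration,
                        stack$ctf$amplitude_contrast, stack$pixel_size)
    tf <- sign(ctf_grid(ctf_s, stack$box, stack$pixel_size))
    tf[tf == 0] <- 1
    stack$images[, , s] <- apply_transfer_2d(stack$images[, , s], tf)
  }
  stack$phase_flipped <- TRUE
  stack
}

#' Backproject aligned segments into a volume
#'
#' Filtered real-space backprojection: each included segment is ramp-filtered
#' along the in-plane direction perpendicular to the projected helix axis
#' (the single-tilt-axis geometry of filaments lying in the ice plane), then
#' smeared into the volume at its assigned orientation. Views are weighted
#' by their azimuthal Voronoi gap (the correct filtered-backprojection
#' weight for non-uniform view angles; uniform weighting of clustered random
#' azimuths systematically distorts the reconstruction). Linear in the input
#' images.
#'
#' @param stack a `segment_stack`
#' @param params alignment data.frame (`segment`, phi, theta, psi, shift_x,
#'   shift_y); only segments flagged included in `stack$meta` are used
#' @param ctf_policy retained for the record; phase flipping is applied to
#'   the stack before reconstruction (see [phase_flip_stack()])
#' @return a [density_volume()]
#' @export
backproject <- function(stack, params, ctf_policy = "phase_flip") {
  inc <- stack$meta$included[params$segment]
  use <- params[inc, , drop = FALSE]
  if (nrow(use) == 0) stop("backproject: no included segments")
  box <- stack$box
  px <- stack$pixel_size
  d3 <- c(box, box, box)
  cx <- axis_coords(box, px)
  pts <- cbind(rep(cx, times = box * box),
               rep(rep(cx, each = box), times = box),
               rep(cx, each = box * box))
  acc <- numeric(box^3)
  fx <- freq_coords(box, px)
  # azimuthal Voronoi weights (view azimuth modulo 180; capped at 4x mean)
  aphi <- use$phi %% 180
  o <- order(aphi)
  nv <- length(aphi)
  w <- numeric(nv)
  if (nv > 1) {
    gaps <- diff(c(aphi[o], aphi[o][1] + 180))
    w[o] <- (gaps + c(gaps[nv], gaps[-nv])) / 2
    w <- pmin(w, 4 * mean(w))
    w <- w / mean(w)
  } else w <- 1
  for (r in seq_len(nrow(use))) {
    R <- euler_matrix(use$phi[r], use$theta[r], use$psi[r])
    img <- stack$images[, , use$segment[r]]
    # ramp filter perpendicular to the projected axis direction
    ax <- as.numeric(R %*% c(0, 0, 1))[1:2]
    ax <- ax / max(sqrt(sum(ax^2)), 1e-9)
    nperp <- c(-ax[2], ax[1])
    ramp <- abs(outer(fx * nperp[1], fx * nperp[2], `+`))
    img_f <- Re(fft(fft(img) * ramp, inverse = TRUE)) / length(img)
    q <- pts %*% t(R)
    iu <- (q[, 1] + use$shift_x[r]) / px + box / 2 + 1
    iv <- (q[, 2] + use$shift_y[r]) / px + box / 2 + 1
    acc <- acc + w[r] * bilinear_at(img_f, iu, iv)
  }
  scale <- pi / nrow(use) * px
  density_volume(array(acc * scale, dim = d3), px)
}

#' Symmetrize a volume under helical symmetry
#'
#' Projection onto the helically symmetric subspace via the canonical
#' asymmetric unit: every voxel is first folded into the canonical rise
#' interval (`z` within half a rise of the origin) by the nearest integer
#' symmetry operator, and its value is replaced by the mean of the volume
#' over all symmetry mates `operator(k)` of that canonical position whose
#' axial offset stays within `z_extent / 2` and inside the grid. The output
#' is invariant under `operator(+/-1)` and re-symmetrization reproduces it
#' up to trilinear interpolation error.
#'
#' @param volume a [density_volume()]
#' @param sym a [helical_symmetry()]
#' @param z_extent axial extent used for mates, A (default: full box)
#' @return symmetrized [density_volume()]
#' @export
symmetrize <- function(volume, sym, z_extent = NULL) {
  d <- dim(volume$data)
  box_a <- d[3] * volume$pixel_size
  if (is.null(z_extent)) z_extent <- box_a
  if (sym$rise < volume$pixel_size)
    stop("symmetrize: rise smaller than one voxel")
  kmax <- floor((z_extent / 2) / sym$rise)
  cx <- axis_coords(d[1], volume$pixel_size)
  cy <- axis_coords(d[2], volume$pixel_size)
  cz <- axis_coords(d[3], volume$pixel_size)
  pts <- cbind(rep(cx, times = d[2] * d[3]),
               rep(rep(cy, each = d[1]), times = d[3]),
               rep(cz, each = d[1] * d[2]))
  # fold each voxel into the canonical rise interval
  m <- round(pts[, 3] / sym$rise)
  th <- -m * sym$twist * pi / 180
  ct <- cos(th); st <- sin(th)
  canon <- cbind(ct * pts[, 1] - st * pts[, 2],
                 st * pts[, 1] + ct * pts[, 2],
                 pts[, 3] - m * sym$rise)
  accum <- numeric(nrow(pts))
  count <- numeric(nrow(pts))
  half <- c(d[1], d[2], d[3]) * volume$pixel_size / 2
  px <- volume$pixel_size
  taper <- 2 * px # soft in-grid weight keeps the average continuous
  edgew <- function(v, h) pmin(pmax((h - px - abs(v)) / taper, 0), 1)
  for (k in -kmax:kmax) {
    src <- transform_points(canon, symmetry_operator(sym, k))
    w <- edgew(src[, 1], half[1]) * edgew(src[, 2], half[2]) *
         edgew(src[, 3], half[3])
    vals <- interp_volume(volume, src)
    accum <- accum + w * vals
    count <- count + w
  }
  out <- ifelse(count > 0, accum / pmax(count, 1e-12), 0)
  density_volume(array(out, dim = d), volume$pixel_size, volume$origin)
}

# decimate a volume by 2x2x2 averaging (for the coarse symmetry search)
bin_volume <- function(vol, factor = 2L) {
  d <- dim(vol$data)
  nd <- d %/% factor
  a <- vol$data[1:(nd[1] * factor), 1:(nd[2] * factor), 1:(nd[3] * factor)]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  density_volume(out, vol$pixel_size * factor)
}

# self-correlation objective: correlation between the volume displaced by
# the half-operators (+1/2 and -1/2 of the screw), inside a central
# cylindrical mask. Using half-operators interpolates both fields with the
# same fractional voxel offsets, cancelling the interpolation-smoothing
# asymmetry that otherwise attracts the optimum to integer-voxel rises.
helical_self_correlation <- function(vol, rise, twist, mask_pts, vals0 = NULL) {
  tp <- rigid_transform(rot_z(twist / 2), c(0, 0, rise / 2))
  v1 <- interp_volume(vol, transform_points(mask_pts, invert_transform(tp)))
  v2 <- interp_volume(vol, transform_points(mask_pts, tp))
  if (sd(v1) == 0 || sd(v2) == 0) return(-Inf)
  cor(v1, v2)
}

golden_section <- function(f, lo, hi, tol, maxit = 40) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in seq_len(maxit)) {
    if (b - a < tol) break
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

#' Search helical symmetry parameters of a volume
#'
#' Finds the (rise, twist) maximizing the masked real-space correlation
#' between the volume and its copy transformed by one helical operator — the
#' self-consistency objective of classical helical parameter search. A
#' coarse grid on a 2x-binned copy of the volume is followed by alternating
#' golden-section refinement of rise and twist on the full grid.
#'
#' @param volume a [density_volume()]
#' @param init starting [helical_symmetry()]
#' @param bounds search half-widths `c(rise_A, twist_deg)` around `init`
#' @param grid coarse grid steps `c(rise_A, twist_deg)`
#' @param final_tol refinement tolerances `c(rise_A, twist_deg)`
#' @param mask_radius_frac cylindrical mask radius as a fraction of the
#'   half-box (default 0.8)
#' @param z_frac central z fraction of the mask (default 0.6)
#' @return a [helical_symmetry()] with attributes `objective` (correlation
#'   at the optimum) and `trace` (coarse-grid objective table)
#' @export
search_symmetry <- function(volume, init, bounds = c(1.5, 3),
                            grid = c(0.1, 0.25), final_tol = c(0.005, 0.01),
                            mask_radius_frac = 0.8, z_frac = 0.6) {
  stopifnot(inherits(init, "helical_symmetry"))
  d <- dim(volume$data)
  if (sd(volume$data) == 0)
    stop("search_symmetry: flat volume has no defined symmetry")
  mask_for <- function(vol) {
    dd <- dim(vol$data)
    box_a <- dd[1] * vol$pixel_size
    m <- cylinder_logical(dd, vol$pixel_size, mask_radius_frac * box_a / 2,
                          z_half = z_frac * box_a / 2)
    cx <- axis_coords(dd[1], vol$pixel_size)
    cy <- axis_coords(dd[2], vol$pixel_size)
    cz <- axis_coords(dd[3], vol$pixel_size)
    pts <- cbind(rep(cx, times = dd[2] * dd[3]),
                 rep(rep(cy, each = dd[1]), times = dd[3]),
                 rep(cz, each = dd[1] * dd[2]))[as.vector(m), , drop = FALSE]
    list(pts = pts, vals = vol$data[m])
  }
  # coarse stage on a binned copy
  vb <- if (d[1] >= 64) bin_volume(volume) else volume
  mb <- mask_for(vb)
  rises <- seq(init$rise - bounds[1], init$rise + bounds[1], by = grid[1])
  twists <- seq(init$twist - bounds[2], init$twist + bounds[2], by = grid[2])
  tr <- expand.grid(rise = rises, twist = twists)
  tr$objective <- vapply(seq_len(nrow(tr)), function(i)
    helical_self_correlation(vb, tr$rise[i], tr$twist[i], mb$pts, mb$vals),
    0.0)
  best <- tr[which.max(tr$objective), ]
  # local 2-D refinement on the full grid (rise and twist are correlated
  # along a ridge, so a joint simplex search beats axis alternation)
  mf <- mask_for(volume)
  scl <- c(grid[1], grid[2])
  fine <- optim(c(best$rise / scl[1], best$twist / scl[2]),
                function(p) -helical_self_correlation(
                  volume, p[1] * scl[1], p[2] * scl[2], mf$pts, mf$vals),
                method = "Nelder-Mead",
                control = list(reltol = 1e-10, maxit = 200))
  rise <- fine$par[1] * scl[1]; twist <- fine$par[2] * scl[2]
  # keep the refined optimum inside the requested search window
  rise <- min(max(rise, init$rise - bounds[1]), init$rise + bounds[1])
  twist <- min(max(twist, init$twist - bounds[2]), init$twist + bounds[2])
  out <- helical_symmetry(rise, twist)
  attr(out, "objective") <- helical_self_correlation(volume, rise, twist,
                                                     mf$pts, mf$vals)
  attr(out, "trace") <- tr
  out
}

#' Exclude poorly aligning segments by cross-correlation cutoff
#'
#' Segments whose cross-correlation falls below `mean - sigma * sd`
#' (statistics over the currently included segments, raw CC scores) are
#' marked excluded; all others are untouched. With zero variance nothing is
#' excluded.
#'
#' @param params alignment data.frame with `segment` and
#'   `cross_correlation` columns
#' @param included logical vector (by segment id) of current inclusion
#' @param sigma cutoff in standard deviations (default 1.5)
#' @return updated logical inclusion vector
#' @export
exclude_low_cc <- function(params, included, sigma = 1.5) {
  stopifnot(nrow(params) >= 2, sigma > 0)
  inc_now <- included[params$segment]
  cc <- params$cross_correlation[inc_now]
  if (length(cc) < 2) return(included)
  s <- sd(cc)
  if (!is.finite(s) || s == 0 || !is.finite(sigma)) return(included)
  cutoff <- mean(cc) - sigma * s
  drop <- params$segment[inc_now & params$cross_correlation < cutoff]
  included[drop] <- FALSE
  included
}
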