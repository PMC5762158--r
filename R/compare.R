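#' Named residue-range domain definition
#'
#' Residue ranges (author numbering, taken verbatim from the files) naming a
#' structural domain used by centroid/RMSD analytics, e.g. the myosin upper
#' 50 kDa subdomain or the actin hydrophobic plug.
#'
#' @param name domain name
#' @param ranges data.frame with columns `chain`, `from`, `to`
#' @return object of class `domain_definition`
#' @export
domain_definition <- function(name, ranges) {
  ranges <- as.data.frame(ranges)
  stopifnot(all(c("chain", "from", "to") %in% names(ranges)),
            nrow(ranges) >= 1, all(ranges$from <= ranges$to))
  structure(list(name = name, ranges = ranges), class = "domain_definition")
}

#' Canonical actomyosin VI domain presets
#'
#' Residue-range presets used in the state-comparison analytics: the myosin
#' upper/lower 50 kDa subdomains flanking the actin-binding cleft, the actin
#' hydrophobic plug (263-273) and D-loop, and the nucleotide-cleft loops.
#' The cleft loop is quoted with two endpoints in different places
#' (670-681 vs 670-684); both presets are provided.
#'
#' @param name one of "U50", "L50", "H-plug", "D-loop", "switchI", "P-loop",
#'   "cleft-loop", "cleft-loop-long", "HCM-loop", "loop2"
#' @param chain chain id the ranges apply to
#' @return a [domain_definition()]
#' @export
domain_preset <- function(name = c("U50", "L50", "H-plug", "D-loop",
                                   "switchI", "P-loop", "cleft-loop",
                                   "cleft-loop-long", "HCM-loop", "loop2"),
                          chain = "A") {
  name <- match.arg(name)
  r <- switch(name,
    "U50" = data.frame(from = c(180, 229, 405), to = c(206, 397, 441)),
    "L50" = data.frame(from = c(467, 638), to = c(597, 661)),
    "H-plug" = data.frame(from = 263, to = 273),
    "D-loop" = data.frame(from = 40, to = 50),
    "switchI" = data.frame(from = 193, to = 205),
    "P-loop" = data.frame(from = 151, to = 156),
    "cleft-loop" = data.frame(from = 670, to = 681),
    "cleft-loop-long" = data.frame(from = 670, to = 684),
    "HCM-loop" = data.frame(from = 392, to = 410),
    "loop2" = data.frame(from = 622, to = 636))
  domain_definition(name, cbind(chain = chain, r))
}

#' Least-squares superposition (Kabsch)
#'
#' Optimal proper rotation and translation minimizing the RMSD between
#' paired coordinate sets; reflections are never returned (determinant
#' forced to +1), so mirror-image inputs superpose with nonzero RMSD.
#'
#' @param reference,mobile n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear)
#' @return list with `transform` (a [rigid_transform()] carrying mobile onto
#'   reference) and `rmsd` (post-superposition, A)
#' @export
superpose <- function(reference, mobile) {
  P <- as.matrix(reference); Q <- as.matrix(mobile)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (sum(svd(P0)$d > 1e-8) < 2 || sum(svd(Q0)$d > 1e-8) < 2)
    stop("superpose: degenerate (collinear) point set")
  H <- crossprod(Q0, P0) # 3x3
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cp - as.numeric(R %*% cq)
  tr <- rigid_transform(R, t)
  moved <- transform_points(Q, tr)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - P)^2))))
}

# matched Calpha table between two models: (chain, resno) correspondence
match_ca <- function(modelA, modelB, domain = NULL) {
  a <- modelA$atoms; b <- modelB$atoms
  ca_a <- a[a$atom == "CA", ]; ca_b <- b[b$atom == "CA", ]
  key_a <- paste(ca_a$chain, ca_a$resno)
  key_b <- paste(ca_b$chain, ca_b$resno)
  shared <- intersect(key_a, key_b)
  if (!is.null(domain)) {
    keep <- rep(FALSE, length(shared))
    parts <- strsplit(shared, " ")
    ch <- vapply(parts, `[`, "", 1)
    rn <- as.integer(vapply(parts, `[`, "", 2))
    for (i in seq_len(nrow(domain$ranges))) {
      r <- domain$ranges[i, ]
      hit <- ch == r$chain & rn >= r$from & rn <= r$to
      if (!any(hit))
        stop(sprintf("match_ca: domain '%s' range %s %d-%d has no matched residues",
                     domain$name, r$chain, r$from, r$to))
      keep <- keep | hit
    }
    shared <- shared[keep]
  }
  if (!length(shared)) stop("match_ca: empty Calpha correspondence")
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  list(keys = shared,
       chain = ca_a$chain[ia], resno = ca_a$resno[ia],
       xyzA = as.matrix(ca_a[ia, c("x", "y", "z")]),
       xyzB = as.matrix(ca_b[ib, c("x", "y", "z")]))
}

# superpose B's matched Calpha onto A over the frame selection and return
# B's coordinates (for the full match) expressed in A's frame
frame_align <- function(m, modelA, modelB, frame) {
  if (is.null(frame)) return(list(xyzB = m$xyzB,
                                  transform = rigid_transform()))
  if (inherits(frame, "rigid_transform"))
    return(list(xyzB = transform_points(m$xyzB, frame), transform = frame))
  fr <- match_ca(modelA, modelB, if (identical(frame, "all")) NULL else frame)
  sp <- superpose(fr$xyzA, fr$xyzB)
  list(xyzB = transform_points(m$xyzB, sp$transform), transform = sp$transform)
}

#' Calpha RMSD between two models
#'
#' Root-mean-square deviation of matched Calpha (correspondence strictly by
#' chain and residue number) after superposing on the stated frame.
#'
#' @param modelA,modelB [atomic_model()]s
#' @param selection [domain_definition()] restricting the measured atoms
#'   (NULL = all matched Calpha)
#' @param frame superposition frame: `"all"` (all shared Calpha), a
#'   [domain_definition()], a precomputed [rigid_transform()] (e.g. from
#'   [align_maps()], the filament reference frame), or NULL (no
#'   superposition; models are already in a common frame)
#' @return RMSD in Angstrom, with attribute `n` (residues compared)
#' @export
rmsd_ca <- function(modelA, modelB, selection = NULL, frame = "all") {
  m <- match_ca(modelA, modelB, selection)
  fa <- frame_align(m, modelA, modelB, frame)
  out <- sqrt(mean(rowSums((fa$xyzB - m$xyzA)^2)))
  attr(out, "n") <- nrow(m$xyzA)
  out
}

#' Per-residue Calpha deviation profile
#'
#' @inheritParams rmsd_ca
#' @return data.frame with chain, resno, rmsd (A)
#' @export
per_residue_rmsd <- function(modelA, modelB, frame = "all") {
  m <- match_ca(modelA, modelB, NULL)
  fa <- frame_align(m, modelA, modelB, frame)
  data.frame(chain = m$chain, resno = m$resno,
             rmsd = sqrt(rowSums((fa$xyzB - m$xyzA)^2)))
}

#' Domain centroid
#'
#' Unweighted mean of the Calpha positions over the domain ranges.
#'
#' @param model an [atomic_model()]
#' @param domain a [domain_definition()]
#' @return 3-vector, Angstrom
#' @export
domain_centroid <- function(model, domain) {
  a <- model$atoms
  ca <- a[a$atom == "CA", ]
  keep <- rep(FALSE, nrow(ca))
  for (i in seq_len(nrow(domain$ranges))) {
    r <- domain$ranges[i, ]
    hit <- ca$chain == r$chain & ca$resno >= r$from & ca$resno <= r$to
    if (!any(hit))
      stop(sprintf("domain_centroid: '%s' range %s %d-%d missing from model",
                   domain$name, r$chain, r$from, r$to))
    keep <- keep | hit
  }
  colMeans(as.matrix(ca[keep, c("x", "y", "z")]))
}

#' Centroid displacement of a domain between two states
#'
#' @inheritParams rmsd_ca
#' @param domain a [domain_definition()]
#' @return displacement in Angstrom after frame alignment
#' @export
centroid_displacement <- function(modelA, modelB, domain, frame = "all") {
  m <- match_ca(modelA, modelB, NULL)
  fa <- frame_align(m, modelA, modelB, frame)
  cA <- domain_centroid(modelA, domain)
  modelB2 <- set_coords(modelB,
                        transform_points(model_coords(modelB), fa$transform))
  cB <- domain_centroid(modelB2, domain)
  sqrt(sum((cA - cB)^2))
}

#' Per-residue Calpha displacement field
#'
#' Vector traces of Calpha displacement from state A to state B in the
#' frame coordinates; the scaled vectors (default scale 1.5, the plotting
#' convention for displacement rods) are exactly `scale` times the raw
#' vectors, and the field norms equal the per-residue RMSD profile.
#'
#' @inheritParams rmsd_ca
#' @param scale vector scale factor (default 1.5)
#' @return object of class `displacement_field`: data.frame with chain,
#'   resno, start x/y/z, raw dx/dy/dz, scaled sdx/sdy/sdz, norm
#' @export
displacement_field <- function(modelA, modelB, frame = "all", scale = 1.5) {
  m <- match_ca(modelA, modelB, NULL)
  fa <- frame_align(m, modelA, modelB, frame)
  dv <- fa$xyzB - m$xyzA
  out <- data.frame(chain = m$chain, resno = m$resno,
                    x = m$xyzA[, 1], y = m$xyzA[, 2], z = m$xyzA[, 3],
                    dx = dv[, 1], dy = dv[, 2], dz = dv[, 3],
                    sdx = scale * dv[, 1], sdy = scale * dv[, 2],
                    sdz = scale * dv[, 3],
                    norm = sqrt(rowSums(dv^2)))
  attr(out, "scale") <- scale
  class(out) <- c("displacement_field", "data.frame")
  out
}

#' Pairwise Calpha RMSD matrix between several models
#'
#' The Table-style state comparison: symmetric matrix with zero diagonal.
#'
#' @param models named list of [atomic_model()]s
#' @param selection,frame as in [rmsd_ca()]
#' @return numeric matrix
#' @export
rmsd_matrix <- function(models, selection = NULL, frame = "all") {
  n <- length(models)
  out <- matrix(0, n, n, dimnames = list(names(models), names(models)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      out[i, j] <- out[j, i] <-
        as.numeric(rmsd_ca(models[[i]], models[[j]], selection, frame))
    }
  }
  out
}

#' Align two density maps of a helical specimen
#'
#' Searches the helical-specimen parameterization — rotation about z,
#' z-shift, small in-plane offsets — for the rigid transform of map B that
#' maximizes the masked real-space correlation with map A; the transform is
#' reported for re-docking atomic models into the aligned frame.
#'
#' @param mapA,mapB [density_volume()]s with equal pixel size
#' @param rot_range,rot_step azimuthal search, degrees
#' @param z_range,z_step axial shift search, A
#' @param xy_range in-plane offset bound for the refinement stage, A
#' @param mask_radius_frac cylindrical mask radius (fraction of half-box)
#' @return a [rigid_transform()] with attribute `correlation`
#' @export
align_maps <- function(mapA, mapB, rot_range = c(-180, 180), rot_step = 4,
                       z_range = c(-20, 20), z_step = 2, xy_range = 3,
                       mask_radius_frac = 0.8) {
  stopifnot(abs(mapA$pixel_size - mapB$pixel_size) < 1e-9)
  if (sd(mapA$data) == 0 || sd(mapB$data) == 0)
    stop("align_maps: flat map")
  d <- dim(mapA$data)
  box_a <- d[1] * mapA$pixel_size
  mask <- cylinder_logical(d, mapA$pixel_size, mask_radius_frac * box_a / 2,
                           z_half = 0.7 * box_a / 2)
  cx <- axis_coords(d[1], mapA$pixel_size)
  cz <- axis_coords(d[3], mapA$pixel_size)
  pts <- cbind(rep(cx, times = d[2] * d[3]),
               rep(rep(cx, each = d[1]), times = d[3]),
               rep(cz, each = d[1] * d[2]))[as.vector(mask), , drop = FALSE]
  valsA <- mapA$data[mask]
  obj <- function(par) { # par = (rot deg, dx, dy, dz)
    tr <- rigid_transform(rot_z(par[1]), par[2:4])
    src <- transform_points(pts, invert_transform(tr))
    v <- interp_volume(mapB, src)
    if (sd(v) == 0) return(-1)
    cor(valsA, v)
  }
  rots <- seq(rot_range[1], rot_range[2] - rot_step, by = rot_step)
  zs <- seq(z_range[1], z_range[2], by = z_step)
  coarse <- expand.grid(rot = rots, dz = zs)
  cc <- vapply(seq_len(nrow(coarse)), function(i)
    obj(c(coarse$rot[i], 0, 0, coarse$dz[i])), 0.0)
  b <- coarse[which.max(cc), ]
  fine <- optim(c(b$rot, 0, 0, b$dz), function(p) -obj(p),
                method = "L-BFGS-B",
                lower = c(b$rot - rot_step, -xy_range, -xy_range,
                          b$dz - z_step),
                upper = c(b$rot + rot_step, xy_range, xy_range,
                          b$dz + z_step),
                control = list(factr = 1e10))
  tr <- rigid_transform(rot_z(fine$par[1]), fine$par[2:4])
  attr(tr, "correlation") <- -fine$value
  attr(tr, "rotation_deg") <- fine$par[1]
  tr
}
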