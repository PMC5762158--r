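test_that("filament building places subunits by the helical operator", {
  sub <- default_subunit(TRUE)
  sym <- rigor_sym()
  one <- build_filament(sub, sym, 1)
  expect_equal(one$positions, sub$positions, ignore_attr = TRUE)
  f <- build_filament(sub, sym, 13)
  n_at <- nrow(sub$positions)
  expect_equal(nrow(f$positions), 13 * n_at)
  z_cent <- tapply(f$positions[, 3], f$subunit_index, mean)
  expect_equal(as.numeric(z_cent - z_cent[1]), (0:12) * 28.06, tolerance = 1e-9)
  sub8 <- pseudo_atom_subunit(matrix(rnorm(24), 8, 3), width = 3)
  expect_equal(nrow(build_filament(sub8, sym, 6)$positions), 48)
  expect_error(build_filament(sub, sym, 0), "n_subunits")
})

test_that("rasterization sums Gaussians with the analytic mass", {
  one <- list(positions = matrix(0, 1, 3), weight = 1, width = 3)
  vol <- rasterize(one, 32, 2)
  expect_equal(which.max(vol$data), which(abs(vol$data - max(vol$data)) < 1e-12)[1])
  peak <- arrayInd(which.max(vol$data), dim(vol$data))
  expect_equal(as.numeric(peak), c(17, 17, 17)) # box/2 + 1 = center voxel
  expect_equal(sum(vol$data), (2 * pi * 9)^1.5 / 8, tolerance = 0.01)
  two <- list(positions = matrix(0, 1, 3), weight = 2, width = 3)
  expect_equal(rasterize(two, 32, 2)$data, 2 * vol$data)
  far <- list(positions = matrix(c(100, 0, 0), 1, 3), weight = 1, width = 3)
  expect_error(rasterize(far, 32, 2), "outside")
})

test_that("CTF follows the phase-contrast formula", {
  ctf <- ctf_params(voltage = 200, defocus = 2.0, spherical_aberration = 2.0,
                    amplitude_contrast = 0.07, pixel_size = 1.27)
  expect_equal(ctf_value(ctf, 0), -0.07)
  s <- seq(0, 1 / (2 * 1.27), length.out = 1000)
  expect_true(all(abs(ctf_value(ctf, s)) <= 1 + 1e-12))
  # first zero against a 1-D root-finding oracle on the phase function
  lam <- electron_wavelength(200)
  expect_equal(lam, 0.0251, tolerance = 1e-3)
  chi <- function(s) pi * lam * 2e4 * s^2 - pi / 2 * 2e7 * lam^3 * s^4
  oracle <- uniroot(function(s) chi(s) + asin(0.07) - pi, c(1e-4, 0.08),
                    tol = 1e-12)$root
  mine <- uniroot(function(s) ctf_value(ctf, s), c(1e-4, 0.08), tol = 1e-12)$root
  expect_equal(mine, oracle, tolerance = 1e-9)
})

test_that("projection integrates density along the view axis", {
  vol <- blob_volume(32, 3)
  p <- project_volume(vol, c(30, 75, 12))
  expect_equal(sum(p), sum(vol$data) * 3, tolerance = 0.01)
  expect_equal(project_volume(vol, c(42 + 360, 90, 7)),
               project_volume(vol, c(42, 90, 7)), tolerance = 1e-12)
  # centered spherical Gaussian projects to a rotationally symmetric image
  sph <- rasterize(list(positions = matrix(0, 1, 3), weight = 1, width = 6),
                   32, 3)
  ps <- project_volume(sph, c(0, 0, 0))
  expect_lt(max(abs(ps - rotate_image(ps, 90))) / max(ps), 2e-3)
  # in-plane rotation of the volume equals 2D rotation of the projection
  p0 <- project_volume(vol, c(10, 90, 0))
  p25 <- project_volume(vol, c(10, 90, 25))
  m <- annulus_mask(32, 0, 13)
  expect_gt(cor(p25[m], rotate_image(p0, 25)[m]), 0.999)
})

test_that("segment counting matches a brute-force sliding window", {
  expect_equal(segment_count(1300, 650, 81), 9L)
  brute <- function(L, box, step) {
    n <- 0L; start <- 0
    while (start + box <= L + 1e-9) { n <- n + 1L; start <- start + step }
    n
  }
  set.seed(42)
  for (i in 1:100) {
    L <- runif(1, 200, 3000); box <- runif(1, 50, 400); step <- runif(1, 10, 150)
    expect_equal(segment_count(L, box, step), brute(L, box, step))
  }
})

test_that("simulated stacks are reproducible and self-consistent", {
  sub <- default_subunit(TRUE)
  sym <- rigor_sym()
  a <- simulate_segments(sub, sym, ctf = ctf_params(pixel_size = 3.2), box = 40,
                         step = 81, n_filaments = 2, snr = 4, seed = 99,
                         n_subunits = 20, pixel_size = 3.2)
  b <- simulate_segments(sub, sym, ctf = ctf_params(pixel_size = 3.2), box = 40,
                         step = 81, n_filaments = 2, snr = 4, seed = 99,
                         n_subunits = 20, pixel_size = 3.2)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth, b$truth)
  # noise-free segments match the reprojection of their ground truth
  clean <- simulate_segments(sub, sym, ctf = NULL, box = 40, step = 81,
                             n_filaments = 2, snr = Inf, seed = 7,
                             n_subunits = 20, pixel_size = 3.2)
  ref <- rasterize(build_filament(sub, sym, 20), 40, 3.2, clip = TRUE)
  # compare inside the filament core, clear of the reference's z-taper
  ctr <- annulus_mask(40, 0, 12)
  for (i in seq_len(dim(clean$stack$images)[3])) {
    rp <- reproject_truth(ref, clean$truth[i, ])
    expect_gt(cor(clean$stack$images[, , i][ctr], rp[ctr]), 0.99)
  }
  expect_error(simulate_segments(sub, sym, ctf = NULL, box = 40, step = 81,
                                 n_filaments = 1, snr = Inf, seed = 1,
                                 n_subunits = 3, pixel_size = 3.2),
               "shorter than one box")
})

test_that("segments at moderate SNR align to a view equivalent to their truth", {
  sub <- default_subunit(TRUE)
  sym <- rigor_sym()
  sim <- simulate_segments(sub, sym, ctf = NULL, box = 48, step = 81,
                           n_filaments = 2, snr = 10, seed = 13,
                           n_subunits = 24, pixel_size = 3.2)
  ref <- rasterize(build_filament(sub, sym, 24), 48, 3.2, clip = TRUE)
  cfg <- refinement_config(phi_step = 6, psi_step = 8, theta_range = c(84, 96),
                           theta_step = 6, shift_range = 5)
  refs <- make_reference_projections(ref, cfg)
  ctr <- annulus_mask(48, 0, 14)
  n_show <- min(6, dim(sim$stack$images)[3])
  ok <- logical(n_show)
  for (i in seq_len(n_show)) {
    al <- align_segment(sim$stack$images[, , i], refs, cfg)
    # the assigned orientation's clean reprojection must match the clean
    # reprojection of the recorded truth: grid-step-equivalent views
    # (azimuth and axial shift trade off along the helical family)
    rp_al <- project_volume(ref, c(al$phi, al$theta, al$psi),
                            c(al$shift_x, al$shift_y))
    rp_tr <- reproject_truth(ref, sim$truth[i, ])
    # one-grid-step quantization leaves correlations ~0.86+; genuine
    # misassignments (e.g. polarity flips) fall to ~0.3-0.5
    ok[i] <- cor(rp_al[ctr], rp_tr[ctr]) > 0.8
  }
  expect_true(all(ok))
})

test_that("segment normalization standardizes the background annulus", {
  set.seed(3)
  img <- matrix(rnorm(48^2, mean = 7, sd = 2.5), 48)
  ann <- annulus_mask(48, 18)
  n1 <- normalize_segment(img, ann)
  expect_equal(mean(n1[ann]), 0, tolerance = 1e-6)
  expect_equal(sd(n1[ann]), 1, tolerance = 1e-6)
  expect_equal(normalize_segment(n1, ann), n1, tolerance = 1e-6)
  expect_equal(normalize_segment(3.7 * img - 11, ann), n1, tolerance = 1e-9)
  expect_error(normalize_segment(matrix(1, 48, 48), ann), "zero-variance")
})
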