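test_that("initial-model filtering attenuates beyond the cutoff", {
  v <- blob_volume(32, 3)
  expect_equal(make_initial_model(v, Inf)$data, v$data)
  f <- make_initial_model(v, 35)
  smag <- helicalem:::freq_magnitude_3d(dim(v$data), 3)
  pf <- abs(fft(f$data))^2
  beyond <- smag > 1 / 35 + 2 / (32 * 3)
  expect_lt(sum(pf[beyond]) / sum(pf), 1e-4)
  # filtering a featureless (soft) cylinder preserves its azimuthal symmetry
  d <- c(32, 32, 32)
  cyl <- cylindrical_mask(density_volume(array(1, d), 3), 24, soft_edge = 12)
  fc <- make_initial_model(cyl, 30)
  rot45 <- resample_volume(fc, rigid_transform(helicalem:::rot_z(45), c(0, 0, 0)))
  core <- helicalem:::cylinder_logical(d, 3, 30, z_half = 24)
  expect_lt(max(abs(fc$data[core] - rot45$data[core])) / max(abs(fc$data)), 0.02)
  expect_error(make_initial_model(v, 4), "Nyquist")
})

test_that("projection matching recovers constructed transformations", {
  vol <- rasterize(build_filament(default_subunit(TRUE), rigor_sym(), 24),
                   48, 3.2, clip = TRUE)
  cfg <- refinement_config(phi_step = 8, psi_step = 8, theta_range = c(90, 90),
                           shift_range = 10)
  refs <- make_reference_projections(vol, cfg)
  # a segment that IS a reference projection
  al <- align_segment(refs$images[, , 5], refs, cfg)
  expect_equal(al$phi, refs$angles$phi[5])
  expect_equal(c(al$psi, al$shift_x, al$shift_y), c(0, 0, 0))
  expect_gte(al$cross_correlation, 0.999)
  # in-plane rotation by 14 degrees -> psi within one grid step
  al2 <- align_segment(rotate_image(refs$images[, , 5], 14), refs, cfg)
  expect_lte(abs(al2$psi - 14), cfg$psi_step)
  # integer-pixel shift (+3, -2) recovered within half a search step
  al3 <- align_segment(shift_image(refs$images[, , 8], 3, -2), refs, cfg)
  expect_equal(al3$shift_x, 3 * 3.2, tolerance = 1.6)
  expect_equal(al3$shift_y, -2 * 3.2, tolerance = 1.6)
  expect_equal(al3$phi, refs$angles$phi[8])
  empty <- refs
  expect_error(align_segment(matrix(0, 48, 48),
                             local({ e <- new.env(); e$images <- array(0, c(48, 48, 0));
                                     e$angles <- data.frame(phi = numeric(0), theta = numeric(0));
                                     e$pixel_size <- 3.2; e$cache <- NULL
                                     class(e) <- "reference_projections"; e }),
                             cfg),
               "empty reference")
})

test_that("filtered backprojection inverts projection on dense clean views", {
  tv <- blob_volume(48, 3.2)
  phis <- seq(0, 358, by = 2)
  imgs <- array(0, c(48, 48, length(phis)))
  for (i in seq_along(phis)) imgs[, , i] <- project_volume(tv, c(phis[i], 90, 0))
  stk <- stack_from_images(imgs, 3.2)
  par <- data.frame(segment = seq_along(phis), phi = phis, theta = 90, psi = 0,
                    shift_x = 0, shift_y = 0, cross_correlation = 1)
  rec <- backproject(stk, par)
  msk <- annulus_mask(48, 0, 18)
  m3 <- array(rep(msk, 48), c(48, 48, 48)) &
    rep(abs(helicalem:::axis_coords(48, 3.2)) < 55, each = 48 * 48)
  expect_gt(cor(rec$data[m3], tv$data[m3]), 0.99)
  # linearity
  stk2 <- stk; stk2$images <- 2 * stk$images
  expect_equal(backproject(stk2, par)$data, 2 * rec$data, tolerance = 1e-9)
  stk0 <- stk; stk0$images[] <- 0
  expect_equal(max(abs(backproject(stk0, par)$data)), 0)
  stk$meta$included <- FALSE
  expect_error(backproject(stk, par), "no included")
})

test_that("helical symmetrization is a near-projection onto the symmetric subspace", {
  sym <- rigor_sym()
  vol <- rasterize(build_filament(default_subunit(TRUE), sym, 24), 48, 3.2,
                   clip = TRUE)
  s1 <- symmetrize(vol, sym)
  s2 <- symmetrize(s1, sym)
  # idempotent at trilinear-interpolation accuracy
  expect_lt(max(abs(s2$data - s1$data)) / max(abs(s1$data)), 0.05)
  expect_gt(cor(as.vector(s1$data), as.vector(s2$data)), 0.999)
  # symmetric input passes through up to interpolation
  expect_lt(max(abs(s2$data - symmetrize(s2, sym)$data)) / max(abs(s2$data)), 0.05)
  # invariance under the unit operator inside the central cylinder
  msk <- helicalem:::cylinder_logical(dim(s1$data), 3.2, 0.8 * 48 * 3.2 / 2,
                                      z_half = 0.6 * 48 * 3.2 / 2)
  moved <- resample_volume(s1, symmetry_operator(sym, 1))
  expect_gt(cor(s1$data[msk], moved$data[msk]), 0.99)
  expect_error(symmetrize(vol, helical_symmetry(1, 10)), "rise smaller")
})

test_that("symmetry search recovers printed filament parameters from perturbed starts", {
  # decorated filament at the rigor-state parameters
  v1 <- rasterize(build_filament(default_subunit(TRUE), rigor_sym(), 12),
                  64, 3, clip = TRUE)
  f1 <- search_symmetry(v1, helical_symmetry(28.06 + 1.5, -166.73 + 3),
                        bounds = c(2, 4), grid = c(0.1, 0.25))
  expect_equal(f1$rise, 28.06, tolerance = 0.05)
  expect_equal(f1$twist, -166.73, tolerance = 0.1)
  # undecorated filament at the actin-alone parameters
  v2 <- rasterize(build_filament(default_subunit(FALSE),
                                 helical_symmetry(28.11, -166.65), 12),
                  64, 3, clip = TRUE)
  f2 <- search_symmetry(v2, helical_symmetry(29.5, -163), bounds = c(2, 4),
                        grid = c(0.1, 0.25))
  expect_equal(f2$rise, 28.11, tolerance = 0.05)
  expect_equal(f2$twist, -166.65, tolerance = 0.1)
  # exhaustive coarse-grid oracle: nothing on the grid beats the optimum
  d <- dim(v1$data)
  msk <- helicalem:::cylinder_logical(d, 3, 0.8 * 64 * 3 / 2,
                                      z_half = 0.6 * 64 * 3 / 2)
  cx <- helicalem:::axis_coords(64, 3)
  pts <- cbind(rep(cx, times = 64 * 64), rep(rep(cx, each = 64), times = 64),
               rep(cx, each = 64 * 64))[as.vector(msk), , drop = FALSE]
  obj <- function(r, t) helicalem:::helical_self_correlation(v1, r, t, pts)
  grid <- expand.grid(rise = seq(27.2, 29, by = 0.3),
                      twist = seq(-168, -165, by = 0.5))
  grid_best <- max(vapply(seq_len(nrow(grid)),
                          function(i) obj(grid$rise[i], grid$twist[i]), 0.0))
  expect_gte(attr(f1, "objective"), grid_best - 1e-6)
  expect_error(search_symmetry(density_volume(array(0, c(16, 16, 16)), 3),
                               rigor_sym()),
               "flat")
})

test_that("cross-correlation exclusion applies the sigma cutoff arithmetic", {
  par <- data.frame(segment = 1:100,
                    cross_correlation = c(rep(0.9, 99), 0.1))
  inc <- exclude_low_cc(par, rep(TRUE, 100), sigma = 1.5)
  expect_false(inc[100])
  expect_true(all(inc[1:99]))
  # direct mean/sd oracle
  cc <- par$cross_correlation
  expect_identical(which(!inc), which(cc < mean(cc) - 1.5 * sd(cc)))
  # equal scores: zero variance, nothing excluded
  eq <- data.frame(segment = 1:5, cross_correlation = rep(0.7, 5))
  expect_true(all(exclude_low_cc(eq, rep(TRUE, 5), 1.5)))
  # infinite sigma excludes nothing
  expect_true(all(exclude_low_cc(par, rep(TRUE, 100), Inf)))
})

test_that("gold-standard refinement recovers symmetry from noisy CTF data", {
  sym <- rigor_sym()
  sub <- default_subunit(TRUE)
  sim <- simulate_segments(sub, sym, ctf = ctf_params(pixel_size = 3.2),
                           box = 48, step = 81, n_filaments = 20, snr = 5,
                           seed = 11, n_subunits = 48, pixel_size = 3.2)
  init_sym <- helical_symmetry(28.3, -166.2)
  init_vol <- rasterize(build_filament(sub, init_sym, 24), 48, 3.2, clip = TRUE)
  cfg <- refinement_config(n_iterations = 3, phi_step = 6, psi_step = 8,
                           theta_range = c(84, 96), theta_step = 6,
                           shift_range = 5, sym_bounds = c(0.8, 1.5),
                           sym_grid = c(0.1, 0.25), seed = 2,
                           initial_lowpass = 18)
  fit <- ihrsr(sim$stack, init_vol, init_sym, cfg, polish = TRUE)
  # desk-scale recovery envelope (5.5 subunits per box, 300 segments)
  expect_lt(abs(fit$sym$rise - 28.06), 0.2)
  expect_lt(abs(fit$sym$twist + 166.73), 0.6)
  expect_true(all(is.finite(fit$log$resolution)))
  expect_true(fit$polished)
  # gold standard: no image of one half ever touched the other's reference
  expect_true(assert_gold_standard(fit))
  for (pv in fit$provenance)
    expect_length(intersect(pv$half1, pv$half2), 0)
  # the exclusion stage dropped some poorly aligning segments, never all
  expect_lt(sum(fit$stack_meta$included), nrow(fit$stack_meta) + 1)
  expect_gt(sum(fit$stack_meta$included), 0.7 * nrow(fit$stack_meta))
  # polishing against the strictly filtered reference did not degrade the map
  truthvol <- rasterize(build_filament(sub, sym, 24), 48, 3.2, clip = TRUE)
  msk <- helicalem:::cylinder_logical(c(48, 48, 48), 3.2, 60, z_half = 46)
  half_mean <- density_volume((fit$half1$data + fit$half2$data) / 2, 3.2)
  cor_pre <- helicalem:::masked_correlation(half_mean, truthvol, msk)
  cor_post <- helicalem:::masked_correlation(fit$map, truthvol, msk)
  expect_gte(cor_post, cor_pre - 0.01)
  # accessor methods
  expect_named(coef(fit), c("rise", "twist"))
  expect_s3_class(fitted(fit), "density_volume")
})

test_that("refinement is deterministic and does not degrade on clean data", {
  sym <- rigor_sym()
  sub <- default_subunit(TRUE)
  sim <- simulate_segments(sub, sym, ctf = NULL, box = 40, step = 81,
                           n_filaments = 4, snr = Inf, seed = 8,
                           n_subunits = 24, pixel_size = 3.4)
  init_sym <- helical_symmetry(28.2, -166.4)
  init_vol <- rasterize(build_filament(sub, init_sym, 18), 40, 3.4, clip = TRUE)
  cfg <- refinement_config(n_iterations = 2, phi_step = 10, psi_step = 12,
                           theta_range = c(84, 96), theta_step = 6,
                           shift_range = 5, sym_bounds = c(0.6, 1.2),
                           sym_grid = c(0.15, 0.4), seed = 5,
                           initial_lowpass = 18)
  f1 <- ihrsr(sim$stack, init_vol, init_sym, cfg, polish = FALSE)
  f2 <- ihrsr(sim$stack, init_vol, init_sym, cfg, polish = FALSE)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  # polishing honours the fixed symmetry exactly
  pol <- polish(phase_flip_stack(sim$stack), f1$map, f1$sym, lowpass = 10,
                config = cfg)
  expect_identical(pol$sym, f1$sym)
  expect_error(polish(sim$stack, f1$map, lowpass = 10, config = cfg),
               "fixed_sym")
})

test_that("half-map resolution does not degrade over iterations on clean data", {
  sym <- rigor_sym()
  sub <- default_subunit(TRUE)
  sim <- simulate_segments(sub, sym, ctf = NULL, box = 48, step = 81,
                           n_filaments = 10, snr = Inf, seed = 11,
                           n_subunits = 24, pixel_size = 3.2)
  init_sym <- helical_symmetry(28.2, -166.4)
  init_vol <- rasterize(build_filament(sub, init_sym, 24), 48, 3.2, clip = TRUE)
  cfg <- refinement_config(n_iterations = 2, phi_step = 8, psi_step = 10,
                           theta_range = c(84, 96), theta_step = 6,
                           shift_range = 5, sym_bounds = c(0.6, 1.2),
                           sym_grid = c(0.15, 0.4), seed = 2,
                           initial_lowpass = 18)
  fit <- ihrsr(sim$stack, init_vol, init_sym, cfg, polish = FALSE)
  expect_lte(fit$log$resolution[nrow(fit$log)], fit$log$resolution[1] + 0.5)
})
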