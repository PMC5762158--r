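# Shared synthetic fixtures. Everything is generated in code; sizes are kept
# small so the whole suite stays within minutes on one core.

rigor_sym <- function() helical_symmetry(28.06, -166.73)

# a toy protein chain on a helical path: N/CA/C/O/CB per residue plus
# side-chain atoms that vary by pseudo-sequence, so the chain is not
# translationally self-similar
toy_model <- function(n_res = 26, chain = "A") {
  atoms <- list()
  kinds <- c("ALA", "LEU", "PHE")
  for (i in seq_len(n_res)) {
    t <- 0.38 * i
    base <- c(8 * cos(t), 8 * sin(t), 2.8 * i - 1.4 * n_res)
    off <- rbind(N = c(-1.1, 0.3, -0.6), CA = c(0, 0, 0),
                 C = c(1.2, 0.2, 0.5), O = c(1.7, 1.1, 0.4),
                 CB = c(-0.4, -1.3, 0.7))
    rn <- kinds[(i - 1) %% 3 + 1]
    if (rn == "LEU") off <- rbind(off, CG = c(-0.8, -2.4, 1.3))
    if (rn == "PHE") off <- rbind(off, CG = c(-0.8, -2.4, 1.3),
                                  CD1 = c(-1.4, -3.4, 2.0))
    for (a in rownames(off)) atoms[[length(atoms) + 1]] <- data.frame(
      type = "ATOM", atom = a, resname = rn, chain = chain, resno = i,
      x = base[1] + off[a, 1], y = base[2] + off[a, 2],
      z = base[3] + off[a, 3], element = "C")
  }
  atomic_model(do.call(rbind, atoms))
}

# random smooth deformation (rigid motion + low-frequency bend) rescaled to
# an exact RMSD: the displacement model of the fit-recovery experiment
smooth_perturb <- function(m, rmsd_target = 2, seed = 1) {
  set.seed(seed)
  xyz <- model_coords(m)
  ctr <- colMeans(xyz)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- axis_angle_matrix(ax, runif(1, 2, 5))
  disp <- sweep(xyz, 2, ctr) %*% t(R) - sweep(xyz, 2, ctr)
  disp <- disp + matrix(rnorm(3, 0, 1), nrow(xyz), 3, byrow = TRUE)
  ph <- runif(3, 0, 2 * pi); kz <- runif(1, 0.05, 0.12)
  disp <- disp + 1.5 * cbind(sin(kz * xyz[, 3] + ph[1]),
                             sin(kz * xyz[, 3] + ph[2]),
                             0.3 * sin(2 * kz * xyz[, 3] + ph[3]))
  disp <- disp * rmsd_target / sqrt(mean(rowSums(disp^2)))
  set_coords(m, xyz + disp)
}

# normalized density map rasterized from a model (fitting target)
toy_map <- function(m, box = 64, pixel = 1.5, width = 2.8) {
  map <- rasterize_model(m, box, pixel, width = width)
  density_volume(map$data / max(map$data), map$pixel_size)
}

# smooth multi-blob test volume (band-limited, good for projection and
# reconstruction consistency checks)
blob_volume <- function(box = 48, pixel = 3.2) {
  blob <- pseudo_atom_subunit(
    rbind(c(8, 4, 6), c(-6, 5, -8), c(3, -9, 2), c(-2, -3, -12), c(10, -2, -4)),
    weight = c(1, .8, 1.2, .9, .7), width = 6)
  rasterize(blob, box, pixel)
}

# minimal segment_stack wrapper around explicitly projected images
stack_from_images <- function(imgs, pixel_size, ctf = NULL) {
  n <- dim(imgs)[3]
  structure(list(images = imgs,
                 meta = data.frame(segment = seq_len(n), filament = 1L,
                                   index = seq_len(n), defocus = NA_real_,
                                   half_set = 1L, included = TRUE),
                 pixel_size = pixel_size, box = dim(imgs)[1], step = 1,
                 ctf = ctf, asu_per_segment = 3L, seed = 1L),
            class = "segment_stack")
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((model_coords(a) - model_coords(b))^2)))

# deposited coordinate sets for the actomyosin state comparisons; offline
# environments without these files exercise the synthetic checks only
deposited_path <- function(file) {
  p <- system.file("extdata", "deposited", file, package = "helicalem")
  if (identical(p, "")) file.path("inst", "extdata", "deposited", file) else p
}
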