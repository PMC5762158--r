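ref_model_with_ligand <- function() {
  m <- toy_model(12)
  lig <- data.frame(type = "HETATM", atom = c("PB", "MG"), resname = c("ADP", "MG"),
                    chain = "A", resno = c(201, 202), x = c(2, 3), y = c(1, -1),
                    z = c(0, 2), element = c("P", "MG"))
  m$atoms <- rbind(m$atoms,
                   cbind(lig[, c("type", "atom", "resname", "chain", "resno",
                                 "x", "y", "z", "element")],
                         serial = max(m$atoms$serial) + 1:2, occ = 1, b = 0,
                         regime = "BACKBONE", mobile = TRUE)[,
                     names(m$atoms)])
  atomic_model(m$atoms)
}

test_that("coupling regimes follow the region rules", {
  m <- atomic_model(data.frame(
    type = c("ATOM", "ATOM", "ATOM", "ATOM", "ATOM", "ATOM", "HETATM"),
    atom = c("CA", "NH1", "CA", "CB", "CA", "CG", "MG"),
    resname = c("ARG", "ARG", "GLY", "LEU", "LEU", "LEU", "MG"),
    chain = c("F", "F", "G", "G", "G", "G", "F"),
    resno = c(10, 10, 400, 400, 625, 625, 900),
    x = seq(0, 30, length.out = 7), y = 0, z = 0))
  rules <- myosin6_rules(motor_chains = "G", actin_chains = "F", variant = "HR")
  r <- assign_regimes(m, rules)
  a <- r$atoms
  # actin Arg side chain feels the full map potential
  expect_equal(a$regime[a$atom == "NH1"], "FULL")
  # motor residue in the HCM-loop tip (397-405) is decoupled
  expect_true(all(a$regime[a$chain == "G" & a$resno == 400] == "DECOUPLED"))
  # motor residue in loop 2 (622-636) is decoupled, backbone included
  expect_true(all(a$regime[a$chain == "G" & a$resno == 625] == "DECOUPLED"))
  # ligand/ion heteroatoms are fixed and immobile
  expect_equal(a$regime[a$atom == "MG"], "FIXED")
  expect_false(a$mobile[a$atom == "MG"])
  # a rule naming absent residues is an error
  bad <- region_rules(decoupled = data.frame(chain = "Z", from = 1, to = 5))
  expect_error(assign_regimes(m, bad), "matches no residues")
})

test_that("map energies and forces are exact gradients of the density term", {
  m <- toy_model(12)
  map <- toy_map(m, box = 48, pixel = 1.5, width = 2.8)
  m$atoms$regime <- ifelse(m$atoms$atom %in% c("N", "CA", "C", "O"),
                           "BACKBONE", "DECOUPLED")
  res <- build_restraints(m)
  set.seed(3)
  mp <- set_coords(m, model_coords(m) + matrix(rnorm(nrow(m$atoms) * 3, 0, 0.3),
                                               ncol = 3))
  g <- 0.1
  f_an <- map_energy_and_forces(mp, map, g)$forces +
    restraint_energy_and_forces(mp, res)$forces
  etot <- function(mm) map_energy_and_forces(mm, map, g)$energy +
    restraint_energy_and_forces(mm, res)$energy
  h <- 1e-5
  set.seed(8)
  for (i in sample(nrow(mp$atoms), 10)) for (cc in 1:3) {
    xp <- model_coords(mp); xp[i, cc] <- xp[i, cc] + h
    xm <- model_coords(mp); xm[i, cc] <- xm[i, cc] - h
    fd <- -(etot(set_coords(mp, xp)) - etot(set_coords(mp, xm))) / (2 * h)
    expect_lt(abs(f_an[i, cc] - fd) / max(abs(fd), abs(f_an[i, cc]), 1), 1e-4)
  }
  # decoupled atoms feel no map force
  fmap <- map_energy_and_forces(mp, map, g)$forces
  dec <- mp$atoms$regime == "DECOUPLED"
  expect_true(all(fmap[dec, ] == 0))
  # an atom at a density maximum feels a much smaller force than on the
  # flank (exactly zero is unattainable with a trilinear gradient)
  gmap <- rasterize(list(positions = matrix(0, 1, 3), weight = 1, width = 9),
                    32, 3)
  mk_probe <- function(x) {
    p <- atomic_model(data.frame(atom = "CA", resname = "GLY", chain = "Q",
                                 resno = 1, x = x, y = 0, z = 0,
                                 element = "C"))
    p$atoms$regime <- "FULL"
    p
  }
  f_center <- map_energy_and_forces(mk_probe(0), gmap, 1)$forces
  f_flank <- map_energy_and_forces(mk_probe(9), gmap, 1)$forces
  # the trilinear gradient is piecewise constant, so the force at the peak
  # is small but not zero (one forward-difference cell of the maximum)
  expect_lt(max(abs(f_center)), 0.35 * max(abs(f_flank)))
  # and the flank force points back toward the maximum
  expect_lt(f_flank[1, 1], 0)
})

test_that("restraints are zero at rest and harmonic away from it", {
  m <- toy_model(10)
  res <- build_restraints(m)
  re <- restraint_energy_and_forces(m, res)
  expect_equal(re$energy, 0, tolerance = 1e-18)
  expect_lt(max(abs(re$forces)), 1e-9)
  # stretching one bond by 0.1 A with k = 100 costs 0.5*100*0.01 = 0.5
  b <- res$bonds[1, ]
  xyz <- model_coords(m)
  dir <- xyz[b[1], ] - xyz[b[2], ]
  dir <- dir / sqrt(sum(dir^2))
  xyz[b[1], ] <- xyz[b[1], ] + 0.1 * dir
  only_bonds <- res
  only_bonds$angles <- res$angles[0, , drop = FALSE]
  only_bonds$theta0 <- numeric(0)
  only_bonds$en_pairs <- res$en_pairs[0, , drop = FALSE]
  only_bonds$en0 <- numeric(0)
  only_bonds$k$rep <- 0
  e <- restraint_energy_and_forces(set_coords(m, xyz), only_bonds)$energy
  expect_equal(e, 0.5 * 100 * 0.01, tolerance = 1e-6)
})

test_that("helical symmetry restraints vanish for operator-related protomers", {
  sym <- rigor_sym()
  base <- toy_model(6, chain = "A")
  moved <- base$atoms
  moved$chain <- "B"
  moved[, c("x", "y", "z")] <- transform_points(model_coords(base),
                                                symmetry_operator(sym, 1))
  m <- atomic_model(rbind(base$atoms[, names(base$atoms)], moved))
  res <- build_restraints(m, symmetry = list(sym = sym, chains = c("A", "B")))
  expect_gt(length(res$sym_groups$groups), 0)
  re <- restraint_energy_and_forces(m, res)
  expect_equal(unname(re$terms["sym"]), 0, tolerance = 1e-18)
  # displacing one protomer's Calpha raises the symmetry term
  xyz <- model_coords(m)
  ca_b <- which(m$atoms$chain == "B" & m$atoms$atom == "CA")[1]
  xyz[ca_b, ] <- xyz[ca_b, ] + c(1, 0, 0)
  re2 <- restraint_energy_and_forces(set_coords(m, xyz), res)
  expect_gt(re2$terms["sym"], 0)
})

test_that("fitting respects fixed atoms, seeds, and monotone minimization", {
  m <- ref_model_with_ligand()
  rules <- region_rules(fixed_hetatm = TRUE, variant = "LPF")
  m <- assign_regimes(m, rules)
  map <- toy_map(m, box = 48, pixel = 1.5, width = 2.8)
  res <- build_restraints(m)
  mp <- smooth_perturb(m, 1.0, seed = 2)
  # restore ligand coordinates so FIXED atoms start where they should stay
  het <- m$atoms$type == "HETATM"
  xyz <- model_coords(mp); xyz[het, ] <- model_coords(m)[het, ]
  mp <- set_coords(mp, xyz)
  sch <- fit_schedule(list(list(mode = "minimize", steps = 150, g = 0.3, lowpass = 10),
                           list(mode = "dynamics", steps = 150, g = 0.5,
                                temperature = 1e-5),
                           list(mode = "minimize", steps = 400, g = 1)), seed = 4)
  f1 <- flexfit(mp, map, restraints = res, schedule = sch)
  f2 <- flexfit(mp, map, restraints = res, schedule = sch)
  expect_identical(model_coords(f1$model), model_coords(f2$model))
  expect_identical(model_coords(f1$model)[het, ], model_coords(m)[het, ])
  # within each minimization phase the logged energy never increases
  lg <- f1$log
  for (ph in unique(lg$phase[lg$mode == "minimize"])) {
    e <- lg$energy[lg$phase == ph & lg$mode == "minimize"]
    expect_true(all(diff(e) <= 1e-6 * (1 + abs(e[-length(e)]))))
  }
  # a different dynamics seed lands in the same basin
  sch3 <- sch; sch3$seed <- 99L
  f3 <- flexfit(mp, map, restraints = res, schedule = sch3)
  expect_lt(rmsd_between(f3$model, f1$model), 0.2)
})

test_that("a 2 A smooth deformation is recovered to sub-0.5 A", {
  m <- toy_model(26)
  m$atoms$regime <- "FULL"
  res <- build_restraints(m, k_angle = 50, k_en = 1)
  map <- toy_map(m, box = 64, pixel = 1.5, width = 2.8)
  mp <- smooth_perturb(m, 2.0, seed = 23)
  expect_equal(rmsd_between(mp, m), 2.0, tolerance = 1e-9)
  ft <- flexfit(mp, map, restraints = res, schedule = fit_schedule(seed = 3))
  expect_lt(rmsd_between(ft$model, m), 0.5)
})

test_that("weight selection balances map correlation against geometry", {
  m <- toy_model(14)
  m$atoms$regime <- "FULL"
  map <- toy_map(m, box = 48, pixel = 1.5, width = 2.8)
  res <- build_restraints(m)
  mp <- smooth_perturb(m, 1.5, seed = 5)
  sch <- fit_schedule(list(list(mode = "minimize", steps = 250, g = 1)), seed = 1)
  # single-element grid returns that weight
  one <- select_weight(mp, map, res, g_grid = 2, schedule = sch)
  expect_equal(one$g, 2)
  # zero weight never wins when others correlate clearly better
  sel <- select_weight(mp, map, res, g_grid = c(0, 1), schedule = sch)
  expect_equal(sel$g, 1)
  expect_gt(sel$report$map_corr[2], 1.02 * sel$report$map_corr[1])
  # an absurdly large weight is rejected by the geometry score
  sel2 <- select_weight(mp, map, res, g_grid = c(1, 100), schedule = sch)
  expect_equal(sel2$g, 1)
  expect_gt(sel2$report$geometry_score[2], sel2$report$geometry_score[1])
})

test_that("geometry reports count clashes and deviations from rest", {
  m <- toy_model(10)
  res <- build_restraints(m)
  base <- geometry_report(m, res)
  expect_equal(base$bond_rmsd, 0, tolerance = 1e-12)
  expect_equal(base$angle_rmsd, 0, tolerance = 1e-12)
  # two non-bonded atoms forced to 1.0 A apart add exactly one clash
  m2 <- atomic_model(data.frame(atom = c("CA", "CA"), resname = "GLY",
                                chain = c("A", "B"), resno = c(1, 1),
                                x = c(0, 1), y = 0, z = 0, element = "C"))
  r2 <- build_restraints(m2, bond_cutoff = 0.5)
  expect_equal(geometry_report(m2, r2)$clashes, 1L)
  # permutation invariance
  perm <- sample(nrow(m$atoms))
  m3 <- m; m3$atoms <- m$atoms[perm, ]
  r3 <- build_restraints(m3)
  g3 <- geometry_report(m3, r3)
  expect_equal(g3$clashes, base$clashes)
})

test_that("backbone averaging truncates side chains and averages equivalents", {
  m <- toy_model(8)
  avg1 <- backbone_average(list(m, m, m))
  keep <- m$atoms$atom %in% c("N", "CA", "C", "O", "OXT", "CB")
  expect_equal(model_coords(avg1), model_coords(m)[keep, ], ignore_attr = TRUE)
  expect_true(all(avg1$atoms$atom %in% c("N", "CA", "C", "O", "CB")))
  # midpoint of a model and its +2 A translated copy, without superposition
  shifted <- set_coords(m, sweep(model_coords(m), 2, c(2, 0, 0), `+`))
  mid <- backbone_average(list(m, shifted), superpose = FALSE)
  expect_equal(model_coords(mid),
               model_coords(m)[keep, ] + matrix(rep(c(1, 0, 0), each = sum(keep)),
                                                ncol = 3),
               ignore_attr = TRUE)
  # order invariance
  mid2 <- backbone_average(list(shifted, m), superpose = FALSE)
  expect_equal(model_coords(mid2), model_coords(mid), ignore_attr = TRUE)
  bad <- toy_model(9)
  expect_error(backbone_average(list(m, bad)), "topology")
})
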