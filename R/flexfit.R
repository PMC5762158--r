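BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
LARGE_SIDECHAIN <- c("PHE", "TYR", "TRP", "HIS", "ARG", "GLN", "LYS", "MET")

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, MG = 24.305, FE = 55.845, ZN = 65.38,
                  CA = 40.078, K = 39.098, `NA` = 22.99)
VDW_RADIUS <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
                MG = 1.73, FE = 1.6, ZN = 1.39, CA = 2.3, K = 2.75,
                `NA` = 2.27)

element_mass <- function(el) {
  m <- ELEMENT_MASS[toupper(el)]
  ifelse(is.na(m), 12.011, m)
}

vdw_radius <- function(el) {
  r <- VDW_RADIUS[toupper(el)]
  ifelse(is.na(r), 1.7, r)
}

#' Region rules for coupling-regime assignment
#'
#' Declares which chains are actin (eligible for large-side-chain FULL
#' coupling in the high-resolution variant), which residue ranges are
#' decoupled from the map (conformationally variable loops with no density),
#' and whether HETATM ligands/ions are held fixed. The bundled myosin VI
#' preset decouples loop 2 (residues 622-636) and the HCM-loop tip
#' (residues 397-405) of the motor chains.
#'
#' @param actin_chains chain ids treated as actin
#' @param decoupled data.frame with columns chain, from, to (residue ranges
#'   whose density term is disabled); NULL for none
#' @param fixed_hetatm hold HETATM records (nucleotide, ions) immobile
#' @param variant "HR" (actin large side chains feel the map) or "LPF"
#'   (backbone-only coupling everywhere)
#' @return object of class `region_rules`
#' @export
region_rules <- function(actin_chains = character(), decoupled = NULL,
                         fixed_hetatm = TRUE, variant = c("HR", "LPF")) {
  variant <- match.arg(variant)
  if (!is.null(decoupled))
    stopifnot(all(c("chain", "from", "to") %in% names(decoupled)),
              all(decoupled$from <= decoupled$to))
  structure(list(actin_chains = actin_chains, decoupled = decoupled,
                 fixed_hetatm = fixed_hetatm, variant = variant),
            class = "region_rules")
}

#' Myosin VI region-rule preset
#' @param motor_chains chain ids of the motor domains
#' @param actin_chains chain ids of the actin protomers
#' @param variant "HR" or "LPF"
#' @return a [region_rules()] with loop 2 (622-636) and the HCM-loop tip
#'   (397-405) decoupled on every motor chain
#' @export
myosin6_rules <- function(motor_chains, actin_chains, variant = "HR") {
  dec <- do.call(rbind, lapply(motor_chains, function(ch)
    data.frame(chain = ch, from = c(622, 397), to = c(636, 405))))
  region_rules(actin_chains = actin_chains, decoupled = dec,
               fixed_hetatm = TRUE, variant = variant)
}

#' Assign per-atom coupling regimes
#'
#' Every atom receives exactly one regime: FIXED (HETATM ligands/ions,
#' immobile), DECOUPLED (listed loop ranges and, implicitly, side chains
#' that do not feel the map), BACKBONE (backbone atoms guided by the map),
#' or FULL (all atoms of large-side-chain residues in actin chains, HR
#' variant only).
#'
#' @param model an [atomic_model()]
#' @param rules a [region_rules()]
#' @return model with updated `regime` and `mobile` columns
#' @export
assign_regimes <- function(model, rules) {
  a <- model$atoms
  bb <- a$atom %in% BACKBONE_ATOMS
  reg <- ifelse(bb, "BACKBONE", "DECOUPLED")
  if (rules$variant == "HR" && length(rules$actin_chains)) {
    full <- a$chain %in% rules$actin_chains & a$resname %in% LARGE_SIDECHAIN &
            a$type == "ATOM"
    reg[full] <- "FULL"
  }
  if (!is.null(rules$decoupled)) {
    for (i in seq_len(nrow(rules$decoupled))) {
      r <- rules$decoupled[i, ]
      hit <- a$chain == r$chain & a$resno >= r$from & a$resno <= r$to
      if (!any(a$chain == r$chain &
               a$resno >= r$from & a$resno <= r$to & a$atom == "CA") &&
          !any(hit))
        stop(sprintf("assign_regimes: rule %s %d-%d matches no residues",
                     r$chain, r$from, r$to))
      reg[hit] <- "DECOUPLED"
    }
  }
  mobile <- rep(TRUE, nrow(a))
  if (rules$fixed_hetatm) {
    het <- a$type == "HETATM"
    reg[het] <- "FIXED"
    mobile[het] <- FALSE
  }
  model$atoms$regime <- reg
  model$atoms$mobile <- mobile
  model
}

# which atoms feel the map potential
map_coupled <- function(model) {
  a <- model$atoms
  a$regime == "FULL" | (a$regime == "BACKBONE" & a$atom %in% BACKBONE_ATOMS)
}

#' Map energy and forces on an atomic model
#'
#' `E = -g * sum_i w_i * rho(x_i)` over map-coupled atoms, with `w_i` the
#' element mass and `rho` the trilinearly interpolated density; the force on
#' a coupled atom is `g * w_i * grad(rho)`. DECOUPLED and FIXED atoms feel
#' nothing. Atoms outside the grid are clamped to the box with a warning.
#'
#' @param model an [atomic_model()] with regimes assigned
#' @param map a [density_volume()]
#' @param g map weighting factor (>= 0)
#' @return list with `energy` (scalar) and `forces` (n x 3, zero rows for
#'   uncoupled atoms)
#' @export
map_energy_and_forces <- function(model, map, g) {
  a <- model$atoms
  n <- nrow(a)
  forces <- matrix(0, n, 3)
  coupled <- map_coupled(model)
  if (!any(coupled) || g == 0)
    return(list(energy = 0, forces = forces))
  xyz <- model_coords(model, coupled)
  d <- dim(map$data)
  px <- map$pixel_size
  ix <- phys_to_index(xyz[, 1], d[1], px)
  iy <- phys_to_index(xyz[, 2], d[2], px)
  iz <- phys_to_index(xyz[, 3], d[3], px)
  lo <- 1 + 1e-6
  clamp <- ix < lo | ix > d[1] - lo | iy < lo | iy > d[2] - lo |
           iz < lo | iz > d[3] - lo
  if (any(clamp)) {
    warning(sprintf("map_energy_and_forces: %d atom(s) outside the grid; clamped",
                    sum(clamp)))
    ix <- pmin(pmax(ix, lo), d[1] - lo)
    iy <- pmin(pmax(iy, lo), d[2] - lo)
    iz <- pmin(pmax(iz, lo), d[3] - lo)
  }
  w <- element_mass(a$element[coupled])
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  gval <- function(dx, dy, dz) map$data[cbind(x0 + dx, y0 + dy, z0 + dz)]
  c000 <- gval(0L,0L,0L); c100 <- gval(1L,0L,0L); c010 <- gval(0L,1L,0L)
  c110 <- gval(1L,1L,0L); c001 <- gval(0L,0L,1L); c101 <- gval(1L,0L,1L)
  c011 <- gval(0L,1L,1L); c111 <- gval(1L,1L,1L)
  rho <- c000*(1-fx)*(1-fy)*(1-fz) + c100*fx*(1-fy)*(1-fz) +
         c010*(1-fx)*fy*(1-fz) + c110*fx*fy*(1-fz) +
         c001*(1-fx)*(1-fy)*fz + c101*fx*(1-fy)*fz +
         c011*(1-fx)*fy*fz + c111*fx*fy*fz
  drho_dx <- (-(c000)*(1-fy)*(1-fz) + c100*(1-fy)*(1-fz) - c010*fy*(1-fz) +
              c110*fy*(1-fz) - c001*(1-fy)*fz + c101*(1-fy)*fz -
              c011*fy*fz + c111*fy*fz) / px
  drho_dy <- (-(c000)*(1-fx)*(1-fz) - c100*fx*(1-fz) + c010*(1-fx)*(1-fz) +
              c110*fx*(1-fz) - c001*(1-fx)*fz - c101*fx*fz +
              c011*(1-fx)*fz + c111*fx*fz) / px
  drho_dz <- (-(c000)*(1-fx)*(1-fy) - c100*fx*(1-fy) - c010*(1-fx)*fy -
              c110*fx*fy + c001*(1-fx)*(1-fy) + c101*fx*(1-fy) +
              c011*(1-fx)*fy + c111*fx*fy) / px
  energy <- -g * sum(w * rho)
  forces[coupled, ] <- g * w * cbind(drho_dx, drho_dy, drho_dz)
  list(energy = energy, forces = forces)
}

#' Build a restraint set from a model's starting geometry
#'
#' Harmonic bonds (heavy-atom pairs within the covalent cutoff), angles
#' (bonded triples), an elastic network over Calpha atoms (all atoms when no
#' Calpha is present) within `en_cutoff`, soft-core steric repulsion, and
#' optional helical symmetry restraints tying equivalent actin Calpha
#' across protomers. All rest values are taken from the input geometry, so
#' the restraint energy of the starting model is exactly zero.
#'
#' @param model an [atomic_model()]
#' @param bond_cutoff covalent bond detection distance, A
#' @param en_cutoff elastic-network cutoff, A (default 10)
#' @param k_bond,k_angle,k_en,k_rep,k_sym force constants (model units)
#' @param rep_dist soft-core repulsion onset distance, A
#' @param symmetry optional list(sym = [helical_symmetry()], chains =
#'   actin chain ids in protomer order) enabling Calpha symmetry restraints
#' @return object of class `restraint_set`
#' @export
build_restraints <- function(model, bond_cutoff = 1.9, en_cutoff = 10,
                             k_bond = 100, k_angle = 20, k_en = 0.5,
                             k_rep = 10, k_sym = 5, rep_dist = 2.6,
                             symmetry = NULL) {
  a <- model$atoms
  xyz <- model_coords(model)
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  heavy <- a$element != "H"
  bonds <- which(dm > 0 & dm <= bond_cutoff & upper.tri(dm), arr.ind = TRUE)
  # exclude spurious bonds between different chains' termini
  keep <- a$chain[bonds[, 1]] == a$chain[bonds[, 2]]
  bonds <- bonds[keep, , drop = FALSE]
  b0 <- dm[bonds]
  # angles: bonded triples i-j-k
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      ang[[length(ang) + 1]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    matrix(integer(0), 0, 3)
  theta0 <- if (nrow(angles)) angle_values(xyz, angles) else numeric(0)
  # elastic network over heavy atoms within the cutoff (pins the internal
  # structure, which bonds and angles alone leave torsionally degenerate)
  en_idx <- which(heavy)
  if (length(en_idx) < 2) en_idx <- seq_len(n)
  sub <- dm[en_idx, en_idx, drop = FALSE]
  enp <- which(sub > bond_cutoff & sub <= en_cutoff & upper.tri(sub),
               arr.ind = TRUE)
  en_pairs <- cbind(en_idx[enp[, 1]], en_idx[enp[, 2]])
  en0 <- sub[enp]
  # 1-2 and 1-3 topological exclusions (used by the clash report), plus
  # contacts already closer than the repulsion onset in the rest geometry
  # (excluded from the repulsion term so the rest energy is exactly zero)
  excl_topo <- rbind(bonds, angles[, c(1, 3), drop = FALSE])
  excl <- excl_topo
  hv0 <- which(heavy)
  if (length(hv0) >= 2) {
    sub0 <- dm[hv0, hv0, drop = FALSE]
    close0 <- which(sub0 > 0 & sub0 < rep_dist & upper.tri(sub0),
                    arr.ind = TRUE)
    if (nrow(close0))
      excl <- rbind(excl, cbind(hv0[close0[, 1]], hv0[close0[, 2]]))
  }
  sym_groups <- NULL
  if (!is.null(symmetry)) {
    sym_groups <- make_symmetry_groups(model, symmetry$sym, symmetry$chains)
  }
  structure(list(bonds = bonds, b0 = b0, angles = angles, theta0 = theta0,
                 en_pairs = en_pairs, en0 = en0,
                 excl = excl, excl_topo = excl_topo, heavy = heavy,
                 k = list(bond = k_bond, angle = k_angle, en = k_en,
                          rep = k_rep, sym = k_sym),
                 rep_dist = rep_dist, sym_groups = sym_groups,
                 symmetry = symmetry),
            class = "restraint_set")
}

# Calpha groups related by the helical operator; chains listed in protomer
# order so chain m maps into chain-0 frame by operator(-m)
make_symmetry_groups <- function(model, sym, chains) {
  a <- model$atoms
  groups <- list()
  resnos <- sort(unique(a$resno[a$chain == chains[1] & a$atom == "CA"]))
  for (rn in resnos) {
    idx <- integer(0); ops <- integer(0)
    for (m in seq_along(chains)) {
      i <- which(a$chain == chains[m] & a$resno == rn & a$atom == "CA")
      if (length(i) == 1) { idx <- c(idx, i); ops <- c(ops, m - 1L) }
    }
    if (length(idx) >= 2)
      groups[[length(groups) + 1]] <- list(idx = idx, k = ops)
  }
  list(groups = groups, sym = sym)
}

angle_values <- function(xyz, triples) {
  u <- xyz[triples[, 1], , drop = FALSE] - xyz[triples[, 2], , drop = FALSE]
  v <- xyz[triples[, 3], , drop = FALSE] - xyz[triples[, 2], , drop = FALSE]
  cu <- sqrt(rowSums(u^2)); cv <- sqrt(rowSums(v^2))
  ct <- rowSums(u * v) / (cu * cv)
  acos(pmax(-1, pmin(1, ct)))
}

#' Restraint energy and forces
#'
#' Harmonic bond/angle/elastic-network terms (zero at the rest geometry),
#' soft-core repulsion between non-bonded heavy atoms, and the helical
#' symmetry term penalizing deviation between operator-mapped equivalent
#' actin Calpha positions.
#'
#' @param model an [atomic_model()]
#' @param restraints a [build_restraints()] set
#' @return list with `energy`, `forces` (n x 3) and `terms` (named energies)
#' @export
restraint_energy_and_forces <- function(model, restraints) {
  xyz <- model_coords(model)
  n <- nrow(xyz)
  forces <- matrix(0, n, 3)
  k <- restraints$k
  terms <- c(bond = 0, angle = 0, en = 0, rep = 0, sym = 0)
  add_pair <- function(pairs, d0, kk) {
    if (!nrow(pairs)) return(0)
    dvec <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    dd <- d - d0
    e <- 0.5 * kk * sum(dd^2)
    fmag <- kk * dd / pmax(d, 1e-9)
    fv <- dvec * fmag
    for (c in 1:3) {
      forces[, c] <<- forces[, c] -
        tabulate_add(pairs[, 1], fv[, c], n) +
        tabulate_add(pairs[, 2], fv[, c], n)
    }
    e
  }
  terms["bond"] <- add_pair(restraints$bonds, restraints$b0, k$bond)
  terms["en"] <- add_pair(restraints$en_pairs, restraints$en0, k$en)
  if (nrow(restraints$angles)) {
    tr <- restraints$angles
    u <- xyz[tr[, 1], , drop = FALSE] - xyz[tr[, 2], , drop = FALSE]
    v <- xyz[tr[, 3], , drop = FALSE] - xyz[tr[, 2], , drop = FALSE]
    lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
    ct <- rowSums(u * v) / (lu * lv)
    ct <- pmax(-1 + 1e-9, pmin(1 - 1e-9, ct))
    th <- acos(ct)
    st <- sqrt(1 - ct^2)
    dth <- th - restraints$theta0
    terms["angle"] <- 0.5 * k$angle * sum(dth^2)
    # dtheta/dxi = -(vhat - ct*uhat)/(lu*st); symmetric for xk
    uh <- u / lu; vh <- v / lv
    gi <- -(vh - ct * uh) / (lu * st)
    gk <- -(uh - ct * vh) / (lv * st)
    gj <- -(gi + gk)
    coefv <- k$angle * dth
    for (c in 1:3) {
      forces[, c] <- forces[, c] -
        tabulate_add(tr[, 1], coefv * gi[, c], n) -
        tabulate_add(tr[, 2], coefv * gj[, c], n) -
        tabulate_add(tr[, 3], coefv * gk[, c], n)
    }
  }
  # soft-core repulsion among heavy atoms, excluding 1-2/1-3 pairs
  hv <- which(restraints$heavy)
  if (length(hv) >= 2) {
    sub <- as.matrix(stats::dist(xyz[hv, , drop = FALSE]))
    cand <- which(sub > 0 & sub < restraints$rep_dist & upper.tri(sub),
                  arr.ind = TRUE)
    if (nrow(cand)) {
      pairs <- cbind(hv[cand[, 1]], hv[cand[, 2]])
      keyp <- paste(pmin(pairs[, 1], pairs[, 2]),
                    pmax(pairs[, 1], pairs[, 2]))
      keyx <- paste(pmin(restraints$excl[, 1], restraints$excl[, 2]),
                    pmax(restraints$excl[, 1], restraints$excl[, 2]))
      keep <- !(keyp %in% keyx)
      pairs <- pairs[keep, , drop = FALSE]
      if (nrow(pairs)) {
        dvec <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
        d <- sqrt(rowSums(dvec^2))
        pen <- restraints$rep_dist - d
        terms["rep"] <- 0.5 * k$rep * sum(pen^2)
        fmag <- -k$rep * pen / pmax(d, 1e-9) # repulsive: pushes apart
        fv <- dvec * fmag
        for (c in 1:3) {
          forces[, c] <- forces[, c] -
            tabulate_add(pairs[, 1], fv[, c], n) +
            tabulate_add(pairs[, 2], fv[, c], n)
        }
      }
    }
  }
  if (!is.null(restraints$sym_groups)) {
    sg <- restraints$sym_groups
    for (g in sg$groups) {
      y <- matrix(0, length(g$idx), 3)
      Rs <- list()
      for (m in seq_along(g$idx)) {
        op <- invert_transform(symmetry_operator(sg$sym, g$k[m]))
        Rs[[m]] <- op$rotation
        y[m, ] <- transform_points(xyz[g$idx[m], , drop = FALSE], op)
      }
      ybar <- colMeans(y)
      dev <- sweep(y, 2, ybar)
      terms["sym"] <- terms["sym"] + 0.5 * k$sym * sum(dev^2)
      for (m in seq_along(g$idx)) {
        grad <- k$sym * as.numeric(t(Rs[[m]]) %*% dev[m, ])
        forces[g$idx[m], ] <- forces[g$idx[m], ] - grad
      }
    }
  }
  list(energy = sum(terms), forces = forces, terms = terms)
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  s <- tapply(vals, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Fitting schedule
#'
#' Ordered phases of minimization or stochastic dynamics. The canonical
#' three-phase schedule mirrors common flexible-fitting practice: a brief
#' minimization to relieve severe clashes, a dynamics stage at low map
#' weight to escape local traps, and a longer minimization at higher map
#' weight to settle into density.
#'
#' Phases may carry a `lowpass` (A): the map is filtered to that resolution
#' for the phase, giving the multi-resolution annealing that funnels a
#' far-from-density start into the right register before full-resolution
#' refinement.
#'
#' @param phases list of phases, each `list(mode = "minimize"|"dynamics",
#'   steps =, g =, temperature =, lowpass =)` (temperature only for
#'   dynamics; lowpass optional, default none)
#' @param seed RNG seed for the dynamics phases
#' @return object of class `fit_schedule`
#' @export
fit_schedule <- function(phases = list(
                           list(mode = "minimize", steps = 200, g = 0.3,
                                lowpass = 12),
                           list(mode = "dynamics", steps = 400, g = 0.5,
                                temperature = 1e-5, lowpass = 8),
                           list(mode = "minimize", steps = 2000, g = 1.0)),
                         seed = 1) {
  stopifnot(length(phases) >= 1)
  for (p in phases) stopifnot(p$steps > 0, p$mode %in% c("minimize", "dynamics"))
  structure(list(phases = phases, seed = as.integer(seed)),
            class = "fit_schedule")
}

#' Flexible fitting of an atomic model into a density map
#'
#' Runs the phases of a [fit_schedule()] in order: minimization is damped
#' steepest descent with backtracking step-size control (the combined
#' map + restraint energy never increases within a minimization phase);
#' dynamics is Langevin-style stochastic descent at the given temperature,
#' seeded and reproducible. FIXED atoms never move. Aborts with a
#' diagnostic if the energy diverges.
#'
#' @param model an [atomic_model()] with regimes assigned
#' @param map target [density_volume()]
#' @param restraints a [build_restraints()] set (built from `model` if NULL)
#' @param schedule a [fit_schedule()]
#' @param checkpoint_every log interval in steps
#' @return object of class `flexfit`: `model` (fitted), `start` (input),
#'   `log` (energy checkpoints), `schedule`, `map_corr_fun` support via
#'   [rasterize_model()]
#' @export
flexfit <- function(model, map, restraints = NULL, schedule = fit_schedule(),
                    checkpoint_every = 50) {
  if (is.null(restraints)) restraints <- build_restraints(model)
  set.seed(schedule$seed)
  xyz <- model_coords(model)
  mobile <- model$atoms$mobile & model$atoms$regime != "FIXED"
  mass <- element_mass(model$atoms$element)
  logs <- list()
  total_energy <- function(m) {
    me <- map_energy_and_forces(m, map_now, g_now)
    re <- restraint_energy_and_forces(m, restraints)
    list(e = me$energy + re$energy, f = me$forces + re$forces,
         map_e = me$energy, res_e = re$energy)
  }
  cur <- model
  for (pi in seq_along(schedule$phases)) {
    ph <- schedule$phases[[pi]]
    g_now <- ph$g
    map_now <- if (!is.null(ph$lowpass) && is.finite(ph$lowpass))
      lowpass_volume(map, ph$lowpass) else map
    st <- total_energy(cur)
    e_start <- st$e
    if (ph$mode == "minimize") {
      # quasi-Newton minimization over the mobile coordinates, chunked so
      # the energy trajectory is logged at intermediate checkpoints
      midx <- which(mobile)
      fn <- function(p) {
        xyz <- model_coords(cur)
        xyz[midx, ] <- matrix(p, ncol = 3)
        total_energy(set_coords(cur, xyz))$e
      }
      grf <- function(p) {
        xyz <- model_coords(cur)
        xyz[midx, ] <- matrix(p, ncol = 3)
        -total_energy(set_coords(cur, xyz))$f[midx, ]
      }
      chunks <- max(1L, min(4L, ph$steps %/% 100L))
      per <- ceiling(ph$steps / chunks)
      for (ck in seq_len(chunks)) {
        opt <- optim(as.numeric(model_coords(cur)[midx, ]), fn, grf,
                     method = "L-BFGS-B",
                     control = list(maxit = per, factr = 1e4))
        xyz <- model_coords(cur)
        xyz[midx, ] <- matrix(opt$par, ncol = 3)
        cur <- set_coords(cur, xyz)
        st <- total_energy(cur)
        logs[[length(logs) + 1]] <- data.frame(
          phase = pi, mode = ph$mode, step = ck * per, g = g_now,
          energy = st$e, map_energy = st$map_e, restraint_energy = st$res_e)
      }
      if (st$e > e_start + abs(e_start) * 1e-8 + 1e-8)
        stop("flexfit: minimization increased the energy; diverged")
    } else {
      step <- 1e-3
      for (s in seq_len(ph$steps)) {
        f <- st$f
        f[!mobile, ] <- 0
        noise <- matrix(rnorm(length(f), 0, sqrt(2 * ph$temperature * step)),
                        ncol = 3)
        noise[!mobile, ] <- 0
        cur <- set_coords(cur, model_coords(cur) + step * f + noise)
        st <- total_energy(cur)
        if (!is.finite(st$e) || st$e > abs(e_start) * 1e4 + 1e6)
          stop("flexfit: dynamics diverged (energy blew up); reduce g or temperature")
        if (s %% checkpoint_every == 0 || s == ph$steps)
          logs[[length(logs) + 1]] <- data.frame(
            phase = pi, mode = ph$mode, step = s, g = g_now,
            energy = st$e, map_energy = st$map_e, restraint_energy = st$res_e)
      }
    }
  }
  structure(list(model = cur, start = model, log = do.call(rbind, logs),
                 schedule = schedule, restraints = restraints, map = map),
            class = "flexfit")
}

#' @export
print.flexfit <- function(x, ...) {
  lg <- x$log
  cat(sprintf("Flexible fit: %d atoms, %d phases, final energy %.4g\n",
              nrow(x$model$atoms), length(x$schedule$phases),
              lg$energy[nrow(lg)]))
  invisible(x)
}

#' @export
summary.flexfit <- function(object, ...) {
  print(object)
  gr <- geometry_report(object$model, object$restraints)
  cat(sprintf("  clashes: %d; bond RMSD %.4f A; angle RMSD %.3f deg\n",
              gr$clashes, gr$bond_rmsd, gr$angle_rmsd))
  disp <- sqrt(mean(rowSums((model_coords(object$model) -
                             model_coords(object$start))^2)))
  cat(sprintf("  RMSD moved from start: %.3f A\n", disp))
  invisible(gr)
}

#' @export
plot.flexfit <- function(x, ...) {
  lg <- x$log
  plot(seq_len(nrow(lg)), lg$energy, type = "l", xlab = "checkpoint",
       ylab = "total energy", main = "Flexible-fitting energy", ...)
  invisible(x)
}

#' @export
coef.flexfit <- function(object, ...) model_coords(object$model)

#' @export
fitted.flexfit <- function(object, ...) object$model

#' Rasterize an atomic model into a density volume
#'
#' Gaussian per atom (sigma = `width`), amplitude proportional to element
#' mass; used for model-to-map correlation scoring.
#'
#' @param model an [atomic_model()]
#' @param box,pixel_size grid geometry
#' @param width Gaussian sigma, A
#' @return a [density_volume()]
#' @export
rasterize_model <- function(model, box, pixel_size, width = 2) {
  xyz <- model_coords(model)
  rasterize(list(positions = xyz,
                 weight = element_mass(model$atoms$element),
                 width = rep(width, nrow(xyz))),
            box, pixel_size, clip = TRUE)
}

#' Select the map weighting factor
#'
#' Runs the schedule once per candidate weight g, scores each fit by map
#' correlation (model rasterization vs target map) and by geometry quality
#' (clash count plus bond/angle RMS deviation), and returns the g with the
#' best geometry among fits whose map correlation is within 2 percent of
#' the best.
#'
#' @param model,map,restraints as in [flexfit()]
#' @param g_grid candidate weights (>= 1 value)
#' @param schedule template [fit_schedule()]; each phase's g is multiplied
#'   by the candidate weight
#' @return list with `g` (selected), `report` (per-candidate data.frame),
#'   `fits` (list of flexfit objects)
#' @export
select_weight <- function(model, map, restraints = NULL,
                          g_grid = c(0.3, 1, 3), schedule = fit_schedule()) {
  stopifnot(length(g_grid) >= 1)
  if (is.null(restraints)) restraints <- build_restraints(model)
  fits <- list(); rows <- list()
  for (i in seq_along(g_grid)) {
    g <- g_grid[i]
    sch <- schedule
    sch$phases <- lapply(sch$phases, function(p) { p$g <- p$g * g; p })
    ft <- tryCatch(flexfit(model, map, restraints, sch),
                   error = function(e) NULL)
    fits[[i]] <- ft
    if (is.null(ft)) {
      rows[[i]] <- data.frame(g = g, map_corr = NA, clashes = NA,
                              bond_rmsd = NA, angle_rmsd = NA,
                              geometry_score = Inf, diverged = TRUE)
      next
    }
    d <- dim(map$data)[1]
    mvol <- rasterize_model(ft$model, d, map$pixel_size)
    mc <- cor(as.numeric(mvol$data), as.numeric(map$data))
    gr <- geometry_report(ft$model, restraints)
    score <- gr$clashes + 100 * gr$bond_rmsd + gr$angle_rmsd
    rows[[i]] <- data.frame(g = g, map_corr = mc, clashes = gr$clashes,
                            bond_rmsd = gr$bond_rmsd,
                            angle_rmsd = gr$angle_rmsd,
                            geometry_score = score, diverged = FALSE)
  }
  rep <- do.call(rbind, rows)
  if (all(rep$diverged)) stop("select_weight: all candidate fits diverged")
  ok <- !rep$diverged
  best_corr <- max(rep$map_corr[ok])
  eligible <- ok & rep$map_corr >= 0.98 * best_corr
  sel <- which(eligible)[which.min(rep$geometry_score[eligible])]
  list(g = rep$g[sel], report = rep, fits = fits)
}

#' Lightweight geometry-quality report
#'
#' Clashes are non-bonded heavy-atom pairs closer than 0.4 A below the sum
#' of their van der Waals radii; bond and angle RMS deviations are measured
#' against the rest geometry of the restraint set. Permutation-invariant in
#' atom order.
#'
#' @param model an [atomic_model()]
#' @param restraints a [build_restraints()] set (built from `model` if
#'   NULL, in which case deviations are zero by construction)
#' @return list with `clashes`, `bond_rmsd` (A), `angle_rmsd` (degrees)
#' @export
geometry_report <- function(model, restraints = NULL) {
  if (is.null(restraints)) restraints <- build_restraints(model)
  xyz <- model_coords(model)
  a <- model$atoms
  hv <- which(a$element != "H")
  clashes <- 0L
  if (length(hv) >= 2) {
    sub <- as.matrix(stats::dist(xyz[hv, , drop = FALSE]))
    rad <- vdw_radius(a$element[hv])
    lim <- outer(rad, rad, `+`) - 0.4
    cand <- which(sub > 0 & sub < lim & upper.tri(sub), arr.ind = TRUE)
    if (nrow(cand)) {
      pairs <- cbind(hv[cand[, 1]], hv[cand[, 2]])
      et <- if (!is.null(restraints$excl_topo)) restraints$excl_topo
            else restraints$excl
      keyp <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      keyx <- paste(pmin(et[, 1], et[, 2]), pmax(et[, 1], et[, 2]))
      clashes <- sum(!(keyp %in% keyx))
    }
  }
  bond_rmsd <- if (nrow(restraints$bonds)) {
    dvec <- xyz[restraints$bonds[, 1], , drop = FALSE] -
            xyz[restraints$bonds[, 2], , drop = FALSE]
    sqrt(mean((sqrt(rowSums(dvec^2)) - restraints$b0)^2))
  } else 0
  angle_rmsd <- if (nrow(restraints$angles)) {
    th <- angle_values(xyz, restraints$angles)
    sqrt(mean((th - restraints$theta0)^2)) * 180 / pi
  } else 0
  list(clashes = as.integer(clashes), bond_rmsd = bond_rmsd,
       angle_rmsd = angle_rmsd)
}

#' Backbone-average equivalent models
#'
#' Averages backbone (and Cbeta) atom positions over models of identical
#' topology, optionally superposing each onto the first on backbone Calpha
#' before averaging; side chains are truncated beyond Cbeta (poly-alanine
#' style representation for low-resolution comparison).
#'
#' @param models list of [atomic_model()]s with identical
#'   (chain, resno, atom) topology
#' @param superpose superpose each model onto the first (Kabsch on Calpha)
#'   before averaging (default FALSE: inputs are already in a common frame)
#' @return averaged [atomic_model()] containing N/CA/C/O/CB atoms only
#' @export
backbone_average <- function(models, superpose = FALSE) {
  stopifnot(length(models) >= 1)
  keyof <- function(m) paste(m$atoms$chain, m$atoms$resno, m$atoms$atom)
  ref <- models[[1]]
  k0 <- keyof(ref)
  keep <- ref$atoms$atom %in% c(BACKBONE_ATOMS, "CB") & ref$atoms$type == "ATOM"
  acc <- matrix(0, sum(keep), 3)
  for (m in models) {
    if (!identical(keyof(m), k0))
      stop("backbone_average: topology mismatch between models")
    xyz <- model_coords(m)
    if (superpose && !identical(m, ref)) {
      ca <- ref$atoms$atom == "CA"
      sp <- superpose(model_coords(ref, ca), model_coords(m, ca))
      xyz <- transform_points(xyz, sp$transform)
    }
    acc <- acc + xyz[keep, , drop = FALSE]
  }
  out <- ref
  out$atoms <- ref$atoms[keep, , drop = FALSE]
  out <- set_coords(out, acc / length(models))
  out
}
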