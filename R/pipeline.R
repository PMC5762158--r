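load_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

cfg_get <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

# write the resolved config + provenance record into the output directory
write_provenance <- function(config, out_dir, stage) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, paste0(stage, "_config.json"))
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  prov <- list(stage = stage, config_md5 = unname(tools::md5sum(cfg_path)),
               seed = cfg_get(config, "seed", NA),
               package_version = as.character(utils::packageVersion("helicalem")))
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path)
}

#' Write a segment stack to disk (MRC images + TSV metadata)
#' @param stack a `segment_stack`
#' @param prefix output path prefix (creates `<prefix>_stack.mrc`,
#'   `<prefix>_meta.tsv`, `<prefix>_stackinfo.json`)
#' @return prefix, invisibly
#' @export
write_stack <- function(stack, prefix) {
  write_mrc(density_volume(stack$images, stack$pixel_size),
            paste0(prefix, "_stack.mrc"))
  write_table_tsv(stack$meta, paste0(prefix, "_meta.tsv"))
  info <- list(pixel_size = stack$pixel_size, box = stack$box,
               step = stack$step, asu_per_segment = stack$asu_per_segment,
               seed = stack$seed,
               ctf = if (is.null(stack$ctf)) NULL else unclass(stack$ctf))
  jsonlite::write_json(info, paste0(prefix, "_stackinfo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a segment stack written by [write_stack()]
#' @param prefix path prefix
#' @return a `segment_stack`
#' @export
read_stack <- function(prefix) {
  vol <- read_mrc(paste0(prefix, "_stack.mrc"))
  meta <- read_table_tsv(paste0(prefix, "_meta.tsv"))
  info <- jsonlite::read_json(paste0(prefix, "_stackinfo.json"),
                              simplifyVector = TRUE)
  ctf <- if (is.null(info$ctf)) NULL else
    do.call(ctf_params, info$ctf[c("voltage", "defocus",
                                   "spherical_aberration",
                                   "amplitude_contrast", "pixel_size")])
  meta$half_set <- suppressWarnings(as.integer(meta$half_set))
  meta$included <- as.logical(meta$included)
  structure(list(images = vol$data, meta = meta,
                 pixel_size = info$pixel_size, box = info$box,
                 step = info$step, asu_per_segment = info$asu_per_segment,
                 seed = info$seed, ctf = ctf),
            class = "segment_stack")
}

#' Pipeline stage: simulate a segment stack
#'
#' Config fields (all optional except `out_dir`): seed, rise, twist, box,
#' pixel_size, step, n_filaments, n_subunits, snr, decorated, ctf (logical).
#'
#' @param config list or JSON path
#' @return output prefix, invisibly; writes stack, ground truth and
#'   provenance under `out_dir`
#' @export
pipeline_simulate <- function(config) {
  config <- load_config(config)
  out <- cfg_get(config, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sym <- helical_symmetry(cfg_get(config, "rise", 28.06),
                          cfg_get(config, "twist", -166.73))
  px <- cfg_get(config, "pixel_size", 2.5)
  use_ctf <- cfg_get(config, "ctf", TRUE)
  sim <- simulate_segments(
    subunit = default_subunit(cfg_get(config, "decorated", TRUE)),
    sym = sym,
    ctf = if (use_ctf) ctf_params(pixel_size = px) else NULL,
    box = cfg_get(config, "box", 64),
    step = cfg_get(config, "step", 81),
    n_filaments = cfg_get(config, "n_filaments", 20),
    snr = cfg_get(config, "snr", 5),
    seed = cfg_get(config, "seed", 1),
    n_subunits = cfg_get(config, "n_subunits", 24),
    pixel_size = px)
  prefix <- file.path(out, "segments")
  write_stack(sim$stack, prefix)
  write_table_tsv(sim$truth, file.path(out, "ground_truth.tsv"))
  write_provenance(config, out, "simulate")
  invisible(prefix)
}

#' Pipeline stage: reconstruct from a segment stack
#'
#' Runs the half-set refinement (and polishing) on a stack written by
#' [pipeline_simulate()]. With `fixed_symmetry = c(rise, twist)` in the
#' config the parameter search is skipped and a single fixed-symmetry
#' alignment/reconstruction pass is run. Re-running with an unchanged
#' config resumes by returning the existing completed outputs.
#'
#' @param config list or JSON path; fields: stack_prefix, out_dir, seed,
#'   rise, twist (search start), n_iterations, phi_step, psi_step,
#'   theta_step, shift_range, polish, fixed_symmetry
#' @return list with the fit's log, invisibly; writes half maps, final map,
#'   iteration log and per-segment parameters
#' @export
pipeline_reconstruct <- function(config) {
  config <- load_config(config)
  out <- cfg_get(config, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  done_flag <- file.path(out, "reconstruct_done.json")
  cfg_path <- write_provenance(config, out, "reconstruct")
  if (file.exists(done_flag)) {
    prev <- jsonlite::read_json(done_flag, simplifyVector = TRUE)
    if (identical(prev$config_md5, unname(tools::md5sum(cfg_path)))) {
      message("pipeline_reconstruct: completed run found; resuming (no-op)")
      return(invisible(read_table_tsv(file.path(out, "iteration_log.tsv"))))
    }
  }
  stack <- read_stack(cfg_get(config, "stack_prefix",
                              file.path(out, "segments")))
  sym0 <- helical_symmetry(cfg_get(config, "rise", 28.5),
                           cfg_get(config, "twist", -165))
  cfgr <- refinement_config(
    n_iterations = cfg_get(config, "n_iterations", 2),
    phi_step = cfg_get(config, "phi_step", 8),
    psi_step = cfg_get(config, "psi_step", 8),
    theta_step = cfg_get(config, "theta_step", 6),
    shift_range = cfg_get(config, "shift_range", 5),
    seed = cfg_get(config, "seed", 1))
  init <- rasterize(build_filament(default_subunit(TRUE), sym0,
                                   cfg_get(config, "init_subunits", 24)),
                    stack$box, stack$pixel_size, clip = TRUE)
  fixed <- config$fixed_symmetry
  if (!is.null(fixed)) {
    fs <- helical_symmetry(fixed[1], fixed[2])
    stack$meta$included <- TRUE
    pol <- polish(phase_flip_stack(stack),
                  lowpass_volume(init, cfgr$initial_lowpass), fs,
                  lowpass = cfgr$polish_lowpass, config = cfgr)
    write_mrc(pol$map, file.path(out, "final_map.mrc"))
    write_table_tsv(pol$params, file.path(out, "segment_params.tsv"))
    lg <- data.frame(iteration = 1, rise = fs$rise, twist = fs$twist,
                     resolution = NA, n_included = nrow(pol$params),
                     mean_cc = mean(pol$params$cross_correlation))
  } else {
    fit <- ihrsr(stack, init, sym0, cfgr,
                 polish = cfg_get(config, "polish", TRUE))
    write_mrc(fit$half1, file.path(out, "half1.mrc"))
    write_mrc(fit$half2, file.path(out, "half2.mrc"))
    write_mrc(fit$map, file.path(out, "final_map.mrc"))
    write_table_tsv(fit$params, file.path(out, "segment_params.tsv"))
    lg <- fit$log
  }
  write_table_tsv(lg, file.path(out, "iteration_log.tsv"))
  jsonlite::write_json(list(config_md5 = unname(tools::md5sum(cfg_path))),
                       done_flag, auto_unbox = TRUE)
  invisible(lg)
}

#' Pipeline stage: post-process half maps
#'
#' FSC curve, 0.143 resolution, B-factor sharpened map and the
#' cylindrical-mask resolution series.
#'
#' @param config fields: half1, half2 (MRC paths), out_dir, bfactor,
#'   radii (A)
#' @return resolution list, invisibly
#' @export
pipeline_postprocess <- function(config) {
  config <- load_config(config)
  out <- cfg_get(config, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  h1 <- read_mrc(config$half1)
  h2 <- read_mrc(config$half2)
  fsc <- compute_fsc(h1, h2)
  res <- resolution_at(fsc)
  write_table_tsv(as.data.frame(fsc), file.path(out, "fsc.tsv"))
  full <- density_volume((h1$data + h2$data) / 2, h1$pixel_size)
  sharp <- sharpen(full, cfg_get(config, "bfactor", -150),
                   lowpass = if (res$nyquist_limited) Inf else res$resolution)
  write_mrc(sharp, file.path(out, "sharpened_map.mrc"))
  radii <- cfg_get(config, "radii", c(120, 90, 40))
  series <- masked_resolution_series(h1, h2, radii)
  write_table_tsv(series, file.path(out, "masked_resolution.tsv"))
  report <- list(resolution = res$resolution,
                 nyquist_limited = res$nyquist_limited,
                 bfactor = cfg_get(config, "bfactor", -150))
  jsonlite::write_json(report, file.path(out, "resolution.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(config, out, "postprocess")
  invisible(report)
}

#' Pipeline stage: flexible fitting
#'
#' @param config fields: model (PDB path), map (MRC path), out_dir,
#'   variant ("HR"/"LPF"), actin_chains, motor_chains, seed, phases
#' @return the flexfit object, invisibly
#' @export
pipeline_fit <- function(config) {
  config <- load_config(config)
  out <- cfg_get(config, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  model <- read_pdb(config$model)
  map <- read_mrc(config$map)
  rules <- region_rules(
    actin_chains = cfg_get(config, "actin_chains", character()),
    variant = cfg_get(config, "variant", "HR"))
  if (!is.null(config$motor_chains))
    rules <- myosin6_rules(config$motor_chains,
                           cfg_get(config, "actin_chains", character()),
                           cfg_get(config, "variant", "HR"))
  model <- assign_regimes(model, rules)
  sch <- fit_schedule(seed = cfg_get(config, "seed", 1))
  ft <- flexfit(model, map, schedule = sch)
  write_pdb(ft$model, file.path(out, "fitted_model.pdb"))
  write_table_tsv(ft$log, file.path(out, "fit_log.tsv"))
  gr <- geometry_report(ft$model, ft$restraints)
  jsonlite::write_json(gr, file.path(out, "geometry_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(config, out, "fit")
  invisible(ft)
}

#' Pipeline stage: state-to-state comparison
#'
#' @param config fields: models (named list or vector of PDB paths),
#'   out_dir, frame ("all"), scale (1.5), domains (names of
#'   [domain_preset()]s), domain_chain
#' @return the RMSD matrix, invisibly
#' @export
pipeline_compare <- function(config) {
  config <- load_config(config)
  out <- cfg_get(config, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- config$models
  models <- lapply(paths, read_pdb)
  if (is.null(names(models)))
    names(models) <- tools::file_path_sans_ext(basename(unlist(paths)))
  mat <- rmsd_matrix(models)
  write_table_tsv(cbind(model = rownames(mat), as.data.frame(mat)),
                  file.path(out, "rmsd_matrix.tsv"))
  if (length(models) >= 2) {
    prof <- per_residue_rmsd(models[[1]], models[[2]])
    write_table_tsv(prof, file.path(out, "per_residue_rmsd.tsv"))
    fld <- displacement_field(models[[1]], models[[2]],
                              scale = cfg_get(config, "scale", 1.5))
    write_table_tsv(as.data.frame(fld), file.path(out, "displacement_field.tsv"))
    dn <- cfg_get(config, "domains", character())
    if (length(dn)) {
      ch <- cfg_get(config, "domain_chain", "A")
      rows <- lapply(dn, function(nm) {
        dom <- domain_preset(nm, chain = ch)
        data.frame(domain = nm,
                   rmsd = as.numeric(rmsd_ca(models[[1]], models[[2]], dom)),
                   centroid_displacement =
                     centroid_displacement(models[[1]], models[[2]], dom))
      })
      write_table_tsv(do.call(rbind, rows), file.path(out, "domains.tsv"))
    }
  }
  write_provenance(config, out, "compare")
  invisible(mat)
}

#' Pipeline stage: conservation mapping
#'
#' @param config fields: alignment (FASTA path), reference_id, out_dir;
#'   optional model (PDB), chain, resno_offset
#' @return the conservation profile, invisibly
#' @export
pipeline_conserve <- function(config) {
  config <- load_config(config)
  out <- cfg_get(config, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  aln <- read_fasta_alignment(config$alignment)
  prof <- conservation_profile(aln, config$reference_id)
  write_table_tsv(as.data.frame(prof), file.path(out, "conservation.tsv"))
  if (!is.null(config$model)) {
    model <- read_pdb(config$model)
    res <- map_scores_to_model(prof, model, cfg_get(config, "chain", "A"),
                               resno_offset = config$resno_offset)
    write_pdb(res$model, file.path(out, "conservation_colored.pdb"))
    write_table_tsv(res$mapped, file.path(out, "conservation_mapping.tsv"))
  }
  write_provenance(config, out, "conserve")
  invisible(prof)
}
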