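#' Pipeline run configuration
#'
#' Collects every knob of the simulate/fit/report workflow in one
#' serializable object. `save_config()`/`load_config()` round-trip it
#' through JSON exactly.
#'
#' @param out_dir output directory for all artifacts.
#' @param n_subjects number of synthetic subjects to simulate.
#' @param seed master seed; all randomness in a run derives from it.
#' @param noise_sd phantom noise SD in dM/M0 units.
#' @param between_subject_cv cohort between-subject coefficient of
#'   variation.
#' @param grid_shape phantom grid (3 integers).
#' @param cp_pv_fraction choroid plexus partial-volume fraction.
#' @param n_starts fitter restarts.
#' @param voxelwise also run voxelwise fits and write parameter maps
#'   (slower).
#' @param schedule_path optional path to a schedule CSV; NULL uses the
#'   built-in 12-OT design.
#' @param constants named list of [acquisition_constants()] overrides.
#' @param bounds_lower,bounds_upper named numeric overrides for
#'   [fit_bounds()].
#' @param alpha significance level for report flags.
#' @return An object of class `run_config` (named list).
#' @export
run_config <- function(out_dir = "cpasl_run", n_subjects = 7, seed = 1,
                       noise_sd = 2.5e-4, between_subject_cv = 0.25,
                       grid_shape = c(48, 48, 48), cp_pv_fraction = 0.5,
                       n_starts = 5, voxelwise = FALSE,
                       schedule_path = NULL, constants = list(),
                       bounds_lower = list(), bounds_upper = list(),
                       alpha = 0.02) {
  cfg <- list(out_dir = as.character(out_dir),
              n_subjects = as.numeric(n_subjects),
              seed = as.numeric(seed),
              noise_sd = as.numeric(noise_sd),
              between_subject_cv = as.numeric(between_subject_cv),
              grid_shape = as.numeric(grid_shape),
              cp_pv_fraction = as.numeric(cp_pv_fraction),
              n_starts = as.numeric(n_starts),
              voxelwise = isTRUE(voxelwise),
              schedule_path = if (is.null(schedule_path)) NULL else as.character(schedule_path),
              constants = lapply(constants, as.numeric),
              bounds_lower = lapply(bounds_lower, as.numeric),
              bounds_upper = lapply(bounds_upper, as.numeric),
              alpha = as.numeric(alpha))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config()
  cfg <- utils::modifyList(unclass(defaults), raw, keep.null = TRUE)
  cfg <- cfg[names(defaults)]
  for (nm in c("constants", "bounds_lower", "bounds_upper")) {
    cfg[[nm]] <- as.list(cfg[[nm]])
  }
  do.call(run_config, cfg)
}

resolve_constants <- function(cfg, voxel_volume = NULL) {
  args <- cfg$constants
  if (!is.null(voxel_volume)) args$voxel_volume <- voxel_volume
  do.call(acquisition_constants, args)
}

resolve_bounds <- function(cfg) {
  b <- fit_bounds()
  lo <- b$lower; hi <- b$upper
  for (nm in names(cfg$bounds_lower)) lo[[nm]] <- cfg$bounds_lower[[nm]]
  for (nm in names(cfg$bounds_upper)) hi[[nm]] <- cfg$bounds_upper[[nm]]
  fit_bounds(lo, hi)
}

#' Load an observation-time schedule from a CSV file
#'
#' Expects two aligned numeric columns named `LD`/`PLD` (or `tau`/`w`),
#' seconds. With `path = NULL` the built-in 12-OT design is returned.
#' Malformed rows are reported by row number.
#'
#' @param path CSV path or NULL.
#' @return an [ot_schedule()].
#' @export
load_ot_schedule <- function(path = NULL) {
  if (is.null(path)) return(ot_schedule())
  if (!file.exists(path)) stop("schedule file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("cannot parse schedule file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  nm <- tolower(names(df))
  tau_col <- match(TRUE, nm %in% c("ld", "tau"))
  w_col <- match(TRUE, nm %in% c("pld", "w"))
  if (is.na(tau_col) || is.na(w_col)) {
    stop("schedule file must have columns LD/PLD (or tau/w): ", path,
         call. = FALSE)
  }
  tau <- suppressWarnings(as.numeric(df[[tau_col]]))
  w <- suppressWarnings(as.numeric(df[[w_col]]))
  if (length(tau) == 0L) stop("schedule file is empty: ", path, call. = FALSE)
  bad <- which(!is.finite(tau) | !is.finite(w) | tau <= 0 | w <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("schedule row %d of %s is invalid (needs positive LD and PLD)",
                 bad[1L], path), call. = FALSE)
  }
  ot_schedule(tau, w)
}

#' @rdname load_ot_schedule
#' @param schedule an [ot_schedule()] to write.
#' @export
save_ot_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(LD = schedule$tau, PLD = schedule$w), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an aligned series of NIfTI volumes
#'
#' Loads one volume per observation time and checks that all share one grid
#' and voxel size; the voxel volume (ml) is derived from the header voxel
#' size. Registration is out of scope: a mismatch is an error naming the
#' offending file.
#'
#' @param paths character vector of NIfTI paths, in schedule order.
#' @return list with `volumes` (list of arrays), `voxel_size_mm`, and
#'   `voxel_volume_ml`.
#' @export
read_volume_series <- function(paths) {
  if (length(paths) == 0L) stop("no volumes given", call. = FALSE)
  vols <- vector("list", length(paths))
  ref_dim <- NULL; ref_vox <- NULL
  for (i in seq_along(paths)) {
    img <- read_nifti(paths[i])
    vx <- attr(img, "voxel_size_mm")
    if (is.null(ref_dim)) {
      ref_dim <- dim(img); ref_vox <- vx
    } else {
      if (!identical(dim(img), ref_dim)) {
        stop("volume grid mismatch at ", paths[i], call. = FALSE)
      }
      if (max(abs(vx - ref_vox)) > 1e-4) {
        stop("voxel size mismatch at ", paths[i], call. = FALSE)
      }
    }
    attr(img, "voxel_size_mm") <- NULL
    vols[[i]] <- img
  }
  list(volumes = vols, voxel_size_mm = ref_vox,
       voxel_volume_ml = prod(ref_vox) / 1000)
}

subject_dir <- function(out_dir, i) {
  file.path(out_dir, sprintf("subject_%02d", i))
}

#' Write one simulated subject to disk
#'
#' Per-OT difference and proton-density volumes (filenames carry the OT
#' index and the (LD, PLD) pair), the tissue label volume, the gray-matter
#' probability map, the choroid plexus mask, the schedule and the truth
#' maps/spec.
#'
#' @param sim a [simulate_subject()] result.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_subject <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- sim$spec$voxel_size_mm
  sched <- sim$schedule
  for (i in seq_len(nrow(sched))) {
    tag <- sprintf("t%02d_LD%.1f_PLD%.1f", i, sched$tau[i], sched$w[i])
    write_nifti(sim$delta_m[[i]],
                file.path(dir, sprintf("deltam_%s.nii.gz", tag)), vx)
    write_nifti(sim$pd[[i]],
                file.path(dir, sprintf("pd_%s.nii.gz", tag)), vx)
  }
  tr <- sim$truth
  write_nifti(array(as.numeric(tr$label_volume), dim(tr$label_volume)),
              file.path(dir, "labels.nii.gz"), vx, datatype = "uint8")
  write_nifti(tr$gm_probability_map, file.path(dir, "gm_prob.nii.gz"), vx)
  cp_mask <- array(as.numeric(tr$label_volume == tr$classes[["choroid_plexus"]]),
                   dim(tr$label_volume))
  write_nifti(cp_mask, file.path(dir, "cp_mask.nii.gz"), vx, datatype = "uint8")
  save_ot_schedule(sched, file.path(dir, "schedule.csv"))
  spec_flat <- sim$spec
  for (nm in c("gm_params", "wm_params", "cp_actual_params")) {
    spec_flat[[nm]] <- unclass(spec_flat[[nm]])
  }
  jsonlite::write_json(unclass(spec_flat), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

list_subject_volumes <- function(dir, prefix) {
  paths <- sort(list.files(dir, pattern = paste0("^", prefix, "_t[0-9]+.*\\.nii(\\.gz)?$"),
                           full.names = TRUE))
  if (length(paths) == 0L) {
    stop("no ", prefix, " volumes found in ", dir, call. = FALSE)
  }
  paths
}

#' Fit one subject directory
#'
#' Reads the per-OT difference and proton-density series plus masks from a
#' subject directory (the [write_subject()] layout), calibrates M0 from the
#' mean proton-density signal in the thresholded gray-matter mask, runs
#' ROI fits for gray matter and choroid plexus, optionally voxelwise maps
#' (written as NIfTI), and returns the [subject_summary()] row.
#'
#' @param dir subject directory.
#' @param subject_id identifier used in the summary row.
#' @param cfg a [run_config()].
#' @return list with `summary` (one-row data.frame), `gm_fit`, `cp_fit`,
#'   and (if requested) `maps`.
#' @export
fit_subject_dir <- function(dir, subject_id, cfg = run_config()) {
  schedule <- load_ot_schedule(
    if (file.exists(file.path(dir, "schedule.csv"))) file.path(dir, "schedule.csv")
    else cfg$schedule_path)
  dm <- read_volume_series(list_subject_volumes(dir, "deltam"))
  pd <- read_volume_series(list_subject_volumes(dir, "pd"))
  if (length(dm$volumes) != nrow(schedule)) {
    stop("found ", length(dm$volumes), " difference volumes for ",
         nrow(schedule), " schedule rows in ", dir, call. = FALSE)
  }
  constants <- resolve_constants(cfg, voxel_volume = dm$voxel_volume_ml)
  bounds <- resolve_bounds(cfg)

  gm_prob_path <- file.path(dir, "gm_prob.nii.gz")
  cp_mask_path <- file.path(dir, "cp_mask.nii.gz")
  if (!file.exists(gm_prob_path) || !file.exists(cp_mask_path)) {
    stop("missing mask file(s) in ", dir, call. = FALSE)
  }
  gm_mask <- threshold_mask(read_nifti(gm_prob_path), 0.5)
  cp_mask <- read_nifti(cp_mask_path) > 0.5
  if (!any(gm_mask) || !any(cp_mask)) stop("empty mask in ", dir, call. = FALSE)

  # per-OT mean proton-density signal over gray matter, averaged across OTs
  m_pd <- mean(vapply(pd$volumes, function(v) mean(v[gm_mask]), numeric(1)))
  m0 <- compute_m0(m_pd, constants)

  fit_seed <- as.integer(cfg$seed %% 1e6) + 17L
  gm_fit <- fit_roi(dm$volumes, gm_mask, m0, constants, bounds, schedule,
                    n_starts = cfg$n_starts, seed = fit_seed)
  cp_fit <- fit_roi(dm$volumes, cp_mask, m0, constants, bounds, schedule,
                    n_starts = cfg$n_starts, seed = fit_seed)

  maps <- NULL
  if (isTRUE(cfg$voxelwise)) {
    maps <- fit_voxelwise(dm$volumes, cp_mask | gm_mask, m0, constants,
                          bounds, schedule, n_starts = cfg$n_starts,
                          seed = fit_seed)
    for (nm in c("flow_map", "att_map", "t1_map", "r2_map")) {
      img <- maps[[nm]]
      write_nifti(img, file.path(dir, paste0(nm, ".nii.gz")),
                  dm$voxel_size_mm)
    }
  }

  summary <- subject_summary(subject_id, gm_fit, cp_fit, sum(cp_mask),
                             constants)
  list(summary = summary, gm_fit = gm_fit, cp_fit = cp_fit, maps = maps)
}

#' Run the full simulate -> fit -> report pipeline
#'
#' Simulates a synthetic cohort (unless subject directories already exist
#' under `config$out_dir`), fits every subject, and writes per-subject
#' summaries, the group report CSV and a provenance log. Per-subject
#' failures are logged and skipped; the run fails only if all subjects
#' fail.
#'
#' @param config a [run_config()].
#' @return the [group_report()] result, invisibly; artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cfg_path <- file.path(out_dir, "config_resolved.json")
  save_config(config, cfg_path)
  logline("run started; seed=%g; R %s; cpasl %s; config=%s",
          config$seed, getRversion(),
          as.character(utils::packageVersion("cpasl")), cfg_path)

  schedule <- load_ot_schedule(config$schedule_path)
  n <- as.integer(config$n_subjects)
  dirs <- vapply(seq_len(n), function(i) subject_dir(out_dir, i), character(1))

  if (!all(dir.exists(dirs))) {
    logline("simulating %d subjects (noise_sd=%g, cv=%g)", n,
            config$noise_sd, config$between_subject_cv)
    spec <- phantom_spec(grid_shape = config$grid_shape,
                         cp_pv_fraction = config$cp_pv_fraction,
                         noise_sd = config$noise_sd,
                         seed = as.integer(config$seed))
    cohort <- simulate_cohort(n, spec, config$between_subject_cv,
                              seed = as.integer(config$seed),
                              schedule = schedule,
                              constants = resolve_constants(config))
    for (i in seq_len(n)) write_subject(cohort$subjects[[i]], dirs[i])
    utils::write.csv(cohort$truth_table,
                     file.path(out_dir, "truth_table.csv"), row.names = FALSE)
  } else {
    logline("using %d existing subject directories", n)
  }

  summaries <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(fit_subject_dir(dirs[i], i, config), error = function(e) e)
    if (inherits(res, "error")) {
      logline("subject %d FAILED: %s", i, conditionMessage(res))
      warning(sprintf("subject %d skipped: %s", i, conditionMessage(res)),
              call. = FALSE)
      next
    }
    summaries[[length(summaries) + 1L]] <- res$summary
    logline("subject %d: gm f=%.2f cp f=%.2f cp F_total=%.3f ml/min", i,
            res$summary$gm_f, res$summary$cp_f, res$summary$cp_total_flow)
  }
  if (length(summaries) == 0L) {
    logline("all subjects failed")
    stop("run_pipeline: all subjects failed", call. = FALSE)
  }
  tab <- do.call(rbind, summaries)
  utils::write.csv(tab, file.path(out_dir, "subject_summaries.csv"),
                   row.names = FALSE)
  report <- group_report(tab, alpha = config$alpha)
  write_group_report(report, file.path(out_dir, "group_report.csv"))
  logline("report written: %d subjects, p(T1)=%.6f", nrow(tab),
          report$p_values[["t1"]])
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `fit` (fit existing
#' subject directories and write summaries), `report` (group report from a
#' summaries CSV), `selftest` (run a quick invariant battery), `pipeline`
#' (all stages). Invoke from a shell via the wrapper script in
#' `system.file("cli", "cpasl.R", package = "cpasl")`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status (0 on success), invisibly.
#' @export
cpasl_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: cpasl.R <simulate|fit|report|pipeline|selftest> [options]"
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  opts <- optparse::OptionParser(
    option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                            default = "cpasl_run"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--n-starts", dest = "n_starts", type = "integer",
                            default = 5L),
      optparse::make_option("--schedule", type = "character", default = NULL),
      optparse::make_option("--noise-sd", dest = "noise_sd", type = "double",
                            default = 2.5e-4),
      optparse::make_option("--subjects", type = "integer", default = 7L),
      optparse::make_option("--summaries", type = "character", default = NULL,
                            help = "CSV of per-subject rows for `report`"),
      optparse::make_option("--voxelwise", action = "store_true",
                            default = FALSE)))
  o <- optparse::parse_args(opts, args = rest)
  cfg <- if (!is.null(o$config)) load_config(o$config) else {
    run_config(out_dir = o$out_dir, n_subjects = o$subjects, seed = o$seed,
               noise_sd = o$noise_sd, n_starts = o$n_starts,
               voxelwise = o$voxelwise, schedule_path = o$schedule)
  }
  status <- 0L
  if (cmd == "simulate") {
    spec <- phantom_spec(cp_pv_fraction = cfg$cp_pv_fraction,
                         noise_sd = cfg$noise_sd,
                         seed = as.integer(cfg$seed))
    cohort <- simulate_cohort(as.integer(cfg$n_subjects), spec,
                              cfg$between_subject_cv,
                              seed = as.integer(cfg$seed),
                              schedule = load_ot_schedule(cfg$schedule_path))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(cohort$subjects)) {
      write_subject(cohort$subjects[[i]], subject_dir(cfg$out_dir, i))
    }
    utils::write.csv(cohort$truth_table,
                     file.path(cfg$out_dir, "truth_table.csv"),
                     row.names = FALSE)
    message("simulated ", length(cohort$subjects), " subjects under ",
            cfg$out_dir)
  } else if (cmd == "fit" || cmd == "pipeline") {
    report <- run_pipeline(cfg)
    print(report)
  } else if (cmd == "report") {
    if (is.null(o$summaries)) {
      message("report requires --summaries <csv>")
      return(invisible(1L))
    }
    tab <- utils::read.csv(o$summaries)
    report <- group_report(tab, alpha = cfg$alpha)
    print(report)
    write_group_report(report, file.path(cfg$out_dir, "group_report.csv"))
  } else if (cmd == "selftest") {
    status <- cpasl_selftest()
  } else {
    message(usage)
    status <- 1L
  }
  invisible(status)
}

#' Quick invariant self-test
#'
#' Checks the forward-model invariants (no-arrival zero signal, linearity
#' in flow, mono-exponential washout), the M0 homogeneity, the total-flow
#' mean/sum identity and an exact Wilcoxon sanity case. Returns 0 when all
#' pass.
#'
#' @return 0 if all checks pass, 1 otherwise (with messages).
#' @export
cpasl_selftest <- function() {
  ok <- TRUE
  check <- function(label, cond) {
    if (!isTRUE(cond)) {
      message("FAIL: ", label)
      ok <<- FALSE
    } else message("ok: ", label)
  }
  cst <- acquisition_constants()
  p <- perfusion_params(50, 1.3, 1.85)
  check("no-arrival zero",
        asl_relative_signal(p, cst, tau = 1.0, w = 0.2) == 0)
  check("linearity in f",
        isTRUE(all.equal(
          asl_relative_signal(perfusion_params(100, 1.3, 1.85), cst, 3, 1.5),
          2 * asl_relative_signal(p, cst, 3, 1.5))))
  s1 <- asl_relative_signal(p, cst, 4, 2.0)
  s2 <- asl_relative_signal(p, cst, 4, 2.5)
  check("mono-exponential washout",
        isTRUE(all.equal(s2 / s1, exp(-0.5 / p$T1))))
  check("M0 homogeneity",
        isTRUE(all.equal(compute_m0(2000, cst), 2 * compute_m0(1000, cst))))
  f <- c(20, 40, 60)
  check("total flow mean/sum identity",
        isTRUE(all.equal(total_flow(mean(f), 3, cst),
                         cst$rho * cst$voxel_volume * sum(f) / 100)))
  check("weight correction identity",
        weight_corrected_flow(0.80, 2, 0.5) == 80)
  w <- wilcoxon_exact_paired(c(2, 3, 4, 5), c(1, 1, 1, 1))
  check("wilcoxon extreme tail", isTRUE(all.equal(w$p, 2 / 16)))
  if (ok) 0L else 1L
}
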