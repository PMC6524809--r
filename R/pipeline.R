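# End-to-end orchestration: a synthetic (or on-disk) ensemble of
# segmentations in, a variability report out.
#
# Stage order follows the analysis protocol: centerline profiles first,
# then morphometrics at the detected ostium, then hemodynamic parameters,
# then ensemble summaries.  Per-group failures are isolated and recorded
# as flagged rows, never fatal to the ensemble.

#' Default five-aneurysm synthetic study definition
#'
#' Five saccular-aneurysm phantoms spanning the size range of a multi-
#' aneurysm clinical case (sac diameters 5.6, 1.5, 4.4, 4.6 and 4.9 mm),
#' with parent-vessel calibres and cycle-mean inflow rates in the range
#' reported for cerebral arteries, and prescribed sac flow intensities.
#' @param vessel_length parent vessel length (mm).
#' @return list of per-aneurysm definitions (label, vessel radius, sac and
#'   neck radii, cycle-mean flow, sac mean speed and wall shear).
#' @export
five_aneurysm_study <- function(vessel_length = 24) {
  defs <- list(
    list(label = "A", parent_radius = 1.28, sac_radius = 2.80,
         neck_radius = 1.55, q_mean = 1.61, sac_speed = 0.08,
         sac_wss = 1.64),
    list(label = "B", parent_radius = 1.15, sac_radius = 0.75,
         neck_radius = 0.50, q_mean = 1.58, sac_speed = 0.07,
         sac_wss = 3.06),
    list(label = "C", parent_radius = 1.27, sac_radius = 2.20,
         neck_radius = 1.30, q_mean = 2.06, sac_speed = 0.10,
         sac_wss = 2.14),
    list(label = "D", parent_radius = 1.10, sac_radius = 2.30,
         neck_radius = 1.45, q_mean = 1.64, sac_speed = 0.23,
         sac_wss = 7.50),
    list(label = "E", parent_radius = 1.16, sac_radius = 2.45,
         neck_radius = 1.60, q_mean = 3.33, sac_speed = 0.24,
         sac_wss = 12.82))
  lapply(defs, function(d) { d$vessel_length <- vessel_length; d })
}

#' Run configuration for the analysis pipeline
#'
#' @param mode `"synthetic"` (generate phantoms and ensembles) or
#'   `"ensemble"` (read surfaces from `ensemble_dir`).
#' @param aneurysms for synthetic mode, a [five_aneurysm_study()]-style list.
#' @param ensemble_dir for ensemble mode, a directory of surface files.
#' @param landmarks for ensemble mode, a list with `source`, `target`,
#'   `dome_seed` coordinates (mm).
#' @param n_groups,radius_noise,correlation_length,neck_bias perturbation
#'   settings, see [perturbation_spec()].
#' @param seed global RNG seed.
#' @param n_times time samples per cycle for the synthetic fields.
#' @param sample_spacing volumetric field sample spacing (mm).
#' @param compute_flow logical; skip hemodynamics when `FALSE`.
#' @param output_dir optional report directory.
#' @return validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "ensemble"),
                       aneurysms = five_aneurysm_study(),
                       ensemble_dir = NULL, landmarks = NULL,
                       n_groups = 24L, radius_noise = 0.13,
                       correlation_length = 8, neck_bias = 0.15,
                       seed = 1L, n_times = 21L, sample_spacing = 0.35,
                       compute_flow = TRUE, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "ensemble") {
    .assert(!is.null(ensemble_dir) && dir.exists(ensemble_dir),
            "aneumorph_usage_error",
            "run_config field 'ensemble_dir' must name an existing directory")
    .assert(length(list.files(ensemble_dir,
                              pattern = "\\.(stl|ply|obj)$")) > 0,
            "aneumorph_usage_error",
            "run_config field 'ensemble_dir' contains no surface files")
    .assert(!is.null(landmarks) &&
              all(c("source", "target") %in% names(landmarks)),
            "aneumorph_usage_error",
            "run_config field 'landmarks' needs source and target seeds")
  } else {
    .assert(length(aneurysms) >= 1, "aneumorph_usage_error",
            "run_config field 'aneurysms' is empty")
  }
  .assert(n_groups >= 2, "aneumorph_usage_error",
          "run_config field 'n_groups' must be >= 2")
  structure(list(mode = mode, aneurysms = aneurysms,
                 ensemble_dir = ensemble_dir, landmarks = landmarks,
                 n_groups = as.integer(n_groups),
                 radius_noise = radius_noise,
                 correlation_length = correlation_length,
                 neck_bias = neck_bias, seed = as.integer(seed),
                 n_times = as.integer(n_times),
                 sample_spacing = sample_spacing,
                 compute_flow = isTRUE(compute_flow),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or key=value text
#' @param path config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), "aneumorph_usage_error",
          "config file does not exist: %s", path)
  vals <- if (grepl("\\.ya?ml$", path) &&
              requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "\\s*[=:]\\s*")
    out <- list()
    for (p in kv) {
      .assert(length(p) == 2, "aneumorph_usage_error",
              "cannot parse config line near '%s'", p[1])
      v <- utils::type.convert(p[2], as.is = TRUE)
      out[[p[1]]] <- v
    }
    out
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  .assert(length(unknown) == 0, "aneumorph_usage_error",
          "unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

# Build one phantom from a study definition.  The surfacing grid is kept
# proportional to the neck calibre so small aneurysms stay resolved while
# large ones do not balloon the triangle count.
.study_phantom <- function(d) {
  grid <- max(min(0.28, d$neck_radius / 3.3), 0.12)
  make_phantom(phantom_spec(
    length = d$vessel_length, radius = d$parent_radius,
    sac = list(neck_radius = d$neck_radius, sac_radius = d$sac_radius,
               station = d$vessel_length / 2, stalk_offset = 0.4),
    grid = grid, label = d$label))
}

# Analyse one group surface of one aneurysm; returns the record fields
# plus profile vectors.  Any stage error propagates (caller isolates).
.analyze_group <- function(surface, phantom, d, cfg, group_label) {
  L <- d$vessel_length
  src <- c(3, 0, 0)
  tgt <- c(L - 3, 0, 0)
  voxel <- max(d$parent_radius / 6, 0.1)
  cl <- extract_centerline(surface, src, tgt, voxel = voxel,
                           spacing = 2 * voxel,
                           source_landmark = "inlet",
                           target_landmark = "outlet")
  mo <- morphometrics(surface, dome_seed = phantom$truth$sac_center,
                      centerline = cl)
  rec <- list(group = group_label, aneurysm = d$label,
              ostium_area = mo$ostium_area, parent_area = mo$parent_area,
              volume = mo$volume, nsi = mo$nsi)
  vel <- NULL
  if (cfg$compute_flow) {
    inlet_area <- parent_cross_section(surface, cl, station = 1)
    wave <- two_harmonic_waveform(q_mean = d$q_mean,
                                  d_ref = 2 * d$parent_radius)
    wave_g <- scale_waveform(wave, inlet_area)
    flow <- analytic_flow(phantom, wave_g,
                          sample_spacing = cfg$sample_spacing,
                          n_times = cfg$n_times,
                          sac_mean_speed = d$sac_speed,
                          sac_wall_wss = d$sac_wss,
                          geometry = list(surface = surface,
                                          centerline = cl, s_offset = 3))
    rec$neck_inflow <- neck_inflow_rate(flow$volume, mo$ostium)
    pf <- vessel_flow_rate(flow$volume, surface, cl,
                           station = mo$proximal_station)
    rec$parent_flow <- pf$rate
    sm <- sac_means(flow$volume, flow$wall, mo$sac, mask_method = "plane")
    rec$mean_velocity <- sm$mean_velocity
    rec$mean_wss <- sm$mean_wss
    vel <- sample_velocity_magnitude(cl, flow$volume)
  }
  list(record = rec, centerline = cl, velocity = vel)
}

#' Run the full variability pipeline
#'
#' Executes, per aneurysm and per segmentation group: centerline
#' extraction with inscribed-radius profile, ostium detection and
#' morphometrics, synthetic hemodynamics and the four flow parameters;
#' then aligns profiles, computes variability bands, and summarises the
#' parameter table into median / std / relative-std statistics.
#' Per-group failures are flagged rows in the table, not errors.
#'
#' @param config a [run_config()].
#' @return object of class `ia_study`: `table` ([parameter_table]),
#'   `summary` ([summarize_parameters()]), `bands` (per aneurysm: radius
#'   and velocity [profile_band()]s), `ok` (at least two groups succeeded
#'   for every aneurysm), `manifest`.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "aneumorph_usage_error",
          "config must be a run_config object")
  t_start <- Sys.time()
  records <- list()
  bands <- list()
  failures <- list()
  if (config$mode == "synthetic") {
    pspec <- perturbation_spec(radius_noise = config$radius_noise,
                               correlation_length = config$correlation_length,
                               neck_bias = config$neck_bias,
                               n_groups = config$n_groups,
                               seed = config$seed)
    for (d in config$aneurysms) {
      phantom <- .study_phantom(d)
      groups <- perturb_ensemble(phantom, pspec)
      cls <- list(); vels <- list()
      for (g in seq_along(groups)) {
        glab <- sprintf("group_%02d", g)
        res <- tryCatch(
          .analyze_group(groups[[g]], phantom, d, config, glab),
          error = function(e) e)
        if (inherits(res, "error")) {
          records[[length(records) + 1]] <-
            list(group = glab, aneurysm = d$label,
                 failure = conditionMessage(res))
          failures[[length(failures) + 1]] <-
            sprintf("%s/%s: %s", d$label, glab, conditionMessage(res))
        } else {
          records[[length(records) + 1]] <- res$record
          cls[[length(cls) + 1]] <- res$centerline
          if (!is.null(res$velocity)) vels[[length(vels) + 1]] <- res$velocity
        }
      }
      ab <- list()
      if (length(cls) >= 2) {
        mp_r <- match_profiles(cls, step = 0.5)
        ab$radius <- profile_band(mp_r)
        if (length(vels) == length(cls)) {
          mp_v <- match_profiles(cls, step = 0.5, values = vels)
          ab$velocity <- profile_band(mp_v)
        }
      }
      bands[[d$label]] <- ab
    }
  } else {
    surfaces <- read_ensemble(config$ensemble_dir)
    lm <- config$landmarks
    cls <- list()
    for (g in seq_along(surfaces)) {
      glab <- sprintf("group_%02d", g)
      res <- tryCatch({
        cl <- extract_centerline(surfaces[[g]], lm$source, lm$target)
        rec <- list(group = glab, aneurysm = "1")
        if (!is.null(lm$dome_seed)) {
          mo <- morphometrics(surfaces[[g]], lm$dome_seed, cl)
          rec$ostium_area <- mo$ostium_area
          rec$parent_area <- mo$parent_area
          rec$volume <- mo$volume
          rec$nsi <- mo$nsi
        }
        list(record = rec, centerline = cl)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        records[[length(records) + 1]] <-
          list(group = glab, aneurysm = "1",
               failure = conditionMessage(res))
        failures[[length(failures) + 1]] <-
          sprintf("1/%s: %s", glab, conditionMessage(res))
      } else {
        records[[length(records) + 1]] <- res$record
        cls[[length(cls) + 1]] <- res$centerline
      }
    }
    ab <- list()
    if (length(cls) >= 2)
      ab$radius <- profile_band(match_profiles(cls, step = 0.5))
    bands[["1"]] <- ab
  }
  table <- parameter_table(records)
  stats <- summarize_parameters(table)
  n_ok <- stats::aggregate(is.na(table$failure),
                           by = list(aneurysm = table$aneurysm), FUN = sum)
  ok <- all(n_ok$x >= 2)
  manifest <- list(
    mode = config$mode, seed = config$seed, n_groups = config$n_groups,
    radius_noise = config$radius_noise, neck_bias = config$neck_bias,
    groups_succeeded = stats::setNames(n_ok$x, n_ok$aneurysm),
    failures = unlist(failures),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    package_version = tryCatch(
      as.character(utils::packageVersion("aneumorph")),
      error = function(e) "dev"))
  study <- structure(list(table = table, summary = stats, bands = bands,
                          ok = ok, manifest = manifest, config = config),
                     class = "ia_study")
  if (!is.null(config$output_dir)) {
    paths <- emit_report(stats, config$output_dir)
    utils::write.csv(table, file.path(config$output_dir,
                                      "parameter_table.csv"),
                     row.names = FALSE)
    manifest$report_md5 <- unname(tools::md5sum(paths["csv"]))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    study$manifest <- manifest
  }
  study
}

#' @export
print.ia_study <- function(x, ...) {
  tb <- x$table
  cat(sprintf("ia_study: %d aneurysm(s) x %d group rows (%d failures)\n",
              length(unique(tb$aneurysm)), nrow(tb),
              sum(!is.na(tb$failure))))
  m <- x$summary[x$summary$aneurysm == "mean", ]
  if (nrow(m)) {
    cat("  mean relative std over aneurysms:\n")
    for (i in seq_len(nrow(m)))
      cat(sprintf("    %-14s %6.1f %%\n", m$parameter[i], m$rel_std[i]))
  }
  for (a in names(x$bands)) {
    b <- x$bands[[a]]
    if (!is.null(b$radius))
      cat(sprintf("  %s: centerline radius band %.3f mm\n", a,
                  b$radius$band_mean_std))
  }
  invisible(x)
}

#' @export
summary.ia_study <- function(object, ...) object$summary

#' @export
plot.ia_study <- function(x, parameters = .param_columns, ...) {
  tb <- x$table
  present <- parameters[vapply(parameters,
                               function(p) any(!is.na(tb[[p]])), logical(1))]
  .assert(length(present) > 0, "aneumorph_domain_error",
          "no parameter values to plot")
  nr <- ceiling(length(present) / 2)
  op <- graphics::par(mfrow = c(nr, min(2, length(present))),
                      mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in present) {
    graphics::boxplot(tb[[p]] ~ tb$aneurysm,
                      ylab = sprintf("%s [%s]", p, .param_units[p]),
                      xlab = "", main = p, ...)
  }
  invisible(x)
}
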