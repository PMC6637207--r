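#' Define a synthetic imaging scenario
#'
#' A scenario bundles everything the generators need to produce kinetic
#' traces, time-lapse stacks, and dual-stain cell populations with known
#' ground truth: per-condition kinetic parameters (optionally with a
#' media switch), noise levels, replication structure, imaging geometry,
#' and the per-timepoint divergence schedule for the single-cell
#' populations. All outputs are deterministic given `seed`.
#'
#' Defaults mirror the experimental designs the package emulates:
#' triplicate wells with 4 fields each, minute-scale time grids,
#' trace noise `sd = 0.02` (giving standard-error bars of a few percent
#' of the normalized signal), 512 x 512 fields with ~30 cells at
#' 10x-like scale, and a detached-probe background at most 1/100 of the
#' initial cell brightness (the fluorogenic >100-fold contrast).
#'
#' @param conditions Named list: condition name -> `kinetic_params`.
#' @param mode `"dissociation"` (post-wash decay) or `"association"`
#'   (staining of initially unlabeled cells).
#' @param times Acquisition time grid (min).
#' @param noise_sd Additive Gaussian noise sd on trace values.
#' @param n_replicates,n_fields Wells per condition and fields per well.
#' @param switch_time Optional media-switch time (min, on the grid).
#' @param post_conditions Named list of `kinetic_params` applied after
#'   `switch_time` (names matching `conditions`; omitted names keep their
#'   pre-switch parameters).
#' @param frame_size Rendered frame edge (pixels).
#' @param cells_per_field Cells rendered per field.
#' @param cell_size_range Semi-major axis range of rendered cells (px).
#' @param cell_spacing `"separated"` (well-separated grid) or
#'   `"touching"` (cells placed in near-touching pairs).
#' @param background_level Constant detached-probe background intensity
#'   relative to unit cell brightness; must be <= 0.01.
#' @param shot_scale Photon scale of the Poisson-like pixel noise (counts
#'   at unit intensity); `Inf` disables pixel noise.
#' @param divergence_schedule Named numeric vector: timepoint (min) ->
#'   effect size separating the condition populations in the dual-stain
#'   generator.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `smat_scenario` object.
#' @export
smat_scenario <- function(conditions,
                          mode = c("dissociation", "association"),
                          times = seq(0, 840, by = 60),
                          noise_sd = 0.02,
                          n_replicates = 3, n_fields = 4,
                          switch_time = NULL, post_conditions = NULL,
                          frame_size = 512, cells_per_field = 30,
                          cell_size_range = c(12, 24),
                          cell_spacing = c("separated", "touching"),
                          background_level = 0.005,
                          shot_scale = 2e4,
                          divergence_schedule = c("60" = 0.7, "480" = 1.4,
                                                  "1440" = 2.8),
                          seed = 1) {
  mode <- match.arg(mode)
  cell_spacing <- match.arg(cell_spacing)
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  for (p in conditions) stopifnot(inherits(p, "kinetic_params"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_replicates < 1 || n_fields < 1 || cells_per_field < 1)
    stop("counts must be at least 1")
  if (background_level > 0.01)
    stop("background_level must be <= 0.01 (>100-fold fluorogenic contrast)")
  if (!is.null(switch_time) && !any(abs(times - switch_time) < 1e-9))
    stop("switch_time must lie on the time grid")
  structure(list(conditions = conditions, mode = mode, times = times,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 n_fields = n_fields, switch_time = switch_time,
                 post_conditions = post_conditions,
                 frame_size = frame_size, cells_per_field = cells_per_field,
                 cell_size_range = cell_size_range,
                 cell_spacing = cell_spacing,
                 background_level = background_level,
                 shot_scale = shot_scale,
                 divergence_schedule = divergence_schedule,
                 seed = as.integer(seed)),
            class = "smat_scenario")
}

#' Built-in scenario presets
#'
#' Presets reproducing the experimental designs the package emulates:
#' \describe{
#'   \item{lineage}{Tri-lineage induction (dissociation): AD slowest
#'     probe decay, then CH, then OS and BA close together.}
#'   \item{lineage_assoc}{The complementary association design on
#'     initially unstained cells, same rate constants, common `L_T`.}
#'   \item{drugs}{Low-dose cytoskeletal drugs: CYTO slows decay, JASP
#'     and NOC indistinguishable from untreated.}
#'   \item{serum}{Serum deprivation with media switches at 60 min.}
#'   \item{switch}{Basal/adipogenic media swap at 240 min with swapped
#'     post-switch kinetics.}
#'   \item{passage}{Early vs late passage: globally slower turnover in
#'     the late-passage condition.}
#'   \item{null}{Two conditions with identical parameters (calibration).}
#' }
#'
#' @param name Preset name.
#' @param seed Scenario seed.
#' @param ... Overrides passed to [smat_scenario()].
#' @return A `smat_scenario`.
#' @export
scenario_preset <- function(name = c("lineage", "lineage_assoc", "drugs",
                                     "serum", "switch", "passage", "null"),
                            seed = 1, ...) {
  name <- match.arg(name)
  kp <- kinetic_params
  lineage <- list(AD = kp(0.004, 0.004), CH = kp(0.003, 0.009),
                  OS = kp(0.002, 0.018), BA = kp(0.002, 0.020))
  args <- switch(name,
    lineage = list(conditions = lineage),
    lineage_assoc = list(
      conditions = lapply(lineage, function(p)
        kinetic_params(p$kf_d, p$kr, L_T = 1.5)),
      mode = "association"),
    drugs = list(conditions = list(
      untreated = kp(0.002, 0.020), CYTO = kp(0.003, 0.008),
      JASP = kp(0.002, 0.021), NOC = kp(0.002, 0.019)),
      times = seq(0, 120, by = 15)),
    serum = list(conditions = list(
      BA = kp(0.002, 0.020), SDM = kp(0.004, 0.006),
      BA_to_SDM = kp(0.002, 0.020), SDM_to_BA = kp(0.004, 0.006)),
      times = seq(0, 120, by = 15), switch_time = 60,
      post_conditions = list(BA_to_SDM = kp(0.004, 0.006),
                             SDM_to_BA = kp(0.002, 0.020))),
    switch = list(conditions = list(
      BA = kp(0.002, 0.020), AD = kp(0.004, 0.004),
      BA_to_AD = kp(0.002, 0.020), AD_to_BA = kp(0.004, 0.004)),
      times = seq(0, 480, by = 30), switch_time = 240,
      post_conditions = list(BA_to_AD = kp(0.004, 0.004),
                             AD_to_BA = kp(0.002, 0.020))),
    passage = list(conditions = list(P5 = kp(0.002, 0.020),
                                     P12 = kp(0.0035, 0.008)),
                   times = seq(0, 120, by = 15)),
    null = list(conditions = list(A = kp(0.002, 0.020),
                                  B = kp(0.002, 0.020))))
  do.call(smat_scenario, utils::modifyList(c(args, list(seed = seed)),
                                           list(...)))
}

#' Ground-truth parameter table of a scenario
#' @param scn A `smat_scenario`.
#' @return Data frame: condition, kf_d, kr, L_T, kr_over_kf_d.
#' @export
scenario_truth <- function(scn) {
  do.call(rbind, lapply(names(scn$conditions), function(cn) {
    p <- scn$conditions[[cn]]
    data.frame(condition = cn, kf_d = p$kf_d, kr = p$kr, L_T = p$L_T,
               kr_over_kf_d = if (p$kf_d > 0) p$kr / p$kf_d else NA_real_)
  }))
}

# Noiseless trajectory for one condition, honoring any media switch.
condition_trajectory <- function(scn, cond) {
  p <- scn$conditions[[cond]]
  times <- scn$times
  traj <- if (scn$mode == "dissociation") {
    simulate_dissociation(p, times)$values
  } else {
    simulate_association(p, times, c_init = 0)$values
  }
  ts <- scn$switch_time
  post <- scn$post_conditions[[cond]]
  if (!is.null(ts) && !is.null(post)) {
    i <- which(abs(times - ts) < 1e-9)[1]
    cs <- traj[i]
    idx <- i:length(times)
    traj[idx] <- if (scn$mode == "dissociation") {
      linear_binding_solution(a = post$kf_d * post$C0,
                              b = post$kf_d + post$kr,
                              c_init = cs, times = times[idx], t0 = times[i])
    } else {
      linear_binding_solution(a = kf_a(post), b = post$kr,
                              c_init = cs, times = times[idx], t0 = times[i])
    }
  }
  traj
}

#' Generate noisy kinetic traces for a scenario
#'
#' For every condition x replicate x field, the closed-form trajectory of
#' the condition's kinetics (with continuous piecewise dynamics across
#' any media switch) plus iid Gaussian noise, truncated at 0.
#'
#' @param scn A `smat_scenario`.
#' @return Long trace table (`condition`, `replicate`, `field`,
#'   `time_min`, `value`).
#' @export
generate_traces <- function(scn) {
  stopifnot(inherits(scn, "smat_scenario"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(scn$seed)
  rows <- list()
  for (cn in names(scn$conditions)) {
    base <- condition_trajectory(scn, cn)
    for (r in seq_len(scn$n_replicates)) for (f in seq_len(scn$n_fields)) {
      v <- pmax(0, base + stats::rnorm(length(base), sd = scn$noise_sd))
      rows[[length(rows) + 1]] <- data.frame(
        condition = cn, replicate = r, field = f,
        time_min = scn$times, value = v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- field rendering -------------------------------------------------------

# Lay out cell centers: jittered grid ("separated") or near-touching pairs.
layout_cells <- function(n, frame, rmax, spacing) {
  margin <- rmax + 6
  if (spacing == "separated") {
    k <- ceiling(sqrt(n))
    if (k < 2) k <- 2
    span <- frame - 2 * margin
    step <- span / (k - 1)
    if (step < 2.3 * rmax)
      stop("cells requested beyond packing capacity: ", n, " cells of radius ",
           rmax, " do not fit a ", frame, "px frame")
    g <- expand.grid(r = seq_len(k), c = seq_len(k))[seq_len(n), ]
    jit <- max(0, min(5, step / 2 - 1.15 * rmax))
    data.frame(
      row = margin + (g$r - 1) * step + stats::runif(n, -jit, jit),
      col = margin + (g$c - 1) * step + stats::runif(n, -jit, jit))
  } else {
    npair <- ceiling(n / 2)
    base <- layout_cells(npair, frame, rmax * 1.6, "separated")
    rows <- numeric(0); cols <- numeric(0)
    for (i in seq_len(npair)) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- 0.95 * rmax
      rows <- c(rows, base$row[i] - cos(ang) * off, base$row[i] + cos(ang) * off)
      cols <- c(cols, base$col[i] - sin(ang) * off, base$col[i] + sin(ang) * off)
    }
    data.frame(row = rows[seq_len(n)], col = cols[seq_len(n)])
  }
}

# Sample per-cell geometry/texture descriptors for one field.
sample_cells <- function(scn, n = scn$cells_per_field) {
  a <- stats::runif(n, scn$cell_size_range[1], scn$cell_size_range[2])
  pos <- layout_cells(n, scn$frame_size, scn$cell_size_range[2],
                      scn$cell_spacing)
  data.frame(row = pos$row, col = pos$col, a = a,
             b = a * stats::runif(n, 0.4, 0.8),
             phi = stats::runif(n, 0, pi),
             amp = stats::runif(n, 0.6, 1.0),
             stripe_freq = stats::runif(n, 0.12, 0.22),
             stripe_phase = stats::runif(n, 0, 2 * pi),
             stripe_depth = stats::runif(n, 0.4, 0.6))
}

# Additively paint one textured elliptical-Gaussian cell into `frame`.
render_cell <- function(frame, cell, intensity, phase_shift = 0,
                        stripe_freq = cell$stripe_freq,
                        stripe_depth = cell$stripe_depth) {
  ext <- ceiling(2.5 * cell$a)
  r0 <- max(1, floor(cell$row - ext)); r1 <- min(nrow(frame), ceiling(cell$row + ext))
  c0 <- max(1, floor(cell$col - ext)); c1 <- min(ncol(frame), ceiling(cell$col + ext))
  if (r0 > r1 || c0 > c1) return(frame)
  dr <- (r0:r1) - cell$row; dc <- (c0:c1) - cell$col
  DR <- matrix(dr, length(dr), length(dc))
  DC <- matrix(dc, length(dr), length(dc), byrow = TRUE)
  u <- DR * cos(cell$phi) + DC * sin(cell$phi)
  v <- -DR * sin(cell$phi) + DC * cos(cell$phi)
  env <- exp(-(u^2 / (2 * (cell$a / 2)^2) + v^2 / (2 * (cell$b / 2)^2)))
  env[env < 0.02] <- 0
  stripes <- 1 + stripe_depth *
    sin(2 * pi * stripe_freq * u + cell$stripe_phase + phase_shift)
  patch <- intensity * env * pmax(stripes, 0)
  frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] + patch
  frame
}

apply_shot_noise <- function(frame, shot_scale) {
  if (!is.finite(shot_scale)) return(frame)
  noisy <- stats::rpois(length(frame), lambda = pmax(frame, 0) * shot_scale) /
    shot_scale
  matrix(noisy, nrow(frame), ncol(frame))
}

#' Generate time-lapse TIFF stacks for a scenario
#'
#' Renders, per condition x replicate x field, a multi-page 16-bit
#' grayscale TIFF whose frames show textured elliptical cells with
#' integrated intensity following the condition's (noisy) kinetic
#' trajectory over a dim constant background (at most 1/100 of initial
#' cell brightness, the fluorogenic contrast of probe detachment).
#' A manifest CSV and ground-truth CSVs (parameters and the per-field
#' trajectories actually rendered) are written alongside.
#'
#' @param scn A `smat_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data frame: path,
#'   condition, replicate, field, time_min semicolon-list, background),
#'   `truth_params`, and `truth_traces`.
#' @export
generate_timelapse_stack <- function(scn, dir) {
  stopifnot(inherits(scn, "smat_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(scn$seed)
  manifest <- list(); truth <- list()
  for (cn in names(scn$conditions)) {
    base <- condition_trajectory(scn, cn)
    for (r in seq_len(scn$n_replicates)) for (f in seq_len(scn$n_fields)) {
      cells <- sample_cells(scn)
      traj <- pmax(0, base + stats::rnorm(length(base), sd = scn$noise_sd))
      frames <- lapply(traj, function(ct) {
        fr <- matrix(scn$background_level, scn$frame_size, scn$frame_size)
        for (i in seq_len(nrow(cells)))
          fr <- render_cell(fr, cells[i, ], intensity = cells$amp[i] * ct)
        pmin(apply_shot_noise(fr, scn$shot_scale), 1)
      })
      path <- file.path(dir, sprintf("%s_rep%d_field%d.tif", cn, r, f))
      tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
      manifest[[length(manifest) + 1]] <- data.frame(
        path = basename(path), condition = cn, replicate = r, field = f,
        time_min = paste(scn$times, collapse = ";"),
        background = scn$background_level)
      truth[[length(truth) + 1]] <- data.frame(
        condition = cn, replicate = r, field = f, time_min = scn$times,
        value = traj)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth_traces <- do.call(rbind, truth)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(scenario_truth(scn), file.path(dir, "truth_params.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_traces, file.path(dir, "truth_traces.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, truth_params = scenario_truth(scn),
                 truth_traces = truth_traces))
}

# Latent 2D condition directions for the divergence schedule.
condition_directions <- function(conds) {
  dirs <- list(c(0, 0), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1), c(0, 1.4),
               c(1.4, 0))
  out <- dirs[seq_along(conds) %% length(dirs) + 1]
  out[[1]] <- c(0, 0)  # first condition is the basal anchor
  names(out) <- conds
  out
}

#' Generate a dual-stain single-cell population at one timepoint
#'
#' Renders, per condition, fields of dual-channel (SA + phalloidin) plus
#' nuclear-channel cells whose intensity balance and stripe-texture
#' coarseness diverge between conditions with the effect size of the
#' scenario's divergence schedule at `timepoint`. Each cell carries a
#' latent turnover score: high scores mean retained SA and little
#' phalloidin (which can only stain F-actin sites the first probe has
#' vacated), so per-cell SA and phalloidin intensities are
#' anticorrelated across the population by construction.
#'
#' @param scn A `smat_scenario` whose `divergence_schedule` covers
#'   `timepoint`.
#' @param timepoint Timepoint (min) of the schedule.
#' @param n_fields Fields rendered per condition (default 2).
#' @return List with `images` (list of `list(condition, field, img)` where
#'   `img` is a [dual_channel_image()]), and `truth` (per-cell data frame:
#'   condition, field, row, col, turnover score, texture score, rendered
#'   SA and Ph amplitudes).
#' @export
generate_dual_stain_population <- function(scn, timepoint, n_fields = 2) {
  stopifnot(inherits(scn, "smat_scenario"))
  key <- as.character(timepoint)
  if (!key %in% names(scn$divergence_schedule))
    stop("divergence schedule not defined at timepoint ", timepoint)
  eff <- scn$divergence_schedule[[key]]
  conds <- names(scn$conditions)
  dirs <- condition_directions(conds)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  # decouple from the trace/stack streams, keep below 2^31
  set.seed((scn$seed * 131L + match(key, names(scn$divergence_schedule))) %%
             2147483647L)
  images <- list(); truth <- list()
  for (cn in conds) {
    mu <- dirs[[cn]] * eff
    for (f in seq_len(n_fields)) {
      cells <- sample_cells(scn)
      n <- nrow(cells)
      u1 <- mu[1] + stats::rnorm(n)          # turnover score
      u2 <- mu[2] + stats::rnorm(n)          # texture score
      sa_amp <- pmin(pmax(0.55 + 0.09 * u1, 0.1), 1)
      ph_amp <- pmin(pmax(0.55 - 0.09 * u1 + 0.02 * stats::rnorm(n), 0.1), 1)
      freq <- pmax(0.04, cells$stripe_freq * (1 + 0.18 * tanh(u2 / 2)))
      depth <- pmin(pmax(cells$stripe_depth + 0.08 * tanh(u2 / 2), 0.1), 0.9)

      sa <- matrix(scn$background_level, scn$frame_size, scn$frame_size)
      ph <- matrix(scn$background_level, scn$frame_size, scn$frame_size)
      nuc <- matrix(0.002, scn$frame_size, scn$frame_size)
      for (i in seq_len(n)) {
        sa <- render_cell(sa, cells[i, ], sa_amp[i],
                          stripe_freq = freq[i], stripe_depth = depth[i])
        ph <- render_cell(ph, cells[i, ], ph_amp[i], phase_shift = pi,
                          stripe_freq = freq[i], stripe_depth = depth[i])
        nuccell <- cells[i, ]  # round nucleus centered in the cell body
        nuccell$a <- cells$a[i] * 0.35; nuccell$b <- cells$a[i] * 0.35
        nuccell$stripe_phase <- 0
        nuc <- render_cell(nuc, nuccell, 0.85, stripe_freq = 0,
                           stripe_depth = 0)
      }
      img <- dual_channel_image(
        pmin(apply_shot_noise(sa, scn$shot_scale), 1),
        pmin(apply_shot_noise(ph, scn$shot_scale), 1),
        pmin(apply_shot_noise(nuc, scn$shot_scale), 1))
      images[[length(images) + 1]] <- list(condition = cn, field = f,
                                           img = img)
      truth[[length(truth) + 1]] <- data.frame(
        condition = cn, field = f, row = cells$row, col = cells$col,
        turnover_score = u1, texture_score = u2,
        sa_amp = sa_amp, ph_amp = ph_amp)
    }
  }
  list(images = images, truth = do.call(rbind, truth), effect_size = eff)
}
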