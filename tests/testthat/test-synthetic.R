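small_scn <- function(...) {
  scenario_preset("lineage", seed = 5, frame_size = 192, cells_per_field = 6,
                  cell_size_range = c(8, 13), n_replicates = 2, n_fields = 2,
                  times = seq(0, 300, by = 60), ...)
}

test_that("trace generation is exact at zero noise and deterministic", {
  scn <- scenario_preset("lineage", seed = 3, noise_sd = 0)
  tr <- generate_traces(scn)
  one <- tr[tr$condition == "AD" & tr$replicate == 1 & tr$field == 1, ]
  expect_equal(one$value,
               simulate_dissociation(scn$conditions$AD, scn$times)$values)
  # all replicates identical without noise
  expect_equal(max(tapply(tr$value, paste(tr$condition, tr$time_min), sd)), 0)

  scn2 <- scenario_preset("lineage", seed = 3)
  expect_identical(generate_traces(scn2), generate_traces(scn2))
  scn3 <- scenario_preset("lineage", seed = 4)
  expect_false(identical(generate_traces(scn2), generate_traces(scn3)))
})

test_that("association scenarios rise from zero toward their plateau", {
  scn <- scenario_preset("lineage_assoc", seed = 6, noise_sd = 0)
  tr <- generate_traces(scn)
  for (cn in names(scn$conditions)) {
    v <- tr[tr$condition == cn & tr$replicate == 1 & tr$field == 1, "value"]
    expect_equal(v[1], 0)
    expect_true(all(diff(v) > 0))
  }
})

test_that("lineage preset orders late-time condition means AD > CH > OS ~ BA", {
  scn <- scenario_preset("lineage", seed = 11)
  tr <- generate_traces(scn)
  late <- tr[tr$time_min >= 600, ]
  m <- tapply(late$value, as.character(late$condition), mean)
  expect_gt(m["AD"], m["CH"])
  expect_gt(m["CH"], m["OS"])
  expect_lt(abs(m["OS"] - m["BA"]), 0.05)
})

test_that("media-switch traces are continuous and respond to the swap", {
  scn <- scenario_preset("switch", seed = 12, noise_sd = 0)
  tr <- generate_traces(scn)
  swp <- tr[tr$condition == "AD_to_BA" & tr$replicate == 1 & tr$field == 1, ]
  # continuity at the swap: the value at the switch frame closes the
  # pre-switch closed form exactly
  pre <- simulate_dissociation(scn$conditions$AD_to_BA, scn$times)$values
  expect_equal(swp$value[swp$time_min == 240], pre[scn$times == 240])
  ad <- tr[tr$condition == "AD" & tr$replicate == 1 & tr$field == 1, ]
  # before: identical to AD; after: decays away from AD
  expect_equal(swp$value[swp$time_min <= 240], ad$value[ad$time_min <= 240])
  expect_lt(swp$value[swp$time_min == 480], ad$value[ad$time_min == 480] - 0.1)

  # a switch to identical parameters is a no-op
  noop <- smat_scenario(conditions = list(X = kinetic_params(0.002, 0.02)),
                        times = seq(0, 300, 60), switch_time = 120,
                        post_conditions = list(X = kinetic_params(0.002, 0.02)),
                        noise_sd = 0, seed = 1)
  plain <- smat_scenario(conditions = list(X = kinetic_params(0.002, 0.02)),
                         times = seq(0, 300, 60), noise_sd = 0, seed = 1)
  expect_equal(generate_traces(noop)$value, generate_traces(plain)$value)
})

test_that("rendered stacks honor the >100-fold fluorogenic contrast", {
  scn <- small_scn(noise_sd = 0, shot_scale = Inf)
  dir <- withr::local_tempdir()
  out <- generate_timelapse_stack(scn, dir)
  frames <- tiff::readTIFF(file.path(dir, out$manifest$path[1]), all = TRUE)
  f1 <- frames[[1]]
  bg <- median(f1)               # most pixels are background
  peak <- max(f1)
  expect_lte(bg / peak, 0.01)
  expect_true(all(out$manifest$background <= 0.01))
  # scenario validation refuses a brighter background
  expect_error(small_scn(background_level = 0.05), "100-fold")
})

test_that("frame mean gray values track the generating trajectory", {
  scn <- small_scn(noise_sd = 0, shot_scale = Inf)
  dir <- withr::local_tempdir()
  out <- generate_timelapse_stack(scn, dir)
  row <- out$manifest[3, ]
  frames <- tiff::readTIFF(file.path(dir, row$path), all = TRUE)
  mg <- vapply(frames, mean, numeric(1)) - row$background
  truth <- out$truth_traces[out$truth_traces$condition == row$condition &
                            out$truth_traces$replicate == row$replicate &
                            out$truth_traces$field == row$field, "value"]
  expect_equal(mg / mg[1], truth / truth[1], tolerance = 0.02)
})

test_that("stack generation is byte-identical under a fixed seed", {
  scn <- small_scn()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_timelapse_stack(scn, d1)
  generate_timelapse_stack(scn, d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("packing capacity is enforced", {
  dense <- scenario_preset("lineage", seed = 5, frame_size = 192,
                           cells_per_field = 400)
  expect_error(generate_timelapse_stack(dense, withr::local_tempdir()),
               "packing capacity")
})

test_that("dual-stain populations anticorrelate SA and phalloidin", {
  scn <- small_scn(cells_per_field = 8)
  pop <- generate_dual_stain_population(scn, 480, n_fields = 2)
  expect_lt(cor(pop$truth$sa_amp, pop$truth$ph_amp, method = "spearman"),
            -0.8)
  # measured per-cell mean intensities inherit the anticorrelation
  # (integrated intensity also carries cell-size variation, so the mean
  # is the clean readout of the turnover-driven intensity balance)
  rows <- list()
  for (fl in pop$images) {
    seg <- segment_cells(fl$img)
    if (seg$n_cells == 0) next
    rows[[length(rows) + 1]] <-
      extract_all_features(fl$img, seg)[, c("sa_mean_intensity",
                                            "ph_mean_intensity")]
  }
  feats <- do.call(rbind, rows)
  expect_lt(cor(feats$sa_mean_intensity, feats$ph_mean_intensity,
                method = "spearman"), -0.3)
  expect_error(generate_dual_stain_population(scn, 999), "schedule")
})

test_that("zero effect size makes conditions exchangeable", {
  scn <- small_scn(cells_per_field = 8,
                   divergence_schedule = c("0" = 0, "60" = 1))
  pop <- generate_dual_stain_population(scn, 0, n_fields = 1)
  m <- tapply(pop$truth$sa_amp, pop$truth$condition, mean)
  expect_lt(max(m) - min(m), 0.15)
})
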