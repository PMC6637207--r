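make_traces <- function(values_list, condition = "A", times = NULL) {
  do.call(rbind, lapply(seq_along(values_list), function(i) {
    v <- values_list[[i]]
    data.frame(condition = condition, replicate = 1L, field = i,
               time_min = if (is.null(times)) seq_along(v) - 1 else times,
               value = v)
  }))
}

test_that("mean gray value matches a brute-force pixel loop", {
  expect_equal(mean_gray_value(matrix(7, 5, 5)), 7)
  expect_equal(mean_gray_value(matrix(c(0, 10, 0, 10), 2, 2)), 5)
  set.seed(11)
  fr <- matrix(runif(30 * 20), 30, 20)
  acc <- 0
  for (r in 1:30) for (c in 1:20) acc <- acc + fr[r, c]
  expect_equal(mean_gray_value(fr), acc / 600)
  mask <- fr > 0.5
  expect_equal(mean_gray_value(fr, mask), sum(fr[mask]) / sum(mask))
  expect_error(mean_gray_value(fr, matrix(FALSE, 30, 20)), "empty mask")
})

test_that("trace normalization is exact at t0 and idempotent", {
  tr <- data.frame(time_min = 0:2, value = c(10, 5, 2.5))
  expect_equal(normalize_trace(tr)$value, c(1, 0.5, 0.25))
  const <- data.frame(time_min = 0:4, value = rep(3, 5))
  expect_equal(normalize_trace(const)$value, rep(1, 5))
  set.seed(2)
  rnd <- data.frame(time_min = 0:9, value = runif(10, 0.1, 5))
  once <- normalize_trace(rnd)
  expect_identical(normalize_trace(once)$value, once$value)
  expect_equal(once$value[1], 1)
  bad <- data.frame(condition = "AD", field = 2, time_min = 0:2,
                    value = c(0, 1, 1))
  expect_error(normalize_trace(bad), "AD")
})

test_that("condition aggregation gives pointwise mean and SEM", {
  tr <- make_traces(list(c(1, 0.4), c(1, 0.6)))
  curve <- aggregate_condition(tr)
  expect_equal(curve$mean, c(1, 0.5))
  expect_equal(curve$sem, c(0, 0.1))
  expect_equal(curve$n, c(2, 2))

  # identical traces: mean is the trace, sem is zero
  same <- make_traces(list(c(1, 0.7, 0.3), c(1, 0.7, 0.3)))
  cs <- aggregate_condition(same)
  expect_equal(cs$mean, c(1, 0.7, 0.3))
  expect_equal(cs$sem, rep(0, 3))

  # 3 replicates x 4 fields vs explicit recomputation, any trace order
  set.seed(4)
  tr12 <- do.call(rbind, lapply(1:3, function(r) lapply(1:4, function(f) {
    data.frame(condition = "X", replicate = r, field = f, time_min = 0:5,
               value = c(1, sort(runif(5), decreasing = TRUE)))
  }) |> (\(l) do.call(rbind, l))()))
  shuffled <- tr12[sample(nrow(tr12)), ]
  curve12 <- aggregate_condition(shuffled)
  M <- matrix(NA_real_, 6, 12)
  k <- 0
  for (r in 1:3) for (f in 1:4) {
    k <- k + 1
    sub <- tr12[tr12$replicate == r & tr12$field == f, ]
    M[, k] <- sub$value[order(sub$time_min)]
  }
  expect_equal(curve12$mean, rowMeans(M))
  expect_equal(curve12$sem, apply(M, 1, sd) / sqrt(12))
  expect_error(aggregate_condition(make_traces(list(c(1, 0.5)))), "2 traces")
})

test_that("per-timepoint comparisons detect a late injected shift only", {
  set.seed(7)
  times <- 0:9
  mk <- function(cond, shift) do.call(rbind, lapply(1:6, function(f) {
    v <- exp(-0.2 * times) + rnorm(10, sd = 0.02)
    v[8:10] <- v[8:10] + shift[8:10]
    data.frame(condition = cond, replicate = 1L, field = f,
               time_min = times, value = v)
  }))
  tr <- rbind(mk("ref", rep(0, 10)), mk("hit", c(rep(0, 7), rep(0.6, 3))))
  cmp <- compare_conditions(tr, reference = "ref")
  tab <- cmp$table
  expect_true(all(tab$p_adj[tab$time_min >= 7] < 0.001))
  expect_true(all(tab$p_adj[tab$time_min <= 4] > 0.05))
  expect_true(all(tab$p_adj >= 0 & tab$p_adj <= 1))
  expect_equal(tab$stars[tab$time_min == 9], "***")
})

test_that("Bonferroni factor is the number of timepoints", {
  set.seed(8)
  one <- rbind(
    data.frame(condition = "A", replicate = 1, field = 1:6, time_min = 0,
               value = rnorm(6, 1)),
    data.frame(condition = "B", replicate = 1, field = 1:6, time_min = 0,
               value = rnorm(6, 1.2)))
  cmp <- compare_conditions(one, reference = "A")
  expect_equal(cmp$table$p_adj, cmp$table$p)  # single timepoint: factor 1
})

test_that("media-switch analysis re-references the post window", {
  scn <- scenario_preset("switch", seed = 5, noise_sd = 0.01)
  tr <- normalize_traces(generate_traces(scn))
  res <- segment_switch_analysis(tr, switch_time = 240, reference = "BA")
  post <- res$post$table
  # swapped condition behaves like AD after the switch: late significance
  late <- post[post$condition == "BA_to_AD" & post$time_min >= 420, ]
  expect_true(all(late$p_adj < 0.01))
  # pre-switch window: the swap conditions match their original media
  pre <- res$pre$table
  pre_ba <- pre[pre$condition == "BA_to_AD", ]
  expect_true(all(pre_ba$p_adj > 0.05))

  # switch at the first timepoint degenerates to a plain comparison
  r0 <- segment_switch_analysis(tr, switch_time = 0, reference = "BA")
  expect_null(r0$pre)
  plain <- compare_conditions(tr, reference = "BA")
  expect_equal(r0$post$table$p_adj, plain$table$p_adj)
  expect_error(segment_switch_analysis(tr, 1e6, "BA"), "outside")
})

test_that("null traces produce no spurious post-switch significance", {
  scn <- scenario_preset("null", seed = 42, times = seq(0, 120, 15))
  tr <- normalize_traces(generate_traces(scn))
  res <- segment_switch_analysis(tr, switch_time = 60, reference = "A")
  expect_true(all(res$post$table$p_adj > 0.05))
})
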