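test_that("a cheap measure identical to the gold standard costs the same", {
  cfg <- simulation_config(validity_r = 1, category_counts = 100,
                           gold_cost = 10, cheap_cost = 10,
                           sd_grid = c(1, 5, 10, 25))
  curves <- run_cost_simulation(cfg)
  expect_equal(curves$cost_ratio, rep(1, nrow(curves)))
  expect_equal(curves$n_cheap, curves$n_gold)
})

test_that("with equal variances the cost ratio is the unit-cost ratio", {
  cfg <- simulation_config(validity_r = 1, category_counts = 100,
                           gold_cost = 50, cheap_cost = 5,
                           sd_grid = c(0.5, 2, 10, 25))
  curves <- run_cost_simulation(cfg)
  expect_equal(curves$cost_ratio, rep(0.1, nrow(curves)))
})

test_that("cost accounting is conserved row by row", {
  cfg <- simulation_config(sd_grid = c(2, 8, 20), include_nonresponse = TRUE)
  curves <- run_cost_simulation(cfg)
  expect_equal(curves$total_cost_cheap, 2 * curves$recruited_cheap * cfg$cheap_cost)
  expect_equal(curves$total_cost_gold, 2 * curves$recruited_gold * cfg$gold_cost)
  expect_true(all(curves$recruited_cheap >= curves$n_cheap))
  expect_true(all(curves$recruited_gold > curves$n_gold))

  off <- run_cost_simulation(simulation_config(sd_grid = c(2, 8, 20)))
  expect_equal(off$recruited_cheap, off$n_cheap)
  expect_equal(off$recruited_gold, off$n_gold)
})

test_that("when lost participants cost nothing only responders are billed", {
  cfg <- simulation_config(sd_grid = 10, include_nonresponse = TRUE,
                           lost_cost_equals_followed = FALSE)
  curves <- run_cost_simulation(cfg)
  expect_equal(curves$total_cost_cheap, 2 * curves$n_cheap * cfg$cheap_cost)
  expect_true(all(curves$recruited_cheap >= curves$n_cheap))
})

test_that("the default simulation is deterministic", {
  cfg <- simulation_config(sd_grid = seq(0.5, 5, by = 0.5))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  export_curves(run_cost_simulation(cfg), f1)
  export_curves(run_cost_simulation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a zero burden slope makes the non-response panel coincide with the base panel", {
  on <- run_cost_simulation(simulation_config(sd_grid = c(1, 10), burden_slope = 0,
                                              include_nonresponse = TRUE))
  off <- run_cost_simulation(simulation_config(sd_grid = c(1, 10), burden_slope = 0))
  expect_equal(on$cost_ratio, off$cost_ratio)
  # every measure gets the same uniform recruitment inflation
  expect_equal(on$recruited_cheap / on$n_cheap,
               rep(1 / 0.97, nrow(on)))
  expect_equal(on$recruited_gold / on$n_gold, on$recruited_cheap / on$n_cheap)
  # ... as does a baseline response probability of 1
  p1 <- run_cost_simulation(simulation_config(sd_grid = c(1, 10),
                                              baseline_response_p = 1,
                                              include_nonresponse = TRUE))
  off2 <- run_cost_simulation(simulation_config(sd_grid = c(1, 10)))
  expect_equal(p1$cost_ratio, off2$cost_ratio)
})

test_that("the default grid yields one row per (sd, M) cell", {
  curves <- run_cost_simulation(simulation_config())
  expect_equal(nrow(curves), 50 * 5)
  expect_equal(sort(unique(curves$M)), c(3, 5, 8, 10, 15))
  expect_equal(length(unique(curves$sd)), 50)
})

test_that("export writes a CSV and only plots when asked", {
  curves <- run_cost_simulation(simulation_config(sd_grid = c(1, 2)))
  csv <- tempfile(fileext = ".csv")
  export_curves(curves[1:2, ], csv)
  lines <- readLines(csv)
  expect_length(lines, 3)  # header + 2 rows
  png <- tempfile(fileext = ".png")
  expect_false(file.exists(png))
  export_curves(curves, csv, plot_path = png)
  expect_true(file.exists(png))
  expect_error(export_curves(curves[0, ], csv), "nrow")
})

test_that("invalid configurations are rejected before any computation", {
  expect_error(simulation_config(gold_cost = 0), "costs")
  expect_error(simulation_config(sd_grid = numeric(0)), "sd_grid")
  expect_error(simulation_config(sd_grid = c(0, 5)), "sd_grid")
  expect_error(simulation_config(category_counts = numeric(0)), "category_counts")
  expect_error(simulation_config(baseline_response_p = 0), "baseline_response_p")
})

test_that("odds-scale response penalty is available and weaker near p = 1", {
  rate <- run_cost_simulation(simulation_config(sd_grid = 10,
                                                include_nonresponse = TRUE,
                                                response_scale = "rate"))
  odds <- run_cost_simulation(simulation_config(sd_grid = 10,
                                                include_nonresponse = TRUE,
                                                response_scale = "odds"))
  expect_true(all(odds$recruited_gold < rate$recruited_gold))
})
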