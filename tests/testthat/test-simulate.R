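test_that("morphometry sampler reduces to the cell means at zero SD", {
  mo <- default_moments_zero_sd <- {
    m <- scarkit:::default_morphometry_moments()
    m$sd <- 0
    m
  }
  tab <- generate_morphometry_table(morphometry_sim_spec(n_per_group = 3,
                                                         moments = mo,
                                                         seed = 2))
  d7 <- tab[tab$group == "CONT" & tab$day == 7, ]
  expect_true(all(d7$D == mo$mean[mo$group == "CONT" & mo$day == 7 &
                                    mo$variable == "D"]))
  expect_equal(stats::sd(d7$N), 0)
})

test_that("morphometry sampler converges to the reference moments", {
  tab <- generate_morphometry_table(morphometry_sim_spec(n_per_group = 1000,
                                                         seed = 4))
  d <- tab$D[tab$group == "CONT" & tab$day == 7]
  se <- 279.3 / sqrt(1000)
  expect_lt(abs(mean(d) - 527.2), 3 * se)
  vars <- c("D", "DPA", "EPI", "L", "N", "NEO", "S", "T", "H", "B")
  expect_true(all(tab[vars] >= 0))
})

test_that("negative SDs are rejected", {
  mo <- scarkit:::default_morphometry_moments()
  mo$sd[1] <- -1
  expect_error(morphometry_sim_spec(moments = mo), "SD")
})

test_that("scar time-series follows the exact decay law at zero noise", {
  gp <- scar_group_params()
  for (g in names(gp)) gp[[g]]$noise_sdlog <- 0
  ts <- generate_scar_timeseries(gp, n_wounds_per_group = 2, seed = 1)
  cont <- ts[ts$group == "CONT" & ts$animal == "CONT_01" &
               ts$wound_site == "rostral", ]
  expect_equal(cont$area_mm2, 30 * exp(-0.08 * cont$day), tolerance = 1e-12)
  expect_equal(cont$length_mm, 15 * exp(-0.005 * cont$day), tolerance = 1e-12)
})

test_that("faster NAC30 decay shows up as a smaller day-3 mean area", {
  ts <- generate_scar_timeseries(n_wounds_per_group = 1000, days = 3,
                                 seed = 8)
  m <- tapply(ts$area_mm2, ts$group, mean)
  expect_lt(m[["NAC30"]], m[["CONT"]])
  expect_lt(abs(m[["NAC15"]] - m[["CONT"]]) / m[["CONT"]], 0.05)
})

test_that("time-series input validation", {
  expect_error(generate_scar_timeseries(days = numeric(0)), "empty")
  gp <- scar_group_params(); gp$CONT$area_decay <- 0
  expect_error(generate_scar_timeseries(gp), "positive")
  one <- generate_scar_timeseries(days = 1, n_wounds_per_group = 1, seed = 1)
  expect_equal(nrow(one), length(scar_group_params()))
})

test_that("rater scores reproduce truth exactly at zero noise", {
  truth <- data.frame(sample = "s1",
                      parameter = c("granulation", "collagen deposition"),
                      truth = c(1.23, 2.87))
  sc <- generate_rater_scores(truth, n_raters = 3, noise_sd = 0, seed = 1)
  expect_equal(sc$value, rep(round(truth$truth * 10) / 10, 3))
})

test_that("rater scores are clipped and quantized", {
  truth <- data.frame(sample = "s1", parameter = "epithelialization",
                      truth = 2.9)
  sc <- generate_rater_scores(truth, n_raters = 50, noise_sd = 2, seed = 2)
  expect_true(all(sc$value >= 0 & sc$value <= 3))
  expect_true(all(abs(sc$value * 10 - round(sc$value * 10)) < 1e-9))
  expect_error(generate_rater_scores(truth, noise_sd = -1), "nonnegative")
  expect_error(generate_rater_scores(truth, n_raters = 0), "rater")
})

test_that("averaging three raters shrinks the error like 1/sqrt(3)", {
  truth <- data.frame(sample = "s1", parameter = "granulation", truth = 1.5)
  reps <- 1000
  single <- numeric(reps); triple <- numeric(reps)
  for (r in seq_len(reps)) {
    sc <- generate_rater_scores(truth, n_raters = 3, noise_sd = 0.4,
                                seed = r)
    single[r] <- sc$value[1]
    triple[r] <- mean(sc$value)
  }
  ratio <- stats::sd(triple) / stats::sd(single)
  expect_lt(abs(ratio - 1 / sqrt(3)), 0.1)
})
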