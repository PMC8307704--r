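test_that("index anchors from canonical configurations", {
  m <- list(D = 0, L = 100, N = 200, S = 100, T = 0, H = 50, B = 300)
  b <- list(H0 = 50, B0 = 300)
  idx <- compute_indices(m, b)
  expect_equal(idx$SCI, 0)
  expect_equal(idx$DCI, 1)
  expect_equal(idx$WSI, 1)
  expect_equal(idx$RHI, 0)
  expect_equal(idx$MRI, 0)
  expect_equal(idx$GRI, 0)
  expect_equal(idx$GCI, 1)
  expect_equal(idx$GHI, 0)
})

test_that("published group means reproduce the published index means", {
  expect_equal(round(sci(L = 793.99, S = 696.69), 2), 0.12)  # 0.1225
  expect_equal(round(mri(B0 = 189079.1, B = 652444.9), 2), -2.45)
  expect_equal(round(dci(N = 1434.4, D = 527.2), 2), 0.63)
})

test_that("identity suite holds exactly for every sample", {
  tab <- generate_morphometry_table(morphometry_sim_spec(n_per_group = 6,
                                                         seed = 14))
  res <- index_table(tab)$per_sample
  expect_equal(res$GCI, res$SCI + res$DCI, tolerance = 1e-12)
  expect_equal(res$GHI, res$GCI - res$WSI, tolerance = 1e-12)
  expect_equal(res$GRI, (res$RHI + res$MRI) / 2, tolerance = 1e-12)
})

test_that("indices are invariant to uniform rescaling of the geometry", {
  m <- list(D = 310, L = 1200, N = 1500, S = 900, T = 1100, H = 800,
            B = 2e5)
  b <- list(H0 = 1600, B0 = 1.9e5)
  a <- compute_indices(m, b)
  c <- 3.7
  m2 <- list(D = m$D * c, L = m$L * c, N = m$N * c, S = m$S * c,
             T = m$T * c, H = m$H * c, B = m$B * c^2)
  b2 <- list(H0 = b$H0 * c, B0 = b$B0 * c^2)
  expect_equal(unlist(compute_indices(m2, b2)), unlist(a),
               tolerance = 1e-12)
})

test_that("zero denominators are signalled per index", {
  expect_warning(v <- sci(L = 0, S = 10), "SCI")
  expect_true(is.na(v))
  expect_warning(v2 <- rhi(H0 = 0, H = 5), "RHI")
  expect_true(is.na(v2))
})

test_that("locked formulas agree with >= 80% of the reference index cells", {
  ref <- reference_morphometry()
  g <- function(day, group, var)
    ref$mean[ref$day == day & ref$group == group & ref$variable == var]
  cols <- list(c(7, "CONT"), c(7, "gNAC"), c(7, "NAC30"), c(14, "CONT"),
               c(14, "gNAC"), c(60, "CONT"), c(60, "gNAC"))
  ok <- 0; total <- 0
  for (cl in cols) {
    day <- as.numeric(cl[1]); grp <- cl[2]
    checks <- list(
      SCI = sci(g(day, grp, "L"), g(day, grp, "S")),
      DCI = dci(g(day, grp, "N"), g(day, grp, "D")),
      WSI = wsi(g(day, grp, "N"), g(day, grp, "T")),
      GCI = gci(g(day, grp, "SCI"), g(day, grp, "DCI")),
      GHI = ghi(g(day, grp, "SCI"), g(day, grp, "DCI"), g(day, grp, "WSI")))
    if (day != 7) {
      base_grp <- if (grp == "NAC30") "gNAC" else grp
      checks$RHI <- rhi(g(7, base_grp, "H"), g(day, grp, "H"))
      checks$MRI <- mri(g(7, base_grp, "B"), g(day, grp, "B"))
      checks$GRI <- gri(g(day, grp, "RHI"), g(day, grp, "MRI"))
    }
    for (nm in names(checks)) {
      total <- total + 1
      if (abs(checks[[nm]] - g(day, grp, nm)) <= 0.02) ok <- ok + 1
    }
  }
  expect_gte(total, 45)
  expect_gte(ok / total, 0.80)
})

test_that("index_table summarizes a zero-variance table exactly", {
  mo <- scarkit:::default_morphometry_moments()
  mo$sd <- 0
  tab <- generate_morphometry_table(morphometry_sim_spec(n_per_group = 3,
                                                         moments = mo,
                                                         seed = 1))
  res <- index_table(tab)
  s <- res$summary
  d60 <- s[s$group == "CONT" & s$day == 60 & s$index == "DCI", ]
  expect_equal(d60$mean, (1680.7 - 157.2) / 1680.7, tolerance = 1e-9)
  expect_equal(d60$sd, 0)
  # permuting sample order leaves the summary unchanged
  res2 <- index_table(tab[sample(nrow(tab)), ])
  expect_equal(res2$summary, s)
})

test_that("Meeh-Rubner scaling and treated-area fraction", {
  expect_equal(body_surface_area_meeh(250), 10 * 250^(2 / 3))
  expect_lt(abs(body_surface_area_meeh(250) - 400), 4)
  expect_equal(body_surface_area_meeh(500) / body_surface_area_meeh(250),
               2^(2 / 3))
  expect_error(body_surface_area_meeh(0), "positive")
  expect_equal(treated_area_fraction(4, 400), 0.01)
  expect_equal(treated_area_fraction(7, 7), 1)
  expect_error(treated_area_fraction(0, 400), "positive")
})
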