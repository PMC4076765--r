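test_that("expected daily walking distance weights classes by trip count", {
  expect_equal(tdwd(500, c(0, 1, 0, 0)), 500)
  expect_equal(tdwd(800, c(0, 0.5, 0.3, 0.2)), 800 * (0.5 + 0.6 + 0.6))
  expect_equal(tdwd(123, c(1, 0, 0, 0)), 0)
  ## the open class is valued at k_cap
  expect_equal(tdwd(100, c(0, 0, 0, 1), k_cap = 5), 500)
  expect_error(tdwd(100, c(0.5, 0.2, 0.2, 0.2)), "summing to 1")
  expect_error(tdwd(-5, c(1, 0, 0, 0)))
})

test_that("weekly walking minutes and compliance follow the guideline algebra", {
  cfg <- guideline_config()
  expect_equal(wwm(2052, cfg), 150)
  expect_equal(wwm(0, cfg), 0)
  cfg10 <- guideline_config(days_per_week = 10)
  expect_equal(wwm(2052, cfg10), 2 * wwm(2052, cfg))
  expect_equal(compliance_percent(150, cfg), 100)
  expect_equal(compliance_percent(22.5, cfg), 15)
  expect_equal(compliance_percent(0, cfg), 0)
  ## not capped at 100
  expect_equal(compliance_percent(450, cfg), 300)
})

test_that("guideline distance equivalent reproduces the published constant", {
  expect_equal(round(guideline_distance_km(guideline_config()), 2), 10.26)
  expect_equal(guideline_distance_km(guideline_config(weekly_minutes = 100,
                                                      walking_speed = 60)),
               6)
})

test_that("compliance is invariant to jointly rescaling speed and guideline", {
  d <- 700; probs <- c(0.2, 0.4, 0.3, 0.1)
  base <- guideline_config()
  scaled <- guideline_config(weekly_minutes = base$weekly_minutes / 2,
                             walking_speed = base$walking_speed * 2)
  expect_equal(compliance_percent(wwm(tdwd(d, probs), base), base),
               compliance_percent(wwm(tdwd(d, probs), scaled), scaled))
})

test_that("single-cell raster equals the hand-chained prediction pipeline", {
  dist_pars <- tiny_joint_params(sigma = 0.7, rho = -0.3)
  freq_pars <- tiny_freq_params()
  sch <- tiny_schema()
  prof <- person_profile(list(income = "top", vehicles = "none",
                              street_density = 6), sch)
  grid <- grid_spec(c(100, 200), 1, 1, cbd_xy = c(2100, 200),
                    cell_size = 250)
  cfg <- guideline_config()
  ras <- build_compliance_raster(prof, dist_pars, freq_pars, grid, cfg)
  centroid <- c(100 + 125, 200 + 125)
  trend <- trend_terms(centroid, unit_scaler(), c(2100, 200))
  d_hat <- predict_distance(prof$design, trend, dist_pars, "walk")
  pr <- marginal_class_probs(prof$design, trend, freq_pars, "walk")
  expect_equal(ras$layers$d_hat[1, 1], d_hat)
  expect_equal(c(ras$layers$p1, ras$layers$p2, ras$layers$p3plus),
               unname(pr[2:4]))
  td <- tdwd(d_hat, pr)
  expect_equal(ras$layers$tdwd[1, 1], td)
  expect_equal(ras$layers$wwm[1, 1], wwm(td, cfg))
  expect_equal(ras$layers$compliance[1, 1],
               compliance_percent(wwm(td, cfg), cfg))
})

test_that("raster layers are finite, nonnegative and reconstruct TDWD cellwise", {
  dist_pars <- tiny_joint_params()
  freq_pars <- tiny_freq_params()
  prof <- person_profile(list(income = "mid", vehicles = "one",
                              street_density = 4), tiny_schema())
  grid <- grid_spec(c(-2000, -2000), 8, 11, cbd_xy = c(0, 0))
  ras <- build_compliance_raster(prof, dist_pars, freq_pars, grid)
  for (nm in names(ras$layers)) {
    expect_equal(dim(ras$layers[[nm]]), c(8L, 11L))
    expect_true(all(is.finite(ras$layers[[nm]])))
    expect_true(all(ras$layers[[nm]] >= 0))
  }
  expect_true(all(ras$layers$p1 + ras$layers$p2 + ras$layers$p3plus <= 1))
  recon <- ras$layers$d_hat * (ras$layers$p1 + 2 * ras$layers$p2 +
                                 3 * ras$layers$p3plus)
  expect_equal(ras$layers$tdwd, recon, tolerance = 1e-12)
  ## deterministic rebuild
  ras2 <- build_compliance_raster(prof, dist_pars, freq_pars, grid)
  expect_identical(ras$layers, ras2$layers)
})

test_that("profiles differing only in a zero-coefficient covariate map identically", {
  dist_pars <- tiny_joint_params()
  freq_pars <- tiny_freq_params()
  ## income:mid carries a zero coefficient in every walk equation
  p1 <- person_profile(list(income = "low", vehicles = "one",
                            street_density = 4), tiny_schema())
  p2 <- person_profile(list(income = "mid", vehicles = "one",
                            street_density = 4), tiny_schema())
  grid <- grid_spec(c(0, 0), 3, 3, cbd_xy = c(500, 500))
  r1 <- build_compliance_raster(p1, dist_pars, freq_pars, grid)
  r2 <- build_compliance_raster(p2, dist_pars, freq_pars, grid)
  expect_equal(r1$layers, r2$layers, tolerance = 1e-14)
})

test_that("area histogram conserves total grid area with explicit overflow", {
  dist_pars <- tiny_joint_params()
  freq_pars <- tiny_freq_params()
  prof <- person_profile(list(income = "low", vehicles = "none",
                              street_density = 8), tiny_schema())
  grid <- grid_spec(c(0, 0), 2, 2, cbd_xy = c(250, 250))
  ras <- build_compliance_raster(prof, dist_pars, freq_pars, grid)
  ## all four 250 m cells into one wide bin: 4 * 0.0625 km^2
  wide <- area_by_compliance(ras, c(0, 1e6))
  expect_equal(wide$area_km2[wide$lower == 0], 0.25)
  expect_equal(sum(wide$area_km2), 0.25)
  ## arbitrary edges still conserve area via underflow/overflow rows
  odd <- area_by_compliance(ras, c(13.7, 13.8, 13.9))
  expect_equal(sum(odd$area_km2), 0.25)
  ## a bin range below every value leaves the finite bins empty
  below <- area_by_compliance(ras, c(-10, -5, -1))
  finite_bins <- is.finite(below$lower) & is.finite(below$upper)
  expect_true(all(below$area_km2[finite_bins] == 0))
})

test_that("schema mismatch between profile and models errors out", {
  dist_pars <- tiny_joint_params()
  freq_pars <- tiny_freq_params()
  other <- covariate_schema(list(age = list(
    type = "categorical", levels = c("a", "b"), reference = "a")))
  prof <- person_profile(list(age = "b"), other)
  grid <- grid_spec(c(0, 0), 1, 1, cbd_xy = c(0, 0))
  expect_error(build_compliance_raster(prof, dist_pars, freq_pars, grid),
               "schema")
})

test_that("ESRI ASCII and CSV writers serialize the grid faithfully", {
  dist_pars <- tiny_joint_params()
  freq_pars <- tiny_freq_params()
  prof <- person_profile(list(income = "high", vehicles = "none",
                              street_density = 5), tiny_schema())
  grid <- grid_spec(c(1000, 2000), 3, 4, cbd_xy = c(0, 0),
                    cell_size = 500)
  ras <- build_compliance_raster(prof, dist_pars, freq_pars, grid)
  asc <- tempfile(fileext = ".asc")
  write_raster_asc(ras, "compliance", asc)
  lines <- readLines(asc)
  expect_equal(lines[1:2], c("ncols 4", "nrows 3"))
  expect_equal(lines[3:5], c("xllcorner 1000", "yllcorner 2000",
                             "cellsize 500"))
  body <- do.call(rbind, lapply(lines[7:9], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  ## first body row is the northernmost (top) grid row
  expect_equal(body[1, ], unname(ras$layers$compliance[3, ]),
               tolerance = 1e-9)
  csv <- tempfile(fileext = ".csv")
  write_raster_csv(ras, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 12L)
  expect_equal(names(df)[1:2], c("cell_x", "cell_y"))
  expect_equal(df$compliance_pct[1], ras$layers$compliance[1, 1])
  expect_equal(df$cell_x[1:4], 1000 + (1:4 - 0.5) * 500)
})
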