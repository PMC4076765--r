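test_that("reference-cell dummy coding expands categoricals and keeps order", {
  sch <- tiny_schema()
  expect_equal(sch$design_names,
               c("income:mid", "income:high", "income:top",
                 "vehicles:one", "vehicles:twoplus", "street_density"))
  ## all reference levels + zero continuous -> zero vector
  v0 <- encode_covariates(list(income = "low", vehicles = "none",
                               street_density = 0), sch)
  expect_equal(unname(v0), rep(0, 6))
  ## a 4-level variable yields 3 indicator columns
  expect_equal(sum(startsWith(sch$design_names, "income:")), 3L)
  ## records differing only in one category differ in exactly one slot
  v1 <- encode_covariates(list(income = "low", vehicles = "twoplus",
                               street_density = 0), sch)
  expect_equal(sum(v1 != v0), 1L)
  expect_equal(unname(v1["vehicles:twoplus"]), 1)
})

test_that("encoding rejects unknown levels and is injective over levels", {
  sch <- tiny_schema()
  expect_error(encode_covariates(list(income = "unknown", vehicles = "none",
                                      street_density = 0), sch),
               "unknown level")
  expect_error(encode_covariates(list(income = "low", vehicles = "none"),
                                 sch), "missing covariates")
  codes <- vapply(c("low", "mid", "high", "top"), function(lv)
    paste(encode_covariates(list(income = lv, vehicles = "none",
                                 street_density = 0), sch),
          collapse = ","), "")
  expect_equal(anyDuplicated(codes), 0L)
})

test_that("trip CSV round-trips and drops non-positive distances with a count", {
  sch <- tiny_schema()
  df <- data.frame(person_id = c("a", "a", "b", "c"),
                   mode = c("walk", "car", "transit", "walk"),
                   distance_m = c(400, 5000, 3000, 700),
                   x = c(0, 10, -5, 3), y = c(1, 2, 3, 4),
                   cbd_km = c(1, 2, 3, 0.5),
                   income = c("low", "mid", "top", "high"),
                   vehicles = c("none", "one", "twoplus", "none"),
                   street_density = c(5, 10, 2, 8))
  trips <- cpm_trips(df, sch)
  path <- tempfile(fileext = ".csv")
  write_table_csv(trips, path)
  back <- read_trips(path, sch)
  expect_equal(attr(back, "n_dropped"), 0L)
  expect_equal(as.data.frame(back), as.data.frame(trips),
               ignore_attr = TRUE)

  df0 <- rbind(df, data.frame(person_id = "d", mode = "walk",
                              distance_m = 0, x = 0, y = 0, cbd_km = 1,
                              income = "low", vehicles = "none",
                              street_density = 3))
  utils::write.csv(df0, path, row.names = FALSE)
  expect_message(back0 <- read_trips(path, sch), "dropped 1")
  expect_equal(nrow(back0), 4L)
  expect_equal(attr(back0, "n_dropped"), 1L)
})

test_that("readers fail with informative schema and parse errors", {
  sch <- tiny_schema()
  path <- tempfile(fileext = ".csv")
  writeLines(c("person_id,mode,distance_m,x,y,cbd_km,income,street_density",
               "a,walk,100,0,0,1,low,5"), path)
  expect_error(read_trips(path, sch), "vehicles")
  writeLines(c(paste("person_id,mode,distance_m,x,y,cbd_km,income,vehicles,",
                     "street_density", sep = ""),
               "a,walk,abc,0,0,1,low,none,5"), path)
  expect_error(read_trips(path, sch), "line 2")
  expect_error(read_trips(tempfile(), sch), "not found")
})

test_that("person tables validate counts and round-trip", {
  sch <- tiny_schema()
  df <- data.frame(person_id = c("a", "b"), n_walk = c(0L, 2L),
                   n_car = c(3L, 1L), n_transit = c(1L, 0L),
                   x = c(0, 5), y = c(0, -2), cbd_km = c(1, 4),
                   income = c("low", "top"), vehicles = c("one", "none"),
                   street_density = c(4, 6))
  per <- cpm_persons(df, sch)
  path <- tempfile(fileext = ".csv")
  write_table_csv(per, path)
  expect_equal(as.data.frame(read_persons(path, sch)), as.data.frame(per))
  df$n_car[1] <- -1
  expect_error(cpm_persons(df, sch), "nonnegative")
})

test_that("published coefficient fixtures load with '-' exclusions and zero constants", {
  dm <- read_joint_model(system.file(
    "extdata", "montreal2008_distance_synthetic_scaler.json",
    package = "cpmap"))
  expect_equal(unname(dm$sigma[["walk"]]), 1.084)
  expect_equal(unname(dm$rho[["car"]]), -0.472)
  expect_equal(unname(dm$distance_coefs$walk[["(Intercept)"]]), 2.2718)
  ## the car constant was printed as the reference cell: loads as zero
  expect_equal(unname(dm$distance_coefs$car[["(Intercept)"]]), 0)
  fm <- read_frequency_model(system.file(
    "extdata", "montreal2008_frequency_synthetic_scaler.json",
    package = "cpmap"))
  expect_equal(unname(fm$corr[2, 3]), -0.656)
  ## variables printed "-" are structurally excluded from that mode
  expect_false("gender:male" %in% names(fm$coefs$walk))
  expect_true("gender:male" %in% names(fm$coefs$car))
  expect_true(all(diff(fm$thresholds$transit) > 0))
})
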