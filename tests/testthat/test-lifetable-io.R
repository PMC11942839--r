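test_that("a valid individual row parses into a record", {
  path <- write_lifetable_csv("Cc,female,25,23.13,true,1")
  lt <- read_lifetable(path)
  expect_s3_class(lt, "lifetable")
  expect_equal(nrow(lt), 1)
  expect_equal(lt$species, "Cc")
  expect_equal(lt$sex, "female")
  expect_equal(lt$temperature, 25)
  expect_equal(lt$dev_time, 23.13)
  expect_true(lt$emerged)
  expect_equal(lt$replicate, 1L)
  expect_null(attr(lt, "rejected"))
})

test_that("malformed rows are rejected individually, not fatally", {
  path <- write_lifetable_csv(c(
    "Cc,female,25,,true,1",      # emerged without dev_time
    "Cc,female,warm,20,true,1",  # non-numeric temperature
    "Cc,male,25,abc,true,2",     # non-numeric dev_time
    "Cc,male,25,-3,true,2",      # non-positive dev_time
    "Cc,female,25,21.9,true,3")) # valid
  lt <- read_lifetable(path)
  expect_equal(nrow(lt), 1)
  rej <- attr(lt, "rejected")
  expect_equal(rej$row, 1:4)
  expect_match(rej$message[1], "without a numeric dev_time")
  expect_match(rej$message[2], "temperature")
})

test_that("a missing required column is fatal and names the column", {
  path <- write_lifetable_csv("Cc,female,25,23.13,true",
                              header = "species,sex,temperature_C,dev_time_days,emerged")
  expect_error(read_lifetable(path), "replicate")
})

test_that("column mapping is configurable", {
  path <- write_lifetable_csv("Cc,female,25,23.13,true,1",
                              header = "species,sex,temp,days,emerged,replicate")
  lt <- read_lifetable(path, columns = c(temperature = "temp",
                                         dev_time = "days"))
  expect_equal(lt$temperature, 25)
  expect_equal(lt$dev_time, 23.13)
  expect_error(read_lifetable(path, columns = c(bogus = "temp")), "bogus")
})

test_that("write_lifetable and read_lifetable round-trip valid records", {
  lt <- simulate_lifetable(sim_config(n_per_cell = 5, seed = 7))
  path <- tempfile(fileext = ".csv")
  write_lifetable(lt, path)
  back <- read_lifetable(path)
  for (col in c("species", "sex", "temperature", "dev_time", "emerged",
                "replicate"))
    expect_equal(back[[col]], lt[[col]], info = col)
})

test_that("group-mean layout expands to n flagged pseudo-records", {
  path <- write_lifetable_csv(
    c("Cc,female,20,48.8,50", "Cc,female,25,23.13,10"),
    header = "species,sex,temperature_C,mean_dev_time_days,n")
  lt <- read_lifetable(path, format = "means")
  expect_equal(nrow(lt), 60)
  expect_true(all(lt$aggregated))
  expect_equal(sum(lt$temperature == 25), 10)
  # weighted single-record mode carries n as the weight instead
  lt1 <- read_lifetable(path, format = "means", expand = FALSE)
  expect_equal(nrow(lt1), 2)
  expect_equal(lt1$weight, c(50, 10))
})

test_that("zero-emergence cells become metadata, never zero-rate records", {
  path <- write_lifetable_csv(
    c("Cc,female,10,,50", "Cc,female,20,48.8,50", "Cc,female,15,--,50"),
    header = "species,sex,temperature_C,mean_dev_time_days,n")
  lt <- read_lifetable(path, format = "means")
  expect_equal(nrow(lt), 50)
  nd <- attr(lt, "non_developing")
  expect_equal(sort(nd$temperature), c(10, 15))
  obs <- rates_from_records(lt)
  expect_false(any(obs$rate == 0))
})

test_that("the packaged parasitoid life table loads with its design intact", {
  lt <- parasitoid_devtimes()
  # 14 developing cells x 50 individuals
  expect_equal(nrow(lt), 700)
  expect_setequal(unique(lt$species), c("C. cunea", "P. omnivorus"))
  nd <- attr(lt, "non_developing")
  expect_equal(nrow(nd), 6)  # both species at 10; P. omnivorus also at 15
  expect_true(all(nd$temperature[nd$species == "C. cunea"] == 10))
  obs <- rates_from_records(lt)
  r15 <- unique(obs$rate[obs$species == "C. cunea" & obs$temperature == 15])
  expect_equal(r15, 1 / 115, tolerance = 1e-12)
})

test_that("rates are exact reciprocals and non-emerged records are excluded", {
  path <- write_lifetable_csv(c(
    "Cc,female,25,20,true,1",
    "Cc,female,25,,false,1",
    "Cc,male,30,21.6,true,2",
    "Cc,male,30,,false,2",
    "Cc,male,30,,false,3"))
  lt <- read_lifetable(path)
  obs <- rates_from_records(lt)
  expect_equal(nrow(obs), 2)
  expect_equal(attr(obs, "excluded"), 3)
  expect_equal(obs$rate[obs$temperature == 25], 0.05)
  # empty input -> empty output
  empty <- rates_from_records(lt[lt$temperature > 100, ])
  expect_equal(nrow(empty), 0)
})

test_that("temperature series accept day/mean and date/min-max layouts", {
  p1 <- write_series_csv(data.frame(day = 1:3, t_mean_C = c(20, 21, 22)))
  s1 <- read_temperature_series(p1)
  expect_equal(s1$t_mean, c(20, 21, 22))
  p2 <- write_series_csv(data.frame(date = c("2024-05-01", "2024-05-02"),
                                    t_min_C = c(10, 12), t_max_C = c(20, 26)))
  s2 <- read_temperature_series(p2)
  expect_equal(s2$t_mean, c(15, 19))  # midpoint of daily min/max
  expect_equal(s2$day, 1:2)
  p3 <- write_series_csv(data.frame(day = c(1, 3), t_mean_C = c(20, 21)))
  expect_error(read_temperature_series(p3), "no gaps")
  p4 <- write_series_csv(data.frame(x = 1, y = 2))
  expect_error(read_temperature_series(p4), "expected columns")
})
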