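test_that("state assignment follows the printed model definitions", {
  ana <- state_model_spec("COL_ANa")
  # Abar = 100: breaks at 30 and 170, middle closed on both ends
  expect_equal(assign_state(20, 20, ana, 100), 1L)
  expect_equal(assign_state(30, 30, ana, 100), 2L)
  expect_equal(assign_state(170, 170, ana, 100), 2L)
  expect_equal(assign_state(170.01, 170.01, ana, 100), 3L)

  lin <- state_model_spec("COL_MAXlin")
  expect_equal(assign_state(150, 150, lin, 300), 2L)   # 100 <= 150 <= 200
  expect_equal(assign_state(99, 99, lin, 300), 1L)
  g <- state_model_spec("COL_MAXg")
  expect_equal(assign_state(99, 99, g, 400), 1L)       # < 100 = MAX/4
  expect_equal(assign_state(100, 100, g, 400), 2L)
  expect_equal(assign_state(201, 201, g, 400), 3L)

  wd <- state_model_spec("COL_wd")
  expect_equal(assign_state(0, 0, wd), 1L)
  expect_equal(assign_state(1, 1, wd), 2L)
  # clouds could hide water: dry lower bound, wet upper bound -> excluded
  expect_true(is.na(assign_state(0, 900, wd)))
  expect_error(assign_state(10, 10, ana, 0), class = "pond_input_error")
  expect_error(assign_state(10, 10, ana, NULL), class = "pond_input_error")
})

test_that("build_table treats years as replicates of the monthly states", {
  wd <- state_model_spec("COL_wd")
  dates <- c(sprintf("2000-%02d-15", 1:12), sprintf("2001-%02d-15", 1:12))
  tab <- build_table(make_series(dates, rep(10, 24)), wd)
  expect_equal(unname(unclass(tab)),
               rbind(rep(0L, 12), rep(2L, 12)), ignore_attr = TRUE)
  # alternating wet/dry years -> each month column {1, 1}
  tab2 <- build_table(make_series(dates, rep(c(10, 0), each = 12)), wd)
  expect_true(all(unclass(tab2) == 1L))
  # all excluded -> estimation error
  s_cl <- pond_series(1, c("2000-01-01", "2000-02-01"), c(0, 0),
                      c(900, 900), c(0.5, 0.5))
  expect_error(build_table(s_cl, wd), class = "pond_estimation_error")
})

test_that("a known 27-year monthly state schedule is tallied exactly", {
  # wet Oct-Mar, dry May-Aug, Apr/Sep alternate by year parity
  dates <- as.Date(unlist(lapply(1985:2011, function(y)
    sprintf("%d-%02d-15", y, 1:12))))
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  area <- ifelse(mo %in% c(10:12, 1:3), 500,
                 ifelse(mo %in% 5:8, 0, ifelse(yr %% 2 == 0, 500, 0)))
  tab <- build_table(make_series(dates, area), state_model_spec("COL_wd"))
  expect_equal(unname(colSums(unclass(tab))), rep(27, 12))
  expect_equal(unname(unclass(tab)[1L, ]),
               c(0, 0, 0, 14, 27, 27, 27, 27, 14, 0, 0, 0))
})

test_that("colwell_metrics reproduces the analytic boundary cases", {
  # one occupied state in every month: pure constancy
  m1 <- rbind(rep(0L, 12), rep(3L, 12))
  r1 <- colwell_metrics(m1)
  expect_equal(r1$constancy, 1)
  expect_equal(r1$contingency, 0)
  expect_equal(r1$predictability, 1)
  # uniform table: zero predictability
  r2 <- colwell_metrics(matrix(4L, 3, 12))
  expect_equal(r2$predictability, 0, tolerance = 1e-12)
  # perfect 2-state seasonality: zero constancy, full contingency
  m3 <- rbind(c(rep(5L, 6), rep(0L, 6)), c(rep(0L, 6), rep(5L, 6)))
  r3 <- colwell_metrics(m3)
  expect_equal(r3$constancy, 0, tolerance = 1e-12)
  expect_equal(r3$contingency, 1, tolerance = 1e-12)
  expect_error(colwell_metrics(matrix(0L, 2, 12)), class = "pond_input_error")
})

test_that("colwell_metrics agrees with the brute-force entropy oracle", {
  set.seed(33)
  for (i in 1:250) {
    s <- sample(2:3, 1)
    tab <- random_table(s)
    if (sum(tab) == 0) next
    got <- colwell_metrics(tab)
    want <- oracle_colwell(tab)
    expect_equal(got$constancy, want$C, tolerance = 1e-10)
    expect_equal(got$contingency, want$M, tolerance = 1e-10)
    expect_equal(got$predictability, want$P, tolerance = 1e-10)
    # decomposition and ranges
    expect_lt(abs(got$predictability - (got$constancy + got$contingency)),
              1e-12)
    expect_true(all(c(got$constancy, got$contingency, got$predictability)
                    >= 0 - 1e-12))
    expect_true(all(c(got$constancy, got$contingency, got$predictability)
                    <= 1 + 1e-12))
  }
})

test_that("the five models are invariant to year permutation and rescaling", {
  tr <- series_truth(noise_sd = 0.3, cloud_prob = 0.3, partial_clouds = TRUE,
                     seed = 17)
  s <- generate_pond_series(tr)
  o <- s$observations
  base <- vapply(DISCRETE_MODELS <- c("COL_wd", "COL_ANa", "COL_ANw",
                                      "COL_MAXlin", "COL_MAXg"),
                 function(m) run_discrete_model(s, m)$predictability, 0)
  # permute years: shuffle the year labels, keep month/day
  yrs <- as.integer(format(o$date, "%Y"))
  u <- sort(unique(yrs))
  set.seed(1); newy <- setNames(sample(u), u)
  nd <- as.Date(sprintf("%d-%s", newy[as.character(yrs)],
                        format(o$date, "%m-%d")))
  ok <- !duplicated(nd) & !is.na(nd)
  sp <- pond_series(1, nd[ok], o$area_m2[ok], o$area_max_m2[ok],
                    o$cloud_fraction[ok])
  sref <- pond_series(1, o$date[ok], o$area_m2[ok], o$area_max_m2[ok],
                      o$cloud_fraction[ok])
  for (m in DISCRETE_MODELS) {
    expect_equal(run_discrete_model(sp, m)$predictability,
                 run_discrete_model(sref, m)$predictability,
                 info = m)
  }
  # rescaling areas by any positive constant
  sk <- pond_series(1, o$date, o$area_m2 * 1e3, o$area_max_m2 * 1e3,
                    o$cloud_fraction)
  scaled <- vapply(DISCRETE_MODELS,
                   function(m) run_discrete_model(sk, m)$predictability, 0)
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("predictability is independent of the entropy log base", {
  # base-2 reimplementation of the whole metric vs the package (natural log)
  set.seed(8)
  for (i in 1:50) {
    tab <- random_table(3)
    if (sum(tab) == 0) next
    got <- colwell_metrics(tab)
    o <- oracle_colwell(tab)   # oracle works in log2
    expect_lt(abs(got$predictability - o$P), 1e-12)
  }
})

test_that("run_discrete_model resolves each model's reference", {
  dates <- as.Date(unlist(lapply(2000:2009, function(y)
    sprintf("%d-%02d-15", y, 1:12))))
  set.seed(2)
  area <- round(runif(120, 0, 1000)); area[sample(120, 30)] <- 0
  s <- make_series(dates, area)
  r <- run_discrete_model(s, "COL_MAXlin")
  expect_equal(r$reference_value, max(area))
  r2 <- run_discrete_model(s, "COL_ANa")
  expect_equal(r2$reference_value, mean_area(s))
  r3 <- run_discrete_model(s, "COL_ANw")
  expect_equal(r3$reference_value, mean_area(s, exclude_zeros = TRUE))
  # COL_ANw drops dry months: its table total is smaller
  expect_lt(r3$n_months_used, r2$n_months_used)
  # never-dry and all-dry are both perfectly predictable under COL_wd
  expect_equal(run_discrete_model(
    generate_pond_series(never_dry_truth(4)), "COL_wd")$predictability, 1)
  s_dry <- make_series(dates, rep(0, 120))
  expect_equal(run_discrete_model(s_dry, "COL_wd")$predictability, 1)
})

test_that("month-independent uniform occupancy drives COL_MAXlin P to ~0", {
  # areas i.i.d. uniform over the three MAX-thirds, independent of month
  dates <- as.Date(unlist(lapply(1958:2011, function(y)
    sprintf("%d-%02d-15", y, 1:12))))
  set.seed(99)
  bin <- sample(0:2, length(dates), replace = TRUE)
  area <- 50 + bin * 100    # 50, 150, 250; MAX = 250 -> thirds at 83.3, 166.7
  s <- make_series(dates, area)
  p <- run_discrete_model(s, "COL_MAXlin")$predictability
  expect_lt(p, 0.05)
})
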