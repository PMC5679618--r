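test_that("mndwi matches its closed form and guards its domain", {
  expect_equal(mndwi(0.30, 0.10), 0.50)
  expect_equal(mndwi(0.25, 0.25), 0.00)
  expect_equal(mndwi(0.00, 0.20), -1.00)
  expect_equal(mndwi(0, 0), 0)      # no-signal sentinel, treated as non-water
  expect_error(mndwi(-0.1, 0.2), class = "pond_input_error")
})

test_that("classify_pixel implements the two-condition assessment", {
  # negative index is soil whatever the NIR says
  expect_equal(classify_pixel(0.2, 0.55, 0.3), "soil")
  expect_equal(classify_pixel(0.2, 0.05, 0.3), "soil")
  # water candidates split on the NIR salt cut; 0.4 itself is salt
  expect_equal(classify_pixel(0.3, 0.55, 0.1), "salt")
  expect_equal(classify_pixel(0.3, 0.40, 0.1), "salt")
  expect_equal(classify_pixel(0.3, 0.10, 0.1), "water")
  # MNDWI exactly zero fails strict candidacy
  expect_equal(classify_pixel(0.25, 0.10, 0.25), "soil")
  # cloud flag wins
  expect_equal(classify_pixel(0.3, 0.1, 0.1, cloud = TRUE), "cloud")
})

test_that("classify_scene equals the per-pixel oracle bit-exactly", {
  set.seed(21)
  st <- scene_truth(pond_layout(nrow = 30, ncol = 30), noise_sd = 0.05)
  gs <- generate_scene(st, seed = 4)
  sc <- gs$scene
  sc$cloud[1:5, 1:5] <- TRUE
  cs <- classify_scene(sc)
  L <- pond_labels()
  want <- matrix(NA_integer_, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    want[i, j] <- L[[oracle_classify(sc$green[i, j], sc$nir[i, j],
                                     sc$mir[i, j], sc$cloud[i, j])]]
  }
  expect_identical(unname(cs$labels), unname(want))
})

test_that("noise-free archetype scenes are recovered exactly; sigma=0.02 >= 99%", {
  st0 <- scene_truth(pond_layout(), noise_sd = 0)
  gs0 <- generate_scene(st0, seed = 1)
  expect_identical(classify_scene(gs0$scene)$labels, gs0$truth$labels)

  st <- scene_truth(pond_layout(), noise_sd = 0.02)
  agree <- vapply(1:20, function(s) {
    gs <- generate_scene(st, seed = s)
    mean(classify_scene(gs$scene)$labels == gs$truth$labels)
  }, 0)
  expect_true(all(agree >= 0.99))
})

test_that("an all-cloud scene classifies as all cloud", {
  sc <- scene("c", "2000-01-01", matrix(0.2, 4, 4), matrix(0.2, 4, 4),
              matrix(0.1, 4, 4), cloud = matrix(TRUE, 4, 4))
  expect_true(all(classify_scene(sc)$labels == pond_labels()[["cloud"]]))
})

test_that("pond_area does the interval bookkeeping", {
  L <- pond_labels()
  lab <- matrix(L[["soil"]], 5, 5)
  lab[1, 1:5] <- L[["water"]]   # 5 water
  lab[2, 1:3] <- L[["cloud"]]   # 3 cloud
  lab[2, 4:5] <- L[["soil"]]
  cs <- structure(list(scene_id = "x", date = as.Date("2000-06-01"),
                       labels = lab, pixel_area = 900,
                       geotransform = NULL), class = "classified_scene")
  mk <- pond_mask(matrix(c(rep(1L, 10), rep(0L, 15)), 5, byrow = TRUE))
  ob <- pond_area(cs, mk, 1)
  expect_equal(ob$area_m2, 4500)
  expect_equal(ob$area_max_m2, 7200)
  expect_equal(ob$cloud_fraction, 0.3)
  expect_error(pond_area(cs, mk, 9), class = "pond_input_error")

  # cloud-free pond: area == area_max
  lab[2, 1:3] <- L[["soil"]]
  cs$labels <- lab
  ob2 <- pond_area(cs, mk, 1)
  expect_equal(ob2$area_m2, ob2$area_max_m2)
  expect_equal(ob2$cloud_fraction, 0)
})

test_that("a never-flooded pond reports zero area in every scene", {
  L <- pond_labels()
  mk <- pond_mask(matrix(c(1L, 1L, 0L, 0L), 2))
  stack <- lapply(1:12, function(i) {
    structure(list(scene_id = paste0("s", i),
                   date = as.Date("2000-01-01") + 30 * i,
                   labels = matrix(L[["soil"]], 2, 2), pixel_area = 900,
                   geotransform = NULL), class = "classified_scene")
  })
  a <- pond_areas(stack, mk)
  expect_equal(nrow(a), 12L)
  expect_true(all(a$area_m2 == 0))
  expect_error(pond_areas(stack, pond_mask(matrix(0L, 2, 2))),
               class = "pond_input_error")
})

test_that("water_frequency_map counts water over usable scenes", {
  L <- pond_labels()
  mk_cs <- function(v) structure(list(scene_id = "s", date = NA,
                                      labels = matrix(v, 1, 3),
                                      pixel_area = 900, geotransform = NULL),
                                 class = "classified_scene")
  # pixel 1: water in 3 of 4 usable; pixel 2: cloud always; pixel 3: never water
  stack <- list(mk_cs(c(L[["water"]], L[["cloud"]], L[["soil"]])),
                mk_cs(c(L[["water"]], L[["cloud"]], L[["salt"]])),
                mk_cs(c(L[["water"]], L[["cloud"]], L[["soil"]])),
                mk_cs(c(L[["soil"]],  L[["cloud"]], L[["soil"]])))
  fm <- water_frequency_map(stack)
  expect_equal(fm[1, 1], 0.75)
  expect_true(is.na(fm[1, 2]))
  expect_equal(fm[1, 3], 0)
  # permutation invariance
  expect_equal(water_frequency_map(rev(stack)), fm)
  expect_error(water_frequency_map(list()), class = "pond_input_error")
})

test_that("deterministic flooding schedule reproduces exact frequencies", {
  L <- pond_labels()
  sched <- c(2, 5, 10)  # pixel k wet in sched[k] of 10 scenes
  stack <- lapply(1:10, function(i) {
    v <- ifelse(i <= sched, L[["water"]], L[["soil"]])
    structure(list(scene_id = paste0("s", i), date = NA,
                   labels = matrix(v, 1, 3), pixel_area = 900,
                   geotransform = NULL), class = "classified_scene")
  })
  expect_equal(as.vector(water_frequency_map(stack)), sched / 10)
})

test_that("disabling the salt filter never decreases any pond area", {
  mk <- pond_mask(matrix(1L, 40, 40))
  for (s in 1:10) {
    gs <- generate_scene(scene_truth(pond_layout(40, 40, 8, 14),
                                     noise_sd = 0.15), seed = s)
    a_filtered <- pond_area(classify_scene(gs$scene), mk, 1)$area_m2
    a_raw <- pond_area(classify_scene(gs$scene, salt_filter = FALSE), mk, 1)$area_m2
    expect_gte(a_raw, a_filtered)
  }
})
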