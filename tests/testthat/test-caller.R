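test_that("background subtraction floors at zero and rejects bad input", {
  w <- tibble::tibble(fam_pre = c(100, 200), fam_post = c(1100, 150),
                      hex_pre = c(100, 50), hex_post = c(150, 40))
  out <- normalize_wells(w)
  expect_equal(out$fam, c(1000, 0))
  expect_equal(out$hex, c(50, 0))
  expect_error(normalize_wells(dplyr::mutate(w, fam_pre = -1)),
               "non-negative")

  # arithmetic oracle on random tables
  withr::with_seed(2, {
    r <- tibble::tibble(fam_pre = runif(200, 0, 500),
                        fam_post = runif(200, 0, 2000),
                        hex_pre = runif(200, 0, 500),
                        hex_post = runif(200, 0, 2000))
    got <- normalize_wells(r)
    expect_equal(got$fam, pmax(r$fam_post - r$fam_pre, 0))
    expect_equal(got$hex, pmax(r$hex_post - r$hex_pre, 0))
  })
})

test_that("polar transform matches closed forms", {
  expect_equal(polar_transform(1000, 0),
               tibble::tibble(theta = 0, magnitude = 1000))
  expect_equal(polar_transform(0, 500),
               tibble::tibble(theta = 90, magnitude = 500))
  p <- polar_transform(300, 300)
  expect_equal(p$theta, 45)
  expect_equal(p$magnitude, 300 * sqrt(2), tolerance = 1e-12)
  expect_true(is.na(polar_transform(0, 0)$theta))
})

sim_calls <- function(n = 96, noise_sd = 0, seed = 1, ...) {
  panel <- load_canonical_panel()
  truth <- toy_truth(n, seed = seed)
  plate <- simulate_plate(panel, truth, noise_sd = noise_sd,
                          seed = seed + 1)
  list(calls = call_plate(plate$wells, ...), truth = plate$truth,
       wells = plate$wells)
}

test_that("noise-free plates are recovered perfectly with no no-calls", {
  r <- sim_calls(93, noise_sd = 0)
  smp <- r$calls[!is.na(r$calls$sample), ]
  expect_equal(nrow(smp), 93)
  expect_false(any(smp$state == "no_call"))
  merged <- dplyr::inner_join(smp, r$truth, by = c("well", "sample", "marker"),
                              suffix = c("", "_true"))
  expect_equal(merged$state, merged$state_true)
})

test_that("NTC wells are reported but never genotyped", {
  r <- sim_calls(50, noise_sd = 30, seed = 3)
  ntc <- r$calls[is.na(r$calls$sample), ]
  expect_gt(nrow(ntc), 0)
  expect_true(all(ntc$state == "no_call"))
})

test_that("an all-NTC plate yields no sample calls and no error", {
  panel <- load_canonical_panel()
  plate <- simulate_plate(panel, toy_truth(1), n_ntc = 10, seed = 4)
  wells <- plate$wells[plate$wells$role == "NTC", ]
  calls <- call_plate(wells)
  expect_true(all(is.na(calls$sample)))
  expect_true(all(calls$state == "no_call"))
})

test_that("the NTC gate precedes band logic", {
  # one perfect-angle well whose magnitude sits below the NTC envelope
  wells <- tibble::tibble(
    plate_id = "p", well = sprintf("A%02d", 1:5),
    role = c("sample", rep("NTC", 4)), marker = "m",
    sample = c("s1", rep(NA, 4)),
    fam_pre = 0, fam_post = c(30 * cospi(0.25), 90, 100, 110, 95),
    hex_pre = 0, hex_post = c(30 * sinpi(0.25), 2, 1, 3, 2)
  )
  calls <- call_plate(wells)
  s1 <- calls[calls$sample == "s1" & !is.na(calls$sample), ]
  expect_equal(s1$state, "no_call")
  expect_equal(s1$reason, "low signal")
})

test_that("plates without NTCs error unless ntc-free mode is enabled", {
  wells <- tibble::tibble(
    plate_id = "p", well = c("A01", "A02"), role = "sample", marker = "m",
    sample = c("s1", "s2"), fam_pre = 0, fam_post = c(1000, 20),
    hex_pre = 0, hex_post = c(100, 900)
  )
  expect_error(call_plate(wells), "no NTC wells")
  calls <- call_plate(wells, kasp_caller_params(ntc_free = TRUE,
                                                abs_floor = 100))
  expect_equal(calls$state[calls$sample == "s1"], "XX")
})

test_that("calls are invariant to well order and global signal scale", {
  r <- sim_calls(80, noise_sd = 50, seed = 9)
  key <- function(calls) {
    df <- calls[order(calls$plate_id, calls$well), ]
    df[, c("well", "state", "reason")]
  }
  shuffled <- withr::with_seed(1, r$wells[sample.int(nrow(r$wells)), ])
  expect_equal(key(call_plate(shuffled)), key(r$calls))

  scaled <- dplyr::mutate(r$wells, dplyr::across(
    c(fam_pre, fam_post, hex_pre, hex_post), function(x) x * 7.3
  ))
  expect_equal(key(call_plate(scaled)), key(r$calls))
})

test_that("noise converts calls to no-calls before it converts them to errors", {
  # averaged over seeds, wrong (non-no_call) calls never increase with noise
  wrong_rate <- function(noise_sd) {
    mean(vapply(1:20, function(seed) {
      r <- sim_calls(60, noise_sd = noise_sd, seed = seed)
      smp <- dplyr::inner_join(r$calls[!is.na(r$calls$sample), ], r$truth,
                               by = c("well", "sample", "marker"),
                               suffix = c("", "_true"))
      sum(smp$state != "no_call" & smp$state != smp$state_true)
    }, numeric(1)))
  }
  # up to twice the default channel noise (beyond ~10% of the cluster
  # magnitude the genotype clusters physically overlap and no endpoint
  # caller can keep confident calls error-free)
  rates <- vapply(c(0, 25, 50, 100), wrong_rate, numeric(1))
  expect_true(all(diff(rates) <= 1e-9))
})
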