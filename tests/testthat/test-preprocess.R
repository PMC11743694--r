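test_that("scalp-average re-referencing zeroes common activity", {
  common <- sin(seq(0, 10, length.out = 500))
  data <- matrix(rep(common, each = 4), 4, byrow = FALSE)
  rec <- toy_recording(data, sfreq = 100)
  out <- rereference(rec, "scalp_average")
  expect_same_numbers(out$data, matrix(0, 4, 500))

  # sum over scalp channels is zero at every sample for any input
  rec2 <- toy_recording(matrix(rnorm(2000), 4), sfreq = 100)
  out2 <- rereference(rec2, "scalp_average")
  expect_same_numbers(colSums(out2$data), numeric(500))
})

test_that("per-ear re-referencing treats the two ears independently", {
  cfg <- tiny_config(n_trials = 1, seed = 30)
  sim <- simulate_recording(cfg, 1)
  out <- rereference(sim$recording, "per_ear_average")
  gl <- sim$recording$groups == "ear_left"
  gr <- sim$recording$groups == "ear_right"
  expect_same_numbers(colSums(out$data[gl, ]), numeric(ncol(out$data)))
  # re-referencing one ear's channels never touches the other groups
  only_left <- out
  expect_identical(out$data[sim$recording$groups == "scalp", ],
                   sim$recording$data[sim$recording$groups == "scalp", ])
  # idempotence: re-running changes nothing
  again <- rereference(out, "per_ear_average")
  expect_same_numbers(again$data, out$data)
  expect_error(rereference(toy_recording(matrix(1, 2, 10)),
                           "per_ear_average"), "empty")
})

test_that("the bandpass is zero-phase with the requested corner behaviour", {
  sfreq <- 1000
  n <- 60000
  t <- (seq_len(n) - 1) / sfreq
  dc <- matrix(5, 1, n)
  s10 <- matrix(sin(2 * pi * 10 * t), 1, n)
  rec <- toy_recording(rbind(dc, s10), sfreq = sfreq)
  out <- bandpass_filter(rec)
  mid <- 20000:40000  # away from edges
  # DC strongly attenuated
  expect_lt(max(abs(out$data[1, mid])), 0.01 * 5)
  # 10 Hz passed within 5% amplitude
  amp <- max(out$data[2, mid])
  expect_lt(abs(amp - 1), 0.05)
  # zero phase: peak cross-correlation with the input at lag 0
  xc <- vapply(-5:5, function(lag) {
    cor(out$data[2, mid], s10[1, mid + lag])
  }, 0)
  expect_equal(which.max(xc), 6)  # lag = 0
  expect_error(bandpass_filter(rec, low = 50, high = 40), "corner")
  expect_error(bandpass_filter(rec, low = 0.1, high = 600), "corner")
})

test_that("a filtered impulse is symmetric about its input position", {
  sfreq <- 1000
  n <- 30000
  x <- matrix(0, 1, n)
  x[1, 15000] <- 1
  out <- bandpass_filter(toy_recording(x, sfreq = sfreq), low = 1,
                         high = 40, trans_low = 1)
  y <- out$data[1, ]
  k <- 2000
  left <- y[(15000 - k):(15000 - 1)]
  right <- y[(15000 + 1):(15000 + k)]
  expect_same_numbers(left, rev(right), tol = 1e-9)
  expect_equal(which.max(abs(y)), 15000)
})

test_that("ICA removes a synthetic blink source from the scalp", {
  cfg <- tiny_config(n_trials = 3, seed = 14, eog_rate = 0.4)
  sim <- simulate_recording(cfg, 1)
  rec <- rereference(sim$recording, "scalp_average")
  rec <- bandpass_filter(rec)
  before <- abs(cor(rec$data["Fp1", ], rec$data["EOG", ]))
  out <- suppressWarnings(remove_eog_ica(rec))
  expect_gte(sum(out$report$removed), 1)
  after <- abs(cor(out$recording$data["Fp1", ], rec$data["EOG", ]))
  expect_gt(before, 0.6)
  expect_lt(after, 0.3)
  # the EOG channel itself and the ears are untouched
  expect_identical(out$recording$data["EOG", ], rec$data["EOG", ])
  expect_identical(out$recording$data["ELA", ], rec$data["ELA", ])
})

test_that("without ocular activity no component crosses the threshold", {
  cfg <- tiny_config(n_trials = 2, seed = 15, eog_rate = 0)
  sim <- simulate_recording(cfg, 1)
  rec <- bandpass_filter(rereference(sim$recording, "scalp_average"))
  out <- suppressWarnings(remove_eog_ica(rec))
  expect_equal(sum(out$report$removed), 0)
  expect_identical(out$recording$data, rec$data)
  expect_error(remove_eog_ica(rec, eog_channel = "NOPE"), "not found")
})

test_that("epoching drops clipped windows and uses a half-open window", {
  rec <- toy_recording(matrix(seq_len(2 * 1000), 2, byrow = TRUE),
                       sfreq = 100)
  ev <- as_event_table(data.frame(
    onset = c(0.1, 2, 5, 9.5), duration = 0.1,
    trial_type = "TARGET", stream = "single", trial = 1L))
  ep <- epoch_recording(rec, ev, -0.2, 1.0)
  # 0.1 s starts before the recording; 9.5 s ends beyond it
  expect_equal(n_epochs(ep), 2)
  expect_equal(nrow(attr(ep, "dropped")), 2)
  expect_equal(dim(ep$data)[2], round(1.2 * 100))
  expect_equal(ep$times[1], -200)
  expect_equal(ep$times[length(ep$times)], 990)  # last sample before 1 s
  # channel 1 holds sample indices: epoch at 2 s starts at sample 181
  expect_equal(unname(ep$data[1, 1, 1]), 181)
})

test_that("baseline correction zeroes the pre-stimulus mean and is shift-invariant", {
  arr <- array(rnorm(3 * 300 * 4), c(3, 300, 4))
  ep <- toy_epochs(arr, rep("TARGET", 4), sfreq = 250)
  bc <- baseline_correct(ep)
  sel <- bc$times >= -200 & bc$times < 0
  bm <- apply(bc$data[, sel, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bm)), 1e-9)
  # constant epochs become exactly zero
  cep <- toy_epochs(array(7, c(2, 300, 1)), "TARGET", sfreq = 250)
  expect_same_numbers(baseline_correct(cep)$data, array(0, c(2, 300, 1)))
  # adding an offset changes nothing after correction
  shifted <- ep
  shifted$data <- shifted$data + 42
  expect_same_numbers(baseline_correct(shifted)$data, bc$data)
  # idempotence
  expect_same_numbers(baseline_correct(bc)$data, bc$data)
  expect_error(baseline_correct(ep, c(-2, -1.5)), "no samples")
})

test_that("peak-to-peak rejection flags any channel exceeding the threshold", {
  arr <- array(0, c(2, 100, 3))
  arr[1, 50, 1] <- 150   # epoch 1: 150 uV span on channel 1 -> kept
  arr[2, 50, 2] <- 201   # epoch 2: 201 uV span on channel 2 -> rejected
  arr[, , 3] <- 0        # epoch 3: flat -> kept
  ep <- toy_epochs(arr, c("TARGET", "TARGET", "NONTARGET"), sfreq = 100)
  out <- reject_peak_to_peak(ep, threshold = 200)
  expect_equal(out$log$kept, c(TRUE, FALSE, TRUE))
  expect_equal(out$log$channel[2], "ch2")
  expect_equal(out$log$p2p[2], 201)
  expect_equal(n_epochs(out$epochs), 2)
  expect_equal(out$epochs$conditions, c("TARGET", "NONTARGET"))
  # empty set in, empty set out
  empty <- reject_peak_to_peak(toy_epochs(arr[, , 0, drop = FALSE],
                                          character(0), sfreq = 100))
  expect_equal(n_epochs(empty$epochs), 0)
  expect_equal(nrow(empty$log), 0)
})

test_that("the full preprocessing chain runs in order and returns epochs", {
  cfg <- tiny_config(n_trials = 2, seed = 18)
  sim <- simulate_recording(cfg, 1)
  pp <- suppressWarnings(preprocess_recording(sim$recording, sim$events))
  expect_s3_class(pp$epochs, "eeg_epochs")
  expect_equal(dim(pp$epochs$data)[2], round(1.2 * cfg$sfreq))
  expect_equal(nrow(pp$rejection_log), 40 - nrow(attr(pp$epochs, "dropped")))
  sel <- pp$epochs$times >= -200 & pp$epochs$times < 0
  bm <- apply(pp$epochs$data[, sel, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bm)), 1e-9)
})
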