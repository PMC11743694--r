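test_that("condition averaging is the sample-wise epoch mean", {
  arr <- array(0, c(1, 2, 2))
  arr[1, , 1] <- c(1, 3)
  arr[1, , 2] <- c(3, 5)
  ep <- toy_epochs(arr, c("TARGET", "TARGET"), sfreq = 10, tmin = 0)
  w <- average_epochs(ep, "TARGET")
  expect_equal(drop(w$data), c(2, 4))
  expect_equal(w$n, 2)
  # single epoch: the ERP is that epoch
  one <- average_epochs(toy_epochs(arr[, , 1, drop = FALSE], "TARGET",
                                   sfreq = 10, tmin = 0), "TARGET")
  expect_equal(drop(one$data), c(1, 3))
  expect_error(average_epochs(ep, "AT"), "no epochs with condition")
})

test_that("averaging is linear in the epoch data", {
  arr <- array(rnorm(3 * 50 * 8), c(3, 50, 8))
  ep <- toy_epochs(arr, rep("AT", 8), sfreq = 100, tmin = 0)
  ep2 <- ep
  ep2$data <- 2.5 * ep2$data
  expect_same_numbers(average_epochs(ep2, "AT")$data,
                      2.5 * average_epochs(ep, "AT")$data)
})

test_that("difference waves subtract sample-wise and are antisymmetric", {
  t <- seq(0, 999)
  a <- erp_wave(matrix(sin(t / 50), 1), t, "AT", 10, "Pz")
  b <- erp_wave(matrix(cos(t / 50), 1), t, "AN", 12, "Pz")
  d <- difference_wave(a, b)
  expect_equal(d$label, "AT-AN")
  expect_same_numbers(d$data, a$data - b$data)
  expect_same_numbers(difference_wave(b, a)$data, -d$data)
  expect_same_numbers(difference_wave(a, a)$data, matrix(0, 1, 1000))
  bad <- erp_wave(matrix(0, 1, 1000), t, "AN", 1, "Cz")
  expect_error(difference_wave(a, bad), "mismatch")
})

test_that("grand averaging weights subjects equally", {
  t <- seq(0, 99)
  w1 <- erp_wave(matrix(rnorm(100), 1), t, "AT", 40, "Pz")
  w2 <- erp_wave(-w1$data, t, "AT", 5, "Pz")
  ga <- grand_average(list(w1, w2))
  expect_same_numbers(ga$data, matrix(0, 1, 100))
  expect_equal(ga$n, 2)
  expect_same_numbers(grand_average(list(w1, w1, w1))$data, w1$data)
  expect_same_numbers(grand_average(list(w1, w2))$data,
                      grand_average(list(w2, w1))$data)
  expect_error(grand_average(list()), "empty")
})

test_that("peak quantification finds the component peak in the window", {
  tpl <- make_erp_template(625, 300, 4.15, 1000, 1000)
  w <- erp_wave(matrix(tpl, 1), seq(0, 999), "diff", 20, "Pz")
  pk <- quantify_peak(w, "Pz", c(450, 920))
  expect_equal(pk$amplitude, 4.15)
  expect_equal(pk$latency, 625)
  expect_false(pk$edge)
  # monotonic wave: maximum on the edge is flagged as non-local
  mono <- erp_wave(matrix(seq(0, 1, length.out = 1000), 1),
                   seq(0, 999), "diff", 1, "Pz")
  expect_true(quantify_peak(mono, "Pz", c(450, 920))$edge)
  # flat zero wave: zero amplitude at the window start, flagged
  flat <- erp_wave(matrix(0, 1, 1000), seq(0, 999), "diff", 1, "Pz")
  pkf <- quantify_peak(flat, "Pz", c(450, 920))
  expect_equal(pkf$amplitude, 0)
  expect_equal(pkf$latency, 450)
  expect_true(pkf$edge)
  expect_error(quantify_peak(w, "Cz", c(450, 920)), "unknown channel")
  expect_error(quantify_peak(w, "Pz", c(2000, 3000)), "no samples")
})

test_that("ERP waves serialize to readable tab-separated tables", {
  t <- seq(-200, 999)
  w <- erp_wave(matrix(rnorm(2 * 1200), 2), t, "AT", 7, c("Pz", "Cz"))
  path <- file.path(withr::local_tempdir(), "erp.tsv")
  write_erp(w, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# label: AT$", lines)))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  expect_equal(tab$channel, c("Pz", "Cz"))
  expect_equal(as.numeric(tab[1, -1]), w$data[1, ], tolerance = 1e-8)
})
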