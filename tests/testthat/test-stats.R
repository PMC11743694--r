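test_that("identical epoch sets give p = 1 and seeded runs reproduce", {
  X <- matrix(rnorm(200), 10, 20)
  r <- permutation_test(X, X, n_perm = 99, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)
  r2 <- permutation_test(X, X + 5, n_perm = 199, seed = 2)
  r3 <- permutation_test(X, X + 5, n_perm = 199, seed = 2)
  expect_identical(r2$null, r3$null)
  expect_identical(r2$p, r3$p)
  expect_error(permutation_test(X, X, n_perm = 0), "n_perm")
})

test_that("a strong embedded effect reaches the minimum attainable p", {
  withr::with_seed(3, {
    a <- matrix(rnorm(50 * 30), 50) + 10  # effect far above the noise
    b <- matrix(rnorm(50 * 30), 50)
    r <- permutation_test(a, b, n_perm = 199, seed = 4)
    expect_equal(r$p, 1 / 200)
    r1 <- permutation_test(a, b, n_perm = 199, sided = "one", seed = 4)
    expect_equal(r1$p, 1 / 200)
  })
})

test_that("permutation test is calibrated under the null", {
  withr::with_seed(5, {
    rej <- vapply(1:200, function(i) {
      X <- matrix(rnorm(40 * 10), 40)
      permutation_test(X[1:10, ], X[11:40, ], n_perm = 99)$p <= 0.05
    }, logical(1))
    # exact binomial 95% interval around 0.05 at n = 200
    expect_gte(mean(rej), 0.02)
    expect_lte(mean(rej), 0.09)
  })
})

test_that("temporal clusters are maximal supra-threshold runs", {
  # observed difference below threshold everywhere: no clusters
  a <- matrix(0.2, 4, 100)
  b <- matrix(0, 4, 100)
  r <- temporal_cluster_test(a, b, threshold = 1, n_perm = 19, seed = 1)
  expect_equal(nrow(r$clusters), 0)
  # one contiguous supra-threshold segment: exactly one cluster spanning it
  d <- numeric(100)
  d[30:60] <- 3
  a2 <- matrix(rep(d, each = 6), 6, byrow = FALSE) +
    matrix(rnorm(600, sd = 1e-3), 6)
  b2 <- matrix(rnorm(600, sd = 1e-3), 6)
  r2 <- temporal_cluster_test(a2, b2, threshold = 1, n_perm = 99, seed = 2)
  expect_equal(nrow(r2$clusters), 1)
  expect_equal(r2$clusters$start, 30)
  expect_equal(r2$clusters$end, 60)
  expect_equal(r2$clusters$stat, sum(r2$observed[30:60]), tolerance = 1e-9)
  expect_equal(r2$clusters$p, 1 / 100)
  expect_error(temporal_cluster_test(a, b, threshold = 0), "threshold")
})

test_that("two-sided tests form separate positive and negative clusters", {
  d <- numeric(200)
  d[20:50] <- 2
  d[120:140] <- -2
  a <- matrix(rep(d, each = 8), 8, byrow = FALSE) +
    matrix(rnorm(1600, sd = 1e-3), 8)
  b <- matrix(rnorm(1600, sd = 1e-3), 8)
  r <- temporal_cluster_test(a, b, threshold = 1, n_perm = 99, seed = 3,
                             times = seq(0, 199))
  expect_equal(nrow(r$clusters), 2)
  expect_equal(r$clusters$start, c(20, 120))
  expect_true(r$clusters$stat[1] > 0 && r$clusters$stat[2] < 0)
  expect_equal(r$clusters$start_ms, c(19, 119))
  # p-values are monotone non-increasing in |cluster statistic|
  ord <- order(-abs(r$clusters$stat))
  expect_true(all(diff(r$clusters$p[ord]) >= 0))
  # one-sided: only the positive cluster remains
  r1 <- temporal_cluster_test(a, b, threshold = 1, n_perm = 99, seed = 3,
                              sided = "one")
  expect_equal(nrow(r1$clusters), 1)
})

test_that("label exchange flips signs but preserves two-sided inference", {
  withr::with_seed(7, {
    a <- matrix(rnorm(40 * 120), 40)
    a[, 40:80] <- a[, 40:80] + 1.6
    b <- matrix(rnorm(60 * 120), 60)
    r_ab <- temporal_cluster_test(a, b, threshold = 1, n_perm = 400,
                                  seed = 11)
    r_ba <- temporal_cluster_test(b, a, threshold = 1, n_perm = 400,
                                  seed = 11)
    expect_same_numbers(r_ab$observed, -r_ba$observed)
    expect_equal(nrow(r_ab$clusters), nrow(r_ba$clusters))
    expect_equal(sort(abs(r_ab$clusters$stat)),
                 sort(abs(r_ba$clusters$stat)), tolerance = 1e-9)
    expect_lt(max(abs(sort(r_ab$clusters$p) - sort(r_ba$clusters$p))),
              0.05)
  })
})

test_that("channel adjacency is symmetric without self-edges", {
  adj <- channel_adjacency(standard_montage32())
  expect_true(all(adj$matrix == t(adj$matrix)))
  expect_true(all(!diag(adj$matrix)))
  expect_true(adj$matrix["Pz", "CP1"])      # neighbours
  expect_false(adj$matrix["Pz", "Fp1"])     # across the head
  expect_true(all(vapply(adj$neighbors, length, 0L) >= 1))
})

test_that("spatial clusters are connected components of supra-threshold channels", {
  mon <- standard_montage32()
  adj <- channel_adjacency(mon)
  groups <- stats::setNames(rep("scalp", 32), mon$channel)
  mk <- function(shift) {
    arr <- array(rnorm(32 * 50 * 20, sd = 1e-3), c(32, 50, 20))
    arr <- arr + shift
    eeg_epochs(arr, seq(0, 49) * 4, rep("AT", 20), 250, mon$channel,
               groups, mon)
  }
  # all channels below threshold: no clusters
  r0 <- spatial_cluster_test(mk(0), mk(0), c(0, 196), adj, threshold = 1,
                             n_perm = 19, seed = 1)
  expect_equal(nrow(r0$clusters), 0)
  # two supra-threshold channels that are not adjacent: two clusters
  shift <- numeric(32)
  shift[mon$channel == "Fp1"] <- 3
  shift[mon$channel == "O2"] <- 3
  a <- mk(array(rep(shift, 50 * 20), c(32, 50, 20)))
  r2 <- spatial_cluster_test(a, mk(0), c(0, 196), adj, threshold = 1,
                             n_perm = 99, seed = 2)
  expect_equal(nrow(r2$clusters), 2)
  expect_setequal(r2$clusters$channels, c("Fp1", "O2"))
  expect_error(spatial_cluster_test(a, mk(0), c(0, 196),
                                    channel_adjacency(mon[1:10, ]),
                                    threshold = 1),
               "missing from the adjacency")
})

test_that("a parietal-maximal effect yields parietal and opposite frontal clusters", {
  withr::with_seed(8, {
    mon <- standard_montage32()
    adj <- channel_adjacency(mon)
    groups <- stats::setNames(rep("scalp", 32), mon$channel)
    lf <- default_leadfields()$cognitive[mon$channel]
    tpl <- c(numeric(50), make_erp_template(625, 300, 4.15, 250, 1000))
    n_ep <- 60
    noise <- function() array(rnorm(32 * 300 * n_ep, sd = 2),
                              c(32, 300, n_ep))
    times <- seq(-200, by = 4, length.out = 300)
    a <- eeg_epochs(array(outer(lf, tpl), c(32, 300, n_ep)) + noise(),
                    times, rep("AT", n_ep), 250, mon$channel, groups, mon)
    b <- eeg_epochs(noise(), times, rep("AN", n_ep), 250, mon$channel,
                    groups, mon)
    r <- spatial_cluster_test(a, b, c(400, 800), adj, threshold = 1,
                              n_perm = 199, seed = 3)
    best <- r$clusters[which.min(r$clusters$p), ]
    expect_true(grepl("\\bPz\\b", best$channels))
    expect_gt(best$stat, 0)
    neg <- r$clusters[r$clusters$stat < 0, ]
    expect_gte(nrow(neg), 1)
    expect_true(any(grepl("Fp1|Fp2|Fz", neg$channels)))
  })
})

test_that("cosine similarity scores proportional and orthogonal waveforms exactly", {
  t <- seq(0, 999)
  s <- make_erp_template(625, 300, 4.15, 1000, 1000)
  # ear difference ERP proportional to the scalp wave: score 1
  ear_t <- matrix(rep(0.2 * s, each = 10), 10, byrow = FALSE)
  ear_n <- matrix(0, 10, 1000)
  r <- cosine_similarity_test(ear_t, ear_n, s, n_perm = 19, seed = 1)
  expect_equal(r$score, 1, tolerance = 1e-12)
  # orthogonal waveforms: score 0
  orth <- sin(2 * pi * 8 * t / 1000)
  orth <- orth - s * sum(orth * s) / sum(s * s)
  r0 <- cosine_similarity_test(matrix(rep(orth, each = 10), 10,
                                      byrow = FALSE),
                               ear_n, s, n_perm = 19, seed = 1)
  expect_lt(abs(r0$score), 1e-10)
  expect_error(cosine_similarity_test(ear_n, ear_n, s, n_perm = 19),
               "zero-norm")
})

test_that("Bonferroni correction matches the reported alpha levels", {
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("cluster results serialize with their metadata header", {
  d <- numeric(100)
  d[30:60] <- 3
  a <- matrix(rep(d, each = 6), 6, byrow = FALSE)
  r <- temporal_cluster_test(a + matrix(rnorm(600, sd = 1e-3), 6),
                             matrix(rnorm(600, sd = 1e-3), 6),
                             threshold = 1, n_perm = 99, seed = 5,
                             times = seq(0, 99))
  path <- file.path(withr::local_tempdir(), "clusters.tsv")
  write_cluster_test(r, path, extra = c(seed = 5))
  lines <- readLines(path)
  expect_true(any(grepl("# threshold: 1", lines)))
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), 1)
})
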