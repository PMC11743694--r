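test_that("covariances follow the average-target / concatenated-non-target rule", {
  # one target epoch, C = 1, samples [1, 2]: R_T = 1 + 4 = 5
  tgt <- array(c(1, 2), c(1, 2, 1))
  non <- array(c(1, 0, 0, 2), c(1, 2, 2))
  cov <- compute_covariances(tgt, non)
  expect_equal(cov$R_T, matrix(5))
  # concatenation: R_N = sum of per-epoch X_i X_i' = (1) + (4) = 5
  expect_equal(cov$R_N, matrix(5))
  expect_equal(cov$n_T, 1)
  expect_equal(cov$n_N, 2)

  # multi-channel: symmetric PSD, and R_T uses the *average* epoch
  arrT <- array(rnorm(3 * 10 * 4), c(3, 10, 4))
  arrN <- array(rnorm(3 * 10 * 5), c(3, 10, 5))
  cov2 <- compute_covariances(arrT, arrN)
  expect_same_numbers(cov2$R_T, t(cov2$R_T))
  expect_same_numbers(cov2$R_N, t(cov2$R_N))
  expect_gte(min(eigen(cov2$R_N, symmetric = TRUE)$values), -1e-10)
  xt <- apply(arrT, c(1, 2), mean)
  expect_same_numbers(cov2$R_T, xt %*% t(xt))
  rn <- Reduce(`+`, lapply(1:5, function(i)
    arrN[, , i] %*% t(arrN[, , i])))
  expect_same_numbers(cov2$R_N, rn)
  expect_error(compute_covariances(arrT[, , 0, drop = FALSE], arrN),
               "empty")
  expect_error(compute_covariances(arrT, arrN[, 1:3, , drop = FALSE]),
               "mismatch")
})

test_that("the GEVD solver handles analytic cases", {
  # diagonal case: top generalized eigenvector is e1, objective 4
  m <- solve_filter(diag(c(4, 1)), diag(2), shrinkage = 0)
  expect_equal(abs(m$w), c(1, 0), tolerance = 1e-10)
  expect_gt(m$w[1], 0)  # sign convention: largest coefficient positive
  expect_equal(m$lambda, 4, tolerance = 1e-10)
  # identity/degenerate direction: any unit vector solves; constraint holds
  m2 <- solve_filter(diag(3), diag(3), shrinkage = 0)
  expect_equal(sum(m2$w^2), 1, tolerance = 1e-10)
  expect_equal(m2$lambda, 1, tolerance = 1e-10)
  expect_error(solve_filter(diag(2), diag(2), shrinkage = 1.2),
               "shrinkage")
})

test_that("constraint and stationarity hold on random SPD pencils", {
  withr::with_seed(21, {
    for (i in 1:20) {
      A <- crossprod(matrix(rnorm(16), 4)) + 0.05 * diag(4)
      B <- crossprod(matrix(rnorm(16), 4)) + 0.05 * diag(4)
      m <- solve_filter(A, B, shrinkage = 0)
      expect_lt(abs(drop(crossprod(m$w, B %*% m$w)) - 1), 1e-8)
      resid <- A %*% m$w - m$lambda * (B %*% m$w)
      expect_lt(max(abs(resid)) / max(abs(A %*% m$w)), 1e-6)
      # objective never below any single channel's Rayleigh quotient
      rq <- diag(A) / diag(B)
      expect_gte(m$lambda + 1e-9, max(rq))
      # scaling the data leaves the direction unchanged
      m2 <- solve_filter(9 * A, 9 * B, shrinkage = 0)
      cosang <- abs(sum(m$w * m2$w)) / sqrt(sum(m$w^2) * sum(m2$w^2))
      expect_equal(cosang, 1, tolerance = 1e-8)
    }
  })
})

test_that("a numerically zero target covariance warns and still returns a filter", {
  B <- crossprod(matrix(rnorm(9), 3)) + 0.1 * diag(3)
  expect_warning(m <- solve_filter(matrix(0, 3, 3), B, shrinkage = 0),
                 "zero")
  expect_lt(abs(drop(crossprod(m$w, B %*% m$w)) - 1), 1e-8)
})

test_that("applying a filter yields the weighted virtual channel", {
  arr <- array(rnorm(3 * 20 * 5), c(3, 20, 5))
  ep <- toy_epochs(arr, rep(c("AT", "AN"), length.out = 5), sfreq = 100)
  m <- structure(list(w = c(1, 0, 0), lambda = 1, shrinkage = 0,
                      channels = NULL, trained_on = NULL, ear = NA),
                 class = "snr_filter")
  out <- apply_filter(ep, m)
  expect_equal(dim(out$data)[1], 1)
  expect_same_numbers(out$data[1, , ], arr[1, , ])
  expect_identical(out$conditions, ep$conditions)
  # linearity
  m$w <- c(0.3, -1.2, 2)
  ep2 <- ep
  ep2$data <- 4 * ep2$data
  expect_same_numbers(apply_filter(ep2, m)$data,
                      4 * apply_filter(ep, m)$data)
  m$w <- c(1, 1)
  expect_error(apply_filter(ep, m), "channel count")
})

test_that("the trained filter makes the target waveform positive-going", {
  withr::with_seed(33, {
    lf <- c(0.5, 0.2, -0.1, -0.6)
    tpl <- c(numeric(50), make_erp_template(625, 300, 2, 250, 1000))
    tgt <- array(outer(lf, tpl), c(4, 300, 30)) +
      array(rnorm(4 * 300 * 30, sd = 0.5), c(4, 300, 30))
    non <- array(rnorm(4 * 300 * 30, sd = 0.5), c(4, 300, 30))
    m <- train_spatial_filter(toy_epochs(tgt, rep("AT", 30), sfreq = 250),
                              toy_epochs(non, rep("AN", 30), sfreq = 250))
    xt <- apply(tgt, c(1, 2), mean)
    f <- drop(crossprod(xt, m$w))
    sel <- seq(round(0.6 * 250), round(1.0 * 250))
    expect_gt(mean(f[sel]), 0)
  })
})

test_that("cross-task validation excludes the held-out paradigm from training", {
  withr::with_seed(44, {
    mk <- function() list(
      target = toy_epochs(array(rnorm(4 * 50 * 10), c(4, 50, 10)),
                          rep("AT", 10), sfreq = 250),
      nontarget = toy_epochs(array(rnorm(4 * 50 * 20), c(4, 50, 20)),
                             rep("AN", 20), sfreq = 250))
    data <- list(P1 = mk(), P2 = mk(), P3 = mk())
    out <- cross_task_validate(data, ear = "left")
    expect_named(out, c("P1", "P2", "P3"))
    for (p in names(out)) {
      expect_false(p %in% out[[p]]$filter$trained_on)
      expect_setequal(out[[p]]$filter$trained_on, setdiff(names(data), p))
      expect_equal(out[[p]]$filter$ear, "left")
      expect_equal(dim(out[[p]]$epochs_target$data)[1], 1)
      expect_equal(out[[p]]$erp_diff$label, "target-nontarget")
    }
    expect_error(cross_task_validate(data["P1"]), "at least two")
    # identical data in every paradigm: identical filters up to sign
    same <- list(A = data$P1, B = data$P1, C = data$P1)
    outs <- cross_task_validate(same)
    w1 <- outs$A$filter$w
    for (p in c("B", "C")) {
      cosang <- abs(sum(w1 * outs[[p]]$filter$w)) /
        sqrt(sum(w1^2) * sum(outs[[p]]$filter$w^2))
      expect_equal(cosang, 1, tolerance = 1e-8)
    }
  })
})

test_that("filters serialize and read back with provenance", {
  m <- solve_filter(diag(c(4, 1)), diag(2), shrinkage = 0)
  m$trained_on <- c("P1", "P3")
  m$ear <- "right"
  m$channels <- c("ERA", "ERB")
  path <- file.path(withr::local_tempdir(), "filter.json")
  write_filter(m, path)
  m2 <- read_filter(path)
  expect_equal(m2$w, m$w)
  expect_equal(m2$lambda, m$lambda)
  expect_identical(m2$trained_on, m$trained_on)
  expect_identical(m2$channels, m$channels)
})
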