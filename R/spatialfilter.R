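# Accept either an eeg_epochs object or a plain C x N x E array.
epochs_array <- function(x) {
  if (inherits(x, "eeg_epochs")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected an eeg_epochs object or a channels x samples x ",
            "epochs array")
}

#' Target and non-target autocorrelation matrices
#'
#' The target matrix is `R_T = X_T X_T'` where `X_T` is the average
#' target epoch; the non-target matrix is `R_N = X_N X_N'` where `X_N`
#' is the concatenation of all non-target epochs along the time axis
#' (equivalently the sum of per-epoch `X_i X_i'`). Both are symmetric
#' positive semidefinite C x C matrices.
#'
#' @param target_epochs,nontarget_epochs [eeg_epochs] objects (or plain
#'   C x N x E arrays) with identical channels and sample counts.
#' @return List with matrices `R_T` and `R_N`, plus `X_T` (the average
#'   target epoch, used downstream for the sign convention) and the
#'   epoch counts `n_T`, `n_N`.
#' @export
compute_covariances <- function(target_epochs, nontarget_epochs) {
  dT <- epochs_array(target_epochs)
  dN <- epochs_array(nontarget_epochs)
  if (dim(dT)[3] == 0 || dim(dN)[3] == 0) {
    stop("empty epoch set: both conditions need at least one epoch")
  }
  if (!identical(dim(dT)[1:2], dim(dN)[1:2])) {
    stop("target and non-target epochs have mismatched dimensions")
  }
  C <- dim(dT)[1]
  X_T <- matrix(rowMeans(matrix(dT, nrow = C * dim(dT)[2])), nrow = C)
  R_T <- tcrossprod(X_T)
  X_N <- matrix(dN, nrow = C)   # concatenation along the time axis
  R_N <- tcrossprod(X_N)
  list(R_T = (R_T + t(R_T)) / 2, R_N = (R_N + t(R_N)) / 2, X_T = X_T,
       n_T = dim(dT)[3], n_N = dim(dN)[3])
}

#' Solve the max-SNR spatial filter (generalized eigenvalue problem)
#'
#' Finds `w` maximizing `w' R_T w` subject to `w' R_N w = 1`: the top
#' generalized eigenvector of the pencil `(R_T, R_N)`. `R_N` is first
#' regularized by shrinkage towards a scaled identity,
#' `R_N <- (1 - gamma) R_N + gamma (tr(R_N)/C) I`, because per-ear
#' average referencing makes the ear covariance rank deficient. The
#' problem is solved by Cholesky whitening of the regularized `R_N`
#' followed by a symmetric eigendecomposition; the returned `w` satisfies
#' the unit non-target-power constraint exactly (w.r.t. the regularized
#' matrix). Any positive multiple of an unconstrained maximizer has the
#' same Rayleigh quotient; the constraint pins the scale, and the sign is
#' fixed so that the largest-magnitude coefficient of `w` is positive
#' (overridden by the waveform-based convention in
#' [train_spatial_filter()]).
#'
#' @param R_T,R_N Symmetric C x C matrices from [compute_covariances()].
#' @param shrinkage Shrinkage fraction gamma in \[0, 1) (default 0.05).
#' @return An object of class `snr_filter`: list with `w`, `lambda` (the
#'   objective value, equal to `w' R_T w`), `shrinkage`, `R_T`, `R_N`
#'   (inputs as given), `channels`, `trained_on`, `ear`.
#' @export
solve_filter <- function(R_T, R_N, shrinkage = 0.05) {
  R_T <- as.matrix(R_T); R_N <- as.matrix(R_N)
  C <- nrow(R_N)
  stopifnot(ncol(R_N) == C, all(dim(R_T) == C))
  if (shrinkage < 0 || shrinkage >= 1) stop("`shrinkage` must be in [0, 1)")
  Rr <- (1 - shrinkage) * R_N + shrinkage * (sum(diag(R_N)) / C) * diag(C)
  U <- tryCatch(chol(Rr), error = function(e) {
    stop("regularized R_N is numerically singular; increase `shrinkage` ",
         "(currently ", shrinkage, ")")
  })
  degenerate <- sum(diag(R_T)) <= 1e-12 * max(sum(diag(Rr)), 1e-300)
  Tgt <- if (degenerate) diag(C) else R_T
  if (degenerate) {
    warning("target covariance is (numerically) zero; returning the ",
            "R_N-whitened direction of largest residual variance")
  }
  B <- backsolve(U, t(backsolve(U, Tgt, transpose = TRUE)),
                 transpose = TRUE)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  v <- e$vectors[, 1]
  w <- backsolve(U, v)           # U w = v  =>  w' Rr w = v'v = 1
  if (w[which.max(abs(w))] < 0) w <- -w
  lambda <- drop(crossprod(w, R_T %*% w))
  structure(list(w = as.numeric(w), lambda = lambda,
                 shrinkage = shrinkage, R_T = R_T, R_N = R_N,
                 channels = rownames(R_N), trained_on = NULL, ear = NA),
            class = "snr_filter")
}

#' @export
print.snr_filter <- function(x, ...) {
  cat("<snr_filter> C =", length(x$w), " lambda =", signif(x$lambda, 5),
      " gamma =", x$shrinkage, "\n")
  if (!is.null(x$trained_on)) {
    cat("  trained on:", paste(x$trained_on, collapse = ", "),
        if (!is.na(x$ear)) paste0(" (", x$ear, " ear)"), "\n")
  }
  invisible(x)
}

#' Train a max-SNR filter from epochs
#'
#' Computes the covariances, solves the generalized eigenvalue problem,
#' and fixes the sign of `w` so that the mean of the filtered average
#' target waveform over `sign_window` is non-negative (making the
#' filtered component positive-going like the scalp P3b).
#'
#' @param target_epochs,nontarget_epochs [eeg_epochs] objects (or 3D
#'   arrays).
#' @param shrinkage Shrinkage fraction for `R_N`.
#' @param sign_window Window (ms) over which the filtered target
#'   waveform's mean must be non-negative; used only when a time axis is
#'   available.
#' @param times Optional time axis (ms) when plain arrays are supplied.
#' @return An `snr_filter` (see [solve_filter()]).
#' @export
train_spatial_filter <- function(target_epochs, nontarget_epochs,
                                 shrinkage = 0.05,
                                 sign_window = c(400, 800), times = NULL) {
  cov <- compute_covariances(target_epochs, nontarget_epochs)
  model <- solve_filter(cov$R_T, cov$R_N, shrinkage)
  if (inherits(target_epochs, "eeg_epochs")) {
    times <- target_epochs$times
    model$channels <- target_epochs$channels
  }
  f <- drop(crossprod(cov$X_T, model$w))
  sel <- if (is.null(times)) seq_along(f) else
    which(times >= sign_window[1] & times <= sign_window[2])
  if (!length(sel)) sel <- seq_along(f)
  if (mean(f[sel]) < 0) {
    model$w <- -model$w
  }
  model
}

#' Apply a spatial filter to epochs
#'
#' Each epoch `X_i` (C x N) is mapped to the single virtual channel
#' `w' X_i` (1 x N); condition metadata is preserved.
#'
#' @param epochs An [eeg_epochs] object whose channel set matches the
#'   filter's training channels (same order).
#' @param model An `snr_filter`.
#' @return An [eeg_epochs] with one channel, `"FILT"`.
#' @export
apply_filter <- function(epochs, model) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(model, "snr_filter"))
  if (dim(epochs$data)[1] != length(model$w)) {
    stop("epoch channel count does not match the filter")
  }
  if (!is.null(model$channels) &&
      !identical(epochs$channels, model$channels)) {
    stop("epoch channels do not match the filter's training channels")
  }
  d <- epochs$data
  out <- crossprod(model$w, matrix(d, nrow = dim(d)[1]))
  arr <- array(out, dim = c(1, dim(d)[2], dim(d)[3]))
  eeg_epochs(arr, epochs$times, epochs$conditions, epochs$sfreq,
             "FILT", c(FILT = "ear_filtered"), NULL, epochs$events)
}

#' Leave-one-paradigm-out cross-task validation of the ear filter
#'
#' For each paradigm, a filter is trained on the pooled target and
#' non-target epochs of all *other* paradigms (per ear: six channels,
#' per-ear average referenced) and applied to the held-out paradigm's
#' epochs; filtered target, non-target and difference ERPs are returned
#' per paradigm together with the filter (whose `trained_on` provenance
#' lists exactly the training paradigms).
#'
#' @param data Named list, one entry per paradigm, each a list with
#'   elements `target` and `nontarget` ([eeg_epochs] of the ear channels,
#'   identical channel sets).
#' @param ear `"left"` or `"right"` (stored as provenance).
#' @param shrinkage Shrinkage fraction for `R_N`.
#' @return Named list per paradigm: `filter`, `epochs_target`,
#'   `epochs_nontarget` (filtered), `erp_target`, `erp_nontarget`,
#'   `erp_diff`.
#' @export
cross_task_validate <- function(data, ear = c("left", "right"),
                                shrinkage = 0.05) {
  ear <- match.arg(ear)
  if (length(data) < 2) {
    stop("cross-task validation needs at least two paradigms ",
         "(no held-out training possible with ", length(data), ")")
  }
  if (is.null(names(data)) || any(!nzchar(names(data)))) {
    stop("`data` must be a named list of paradigms")
  }
  pool <- function(sets) {
    arrs <- lapply(sets, epochs_array)
    dims <- dim(arrs[[1]])[1:2]
    arr <- array(unlist(arrs, use.names = FALSE),
                 dim = c(dims, sum(vapply(arrs, function(a) dim(a)[3], 0))))
    first <- sets[[1]]
    if (inherits(first, "eeg_epochs")) {
      eeg_epochs(arr, first$times, rep("pooled", dim(arr)[3]),
                 first$sfreq, first$channels, first$groups)
    } else arr
  }
  out <- list()
  for (p in names(data)) {
    train_names <- setdiff(names(data), p)
    tr_t <- pool(lapply(data[train_names], `[[`, "target"))
    tr_n <- pool(lapply(data[train_names], `[[`, "nontarget"))
    model <- train_spatial_filter(tr_t, tr_n, shrinkage)
    model$trained_on <- train_names
    model$ear <- ear
    ft <- apply_filter(data[[p]]$target, model)
    fn <- apply_filter(data[[p]]$nontarget, model)
    et <- average_epochs(ft)
    et$label <- "target"
    en <- average_epochs(fn)
    en$label <- "nontarget"
    out[[p]] <- list(filter = model, epochs_target = ft,
                     epochs_nontarget = fn, erp_target = et,
                     erp_nontarget = en,
                     erp_diff = difference_wave(et, en))
  }
  out
}

#' Serialize / read a spatial filter
#'
#' Filters are stored as JSON sidecars with the weight vector, shrinkage,
#' objective value, channel order and training provenance.
#'
#' @param model An `snr_filter`.
#' @param path Output path.
#' @return `path` invisibly (`write_filter`); an `snr_filter`
#'   (`read_filter`).
#' @export
write_filter <- function(model, path) {
  jsonlite::write_json(
    list(w = model$w, lambda = model$lambda, shrinkage = model$shrinkage,
         channels = model$channels, trained_on = model$trained_on,
         ear = model$ear),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.numeric(x$w), lambda = x$lambda,
                 shrinkage = x$shrinkage, R_T = NULL, R_N = NULL,
                 channels = x$channels, trained_on = x$trained_on,
                 ear = x$ear),
            class = "snr_filter")
}
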