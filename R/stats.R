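# Coerce a permutation-test input to an epochs x values matrix: accepts
# an epochs x samples matrix, a numeric vector (one value per epoch), or
# a single-channel eeg_epochs object.
perm_input <- function(x, channel = NULL) {
  if (inherits(x, "eeg_epochs")) {
    if (!is.null(channel)) {
      if (is.character(channel)) channel <- match(channel, x$channels)
      if (is.na(channel)) stop("unknown channel")
      return(t(x$data[channel, , ]))
    }
    if (dim(x$data)[1] != 1L) {
      stop("select a channel for multi-channel epochs")
    }
    return(t(x$data[1, , ]))
  }
  if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
}

# Row weights implementing difference-of-subset-means for each random
# relabelling: one row per permutation over the pooled epochs.
perm_weight_matrix <- function(n_total, n_a, n_perm) {
  W <- matrix(-1 / (n_total - n_a), n_perm, n_total)
  for (i in seq_len(n_perm)) {
    W[i, sample.int(n_total, n_a)] <- 1 / n_a
  }
  W
}

add_one_p <- function(n_exceed, n_perm) (1 + n_exceed) / (1 + n_perm)

#' Permutation test of a difference in condition means
#'
#' The test statistic is the difference of condition means (grand mean
#' over epochs and any remaining dimensions). Epochs are pooled, randomly
#' repartitioned into two subsets of the original sizes `n_perm` times,
#' and the p-value is the add-one proportion of partitions at least as
#' extreme as the observed statistic, so the smallest attainable p is
#' `1/(n_perm + 1)`.
#'
#' @param a,b Epochs x samples matrices, per-epoch numeric vectors, or
#'   single-channel [eeg_epochs] objects.
#' @param n_perm Number of random partitions (default 1000).
#' @param sided `"two"` (default) or `"one"` (tests a > b).
#' @param seed Optional seed for reproducibility.
#' @return List with `p`, `observed`, and the permutation `null` values.
#' @export
permutation_test <- function(a, b, n_perm = 1000,
                             sided = c("two", "one"), seed = NULL) {
  sided <- match.arg(sided)
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  A <- perm_input(a); B <- perm_input(b)
  if (ncol(A) != ncol(B)) stop("inputs have mismatched sample counts")
  if (nrow(A) == 0 || nrow(B) == 0) stop("both epoch sets must be nonempty")
  obs <- mean(A) - mean(B)
  X <- rbind(A, B)
  run <- function() {
    W <- perm_weight_matrix(nrow(X), nrow(A), n_perm)
    rowMeans(W %*% X)  # per-permutation grand mean difference
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n_exceed <- if (sided == "two") sum(abs(null) >= abs(obs)) else
    sum(null >= obs)
  list(p = add_one_p(n_exceed, n_perm), observed = obs, null = null,
       sided = sided, n_perm = n_perm)
}

# Maximal runs of supra-threshold samples in a difference waveform.
# Two-sided: positive (d > thr) and negative (d < -thr) runs are separate
# clusters; the cluster statistic is the signed sum of d over the run.
find_clusters_1d <- function(d, threshold, sided = "two") {
  res <- data.frame(start = integer(0), end = integer(0),
                    stat = numeric(0))
  collect <- function(mask, sign) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(start = starts[keep], end = ends[keep],
               stat = vapply(keep, function(k)
                 sum(d[starts[k]:ends[k]]), 0))
  }
  out <- collect(d > threshold)
  if (sided == "two") out <- rbind(out, collect(d < -threshold))
  if (is.null(out)) res else out[order(out$start), , drop = FALSE]
}

# Permutation-null of the maximal cluster statistic for a matrix of
# permuted difference waveforms (one row per permutation).
max_cluster_stat <- function(D, threshold, sided) {
  apply(D, 1, function(d) {
    cl <- find_clusters_1d(d, threshold, sided)
    if (!nrow(cl)) 0 else max(abs(cl$stat))
  })
}

#' Temporal cluster-based permutation test
#'
#' Clusters are maximal runs of temporally adjacent samples whose
#' condition-mean difference exceeds `threshold` (absolutely, for the
#' two-sided test, with positive and negative runs forming separate
#' clusters); each cluster's statistic is the sum of the mean difference
#' over its samples. The permutation null is the distribution of the
#' largest absolute cluster statistic under random relabellings of the
#' pooled epochs (permutations without a supra-threshold cluster
#' contribute 0), and each observed cluster's p-value is the add-one
#' proportion of null values at least as large as its own |statistic|.
#' The cluster-forming threshold affects sensitivity but not the false
#' alarm rate.
#'
#' @param a,b Epochs x samples matrices or [eeg_epochs] (with `channel`).
#' @param channel Channel to test when epochs objects are supplied.
#' @param threshold Cluster-forming threshold, uV (> 0). Defaults: 0.5
#'   for ear (filtered) data, 1.0 for scalp — pass explicitly.
#' @param n_perm Number of permutations (default 1000).
#' @param sided `"two"` (default) or `"one"`.
#' @param seed Optional seed.
#' @param times Optional time axis (ms) for reporting cluster extents.
#' @return Object of class `cluster_test`: `clusters` data.frame
#'   (`start`, `end` sample indices, `start_ms`, `end_ms` when times are
#'   known, `stat`, `p`), `observed` difference waveform, `threshold`,
#'   `n_perm`, `sided`, `null`.
#' @export
temporal_cluster_test <- function(a, b, channel = NULL, threshold = 1.0,
                                  n_perm = 1000, sided = c("two", "one"),
                                  seed = NULL, times = NULL) {
  sided <- match.arg(sided)
  if (threshold <= 0) stop("`threshold` must be positive")
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  if (is.null(times) && inherits(a, "eeg_epochs")) times <- a$times
  A <- perm_input(a, channel); B <- perm_input(b, channel)
  if (ncol(A) != ncol(B)) stop("inputs have mismatched sample counts")
  d_obs <- colMeans(A) - colMeans(B)
  clusters <- find_clusters_1d(d_obs, threshold, sided)
  X <- rbind(A, B)
  run <- function() {
    W <- perm_weight_matrix(nrow(X), nrow(A), n_perm)
    max_cluster_stat(W %*% X, threshold, sided)
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  clusters$p <- vapply(clusters$stat, function(s)
    add_one_p(sum(null >= abs(s)), n_perm), 0)
  if (!is.null(times) && nrow(clusters)) {
    clusters$start_ms <- times[clusters$start]
    clusters$end_ms <- times[clusters$end]
  }
  structure(list(clusters = clusters, observed = d_obs,
                 threshold = threshold, n_perm = n_perm, sided = sided,
                 null = null, times = times, mode = "temporal"),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", x$mode, ", ", x$sided, "-sided, threshold ",
      x$threshold, ", ", x$n_perm, " permutations\n", sep = "")
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else if (x$mode == "temporal") {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      ext <- if (!is.null(cl$start_ms)) {
        sprintf("[%g, %g] ms", cl$start_ms, cl$end_ms)
      } else sprintf("samples %d-%d", cl$start, cl$end)
      cat(sprintf("  cluster %d: %s, stat = %.3g, p = %.4g\n",
                  i, ext, cl$stat, cl$p))
    }
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: {%s}, stat = %.3g, p = %.4g\n", i,
                  x$clusters$channels[[i]], x$clusters$stat[i],
                  x$clusters$p[i]))
    }
  }
  invisible(x)
}

#' Channel adjacency from the 2D montage
#'
#' Two channels are neighbours when their planar distance is at most
#' `factor` times the median nearest-neighbour distance of the montage.
#'
#' @param montage data.frame with `channel`, `x`, `y`.
#' @param factor Distance multiplier (default 1.5).
#' @return List of class `adjacency_graph`: `channels`, logical
#'   `matrix`, and `neighbors` (list of integer vectors).
#' @export
channel_adjacency <- function(montage, factor = 1.5) {
  D <- as.matrix(dist(montage[, c("x", "y")]))
  diag(D) <- Inf
  thr <- factor * median(apply(D, 1, min))
  M <- D <= thr
  M <- M | t(M)
  diag(M) <- FALSE
  dimnames(M) <- list(montage$channel, montage$channel)
  structure(list(channels = montage$channel, matrix = M,
                 neighbors = apply(M, 1, which, simplify = FALSE)),
            class = "adjacency_graph")
}

# Connected components of a channel subset under an adjacency neighbour
# list (plain breadth-first search; graphs here have tens of nodes).
connected_components <- function(members, neighbors) {
  unseen <- members
  comps <- list()
  while (length(unseen)) {
    queue <- unseen[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!v %in% unseen) next
      unseen <- setdiff(unseen, v)
      comp <- c(comp, v)
      queue <- c(queue, intersect(neighbors[[v]], unseen))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Spatial clusters: same-sign connected components of supra-threshold
# channels; statistic = sum of per-channel differences.
find_clusters_spatial <- function(d, threshold, neighbors, sided) {
  build <- function(mask) {
    comps <- connected_components(which(mask), neighbors)
    if (!length(comps)) return(NULL)
    data.frame(members = I(comps),
               stat = vapply(comps, function(m) sum(d[m]), 0))
  }
  out <- build(d > threshold)
  if (sided == "two") out <- rbind(out, build(d < -threshold))
  if (is.null(out)) data.frame(members = I(list()), stat = numeric(0))[0, ]
  else out
}

#' Spatial (topographic) cluster-based permutation test
#'
#' The per-channel statistic is the condition-mean difference averaged
#' over `window`; spatial clusters are connected components of
#' supra-threshold channels in the adjacency graph (same sign, for the
#' two-sided test), with the summed per-channel statistic as cluster
#' statistic. Otherwise the machinery is identical to
#' [temporal_cluster_test()].
#'
#' @param a,b [eeg_epochs] objects over the same (scalp) channels.
#' @param window Time window in ms over which channel differences are
#'   averaged.
#' @param adjacency An `adjacency_graph` from [channel_adjacency()]
#'   covering all tested channels.
#' @param threshold Cluster-forming threshold, uV.
#' @param n_perm,sided,seed As in [temporal_cluster_test()].
#' @param channels Channels to test (default: the scalp group).
#' @return A `cluster_test` whose `clusters` lists channel sets.
#' @export
spatial_cluster_test <- function(a, b, window, adjacency, threshold = 1.0,
                                 n_perm = 1000, sided = c("two", "one"),
                                 seed = NULL, channels = NULL) {
  sided <- match.arg(sided)
  if (threshold <= 0) stop("`threshold` must be positive")
  stopifnot(inherits(a, "eeg_epochs"), inherits(b, "eeg_epochs"))
  if (is.null(channels)) {
    channels <- if (!is.null(a$groups)) {
      a$channels[a$groups[a$channels] == "scalp"]
    } else a$channels
  }
  missing <- setdiff(channels, adjacency$channels)
  if (length(missing)) {
    stop("channels missing from the adjacency graph: ",
         paste(missing, collapse = ", "))
  }
  ci <- match(channels, a$channels)
  sel <- a$times >= window[1] & a$times <= window[2]
  # per-epoch, per-channel window means; epochs x channels
  win_means <- function(ep) {
    d <- ep$data[ci, sel, , drop = FALSE]
    t(matrix(colMeans(matrix(aperm(d, c(2, 1, 3)), nrow = sum(sel))),
             nrow = length(ci)))
  }
  A <- win_means(a); B <- win_means(b)
  d_obs <- colMeans(A) - colMeans(B)
  names(d_obs) <- channels
  nb_idx <- lapply(adjacency$neighbors[match(channels, adjacency$channels)],
                   function(v) match(intersect(adjacency$channels[v],
                                               channels), channels))
  obs_cl <- find_clusters_spatial(d_obs, threshold, nb_idx, sided)
  X <- rbind(A, B)
  run <- function() {
    D <- perm_weight_matrix(nrow(X), nrow(A), n_perm) %*% X
    apply(D, 1, function(d) {
      cl <- find_clusters_spatial(d, threshold, nb_idx, sided)
      if (!nrow(cl)) 0 else max(abs(cl$stat))
    })
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  clusters <- data.frame(
    channels = vapply(obs_cl$members, function(m)
      paste(channels[m], collapse = ","), ""),
    stat = obs_cl$stat,
    p = vapply(obs_cl$stat, function(s)
      add_one_p(sum(null >= abs(s)), n_perm), 0))
  clusters$members <- obs_cl$members
  structure(list(clusters = clusters, observed = d_obs,
                 threshold = threshold, n_perm = n_perm, sided = sided,
                 null = null, window = window, mode = "spatial"),
            class = "cluster_test")
}

#' Cosine-similarity permutation test between ear and scalp ERPs
#'
#' The score is the cosine of the angle between the ear difference ERP
#' (mean target minus mean non-target over the filtered single-channel
#' ear epochs) and the scalp difference wave, both taken as flattened
#' time vectors. The null is built by shuffling the ear epochs'
#' target/non-target labels, recomputing the ear difference ERP and
#' rescoring; p is the add-one proportion of permuted scores at least as
#' large as the observed score.
#'
#' @param ear_target,ear_nontarget Epochs x samples matrices or
#'   single-channel [eeg_epochs] (spatially filtered ear data).
#' @param scalp_diff Numeric vector, or an [erp_wave] with one channel
#'   (or a `channel` row name to select).
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Optional seed.
#' @param channel Channel of `scalp_diff` to use when it is a
#'   multi-channel wave (default `"Pz"`).
#' @return List with `score`, `p` and the permutation `null` scores.
#' @export
cosine_similarity_test <- function(ear_target, ear_nontarget, scalp_diff,
                                   n_perm = 1000, seed = NULL,
                                   channel = "Pz") {
  A <- perm_input(ear_target); B <- perm_input(ear_nontarget)
  s <- if (inherits(scalp_diff, "erp_wave")) {
    if (nrow(scalp_diff$data) == 1L) drop(scalp_diff$data) else
      scalp_diff$data[channel, ]
  } else as.numeric(scalp_diff)
  if (length(s) != ncol(A)) stop("scalp wave length does not match epochs")
  cosine <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) {
      stop("cosine similarity undefined for a zero-norm waveform")
    }
    sum(u * v) / (nu * nv)
  }
  d_obs <- colMeans(A) - colMeans(B)
  score <- cosine(d_obs, s)
  X <- rbind(A, B)
  run <- function() {
    D <- perm_weight_matrix(nrow(X), nrow(A), n_perm) %*% X
    norms <- sqrt(rowSums(D^2))
    out <- numeric(n_perm)
    # a permuted difference that is exactly zero carries no similarity
    ok <- norms > 0
    out[ok] <- drop(D[ok, , drop = FALSE] %*% s) /
      (norms[ok] * sqrt(sum(s^2)))
    out
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(score = score, p = add_one_p(sum(null >= score), n_perm),
       null = null, n_perm = n_perm)
}

#' Bonferroni-corrected significance level
#'
#' @param base_alpha Uncorrected significance level.
#' @param n_comparisons Number of comparisons (>= 1).
#' @return `base_alpha / n_comparisons`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.0125
#' bonferroni_alpha(0.05, 2)  # 0.025
bonferroni_alpha <- function(base_alpha, n_comparisons) {
  if (n_comparisons < 1) stop("`n_comparisons` must be at least 1")
  base_alpha / n_comparisons
}

#' Write a cluster test result as a tab-separated table
#'
#' @param x A `cluster_test`.
#' @param path Output path.
#' @param extra Named character vector of extra header fields (e.g. seed).
#' @return `path`, invisibly.
#' @export
write_cluster_test <- function(x, path, extra = NULL) {
  hdr <- c(mode = x$mode, threshold = x$threshold, n_perm = x$n_perm,
           sided = x$sided, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  cl <- x$clusters
  cl$members <- NULL
  utils::write.table(format(cl, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
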