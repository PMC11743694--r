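#' Standard 32-channel scalp montage with 2D layout
#'
#' Planar (top-view) coordinates for a standard 32-electrode 10/20 layout,
#' used for topographies, channel adjacency and the synthetic leadfields.
#' x is positive towards the right ear, y positive towards the nasion; the
#' outer electrode ring sits near radius 1.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' head(standard_montage32())
standard_montage32 <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "FT9", "FC5", "FC1", "FC2", "FC6", "FT10",
                "T7", "C3", "Cz", "C4", "T8",
                "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
                "P7", "P3", "Pz", "P4", "P8",
                "O1", "Oz", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.38, 0, 0.38, 0.81,
          -0.95, -0.67, -0.25, 0.25, 0.67, 0.95,
          -1, -0.5, 0, 0.5, 1,
          -0.95, -0.67, -0.25, 0.25, 0.67, 0.95,
          -0.81, -0.38, 0, 0.38, 0.81,
          -0.31, 0, 0.31),
    y = c(0.95, 0.95, 0.59, 0.54, 0.5, 0.54, 0.59,
          0.31, 0.3, 0.28, 0.28, 0.3, 0.31,
          0, 0, 0, 0, 0,
          -0.31, -0.3, -0.28, -0.28, -0.3, -0.31,
          -0.59, -0.54, -0.5, -0.54, -0.59,
          -0.95, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Default channel set: 32 scalp + 6 left-ear + 6 right-ear + EOG
#'
#' Ear electrodes follow the in-ear position naming A, B, C, T, E, I,
#' prefixed by EL (left) / ER (right). A dedicated EOG channel records the
#' ocular source.
#'
#' @return Named character vector mapping channel label to group
#'   (`"scalp"`, `"ear_left"`, `"ear_right"`, `"eog"`).
#' @export
default_channel_groups <- function() {
  scalp <- standard_montage32()$channel
  earL <- paste0("EL", c("A", "B", "C", "T", "E", "I"))
  earR <- paste0("ER", c("A", "B", "C", "T", "E", "I"))
  groups <- c(rep("scalp", length(scalp)),
              rep("ear_left", 6), rep("ear_right", 6), "eog")
  names(groups) <- c(scalp, earL, earR, "EOG")
  groups
}

#' Infer channel groups from labels
#'
#' Channels prefixed `EL`/`ER` are assigned to the left/right ear groups,
#' labels containing `EOG` to the EOG group, everything else to scalp.
#'
#' @param labels Character vector of channel labels.
#' @return Named character vector of groups.
#' @export
infer_channel_groups <- function(labels) {
  groups <- rep("scalp", length(labels))
  groups[startsWith(labels, "EL")] <- "ear_left"
  groups[startsWith(labels, "ER")] <- "ear_right"
  groups[grepl("EOG", labels, fixed = TRUE)] <- "eog"
  names(groups) <- labels
  groups
}

# Gaussian bump on the 2D montage, used by the synthetic leadfields.
montage_gaussian <- function(montage, center, sigma) {
  d2 <- (montage$x - center[1])^2 + (montage$y - center[2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Default leadfields for the synthetic forward model
#'
#' The cognitive source projects with a parietal maximum (centred near Pz)
#' and an opposite-polarity frontal lobe, representing the two ends of a
#' single dipolar source; scalp weights are zero-mean across the scalp (so
#' average re-referencing leaves them unchanged) and scaled so the Pz
#' weight is exactly 1. Ear channels receive the parietal weight times an
#' attenuation factor with a zero-mean sign gradient across the six in-ear
#' positions (so per-ear average re-referencing leaves them unchanged).
#' The ocular source projects frontally, with weight 1 on the EOG channel
#' and nothing on the ears.
#'
#' @param ear_attenuation Ear weight relative to the Pz scalp weight
#'   (default 0.15).
#' @return List with numeric vectors `cognitive` and `ocular`, both named
#'   by channel, covering all channels of [default_channel_groups()].
#' @export
default_leadfields <- function(ear_attenuation = 0.15) {
  mon <- standard_montage32()
  groups <- default_channel_groups()
  channels <- names(groups)

  parietal <- montage_gaussian(mon, c(0, -0.5), 0.45)
  frontal <- montage_gaussian(mon, c(0, 0.95), 0.40)
  cog_scalp <- parietal - 0.5 * frontal
  cog_scalp <- cog_scalp - mean(cog_scalp)
  cog_scalp <- cog_scalp / cog_scalp[mon$channel == "Pz"]

  ear_grad <- c(0.8, 0.5, 0.2, -0.2, -0.5, -0.8)  # zero-mean across the ear
  cog <- c(cog_scalp, ear_attenuation * ear_grad, ear_attenuation * ear_grad, 0)
  names(cog) <- channels

  ocu_scalp <- montage_gaussian(mon, c(0, 1.1), 0.30)
  ocu <- c(ocu_scalp, rep(0, 12), 1)
  names(ocu) <- channels

  list(cognitive = cog, ocular = ocu)
}
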