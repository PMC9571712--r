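#' Default sensor montages
#'
#' 2-D projected scalp layouts used by the synthetic generator and the
#' topographic maps. `"eeg30"` is a 30-channel 10-20 layout including the
#' posterior midline/occipital channels (POz, O1, O2) and the frontal set
#' (Fp1, Fp2, AFz, F1, F2) that carry the planted workload effects.
#' `"eeg28"` is the same layout without the temporal pair (T7, T8) and is
#' the channel set under which the feature-count identities (84 PSD,
#' 4536 FBC columns) hold. `"fnirs36"` is a 36-channel optode layout
#' spanning frontal to occipital rows, including the right-frontal AF8
#' position.
#'
#' Coordinates are a unit-radius top view: x positive towards the right
#' ear, y positive towards the nasion.
#'
#' @param name one of `"eeg30"`, `"eeg28"`, `"fnirs36"`.
#' @return data.frame with columns `label`, `x`, `y`.
#' @examples
#' head(default_montage("eeg30"))
#' @export
default_montage <- function(name = c("eeg30", "eeg28", "fnirs36")) {
  name <- match.arg(name)
  if (name %in% c("eeg30", "eeg28")) {
    m <- data.frame(
      label = c("Fp1", "Fp2", "AFz", "F7", "F3", "F1", "Fz", "F2", "F4",
                "F8", "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4",
                "T8", "CP5", "CP1", "CP2", "CP6", "P7", "P3", "P4", "P8",
                "POz", "O1", "O2"),
      x = c(-0.31, 0.31, 0.00, -0.80, -0.43, -0.22, 0.00, 0.22, 0.43,
            0.80, -0.67, -0.22, 0.22, 0.67, -1.00, -0.45, 0.00, 0.45,
            1.00, -0.67, -0.22, 0.22, 0.67, -0.80, -0.43, 0.43, 0.80,
            0.00, -0.31, 0.31),
      y = c(0.95, 0.95, 0.82, 0.59, 0.57, 0.55, 0.55, 0.55, 0.57,
            0.59, 0.30, 0.28, 0.28, 0.30, 0.00, 0.00, 0.00, 0.00,
            0.00, -0.30, -0.28, -0.28, -0.30, -0.59, -0.57, -0.57, -0.59,
            -0.72, -0.95, -0.95),
      stringsAsFactors = FALSE
    )
    if (name == "eeg28") m <- m[!m$label %in% c("T7", "T8"), , drop = FALSE]
    rownames(m) <- NULL
    return(m)
  }
  # fNIRS: 9 frontal, then rows marching back to the occiput
  lab <- c("AF7", "AF5", "AF3", "AF1", "AFz", "AF2", "AF4", "AF6", "AF8",
           "F5h", "F1h", "F2h", "F6h",
           "FC3h", "FC4h",
           "C5h", "C3h", "C1h", "C2h", "C4h", "C6h",
           "CP3h", "CP4h",
           "P5h", "P1h", "P2h", "P6h",
           "PPO1", "PPOz", "PPO2",
           "O1h", "Ozh", "O2h",
           "OI1", "OIz", "OI2")
  x <- c(-0.72, -0.54, -0.36, -0.18, 0.00, 0.18, 0.36, 0.54, 0.72,
         -0.55, -0.18, 0.18, 0.55,
         -0.35, 0.35,
         -0.75, -0.45, -0.15, 0.15, 0.45, 0.75,
         -0.35, 0.35,
         -0.55, -0.18, 0.18, 0.55,
         -0.25, 0.00, 0.25,
         -0.35, 0.00, 0.35,
         -0.20, 0.00, 0.20)
  y <- c(rep(0.78, 9),
         rep(0.50, 4),
         rep(0.25, 2),
         rep(0.00, 6),
         rep(-0.25, 2),
         rep(-0.50, 4),
         rep(-0.68, 3),
         rep(-0.85, 3),
         rep(-0.98, 3))
  data.frame(label = lab, x = x, y = y, stringsAsFactors = FALSE)
}

check_montage <- function(m) {
  stopifnot(is.data.frame(m), all(c("label", "x", "y") %in% names(m)))
  if (anyDuplicated(m$label)) stop("montage labels must be unique")
  invisible(m)
}
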