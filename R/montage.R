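#' Scalp montage of the 56-channel extended 10-20 recording
#'
#' The recordings modelled here use 56 passive scalp electrodes laid out on
#' the extended 10-20 system, plus one EOG lead. The montage order below is
#' the canonical channel order used throughout the package: feature blocks,
#' CSV columns and channel-selection passes all follow it.
#'
#' @return Character vector of the 56 scalp channel names, in montage order.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "POz", "PO8", "O1", "O2")
}

#' Schematic 2-D electrode layout
#'
#' A flat schematic projection of the montage (x: left negative to right
#' positive; y: nasion positive to inion negative, both roughly in units of
#' head radius). It is used only to shape the spatial spread of the
#' synthetic ErrP template and of the posterior alpha rhythm; it is a layout
#' sketch, not a volume-conduction head model.
#'
#' @return A data.frame with columns `channel`, `x`, `y` (56 rows, montage
#'   order).
#' @export
montage_layout <- function() {
  rows <- list(
    Fp = 1.00, AF = 0.80, F = 0.60, FT = 0.35, FC = 0.35,
    T = 0.00, C = 0.00, TP = -0.35, CP = -0.35, P = -0.60,
    PO = -0.80, O = -1.00
  )
  ch <- montage_channels()
  prefix <- sub("([0-9]+|z)$", "", ch)
  suffix <- sub("^.*?([0-9]+|z)$", "\\1", ch)
  y <- unlist(rows[prefix], use.names = FALSE)
  lat <- vapply(suffix, function(s) {
    if (s == "z") return(0)
    n <- as.integer(s)
    side <- if (n %% 2 == 1) -1 else 1
    side * switch(as.character(ceiling(n / 2)),
                  "1" = 0.20, "2" = 0.45, "3" = 0.70, "4" = 0.95)
  }, numeric(1))
  # outermost temporal leads sit on the equator
  lat[ch %in% c("T7")] <- -1.0
  lat[ch %in% c("T8")] <- 1.0
  data.frame(channel = ch, x = unname(lat), y = y,
             stringsAsFactors = FALSE)
}

#' Spatial weights of the fronto-central ErrP template
#'
#' The synthetic error response is maximal over the fronto-central midline
#' (Cz/FCz) and falls off smoothly with scalp distance, mimicking the
#' topography of the feedback-locked error negativity. Weights are a
#' Gaussian function of the schematic-layout distance to the nearer of Cz
#' and FCz, normalised so Cz and FCz carry weight 1.
#'
#' @param sigma spatial decay scale in layout units (default 0.45).
#' @return Named numeric vector of weights in (0, 1], one per scalp channel.
#' @export
errp_topography <- function(sigma = 0.45) {
  lay <- montage_layout()
  cz <- as.numeric(lay[lay$channel == "Cz", c("x", "y")])
  fcz <- as.numeric(lay[lay$channel == "FCz", c("x", "y")])
  d1 <- sqrt((lay$x - cz[1])^2 + (lay$y - cz[2])^2)
  d2 <- sqrt((lay$x - fcz[1])^2 + (lay$y - fcz[2])^2)
  d <- pmin(d1, d2)
  w <- exp(-d^2 / (2 * sigma^2))
  names(w) <- lay$channel
  w
}
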