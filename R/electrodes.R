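#' Synthetic 10-10 electrode montage on the unit sphere
#'
#' Spherical-approximation coordinates for the standard 10-10 grid rows
#' Fp/AF/F/FC/C/CP/P/PO/O. Each label maps to an anterior-posterior fraction
#' and a lateral fraction of the hemispherical arc; the two arcs are
#' combined on the unit sphere and normalized. This is a geometric stand-in
#' for a digitized montage, adequate for the synthetic head model.
#'
#' @return data.frame with columns \code{label}, \code{x} (right),
#'   \code{y} (anterior), \code{z} (superior); rows are the known labels.
#' @export
tenTenMontage <- function() {
  rows <- list(
    Fp = list(u = 0.8,  cols = c(1, 0, 2)),
    AF = list(u = 0.6,  cols = c(7, 3, 0, 4, 8)),
    F  = list(u = 0.4,  cols = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    FC = list(u = 0.2,  cols = c(5, 3, 1, 0, 2, 4, 6)),
    C  = list(u = 0.0,  cols = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    CP = list(u = -0.2, cols = c(5, 3, 1, 0, 2, 4, 6)),
    P  = list(u = -0.4, cols = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    PO = list(u = -0.6, cols = c(7, 3, 0, 4, 8)),
    O  = list(u = -0.8, cols = c(1, 0, 2)))
  lab <- character(0); xs <- ys <- zs <- numeric(0)
  for (rn in names(rows)) {
    r <- rows[[rn]]
    for (cc in r$cols) {
      name <- if (cc == 0) paste0(rn, "z") else paste0(rn, cc)
      # lateral C-row extremes carry temporal names
      if (rn == "C" && cc == 7) name <- "T7"
      if (rn == "C" && cc == 8) name <- "T8"
      w <- (if (cc == 0) 0 else ceiling(cc / 2) * 0.2) *
           (if (cc %% 2 == 1) -1 else 1)     # odd indices on the left
      ta <- r$u * pi / 2; tl <- w * pi / 2
      v <- c(sin(tl) * cos(ta), sin(ta) * cos(tl), cos(ta) * cos(tl))
      v <- v / sqrt(sum(v^2))
      lab <- c(lab, name); xs <- c(xs, v[1]); ys <- c(ys, v[2]); zs <- c(zs, v[3])
    }
  }
  data.frame(label = lab, x = xs, y = ys, z = zs, stringsAsFactors = FALSE)
}

#' The 20 centro-parietal electrodes of the simulation study
#'
#' FC3, FC1, FCz, FC2, FC4, C3, C1, Cz, C2, C4, CP3, CP1, CPz, CP2, CP4,
#' P3, P1, Pz, P2, P4 - a grid covering the fronto-central to parietal
#' scalp.
#'
#' @return character vector of 20 labels.
#' @export
simulationElectrodes <- function() {
  c("FC3", "FC1", "FCz", "FC2", "FC4", "C3", "C1", "Cz", "C2", "C4",
    "CP3", "CP1", "CPz", "CP2", "CP4", "P3", "P1", "Pz", "P2", "P4")
}
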