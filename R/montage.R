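#' Extended 10/20 EEG montage for the simulator
#'
#' A static 60-channel montage on the extended international 10/20 grid with
#' schematic 2-D scalp coordinates (head radius 1, nose up: `x` increases to
#' the right, `y` to the front). The coordinates are used to place planted
#' ERD topographies and to smooth the simulated volume-conduction noise; they
#' are schematic, not digitized electrode positions.
#'
#' Channel names are ordered so that every left/right mirror pair is adjacent
#' and the sensorimotor strip (C3/C4/Cz and neighbours) comes first. A request
#' for fewer than 60 channels therefore keeps the motor cortex coverage and
#' left/right symmetry needed for lateralized motor imagery: `bci_montage(22)`
#' is a central strip suitable for reduced-size simulations.
#'
#' @param n_channels Number of channels to keep (4-60). C3, C4 and Cz are
#'   always present.
#' @return A data.frame with columns `name`, `x`, `y`.
#' @examples
#' m <- bci_montage(22)
#' subset(m, name %in% c("C3", "C4", "Cz"))
#' @export
bci_montage <- function(n_channels = 60) {
  tab <- montage_table()
  if (!is.numeric(n_channels) || length(n_channels) != 1 ||
      n_channels < 4 || n_channels > nrow(tab)) {
    stop("n_channels must be a single value between 4 and ", nrow(tab))
  }
  out <- tab[seq_len(as.integer(n_channels)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Priority-ordered montage: mirror pairs adjacent, central strip first.
# y rows (front  -> back): Fp=0.9, AF=0.7, F=0.5, FC=0.25, C=0, CP=-0.25,
# P=-0.5, PO=-0.7, O=-0.9.  x spacing 0.22 per 10/10 step.
montage_table <- function() {
  row_y <- c(Fp = 0.9, AF = 0.7, F = 0.5, FT = 0.3, FC = 0.25, T = 0,
             C = 0, TP = -0.3, CP = -0.25, P = -0.5, PO = -0.7, O = -0.9)
  # digit -> |x| ; z = 0
  dx <- c("1" = 0.22, "2" = 0.22, "3" = 0.44, "4" = 0.44,
          "5" = 0.66, "6" = 0.66, "7" = 0.88, "8" = 0.88)
  names60 <- c(
    # sensorimotor strip first (pairs adjacent, midline after its pair)
    "C3", "C4", "Cz", "C1", "C2", "C5", "C6",
    "FC3", "FC4", "FCz", "FC1", "FC2", "FC5", "FC6",
    "CP3", "CP4", "CPz", "CP1", "CP2", "CP5", "CP6",
    "T7", "T8",
    # frontal
    "F3", "F4", "Fz", "F1", "F2", "F5", "F6", "F7", "F8",
    "FT7", "FT8",
    # parietal
    "P3", "P4", "Pz", "P1", "P2", "P5", "P6", "P7", "P8",
    "TP7", "TP8",
    # far frontal / occipital
    "Fp1", "Fp2", "Fpz", "AF3", "AF4",
    "PO3", "PO4", "POz", "PO5", "PO6", "PO7", "PO8",
    "O1", "O2", "Oz"
  )
  coord <- function(nm) {
    base <- sub("[0-9z]+$", "", nm)
    suffix <- sub("^[A-Za-z]*?(?=[0-9z]+$)", "", nm, perl = TRUE)
    y <- row_y[[base]]
    if (suffix == "z") return(c(0, y))
    d <- dx[[suffix]]
    # T7/T8, FT7/FT8, TP7/TP8 sit on the 10% ring
    if (base %in% c("T", "FT", "TP")) d <- 0.88
    sgn <- if (as.integer(suffix) %% 2 == 1) -1 else 1
    c(sgn * d, y)
  }
  xy <- t(vapply(names60, coord, numeric(2)))
  data.frame(name = names60, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Mirror channel names across the midline
#'
#' Swaps odd and even 10/20 digits (C3 <-> C4, FC1 <-> FC2, ...); midline
#' `z` channels map to themselves.
#'
#' @param names Character vector of 10/20 channel names.
#' @return Character vector of mirrored names.
#' @export
mirror_channels <- function(names) {
  vapply(names, function(nm) {
    suffix <- sub("^[A-Za-z]*?(?=[0-9z]+$)", "", nm, perl = TRUE)
    if (suffix == "z") return(nm)
    d <- as.integer(suffix)
    d2 <- if (d %% 2 == 1) d + 1L else d - 1L
    paste0(sub("[0-9z]+$", "", nm), d2)
  }, character(1), USE.NAMES = FALSE)
}
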