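#' Idealised 60-channel 10-10 electrode layout
#'
#' Constructs a parametric approximation of a 60-electrode subset of the
#' extended international 10-20 (10-10) system on the unit hemisphere.  Each
#' electrode is placed by a lateral and an anterior-posterior arc angle in 18
#' degree (10\%) steps; positions falling outside the head circumference are
#' clamped radially to the rim.  The layout is idealised: it is meant to give
#' spatially smooth, plausibly arranged sensor positions for template-map
#' construction and plotting, not digitised head coordinates.
#'
#' @return A data frame with one row per electrode and columns `channel`,
#'   `x` (left negative, right positive), `y` (posterior negative, anterior
#'   positive) and `z` (all on the unit sphere; `x`,`y` double as the 2-D
#'   top-down projection).
#' @examples
#' m <- standard_montage()
#' nrow(m)   # 60
#' @export
standard_montage <- function() {
  rows <- list(
    Fp = list(c("Fp1", "Fpz", "Fp2"), 72),
    AF = list(c("AF3", "AF4"), 54),
    F  = list(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), 36),
    FC = list(c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"), 18),
    C  = list(c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"), 0),
    CP = list(c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"), -18),
    P  = list(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), -36),
    PO = list(c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"), -54),
    O  = list(c("O1", "Oz", "O2"), -72)
  )
  # lateral arc angle by the 10-10 digit; z-line electrodes sit on the midline
  digit_angle <- c("1" = 18, "2" = 18, "3" = 36, "4" = 36,
                   "5" = 54, "6" = 54, "7" = 72, "8" = 72)
  ch <- character(0); ax <- numeric(0); ay <- numeric(0)
  for (r in rows) {
    for (nm in r[[1]]) {
      d <- sub("^[A-Za-z]+", "", nm)
      if (d == "z" || d == "") {
        a <- 0
      } else {
        a <- digit_angle[[d]]
        if (as.integer(d) %% 2 == 1) a <- -a  # odd digits are left hemisphere
      }
      ch <- c(ch, nm); ax <- c(ax, a); ay <- c(ay, r[[2]])
    }
  }
  ux <- sin(ax * pi / 180)
  uy <- sin(ay * pi / 180)
  rad <- sqrt(ux^2 + uy^2)
  over <- rad > 0.95
  ux[over] <- ux[over] * 0.95 / rad[over]
  uy[over] <- uy[over] * 0.95 / rad[over]
  data.frame(channel = ch, x = ux, y = uy,
             z = sqrt(pmax(0, 1 - ux^2 - uy^2)))
}

#' Canonical microstate reference maps (A-D)
#'
#' Builds the four canonical microstate reference topographies on a given
#' montage as parametric patterns: A and B are mirrored diagonal gradients
#' (left-right and right-left orientation), C is an anterior-posterior
#' gradient, and D is a fronto-central maximum (Gaussian).  Maps are
#' average-referenced and unit-L2-normalised.  The coefficients are
#' repo-defined idealisations of the well-known published class topographies;
#' their role is to anchor the A/B/C/D labels, and any user-supplied sorted
#' template set can replace them.
#'
#' @param montage A montage data frame as returned by [standard_montage()].
#' @return A [template_set()] with labels `A`,`B`,`C`,`D`, level `"canonical"`.
#' @examples
#' atlas <- canonical_atlas()
#' round(crossprod(atlas$maps), 2)  # modest pairwise correlations
#' @export
canonical_atlas <- function(montage = standard_montage()) {
  x <- montage$x; y <- montage$y
  maps <- cbind(
    A = -x + 0.5 * y,                              # left-right orientation
    B =  x + 0.5 * y,                              # right-left orientation
    C =  y,                                        # anterior-posterior
    D =  exp(-((x^2 + (y - 0.15)^2) / (2 * 0.4^2)))  # fronto-central maximum
  )
  template_set(maps, labels = c("A", "B", "C", "D"),
               channel_names = montage$channel, level = "canonical")
}
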