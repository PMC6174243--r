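#' Standard 10-channel clinical montage
#'
#' Electrode positions for the reduced 10-20 montage used by the pipeline
#' (FP1/2, F7/8, T5/6, O1/2, C3/4) as unit-sphere Cartesian coordinates.
#' The head is idealized as a unit sphere with the vertex (Cz) at +z, the
#' nasion direction at +y and the right ear at +x. The outer ring of the
#' 10-20 system (frontopolar, lateral frontal, posterior temporal and
#' occipital electrodes) sits on the equator; C3/C4 sit halfway up the
#' ear-to-ear arc.
#'
#' @param labels Character vector of channel labels to keep, in order.
#'   Defaults to the full 10-channel montage.
#'
#' @return A tibble with columns `label`, `x`, `y`, `z`; every row has
#'   unit norm.
#' @export
#'
#' @examples
#' standard_montage()
standard_montage <- function(labels = c("FP1", "FP2", "F7", "F8", "T5",
                                        "T6", "O1", "O2", "C3", "C4")) {
  # equatorial ring: azimuth from the anterior midline in 36 degree steps
  ring <- function(deg, side) {
    a <- deg * pi / 180
    c(x = side * sin(a), y = cos(a), z = 0)
  }
  pos <- rbind(
    FP1 = ring(18, -1), FP2 = ring(18, +1),
    F7  = ring(54, -1), F8  = ring(54, +1),
    T5  = ring(126, -1), T6 = ring(126, +1),
    O1  = ring(162, -1), O2 = ring(162, +1),
    C3  = c(-sin(pi / 4), 0, cos(pi / 4)),
    C4  = c(+sin(pi / 4), 0, cos(pi / 4))
  )
  labels <- toupper(labels)
  missing <- setdiff(labels, rownames(pos))
  if (length(missing) > 0) {
    abort(paste0("unknown montage label(s): ", paste(missing, collapse = ", ")))
  }
  pos <- pos[labels, , drop = FALSE]
  tibble(label = labels, x = unname(pos[, 1]), y = unname(pos[, 2]),
         z = unname(pos[, 3]))
}
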