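#' Central white-matter analysis mask
#'
#' Restricts a white-matter mask to pixels lying strictly more than
#' `margin_px` (Euclidean) from the outside contour of the brain-slice
#' mask, excluding peripheral WM where vessels running over the cortex
#' and mask-edge effects would contaminate perforator detection. The
#' distance is the Euclidean distance transform of the brain mask
#' (distance from each brain pixel to the nearest non-brain pixel), and
#' the inequality is strict: a pixel exactly at `margin_px` is excluded.
#'
#' @param wm 0/1 white-matter mask matrix.
#' @param brain 0/1 brain-slice mask matrix, same shape, nonempty.
#' @param margin_px margin in pixels (default 80 on the 0.2 mm grid).
#' @return 0/1 matrix (subset of `wm`), with attribute `margin_px`. An
#'   empty result triggers a warning, not an error.
#' @export
central_wm <- function(wm, brain, margin_px = 80) {
  stopifnot(is.matrix(wm), is.matrix(brain),
            identical(dim(wm), dim(brain)))
  if (!any(brain == 1)) stop("brain mask is empty")
  if (margin_px == 0) {
    out <- matrix(as.integer(wm == 1 & brain == 1), nrow(wm), ncol(wm))
  } else {
    d <- array(EBImage::distmap(brain, metric = "euclidean"), dim = dim(brain))
    out <- matrix(as.integer(wm == 1 & d > margin_px), nrow(wm), ncol(wm))
  }
  if (!any(out == 1))
    warning("central WM mask is empty at margin ", margin_px, " px")
  attr(out, "margin_px") <- margin_px
  out
}
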