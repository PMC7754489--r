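#' Detrend the temporal-mean magnitude image
#'
#' Removes spatial intensity inhomogeneity before vessel thresholding:
#' a median-filtered copy (default 70-px window, realized as the nearest
#' odd size 71, reflect padding) is subtracted from the mean magnitude
#' image, leaving compact bright structures (vessels) on a flat
#' background.
#'
#' @param mean_magnitude matrix: magnitude averaged over cardiac phases.
#' @param window_px median window (default 70; even values rounded up to
#'   odd).
#' @return detrended matrix, same shape.
#' @export
detrend_magnitude <- function(mean_magnitude, window_px = 70L) {
  stopifnot(is.matrix(mean_magnitude))
  mean_magnitude - median_filter_2d(mean_magnitude, window_px)
}

#' Identify large-vessel clusters by relative intensity threshold
#'
#' Sorts brain-mask voxel intensities of the detrended mean-magnitude
#' image from high to low and selects the top `top_fraction` (default
#' 0.3%): the threshold is the intensity of the
#' `ceiling(top_fraction * N_brain)`-th brightest brain voxel, and all
#' voxels at or above it (ties included) are candidates. Connected
#' candidate components with at least `min_cluster` voxels (default 3,
#' i.e. "more than two") become vessel clusters; smaller ones are left
#' alone so single-voxel perforators are not misidentified as vessels.
#' Each cluster is assigned its censoring geometry by the size rule:
#' clusters with `size >= big_cluster_threshold` (default 80) get
#' (dilate `big_dilate` = 2 px, extend `big_extend` = 200 px), smaller
#' clusters get (`small_dilate` = 1 px, `small_extend` = 110 px).
#'
#' @param detrended detrended mean-magnitude matrix
#'   (see [detrend_magnitude()]).
#' @param brain 0/1 brain-slice mask (the percentile is taken over brain
#'   voxels, not the full field of view).
#' @param config a [default_config()]-style list supplying
#'   `vessel_top_fraction`, `vessel_min_cluster`,
#'   `big_cluster_threshold`, `big_dilate`, `big_extend`, `small_dilate`,
#'   `small_extend` and `connectivity`.
#' @return list of vessel clusters sorted by descending size; each is a
#'   list with `voxels` (n x 2 matrix of row/col), `size`, `dilate_px`,
#'   `extend_px`.
#' @export
identify_large_vessels <- function(detrended, brain,
                                   config = default_config()) {
  stopifnot(is.matrix(detrended), is.matrix(brain),
            identical(dim(detrended), dim(brain)))
  idx <- which(brain == 1)
  if (length(idx) == 0) stop("brain mask is empty")
  f <- config$vessel_top_fraction
  stopifnot(f > 0, f < 1)
  vals <- detrended[idx]
  nsel <- ceiling(f * length(vals))
  threshold <- sort(vals, decreasing = TRUE)[nsel]
  cand <- matrix(as.integer(brain == 1 & detrended >= threshold),
                 nrow(brain), ncol(brain))
  lab <- label_components_2d(cand, config$connectivity)
  nlab <- max(lab)
  clusters <- list()
  for (g in seq_len(nlab)) {
    vidx <- which(lab == g)
    if (length(vidx) < config$vessel_min_cluster) next
    vox <- cbind((vidx - 1L) %% nrow(lab) + 1L,
                 (vidx - 1L) %/% nrow(lab) + 1L)
    big <- length(vidx) >= config$big_cluster_threshold
    clusters[[length(clusters) + 1L]] <- list(
      voxels = vox, size = length(vidx),
      dilate_px = if (big) config$big_dilate else config$small_dilate,
      extend_px = if (big) config$big_extend else config$small_extend)
  }
  if (length(clusters) > 1) {
    ord <- order(vapply(clusters, `[[`, integer(1), "size"),
                 decreasing = TRUE)
    clusters <- clusters[ord]
  }
  clusters
}

# moving-any (binary dilation) along one axis by e pixels each side,
# clipped at the borders; exact via cumulative sums
dilate_axis <- function(m, e, axis) {
  if (e <= 0) return(m)
  if (axis == 2L) return(t(dilate_axis(t(m), e, 1L)))
  nr <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))           # cs[i+1, ] = sum rows 1..i
  hi <- pmin(nr, seq_len(nr) + e)
  lo <- pmax(0L, seq_len(nr) - e - 1L)
  matrix(as.integer((cs[hi + 1L, , drop = FALSE] -
                     cs[lo + 1L, , drop = FALSE]) > 0), nr, ncol(m))
}

#' Build the ghost-stripe censoring mask from vessel clusters
#'
#' Each vessel cluster is dilated by its `dilate_px` along the readout
#' axis (the axis orthogonal to `pe_axis`) and extended by its
#' `extend_px` on each side along the phase-encoding axis, producing the
#' stripe-shaped exclusion footprint a ghosting vessel casts. Footprints
#' are clipped at the image border (no wrap) and unioned.
#'
#' @param clusters list of clusters from [identify_large_vessels()].
#' @param shape image shape (rows, cols).
#' @param pe_axis `"rows"` or `"cols"`.
#' @param extend_mode `"per_side"` (default: `extend_px` on each side,
#'   the reading that reproduces stripes traversing most of the image)
#'   or `"total"` (`extend_px` split over both sides).
#' @return list of class `stripe_mask`: `data` (0/1 matrix), `clusters`,
#'   `pe_axis`.
#' @export
build_stripe_mask <- function(clusters, shape, pe_axis = c("rows", "cols"),
                              extend_mode = c("per_side", "total")) {
  pe_axis <- match.arg(pe_axis)
  extend_mode <- match.arg(extend_mode)
  data <- matrix(0L, shape[1], shape[2])
  pe_ax <- if (pe_axis == "rows") 1L else 2L
  ro_ax <- 3L - pe_ax
  for (cl in clusters) {
    vox <- cl$voxels
    stopifnot(all(vox[, 1] >= 1 & vox[, 1] <= shape[1]),
              all(vox[, 2] >= 1 & vox[, 2] <= shape[2]))
    m <- matrix(0L, shape[1], shape[2])
    m[vox] <- 1L
    e <- if (extend_mode == "per_side") cl$extend_px else cl$extend_px %/% 2L
    m <- dilate_axis(m, cl$dilate_px, ro_ax)
    m <- dilate_axis(m, e, pe_ax)
    data <- pmax(data, m)
  }
  structure(list(data = data, clusters = clusters, pe_axis = pe_axis),
            class = "stripe_mask")
}

#' Censor perforators lying on ghost stripes
#'
#' Partitions detected perforators into included (outside all stripes)
#' and excluded (located on a stripe pixel, edge pixels counting as on).
#' The input order is preserved; excluded records get
#' `exclusion_reason = "ghost_stripe"`.
#'
#' @param records perforator data.frame from [detect_perforators()].
#' @param stripes a `stripe_mask` from [build_stripe_mask()].
#' @return the records data.frame with `included` / `exclusion_reason`
#'   updated; attributes `n_included` and `n_excluded`.
#' @export
censor_perforators <- function(records, stripes) {
  stopifnot(is.data.frame(records), inherits(stripes, "stripe_mask"))
  if (nrow(records)) {
    stopifnot(all(records$row >= 1 & records$row <= nrow(stripes$data)),
              all(records$col >= 1 & records$col <= ncol(stripes$data)))
    on_stripe <- stripes$data[cbind(records$row, records$col)] == 1L
    records$included <- !on_stripe
    records$exclusion_reason <- ifelse(on_stripe, "ghost_stripe", "none")
  }
  attr(records, "n_included") <- sum(records$included)
  attr(records, "n_excluded") <- sum(!records$included)
  records
}

#' Fraction of the white-matter mask covered by ghost stripes
#'
#' @param wm 0/1 white-matter mask.
#' @param stripes a `stripe_mask`.
#' @return percentage in `[0, 100]`.
#' @export
ghost_fraction <- function(wm, stripes) {
  stopifnot(is.matrix(wm), inherits(stripes, "stripe_mask"),
            identical(dim(wm), dim(stripes$data)))
  n_wm <- sum(wm == 1)
  if (n_wm == 0) stop("degenerate input: empty white-matter mask")
  100 * sum(wm == 1 & stripes$data == 1L) / n_wm
}
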