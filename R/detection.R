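#' Median filtering and component labelling (internal wrappers)
#'
#' `median_filter_2d` applies a sliding median with symmetric reflect
#' padding; even windows are rounded up to the next odd size. Two
#' backends: `"exact"` (double-precision order statistic) and
#' `"histogram"` (Huang-style sliding 16-bit histogram, output precision
#' 1/65535 of the image value range). The default `"auto"` uses the
#' exact filter up to about 3e7 window-element operations and the
#' histogram beyond, where the two differ by far less than any noise
#' level the filter is applied at. `label_components_2d` labels
#' connected foreground components under 4- or 8-connectivity.
#'
#' @param x numeric matrix.
#' @param window window side length (>= 3; even values rounded up).
#' @param method `"auto"`, `"exact"` or `"histogram"`.
#' @return `median_filter_2d`: filtered matrix.
#' @export
median_filter_2d <- function(x, window,
                             method = c("auto", "exact", "histogram")) {
  stopifnot(is.matrix(x))
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 3) stop("window must be >= 3")
  if (window %% 2L == 0L) window <- window + 1L
  if (window > nrow(x) || window > ncol(x))
    stop("window larger than image")
  if (method == "auto") {
    work <- as.numeric(nrow(x)) * ncol(x) * window * window
    method <- if (work > 3e7) "histogram" else "exact"
  }
  if (method == "exact") .median_filter2d(x, window)
  else .median_filter2d_hist(x, window)
}

#' @param mask binary matrix (nonzero = foreground).
#' @param connectivity 4 or 8.
#' @rdname median_filter_2d
#' @return `label_components_2d`: integer label matrix (0 = background).
#' @export
label_components_2d <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  .label_components(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)),
                    as.integer(connectivity))
}

#' Background phase correction of the velocity stack
#'
#' Removes slowly varying background phase offsets so that static tissue
#' has mean velocity ~0 cm/s: for each cardiac phase independently, the
#' median-filtered velocity map is subtracted from the velocity map. The
#' window must be much larger than a perforator footprint (1-2 px) so
#' the filter estimates the background, not the vessels.
#'
#' @param series a [pc_series()], or a bare `[row, col, phase]` velocity
#'   array.
#' @param window_px median-filter window (odd, >= 3; default 31).
#' @return corrected velocity array `[row, col, phase]`, cm/s.
#' @export
correct_background_phase <- function(series, window_px = 31L) {
  v <- if (inherits(series, "pc_series")) series$velocity else series
  stopifnot(length(dim(v)) == 3L)
  out <- v
  for (t in seq_len(dim(v)[3]))
    out[, , t] <- v[, , t] - median_filter_2d(v[, , t], window_px)
  out
}

#' Estimate velocity noise and confidence-interval half-widths
#'
#' The velocity noise SD is derived from the magnitude SNR via the
#' phase-contrast relation `sigma_v = sqrt(2) * venc / (pi * SNR)`.
#' SNR is estimated self-containedly from white matter: signal = mean
#' over the WM mask of the temporal-mean magnitude; noise SD = the
#' median over WM pixels of the temporal (across cardiac phases)
#' magnitude SD, corrected for the median bias of the sample SD under
#' Gaussian noise (perforator pixels are rare enough not to bias a
#' median-based estimate). The 95% CI half-width of the temporal mean
#' velocity is `z(1 - alpha/2) * sigma_v / sqrt(n_phases)` (normal
#' quantile; sigma_v is estimated from thousands of voxels, not
#' per-voxel samples).
#'
#' @param series a [pc_series()].
#' @param wm 0/1 central white-matter mask.
#' @param alpha two-sided significance level (default 0.05).
#' @return list of class `velocity_stats`: `sigma_v` (scalar, cm/s),
#'   `snr`, `noise_sd_magnitude`, `ci_half_width` (scalar, cm/s),
#'   `sigma_v_map` and `ci_half_width_map` (constant rasters), `alpha`,
#'   `n_phases`.
#' @export
estimate_velocity_noise <- function(series, wm, alpha = 0.05) {
  stopifnot(inherits(series, "pc_series"), is.matrix(wm))
  if (!any(wm == 1)) stop("white-matter mask is empty")
  np <- series$n_phases
  idx <- which(wm == 1)
  mag <- series$magnitude
  nrnc <- dim(mag)[1] * dim(mag)[2]
  mwm <- matrix(mag, nrow = nrnc)[idx, , drop = FALSE]  # WM pixels x phases
  mean_mag <- mean(rowMeans(mwm))
  if (mean_mag <= 0) stop("degenerate input: non-positive WM magnitude")
  s_t <- apply(mwm, 1, sd)
  # median-unbiased correction: median of s for Gaussian noise is
  # sigma * sqrt(qchisq(0.5, n-1) / (n-1))
  noise_sd <- median(s_t) / sqrt(qchisq(0.5, np - 1) / (np - 1))
  if (noise_sd <= 0) {
    sigma_v <- series$venc * .Machine$double.eps  # noiseless guard
    snr <- Inf
  } else {
    snr <- mean_mag / noise_sd
    sigma_v <- sqrt(2) * series$venc / (pi * snr)
  }
  z <- qnorm(1 - alpha / 2)
  ci_half <- z * sigma_v / sqrt(np)
  shape <- dim(mag)[1:2]
  structure(list(sigma_v = sigma_v, snr = snr,
                 noise_sd_magnitude = noise_sd,
                 ci_half_width = ci_half,
                 sigma_v_map = matrix(sigma_v, shape[1], shape[2]),
                 ci_half_width_map = matrix(ci_half, shape[1], shape[2]),
                 alpha = alpha, n_phases = np),
            class = "velocity_stats")
}

#' Detect perforators with significant downward flow
#'
#' A WM voxel is significant when the two-sided `1 - alpha` confidence
#' interval of its temporal-mean velocity excludes 0 cm/s. Neighbouring
#' significant voxels (4- or 8-connectivity) are grouped into one
#' candidate perforator; groups whose peak voxel has nonnegative mean
#' velocity are discarded (only downward flow counts), and for each kept
#' group the voxel with the highest absolute mean velocity becomes the
#' perforator, carrying its full velocity-time curve.
#'
#' @param v_corrected background-corrected velocity array
#'   `[row, col, phase]` (see [correct_background_phase()]).
#' @param stats a `velocity_stats` object from
#'   [estimate_velocity_noise()].
#' @param wm 0/1 central white-matter mask.
#' @param alpha two-sided significance level; defaults to the level the
#'   noise stats were built with.
#' @param connectivity 4 or 8 (default 8).
#' @return data.frame with one row per perforator (id, row, col,
#'   cluster_id, cluster_size, v_mean, ci_low, ci_high, included,
#'   exclusion_reason, v1..vT curve columns), sorted by (row, col);
#'   attribute `significant` holds the binary significance map.
#' @export
detect_perforators <- function(v_corrected, stats, wm,
                               alpha = stats$alpha, connectivity = 8L) {
  stopifnot(length(dim(v_corrected)) == 3L, is.matrix(wm),
            inherits(stats, "velocity_stats"))
  np <- dim(v_corrected)[3]
  vbar <- rowMeans(v_corrected, dims = 2)
  z <- qnorm(1 - alpha / 2)
  ci_half <- z * stats$sigma_v / sqrt(np)
  sig <- matrix(as.integer(wm == 1 & abs(vbar) > ci_half),
                nrow(vbar), ncol(vbar))
  lab <- label_components_2d(sig, connectivity)
  nlab <- max(lab)
  rows <- list()
  if (nlab > 0) {
    for (g in seq_len(nlab)) {
      idx <- which(lab == g)
      peak <- idx[which.max(abs(vbar[idx]))]
      if (vbar[peak] >= 0) next            # downward flow only
      r <- (peak - 1L) %% nrow(vbar) + 1L
      c <- (peak - 1L) %/% nrow(vbar) + 1L
      rows[[length(rows) + 1L]] <-
        c(row = r, col = c, cluster_id = g, cluster_size = length(idx),
          v_mean = vbar[peak], curve = v_corrected[r, c, ])
    }
  }
  if (length(rows) == 0) {
    out <- empty_perforator_table(np)
  } else {
    m <- do.call(rbind, rows)
    out <- data.frame(
      id = integer(nrow(m)),
      row = as.integer(m[, "row"]), col = as.integer(m[, "col"]),
      cluster_id = as.integer(m[, "cluster_id"]),
      cluster_size = as.integer(m[, "cluster_size"]),
      v_mean = m[, "v_mean"],
      ci_low = m[, "v_mean"] - ci_half,
      ci_high = m[, "v_mean"] + ci_half,
      included = TRUE, exclusion_reason = "none",
      stringsAsFactors = FALSE)
    curves <- m[, grep("^curve", colnames(m)), drop = FALSE]
    colnames(curves) <- paste0("v", seq_len(np))
    out <- cbind(out, as.data.frame(curves))
    out <- out[order(out$row, out$col), , drop = FALSE]
    out$id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "significant") <- sig
  attr(out, "ci_half_width") <- ci_half
  out
}

empty_perforator_table <- function(n_phases) {
  out <- data.frame(id = integer(0), row = integer(0), col = integer(0),
                    cluster_id = integer(0), cluster_size = integer(0),
                    v_mean = numeric(0), ci_low = numeric(0),
                    ci_high = numeric(0), included = logical(0),
                    exclusion_reason = character(0),
                    stringsAsFactors = FALSE)
  for (t in seq_len(n_phases)) out[[paste0("v", t)]] <- numeric(0)
  out
}
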