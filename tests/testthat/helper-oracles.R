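# Brute-force oracles, deliberately independent of the package's
# implementation paths.

# reflect-padded median filter, direct per-pixel evaluation
bf_median_filter <- function(x, window) {
  h <- window %/% 2
  nr <- nrow(x); nc <- ncol(x)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- x
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- refl((i - h):(i + h), nr)
    jj <- refl((j - h):(j + h), nc)
    out[i, j] <- median(x[ii, jj])
  }
  out
}

# flood-fill component labelling
bf_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
             c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lbl <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      lbl <- lbl + 1L
      queue <- list(c(i, j)); lab[i, j] <- lbl
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (q in seq_len(nrow(nb))) {
          r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] != 0 && lab[r, c] == 0L) {
            lab[r, c] <- lbl
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# same partition of foreground pixels, label values ignored
same_labelling <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- which(a > 0)
  if (length(fg) == 0) return(TRUE)
  ta <- a[fg]; tb <- b[fg]
  length(unique(paste(ta, tb))) == length(unique(ta)) &&
    length(unique(ta)) == length(unique(tb))
}

# per-voxel stripe construction: loop over cluster voxels and all
# dilate/extend offsets
bf_stripe <- function(clusters, shape, pe_axis) {
  out <- matrix(0L, shape[1], shape[2])
  for (cl in clusters) {
    d <- cl$dilate_px; e <- cl$extend_px
    for (v in seq_len(nrow(cl$voxels))) {
      r0 <- cl$voxels[v, 1]; c0 <- cl$voxels[v, 2]
      for (dro in -d:d) for (dpe in -e:e) {
        if (pe_axis == "rows") { r <- r0 + dpe; c <- c0 + dro }
        else { r <- r0 + dro; c <- c0 + dpe }
        if (r >= 1 && r <= shape[1] && c >= 1 && c <= shape[2])
          out[r, c] <- 1L
      }
    }
  }
  out
}

# explicit sums-of-squares two-way ANOVA ICC (no aov)
bf_icc <- function(x, model) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rmeans <- rowMeans(x); cmeans <- colMeans(x)
  ssr <- k * sum((rmeans - grand)^2)
  ssc <- n * sum((cmeans - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (model == "consistency") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# compact phantom + matching config for fast unit tests (128^2 grid,
# brain radius 55, central margin 28)
small_spec <- function(...) {
  args <- list(image_shape = c(128L, 128L), brain_radius = 55,
               plant_margin = 30, n_perforators = 6L,
               vessel_cluster_sizes = c(90L, 10L))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

small_config <- function(...) {
  cfg <- default_config()
  cfg$wm_margin <- 28
  over <- list(...)
  for (key in names(over)) cfg[[key]] <- over[[key]]
  validate_config(cfg)
}
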