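#' Build a pulsatile velocity waveform with an exact pulsatility index
#'
#' Constructs a raised-cosine systolic pulse on a constant baseline whose
#' arithmetic mean equals `v_mean` and whose pulsatility index
#' `(max - min) / mean` of the speed (magnitude) curve equals `pi_target`
#' exactly. Downward flow is negative, so for negative `v_mean` the peak
#' is the most negative sample.
#'
#' @param v_mean target mean velocity, cm/s, nonzero (negative = downward).
#' @param pi_target target pulsatility index, >= 0.
#' @param n_phases number of cardiac phases (>= 3).
#' @param peak_phase_index 1-based index of the systolic peak.
#' @param pulse_width pulse support in cardiac phases; default about half
#'   the cycle, emulating a systolic upstroke within a diastolic baseline.
#' @return numeric vector of length `n_phases`, cm/s.
#' @export
make_waveform <- function(v_mean, pi_target, n_phases,
                          peak_phase_index = 4L, pulse_width = NULL) {
  if (v_mean == 0) stop("v_mean must be nonzero")
  if (pi_target < 0) stop("pi_target must be >= 0")
  if (n_phases < 3) stop("need at least 3 cardiac phases")
  if (pi_target == 0) return(rep(v_mean, n_phases))
  if (is.null(pulse_width)) pulse_width <- max(3, floor(n_phases / 2))
  i <- seq_len(n_phases)
  d <- abs(i - peak_phase_index)
  d <- pmin(d, n_phases - d)             # circular distance to the peak
  p <- ifelse(d <= pulse_width / 2,
              0.5 * (1 + cos(2 * pi * d / pulse_width)), 0)
  w <- p - mean(p)                        # zero-mean pulse shape
  denom <- max(w) - min(w)
  a <- pi_target / denom
  if (1 + a * min(w) <= 0)
    stop("pi_target too large: speed curve would change sign")
  v_mean * (1 + a * w)
}

#' Specification of a synthetic phase-contrast phantom
#'
#' Defines the study conditions the phantom emulates: a 256 x 256 slice
#' with 14 reconstructed cardiac phases and venc 4 cm/s; subvoxel
#' perforators as single-pixel pulsatile downward-flow sources with a
#' partial-volume magnitude/velocity scaling; bright large-vessel
#' clusters; attenuated ghost replicas of each vessel at multiples of
#' `ghost_spacing` along the phase-encoding axis; multiplicative
#' low-frequency intensity inhomogeneity; and Gaussian magnitude and
#' velocity noise. Ghost amplitude and spacing are free parameters of the
#' phantom (no quantitative published characterization exists); defaults
#' are chosen to produce clearly visible stripes.
#'
#' @param image_shape (rows, cols).
#' @param n_phases reconstructed cardiac phases.
#' @param venc velocity encoding, cm/s.
#' @param brain_radius brain-disk radius, px.
#' @param n_perforators number of planted perforators.
#' @param n_on_ghost how many of them to plant inside ghost-truth bands
#'   (the rest are planted with at least `ghost_clearance` px clearance).
#' @param perforator_vmean_range range (cm/s, both negative) from which
#'   true mean velocities are drawn.
#' @param perforator_pi true pulsatility index of every planted waveform.
#' @param perforator_pv_fraction partial-volume scaling in (0, 1] applied
#'   to the planted single-pixel velocity curves.
#' @param peak_phase_index systolic peak location (shared by all
#'   perforators so the mean normalized curve preserves the true PI).
#' @param n_big_vessels number of bright vessel clusters.
#' @param vessel_cluster_sizes voxel counts, recycled over vessels.
#' @param vessel_intensity added magnitude intensity of vessel voxels.
#' @param base_intensity brain-tissue magnitude intensity.
#' @param ghost_amplitude_decay per-replica amplitude attenuation (0, 1).
#' @param ghost_spacing replica offset along the phase-encoding axis, px.
#' @param n_ghost_replicas replicas per side of each vessel.
#' @param ghost_velocity_factor spurious velocity noise inside ghost
#'   bands, as a multiple (>= 3) of the background velocity noise SD.
#' @param inhomogeneity_amplitude multiplicative inhomogeneity amplitude
#'   (fraction of base intensity).
#' @param noise_sd_magnitude Gaussian magnitude noise SD.
#' @param noise_sd_velocity Gaussian velocity noise SD (cm/s); `NULL`
#'   (default) derives it at synthesis time from the realized magnitude
#'   SNR of the central analysis region via the phase-contrast relation
#'   `sigma_v = sqrt(2) * venc / (pi * SNR)`, so the injected velocity
#'   noise is exactly the noise a scanner with this magnitude SNR would
#'   produce (the resolved value is recorded in the returned truth
#'   spec).
#' @param rician use Rician (instead of Gaussian) magnitude noise.
#' @param min_separation minimum Euclidean distance between planted
#'   perforators, px.
#' @param ghost_clearance minimum distance of off-ghost perforators from
#'   any ghost-truth band, px.
#' @param plant_margin perforators are planted strictly inside the
#'   central-WM region (distance to brain exterior > this), px.
#' @param pe_axis `"rows"` or `"cols"`.
#' @param seed seed of the noise stream.
#' @param geometry_seed seed of the geometry stream (vessel/perforator
#'   placement, waveform draws); defaults to `seed`. Fixing it while
#'   varying `seed` changes the noise but not the ground-truth geometry.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         n_phases = 14L,
                         venc = 4,
                         brain_radius = 110,
                         n_perforators = 12L,
                         n_on_ghost = 0L,
                         perforator_vmean_range = c(-1.2, -0.5),
                         perforator_pi = 0.45,
                         perforator_pv_fraction = 0.6,
                         peak_phase_index = 4L,
                         n_big_vessels = 2L,
                         vessel_cluster_sizes = c(100L, 10L),
                         vessel_intensity = 400,
                         base_intensity = 100,
                         ghost_amplitude_decay = 0.35,
                         ghost_spacing = 40L,
                         n_ghost_replicas = 2L,
                         ghost_velocity_factor = 3,
                         inhomogeneity_amplitude = 0.15,
                         noise_sd_magnitude = 5,
                         noise_sd_velocity = NULL,
                         rician = FALSE,
                         min_separation = 5,
                         ghost_clearance = 12,
                         plant_margin = 82,
                         pe_axis = c("rows", "cols"),
                         seed = 1L,
                         geometry_seed = NULL) {
  pe_axis <- match.arg(pe_axis)
  if (n_perforators < 0 || n_big_vessels < 0 || n_ghost_replicas < 0)
    stop("counts must be nonnegative")
  if (any(perforator_vmean_range >= 0))
    stop("perforator_vmean_range must be strictly negative (downward flow)")
  if (ghost_amplitude_decay <= 0 || ghost_amplitude_decay >= 1)
    stop("ghost_amplitude_decay must lie strictly in (0, 1)")
  if (perforator_pv_fraction <= 0 || perforator_pv_fraction > 1)
    stop("perforator_pv_fraction must lie in (0, 1]")
  if (n_on_ghost > n_perforators)
    stop("n_on_ghost cannot exceed n_perforators")
  if (n_on_ghost > 0 && n_big_vessels == 0)
    stop("on-ghost perforators require at least one vessel")
  if (is.null(noise_sd_velocity)) noise_sd_velocity <- NA_real_
  if (is.null(geometry_seed)) geometry_seed <- seed
  spec <- list(image_shape = as.integer(image_shape), n_phases = as.integer(n_phases),
               venc = venc, brain_radius = brain_radius,
               n_perforators = as.integer(n_perforators),
               n_on_ghost = as.integer(n_on_ghost),
               perforator_vmean_range = perforator_vmean_range,
               perforator_pi = perforator_pi,
               perforator_pv_fraction = perforator_pv_fraction,
               peak_phase_index = as.integer(peak_phase_index),
               n_big_vessels = as.integer(n_big_vessels),
               vessel_cluster_sizes = as.integer(vessel_cluster_sizes),
               vessel_intensity = vessel_intensity,
               base_intensity = base_intensity,
               ghost_amplitude_decay = ghost_amplitude_decay,
               ghost_spacing = as.integer(ghost_spacing),
               n_ghost_replicas = as.integer(n_ghost_replicas),
               ghost_velocity_factor = ghost_velocity_factor,
               inhomogeneity_amplitude = inhomogeneity_amplitude,
               noise_sd_magnitude = noise_sd_magnitude,
               noise_sd_velocity = noise_sd_velocity,
               rician = isTRUE(rician),
               min_separation = min_separation,
               ghost_clearance = ghost_clearance,
               plant_margin = plant_margin,
               pe_axis = pe_axis,
               seed = as.integer(seed),
               geometry_seed = as.integer(geometry_seed))
  class(spec) <- "phantom_spec"
  spec
}

# distance-from-center matrix
radial_distance <- function(nr, nc) {
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`)^0.5
}

# grow a random connected blob of `size` pixels from a seed pixel,
# 4-connected random frontier growth (uses the current RNG stream)
grow_blob <- function(seed_rc, size, nr, nc) {
  vox <- matrix(seed_rc, nrow = 1)
  taken <- new.env(hash = TRUE)
  key <- function(r, c) paste0(r, ",", c)
  assign(key(seed_rc[1], seed_rc[2]), TRUE, envir = taken)
  frontier <- matrix(numeric(0), ncol = 2)
  push_nbrs <- function(r, c) {
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, , drop = FALSE]
    nb[!vapply(seq_len(nrow(nb)),
               function(i) exists(key(nb[i, 1], nb[i, 2]), envir = taken),
               logical(1)), , drop = FALSE]
  }
  frontier <- push_nbrs(seed_rc[1], seed_rc[2])
  while (nrow(vox) < size && nrow(frontier) > 0) {
    pick <- sample.int(nrow(frontier), 1L)
    p <- frontier[pick, ]
    frontier <- frontier[-pick, , drop = FALSE]
    if (exists(key(p[1], p[2]), envir = taken)) next
    assign(key(p[1], p[2]), TRUE, envir = taken)
    vox <- rbind(vox, p)
    frontier <- rbind(frontier, push_nbrs(p[1], p[2]))
  }
  unname(vox)
}

#' Synthesize a phantom phase-contrast series with ground truth
#'
#' Renders the magnitude and velocity stacks described by a
#' [phantom_spec()] and returns them as a [pc_series()] together with a
#' `phantom_truth` object holding the planted perforator positions and
#' waveforms, vessel clusters, the ghost-truth band mask (every
#' ghost-replica footprint extended across the image along the
#' phase-encoding axis), and the white-matter and brain masks. Two
#' independent seeded RNG streams are used: geometry (placement,
#' waveforms) and noise, so phantoms with equal `geometry_seed` share
#' ground truth exactly. Identical specs give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `series` ([pc_series()]) and `truth`
#'   (`phantom_truth`: `perforators` data.frame with true curves,
#'   `ghost_truth`, `vessel_clusters`, `wm_mask`, `brain_mask`, `spec`).
#' @export
synthesize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  np <- spec$n_phases
  R <- spec$brain_radius
  dist_c <- radial_distance(nr, nc)
  brain <- matrix(as.integer(dist_c <= R), nr, nc)
  wm <- matrix(as.integer(dist_c <= R - 10), nr, nc)

  # ---- geometry stream -------------------------------------------------
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$geometry_seed)
  scale <- R / 110

  gen_geometry <- function() {
    # vessel clusters: peripheral along pe, near the image midline across
    # pe, so that their censoring stripes traverse the central WM
    clusters <- list()
    struct2d <- matrix(0, nr, nc)
    sizes <- rep_len(spec$vessel_cluster_sizes,
                     max(spec$n_big_vessels, length(spec$vessel_cluster_sizes)))
    if (spec$n_big_vessels > 0) {
      for (v in seq_len(spec$n_big_vessels)) {
        off_pe <- sample(c(-1, 1), 1) * runif(1, 45, 75) * scale
        off_ro <- runif(1, -25, 25) * scale
        if (spec$pe_axis == "rows") {
          ctr <- c(round(nr / 2 + off_pe), round(nc / 2 + off_ro))
        } else {
          ctr <- c(round(nr / 2 + off_ro), round(nc / 2 + off_pe))
        }
        vox <- grow_blob(ctr, sizes[v], nr, nc)
        clusters[[v]] <- list(voxels = vox, size = nrow(vox))
        struct2d[vox] <- struct2d[vox] + spec$vessel_intensity
      }
    }

    # ghost replicas of each vessel along pe_axis (displaced, attenuated
    # image-space copies; clipped at the image border, no wrap)
    if (spec$n_big_vessels > 0 && spec$n_ghost_replicas > 0) {
      for (cl in clusters) {
        for (k in seq_len(spec$n_ghost_replicas)) {
          amp <- spec$vessel_intensity * spec$ghost_amplitude_decay^k
          for (sgn in c(-1, 1)) {
            sh <- cl$voxels
            if (spec$pe_axis == "rows") sh[, 1] <- sh[, 1] + sgn * k * spec$ghost_spacing
            else sh[, 2] <- sh[, 2] + sgn * k * spec$ghost_spacing
            keep <- sh[, 1] >= 1 & sh[, 1] <= nr & sh[, 2] >= 1 & sh[, 2] <= nc
            sh <- sh[keep, , drop = FALSE]
            if (nrow(sh)) struct2d[sh] <- struct2d[sh] + amp
          }
        }
      }
    }

    # ghost-truth bands: each vessel's footprint across pe, spanning the
    # full image along pe_axis
    ghost_truth <- matrix(0L, nr, nc)
    for (cl in clusters) {
      if (spec$pe_axis == "rows") {
        rng <- range(cl$voxels[, 2])
        ghost_truth[, rng[1]:rng[2]] <- 1L
      } else {
        rng <- range(cl$voxels[, 1])
        ghost_truth[rng[1]:rng[2], ] <- 1L
      }
    }

    # perforator placement
    central <- wm == 1 & dist_c < (R - spec$plant_margin)
    if (any(ghost_truth == 1)) {
      dist_to_band <- array(EBImage::distmap(1L - ghost_truth), dim = c(nr, nc))
    } else {
      dist_to_band <- matrix(Inf, nr, nc)
    }
    on_ok <- central & ghost_truth == 1
    off_ok <- central & dist_to_band > spec$ghost_clearance
    want_on <- spec$n_on_ghost
    want_off <- spec$n_perforators - want_on
    if ((want_on > 0 && sum(on_ok) == 0) || (want_off > 0 && sum(off_ok) == 0))
      stop("no admissible white-matter pixels for the requested perforator placement")
    placed <- matrix(numeric(0), ncol = 2)
    draw_one <- function(pool) {
      idx <- which(pool)
      for (attempt in seq_len(5000L)) {
        i <- idx[sample.int(length(idx), 1L)]
        rc <- c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
        if (nrow(placed) == 0 ||
            min(sqrt((placed[, 1] - rc[1])^2 + (placed[, 2] - rc[2])^2)) >=
              spec$min_separation)
          return(rc)
      }
      stop("cannot place perforators at the requested minimum spacing")
    }
    kinds <- c(rep("on_ghost", want_on), rep("off_ghost", want_off))
    for (kind in kinds)
      placed <- rbind(placed, draw_one(if (kind == "on_ghost") on_ok else off_ok))
    list(clusters = clusters, struct2d = struct2d,
         ghost_truth = ghost_truth, placed = placed, kinds = kinds)
  }

  # unlucky vessel layouts can leave too little clear white matter for
  # the requested off-ghost placement; redraw the geometry (same seeded
  # stream, so still deterministic) a bounded number of times
  geom <- NULL
  for (attempt in seq_len(20L)) {
    geom <- tryCatch(gen_geometry(), error = function(e) e)
    if (!inherits(geom, "error")) break
  }
  if (inherits(geom, "error")) stop(geom)
  clusters <- geom$clusters
  struct2d <- geom$struct2d
  ghost_truth <- geom$ghost_truth
  placed <- geom$placed
  kinds <- geom$kinds

  # true waveforms
  vmeans <- if (spec$n_perforators > 0)
    runif(spec$n_perforators, min(spec$perforator_vmean_range),
          max(spec$perforator_vmean_range)) else numeric(0)
  curves <- matrix(0, spec$n_perforators, np)
  for (i in seq_len(spec$n_perforators))
    curves[i, ] <- make_waveform(vmeans[i], spec$perforator_pi, np,
                                 spec$peak_phase_index)

  # ---- render ----------------------------------------------------------
  prof <- spec$base_intensity / (1 + exp((dist_c - R) / 1.5))
  ang1 <- runif(1, 0, 2 * pi); ang2 <- runif(1, 0, 2 * pi)
  inhom <- 1 + spec$inhomogeneity_amplitude *
    outer(cos(2 * pi * 0.9 * seq_len(nr) / nr + ang1),
          cos(2 * pi * 1.3 * seq_len(nc) / nc + ang2))
  mag2d <- prof * inhom + struct2d

  magnitude <- array(rep(mag2d, np), dim = c(nr, nc, np))
  velocity <- array(0, dim = c(nr, nc, np))
  for (i in seq_len(spec$n_perforators))
    velocity[placed[i, 1], placed[i, 2], ] <-
      curves[i, ] * spec$perforator_pv_fraction

  # resolve an "auto" velocity-noise SD from the realized magnitude SNR
  # in the central analysis region, via the phase-contrast relation
  # sigma_v = sqrt(2) venc / (pi SNR): the velocity noise a scanner with
  # this magnitude SNR would produce
  if (is.na(spec$noise_sd_velocity)) {
    if (spec$noise_sd_magnitude == 0) {
      spec$noise_sd_velocity <- 0
    } else {
      central_ref <- wm == 1 & dist_c < (R - spec$plant_margin + 2)
      if (!any(central_ref)) central_ref <- wm == 1
      snr_eff <- mean(mag2d[central_ref]) / spec$noise_sd_magnitude
      spec$noise_sd_velocity <- sqrt(2) * spec$venc / (pi * snr_eff)
    }
  }

  # ---- noise stream ----------------------------------------------------
  set.seed(spec$seed)
  if (spec$noise_sd_magnitude > 0) {
    if (spec$rician) {
      re <- magnitude + array(rnorm(nr * nc * np, sd = spec$noise_sd_magnitude),
                              dim = dim(magnitude))
      im <- array(rnorm(nr * nc * np, sd = spec$noise_sd_magnitude),
                  dim = dim(magnitude))
      magnitude <- sqrt(re^2 + im^2)
    } else {
      magnitude <- magnitude +
        array(rnorm(nr * nc * np, sd = spec$noise_sd_magnitude),
              dim = dim(magnitude))
    }
  }
  if (spec$noise_sd_velocity > 0) {
    velocity <- velocity +
      array(rnorm(nr * nc * np, sd = spec$noise_sd_velocity),
            dim = dim(velocity))
    # spurious pulsation-like fluctuations inside the ghost bands,
    # total SD = ghost_velocity_factor x background SD
    if (any(ghost_truth == 1) && spec$ghost_velocity_factor > 1) {
      extra_sd <- spec$noise_sd_velocity *
        sqrt(spec$ghost_velocity_factor^2 - 1)
      band_idx <- which(ghost_truth == 1 & brain == 1)
      for (t in seq_len(np)) {
        plane <- velocity[, , t]
        plane[band_idx] <- plane[band_idx] +
          rnorm(length(band_idx), sd = extra_sd)
        velocity[, , t] <- plane
      }
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  series <- pc_series(magnitude, velocity, venc = spec$venc,
                      pe_axis = spec$pe_axis)
  perf <- data.frame(row = if (nrow(placed)) as.integer(placed[, 1]) else integer(0),
                     col = if (nrow(placed)) as.integer(placed[, 2]) else integer(0),
                     on_ghost = kinds == "on_ghost",
                     v_mean_true = vmeans)
  truth <- structure(list(perforators = perf, curves = curves,
                          ghost_truth = ghost_truth,
                          vessel_clusters = clusters,
                          wm_mask = wm, brain_mask = brain, spec = spec),
                     class = "phantom_truth")
  list(series = series, truth = truth)
}

#' Write a phantom and its ground truth to disk
#'
#' Writes the magnitude/velocity NIfTI pair, the truth masks (WM, brain,
#' ghost bands), the planted-perforator CSV and the spec as YAML.
#'
#' @param phantom result of [synthesize_phantom()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pc_series(phantom$series,
                  file.path(dir, "magnitude.nii.gz"),
                  file.path(dir, "velocity.nii.gz"))
  write_mask(phantom$truth$wm_mask, file.path(dir, "wm_mask.nii.gz"))
  write_mask(phantom$truth$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  write_mask(phantom$truth$ghost_truth, file.path(dir, "ghost_truth.nii.gz"))
  truth <- cbind(phantom$truth$perforators,
                 as.data.frame(phantom$truth$curves))
  names(truth)[-(1:4)] <- paste0("v", seq_len(ncol(phantom$truth$curves)))
  write.csv(truth, file.path(dir, "perforator_truth.csv"), row.names = FALSE)
  sp <- phantom$truth$spec
  yaml::write_yaml(unclass(sp), file.path(dir, "phantom_spec.yaml"))
  invisible(dir)
}
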