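#' Two-way single-measure intraclass correlation with 95% CI
#'
#' Single-measurement two-way mixed-effects ICC in its two standard
#' forms (McGraw & Wong conventions): consistency
#' `ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)` and absolute agreement
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with mean squares from the two-way ANOVA decomposition (subjects x
#' raters, fitted via [stats::aov()]). Confidence intervals use the
#' standard F-distribution formulas for each form (Satterthwaite degrees
#' of freedom for agreement). The qualitative band follows the
#' conventional thresholds: poor < 0.5, moderate 0.5-0.75, good
#' 0.75-0.90, excellent > 0.90.
#'
#' @param x numeric matrix or data.frame, one row per subject, one
#'   column per rating/measurement (k >= 2; k = 2 for paired scans or
#'   raters). No missing cells; n >= 3 subjects.
#' @param model `"two_way_consistency_single"` or
#'   `"two_way_agreement_single"`.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @return list of class `icc_result`: `icc`, `ci95` (low, high),
#'   `model`, `n_subjects`, `n_raters`, `qualitative`, and the ANOVA
#'   mean squares `ms` (MSR, MSC, MSE).
#' @export
icc_two_way <- function(x,
                        model = c("two_way_consistency_single",
                                  "two_way_agreement_single"),
                        alpha = 0.05) {
  model <- match.arg(model)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("missing or non-finite cells in ICC input")
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 ratings per subject")
  if (var(as.vector(x)) == 0)
    stop("degenerate input: zero total variance")
  df <- data.frame(value = as.vector(x),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  fit <- aov(value ~ subject + rater, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- c("MSR", "MSC", "MSE")
  MSR <- ms[["MSR"]]; MSC <- ms[["MSC"]]; MSE <- ms[["MSE"]]
  if (MSR + MSC + MSE <= 0) stop("degenerate input: zero total variance")
  if (model == "two_way_consistency_single") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) {
      ci <- c(1, 1)
    } else {
      Fobs <- MSR / MSE
      df2 <- (n - 1) * (k - 1)
      FL <- Fobs / qf(1 - alpha / 2, n - 1, df2)
      FU <- Fobs * qf(1 - alpha / 2, df2, n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    }
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0 && MSC == 0) {
      ci <- c(1, 1)
    } else {
      r <- icc
      a <- k * r / (n * (1 - r))
      b <- 1 + k * r * (n - 1) / (n * (1 - r))
      if (!is.finite(a) || !is.finite(b)) {
        ci <- c(1, 1)
      } else {
        v <- (a * MSC + b * MSE)^2 /
          ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
        FL <- qf(1 - alpha / 2, n - 1, v)
        FU <- qf(1 - alpha / 2, v, n - 1)
        lower <- n * (MSR - FL * MSE) /
          (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
        upper <- n * (FU * MSR - MSE) /
          (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
        ci <- c(lower, upper)
      }
    }
  }
  ci <- pmin(pmax(ci, -1), 1)
  structure(list(icc = unname(icc), ci95 = unname(ci), model = model,
                 n_subjects = n, n_raters = k,
                 qualitative = icc_qualitative(icc), ms = ms),
            class = "icc_result")
}

#' Qualitative ICC band
#'
#' poor < 0.5, moderate 0.5-0.75, good 0.75-0.90, excellent > 0.90.
#'
#' @param icc numeric ICC value.
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
icc_qualitative <- function(icc) {
  if (icc > 0.90) "excellent"
  else if (icc > 0.75) "good"
  else if (icc >= 0.5) "moderate"
  else "poor"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s) = %.3f [%.3f, %.3f], n = %d, k = %d (%s)\n",
              x$model, x$icc, x$ci95[1], x$ci95[2],
              x$n_subjects, x$n_raters, x$qualitative))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x2 - x1`; bias = mean(d); limits of agreement
#' `bias +/- 1.96 sd(d)` (sample SD, n - 1 denominator).
#'
#' @param x1,x2 paired numeric vectors (n >= 2).
#' @return list of class `bland_altman_result`: `bias`, `loa` (low,
#'   high), `sd_diff`, `n`.
#' @export
bland_altman <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  d <- x2 - x1
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
                 sd_diff = s, n = length(d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' Compare two censoring methods across a cohort
#'
#' For each outcome (N_included, V_mean, PI), computes both two-way
#' single-measure ICC forms and the Bland-Altman statistics between the
#' per-subject values of the two methods.
#'
#' @param metrics_a,metrics_b data.frames with one row per subject
#'   (same subjects, same order or a shared `subject` column) and
#'   columns `n_included`, `v_mean`, `pi`.
#' @param outcomes outcome columns to compare.
#' @return data.frame with one row per outcome: consistency and
#'   agreement ICCs with CIs, bias and limits of agreement.
#' @export
compare_methods <- function(metrics_a, metrics_b,
                            outcomes = c("n_included", "v_mean", "pi")) {
  stopifnot(is.data.frame(metrics_a), is.data.frame(metrics_b),
            nrow(metrics_a) == nrow(metrics_b))
  if ("subject" %in% names(metrics_a) && "subject" %in% names(metrics_b)) {
    if (!setequal(metrics_a$subject, metrics_b$subject))
      stop("subject sets differ between the two methods")
    metrics_b <- metrics_b[match(metrics_a$subject, metrics_b$subject), ,
                           drop = FALSE]
  }
  rows <- lapply(outcomes, function(oc) {
    a <- metrics_a[[oc]]; b <- metrics_b[[oc]]
    if (is.null(a) || is.null(b)) stop("outcome column missing: ", oc)
    cons <- icc_two_way(cbind(a, b), "two_way_consistency_single")
    agr <- icc_two_way(cbind(a, b), "two_way_agreement_single")
    ba <- bland_altman(a, b)
    data.frame(outcome = oc,
               icc_consistency = cons$icc,
               icc_consistency_low = cons$ci95[1],
               icc_consistency_high = cons$ci95[2],
               icc_agreement = agr$icc,
               icc_agreement_low = agr$ci95[1],
               icc_agreement_high = agr$ci95[2],
               ba_bias = ba$bias,
               ba_loa_low = ba$loa[1], ba_loa_high = ba$loa[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sensitivity sweep over censoring parameters
#'
#' Re-runs the detect -> censor -> metrics pipeline on fixed input for
#' every row of a parameter grid, recording the resulting outcomes.
#' Deterministic given the input.
#'
#' @param series a [pc_series()].
#' @param wm,brain 0/1 masks.
#' @param grid data.frame whose columns are [default_config()] keys
#'   (e.g. `vessel_top_fraction`, `big_extend`, `small_extend`,
#'   `big_dilate`, `small_dilate`), one row per setting.
#' @param config base configuration for the unswept parameters.
#' @return data.frame: the grid columns plus `n_detected`, `n_included`,
#'   `v_mean`, `pi`, `ghost_fraction`.
#' @export
parameter_sweep <- function(series, wm, brain, grid,
                            config = default_config()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  unknown <- setdiff(names(grid), names(config))
  if (length(unknown))
    stop("unknown config key(s) in grid: ", paste(unknown, collapse = ", "))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    for (key in names(grid)) cfg[[key]] <- grid[[key]][i]
    cfg <- validate_config(cfg)
    res <- run_pipeline(series, wm, brain, cfg)
    cbind(grid[i, , drop = FALSE],
          data.frame(n_detected = nrow(res$records),
                     n_included = res$metrics$n_included,
                     v_mean = res$metrics$v_mean,
                     pi = res$metrics$pi,
                     ghost_fraction = res$metrics$ghost_fraction))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
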