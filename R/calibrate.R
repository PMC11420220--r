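# Data-driven calibration of the gain/loss log2-ratio cutoffs.

#' Calibrate loss/gain cutoffs from pooled per-chromosome log2 ratios
#'
#' Pooled per-(cell, chromosome) mean log2 copy ratios from a batch of cells
#' typically show three density peaks: monosomy near log2(1/2) = -1,
#' disomy near 0, and trisomy near log2(3/2) = +0.585. A kernel-density
#' scan first checks that all three modes are present (each within
#' `mode_tol` of its expected location). If so, a three-component Gaussian
#' mixture is fitted to the pooled values and the cutoffs are placed at the
#' density minima of the fitted mixture between adjacent components,
#' located on a fine grid -- the best partition of the three peaks. When the
#' peaks are well separated the raw kernel density is essentially zero over
#' a wide valley and its argmin is numerically meaningless, which is why
#' the minima are taken on the fitted mixture. If the three modes are not
#' found (or the mixture fit degenerates) the calibration falls back to the
#' fixed defaults (-0.45, +0.35).
#'
#' @param values Numeric vector of pooled per-(cell, chromosome) mean log2
#'   ratios; at least 100 values required.
#' @param mode_tol Maximal distance of a detected mode from its expected
#'   location.
#' @param min_height Minimal density height of a mode, as a fraction of the
#'   tallest mode.
#' @param bw Bandwidth spec passed to [stats::density()]; `"SJ"` falls back
#'   to `"nrd0"` if it fails.
#' @return A one-row tibble: `loss_cutoff`, `gain_cutoff`,
#'   `calibration_mode` (`"calibrated"` or `"default_fallback"`).
#' @export
calibrate_cutoffs <- function(values, mode_tol = 0.25, min_height = 0.02,
                              bw = "SJ") {
  values <- values[is.finite(values)]
  abort_if(length(values) < 100,
           "cutoff calibration needs >= 100 pooled (cell, chromosome) values")
  d <- tryCatch(stats::density(values, bw = bw, n = 2048),
                error = function(e) stats::density(values, bw = "nrd0", n = 2048))
  y <- d$y
  x <- d$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  modes <- x[is_max & y > min_height * max(y)]
  pick <- function(center) {
    cand <- modes[abs(modes - center) <= mode_tol]
    if (length(cand) == 0) return(NA_real_)
    cand[which.min(abs(cand - center))]
  }
  m_loss <- pick(log2(1 / 2))
  m_neut <- pick(0)
  m_gain <- pick(log2(3 / 2))
  if (anyNA(c(m_loss, m_neut, m_gain))) {
    return(default_fallback())
  }
  # Mclust() resolves mclustBIC in the caller's frame; bind it locally so
  # the package works without attaching mclust.
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 3, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(default_fallback())
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]; w <- w[o]
  if (!(mu[1] < mu[2] && mu[2] < mu[3])) return(default_fallback())
  dens <- function(x) {
    w[1] * stats::dnorm(x, mu[1], sig[1]) +
      w[2] * stats::dnorm(x, mu[2], sig[2]) +
      w[3] * stats::dnorm(x, mu[3], sig[3])
  }
  valley <- function(a, b) {
    grid <- seq(a, b, length.out = 4001)
    grid[which.min(dens(grid))]
  }
  loss_cut <- valley(mu[1], mu[2])
  gain_cut <- valley(mu[2], mu[3])
  if (!(loss_cut < 0 && gain_cut > 0)) return(default_fallback())
  tibble::tibble(loss_cutoff = loss_cut, gain_cutoff = gain_cut,
                 calibration_mode = "calibrated")
}

default_fallback <- function() {
  tibble::tibble(loss_cutoff = -0.45, gain_cutoff = 0.35,
                 calibration_mode = "default_fallback")
}

#' Fixed default cutoffs
#'
#' The fixed log2 copy-ratio cutoffs (loss < -0.45, gain > +0.35) used when
#' no batch calibration is requested or calibration falls back.
#' @return A one-row tibble like [calibrate_cutoffs()].
#' @export
default_cutoffs <- function() {
  tibble::tibble(loss_cutoff = -0.45, gain_cutoff = 0.35,
                 calibration_mode = "default_fallback")
}

#' Pool per-(cell, chromosome) mean log2 ratios for calibration
#'
#' @param profiles Corrected profiles ([correct_profile()]).
#' @return Numeric vector, one value per (cell, chromosome) over usable bins.
#' @export
pool_chrom_log2 <- function(profiles) {
  profiles |>
    dplyr::filter(.data$usable, .data$cell_usable) |>
    dplyr::group_by(.data$cell_id, .data$chrom) |>
    dplyr::summarise(m = mean(.data$log2_ratio), .groups = "drop") |>
    dplyr::pull("m")
}
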