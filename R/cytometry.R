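# Gating and DNA-content histogram deconvolution.

#' Gating configuration
#'
#' @param fsc_min,ssc_min Scatter thresholds below which events are debris.
#' @param doublet_ratio_min Minimum peak/integrated fluorescence ratio; a
#'   doublet takes roughly twice as long to cross the laser, so its ratio
#'   falls well below a singlet's.
#' @param target_events Number of events retained after gating (uniform
#'   subsample when more survive; default 10000).
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(fsc_min = 150, ssc_min = 150,
                        doublet_ratio_min = 0.6, target_events = 10000) {
  stopifnot(fsc_min >= 0, ssc_min >= 0,
            doublet_ratio_min > 0, doublet_ratio_min < 1, target_events >= 1)
  structure(list(fsc_min = fsc_min, ssc_min = ssc_min,
                 doublet_ratio_min = doublet_ratio_min,
                 target_events = target_events), class = "gate_config")
}

#' DNA-content model configuration
#'
#' @param n_bins Histogram bins for the fit (>= 64; default 256).
#' @param g2_g1_ratio G2/G1 mean constraint (default 2.0; must stay in
#'   \[1.8, 2.2\]).
#' @param subG1_boundary_k Number of G1 standard deviations below the G1 mean
#'   defining the sub-G1 upper edge (default 3).
#' @param max_iter,tol Optimizer controls for the peak-location refinement.
#' @param round_proportions Emulated rounding mode: round each proportion to
#'   2 decimals independently before reporting, so the raw sum may drift from
#'   100 the way capped-precision software output does. Off by default.
#' @return A list of class `dna_model_config`.
#' @export
dna_model_config <- function(n_bins = 256, g2_g1_ratio = 2.0,
                             subG1_boundary_k = 3, max_iter = 200,
                             tol = 1e-8, round_proportions = FALSE) {
  stopifnot(n_bins >= 64, g2_g1_ratio >= 1.8, g2_g1_ratio <= 2.2,
            subG1_boundary_k > 0, max_iter >= 1, tol > 0)
  structure(list(n_bins = n_bins, g2_g1_ratio = g2_g1_ratio,
                 subG1_boundary_k = subG1_boundary_k, max_iter = max_iter,
                 tol = tol, round_proportions = round_proportions),
            class = "dna_model_config")
}

#' Phase-proportion container
#'
#' @param p_subG1,p_G1,p_S,p_G2 Phase proportions in percent (non-negative).
#' @param normalized Logical; when `TRUE` the four values sum to 100.
#' @param fit_quality Optional list with fit diagnostics.
#' @return An object of class `phase_profile`.
#' @export
phase_profile <- function(p_subG1, p_G1, p_S, p_G2, normalized = FALSE,
                          fit_quality = NULL) {
  p <- c(p_subG1, p_G1, p_S, p_G2)
  if (any(!is.finite(p)) || any(p < 0))
    stop("phase proportions must be finite and non-negative")
  if (normalized && abs(sum(p) - 100) > 1e-9)
    stop("normalized profile must sum to 100")
  structure(list(p_subG1 = p_subG1, p_G1 = p_G1, p_S = p_S, p_G2 = p_G2,
                 normalized = normalized, fit_quality = fit_quality),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat(sprintf("phase_profile (%s): sub-G1 %.2f | G1 %.2f | S %.2f | G2 %.2f  (sum %.2f)\n",
              if (x$normalized) "normalized" else "raw",
              x$p_subG1, x$p_G1, x$p_S, x$p_G2,
              x$p_subG1 + x$p_G1 + x$p_S + x$p_G2))
  invisible(x)
}

phase_values <- function(profile)
  c(subG1 = profile$p_subG1, G1 = profile$p_G1, S = profile$p_S, G2 = profile$p_G2)

#' Gate a raw event table
#'
#' Removes debris (low FSC or SSC) and doublets (low peak/integrated
#' fluorescence ratio), then uniformly subsamples without replacement to the
#' configured target count when more events survive.
#'
#' @param events Data.frame with columns `fsc`, `ssc`, `peak_fluor`,
#'   `integrated_fluor`.
#' @param cfg A [gate_config()].
#' @param seed Optional integer seed for the subsampling draw.
#' @return A list with `events` (the gated table) and `report` (counts
#'   removed per rule).
#' @export
gate_events <- function(events, cfg = gate_config(), seed = NULL) {
  required <- c("fsc", "ssc", "peak_fluor", "integrated_fluor")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols))
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(events) == 0) stop("empty event table")

  is_debris <- events$fsc < cfg$fsc_min | events$ssc < cfg$ssc_min
  ratio <- events$peak_fluor / pmax(events$integrated_fluor, .Machine$double.eps)
  is_doublet <- !is_debris & ratio < cfg$doublet_ratio_min
  kept <- events[!is_debris & !is_doublet, , drop = FALSE]

  report <- list(n_input = nrow(events),
                 n_debris_removed = sum(is_debris),
                 n_doublet_removed = sum(is_doublet),
                 n_after_gates = nrow(kept))
  if (nrow(kept) == 0)
    stop("all events gated out (debris: ", report$n_debris_removed,
         ", doublets: ", report$n_doublet_removed, ")")

  if (nrow(kept) > cfg$target_events) {
    if (!is.null(seed)) set.seed(seed)
    kept <- kept[sort(sample.int(nrow(kept), cfg$target_events)), , drop = FALSE]
  }
  report$n_retained <- nrow(kept)
  rownames(kept) <- NULL
  list(events = kept, report = report)
}

# Per-bin model component masses at given G1 mean/sd. Columns: subG1 (a
# truncated exponential decaying below the sub-G1 boundary), G1, S, G2.
dna_component_matrix <- function(centers, width, mu, sigma, ratio,
                                 boundary, sub_scale) {
  mu2 <- ratio * mu
  sigma2 <- sigma * ratio
  g1 <- stats::dnorm(centers, mu, sigma) * width
  g2 <- stats::dnorm(centers, mu2, sigma2) * width
  # S: uniform on [mu, mu2] convolved with the G1 Gaussian width
  s <- (stats::pnorm((centers - mu) / sigma) -
          stats::pnorm((centers - mu2) / sigma)) / (mu2 - mu) * width
  sub <- ifelse(centers < boundary,
                stats::dexp(boundary - centers, 1 / sub_scale) * width, 0)
  z <- sum(sub)
  if (z > 0) sub <- sub / z else sub[] <- 0
  cbind(subG1 = sub, G1 = g1, S = pmax(s, 0), G2 = g2)
}

#' Deconvolve a DNA-content histogram into cell-cycle phase proportions
#'
#' Bins the integrated fluorescence of gated events and decomposes the
#' histogram into a Gaussian G1 peak, a broadened-uniform S plateau, a
#' Gaussian G2 peak constrained at `g2_g1_ratio` times the G1 mean, and a
#' sub-G1 fraction counted below `G1_mean - k * sigma_G1`. Component
#' amplitudes are fitted by non-negativity-constrained least squares on the
#' binned counts, with the G1 location and width refined by Nelder-Mead.
#'
#' @param gated Data.frame of gated events (needs `integrated_fluor`;
#'   >= 500 rows).
#' @param cfg A [dna_model_config()].
#' @return A raw (unnormalized) [phase_profile()]; proportions are percent of
#'   gated events and may sum slightly away from 100.
#' @export
fit_dna_histogram <- function(gated, cfg = dna_model_config()) {
  x <- gated$integrated_fluor
  if (is.null(x)) stop("gated table lacks integrated_fluor")
  if (length(x) < 500) stop("need at least 500 gated events, got ", length(x))

  n <- length(x)
  breaks <- seq(0, max(x) * 1.02, length.out = cfg$n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  width <- diff(breaks)[1]

  # initial G1 peak: highest histogram bin (G1 dominates all study profiles)
  mu0 <- centers[which.max(counts)]
  sigma0 <- 0.04 * mu0

  fit_amplitudes <- function(mu, sigma, sub_scale) {
    boundary <- mu - cfg$subG1_boundary_k * sigma
    M <- dna_component_matrix(centers, width, mu, sigma, cfg$g2_g1_ratio,
                              boundary, sub_scale)
    a <- pracma::lsqnonneg(M, counts)$x
    resid <- counts - M %*% a
    list(a = a, sse = sum(resid^2), boundary = boundary,
         rmse = sqrt(mean(resid^2)))
  }

  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); sub_scale <- exp(par[3])
    # keep the G1 location near the detected mode so the fit cannot hop
    # to the sub-G1 shoulder or the G2 peak
    if (mu < 0.75 * mu0 || mu > 1.3 * mu0 ||
        sigma < 0.01 * mu || sigma > 0.15 * mu) return(1e18)
    fit_amplitudes(mu, sigma, sub_scale)$sse
  }
  opt <- stats::optim(c(mu0, log(sigma0), log(mu0 / 4)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = cfg$max_iter, reltol = cfg$tol))
  if (!is.finite(opt$value) || opt$value >= 1e18)
    stop("DNA-content model failed to converge; last residual ", opt$value)
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  fit <- fit_amplitudes(mu, sigma, exp(opt$par[3]))

  p_sub <- sum(x < fit$boundary) / n * 100
  p <- fit$a[-1] / n * 100
  if (cfg$round_proportions) {
    p_sub <- round(p_sub, 2); p <- round(p, 2)
  }
  phase_profile(p_subG1 = p_sub, p_G1 = p[1], p_S = p[2], p_G2 = p[3],
                normalized = FALSE,
                fit_quality = list(g1_mean = mu, g1_sd = sigma,
                                   rmse = fit$rmse,
                                   converged = opt$convergence == 0,
                                   sse = fit$sse))
}

#' Normalize phase proportions to sum to 100
#'
#' Each phase value is divided by the sum of all four proportions and
#' multiplied by 100, so any raw profile (whose sum drifts from 100 because
#' the four phases are modeled and rounded independently) is mapped onto a
#' true composition.
#'
#' @param profile A [phase_profile()].
#' @return The normalized [phase_profile()].
#' @export
normalize_proportions <- function(profile) {
  p <- phase_values(profile)
  s <- sum(p)
  if (s <= 0) stop("cannot normalize an all-zero profile")
  p <- p / s * 100
  phase_profile(p[["subG1"]], p[["G1"]], p[["S"]], p[["G2"]],
                normalized = TRUE, fit_quality = profile$fit_quality)
}
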