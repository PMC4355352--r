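# Synthetic PI-stained DNA-content event generator with known ground truth.

#' Ground-truth stage description for one follicle
#'
#' Bundles the true cell-cycle phase composition of a granulosa-cell sample
#' together with optional expression ground truth, for use by the
#' synthetic-data generators.
#'
#' @param stage One of `"growing"`, `"plateau"`, `"atretic"`.
#' @param p_subG1,p_G1,p_S,p_G2 Phase percentages; must be non-negative and
#'   sum to 100 (within 1e-9).
#' @param de_genes Optional named numeric vector of signed log2 effects.
#' @param marker_levels Optional named numeric vector of relative quantities.
#' @return An object of class `stage_truth`.
#' @export
stage_truth <- function(stage, p_subG1, p_G1, p_S, p_G2,
                        de_genes = NULL, marker_levels = NULL) {
  stage <- match.arg(stage, c("growing", "plateau", "atretic"))
  p_subG1 <- unname(p_subG1); p_G1 <- unname(p_G1)
  p_S <- unname(p_S); p_G2 <- unname(p_G2)
  p <- c(p_subG1 = p_subG1, p_G1 = p_G1, p_S = p_S, p_G2 = p_G2)
  validate_phase_percentages(p)
  if (!is.null(de_genes) && any(!is.finite(de_genes)))
    stop("de_genes effects must be finite")
  structure(list(stage = stage, p_subG1 = p_subG1, p_G1 = p_G1,
                 p_S = p_S, p_G2 = p_G2, de_genes = de_genes,
                 marker_levels = marker_levels),
            class = "stage_truth")
}

validate_phase_percentages <- function(p) {
  bad <- names(p)[!is.finite(p) | p < 0]
  if (length(bad))
    stop("invalid phase percentage(s): ", paste(bad, collapse = ", "),
         " (must be finite and non-negative)")
  if (abs(sum(p) - 100) > 1e-9)
    stop("phase percentages must sum to 100, got ", format(sum(p), digits = 12))
  invisible(TRUE)
}

#' Noise configuration for the event generator
#'
#' The DNA-content scale puts the G1 (2n) peak at channel 200 of a
#' 1024-channel axis and the G2 (4n) peak at exactly twice the G1 mean,
#' both Gaussian with a common coefficient of variation. S-phase cells are
#' uniform between the two peaks convolved with the G1 width; sub-G1 events
#' (apoptotic DNA loss) decay exponentially below the G1 peak region.
#'
#' @param g1_mean G1 peak mean, channels (default 200 on a 1024-channel axis).
#' @param g1_cv Coefficient of variation of the G1 and G2 peaks (default 0.04).
#' @param g2_ratio G2/G1 DNA-content ratio (default 2, PI linearity).
#' @param subg1_margin_k Sub-G1 events are generated strictly below
#'   `g1_mean - subg1_margin_k * g1_sd` (default 3).
#' @param subg1_scale Exponential decay scale of sub-G1 DNA content, channels.
#' @param peak_ratio_mean,peak_ratio_sd Peak/integrated fluorescence ratio of
#'   singlets (doublets fall well below via max-vs-sum geometry).
#' @param debris_frac,doublet_frac Fractions of events generated as debris /
#'   doublets (defaults 0).
#' @param fsc_mean,fsc_sd,ssc_mean,ssc_sd Scatter channels of intact cells.
#' @param debris_fsc_mean,debris_fsc_sd Scatter of debris (low FSC/SSC).
#' @return A list of class `event_noise_config`.
#' @export
event_noise_config <- function(g1_mean = 200, g1_cv = 0.04, g2_ratio = 2,
                               subg1_margin_k = 3, subg1_scale = 50,
                               peak_ratio_mean = 0.92, peak_ratio_sd = 0.03,
                               debris_frac = 0, doublet_frac = 0,
                               fsc_mean = 500, fsc_sd = 80,
                               ssc_mean = 400, ssc_sd = 70,
                               debris_fsc_mean = 60, debris_fsc_sd = 25) {
  stopifnot(g1_mean > 0, g1_cv > 0, g2_ratio >= 1.8, g2_ratio <= 2.2,
            debris_frac >= 0, debris_frac < 1,
            doublet_frac >= 0, doublet_frac < 1,
            peak_ratio_mean > 0, peak_ratio_mean < 1)
  structure(as.list(environment()), class = "event_noise_config")
}

# Truncated positive normal draw (values clipped away from zero).
rnorm_pos <- function(n, mean, sd, min = 1) pmax(stats::rnorm(n, mean, sd), min)

#' Simulate flow-cytometry events for one follicle sample
#'
#' Draws per-class event counts from a multinomial around the true phase
#' percentages, then generates the four cytometer channels (FSC, SSC, peak
#' and integrated fluorescence) per class. Doublets take the sum of two
#' singlet integrated fluorescences and the max of their peak values;
#' debris sits at low FSC/SSC.
#'
#' @param truth A [stage_truth()] object (or a list with the four `p_*`
#'   fields).
#' @param n_events Total number of events to generate (default 10000).
#' @param noise An [event_noise_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   (truth, n_events, noise, seed).
#' @return A data.frame with columns `fsc`, `ssc`, `peak_fluor`,
#'   `integrated_fluor` and the generator-only column `truth_class`
#'   (one of subG1/G1/S/G2/debris/doublet).
#' @export
simulate_follicle_events <- function(truth, n_events = 10000,
                                     noise = event_noise_config(),
                                     seed = 1L) {
  p <- c(subG1 = truth$p_subG1, G1 = truth$p_G1, S = truth$p_S, G2 = truth$p_G2)
  validate_phase_percentages(stats::setNames(p, c("p_subG1", "p_G1", "p_S", "p_G2")))
  stopifnot(n_events >= 100)
  set.seed(seed)

  n_debris  <- round(noise$debris_frac * n_events)
  n_doublet <- round(noise$doublet_frac * n_events)
  n_singlet <- n_events - n_debris - n_doublet
  counts <- as.vector(stats::rmultinom(1, n_singlet, p / sum(p)))
  names(counts) <- names(p)

  mu  <- noise$g1_mean
  sd1 <- noise$g1_cv * mu
  mu2 <- noise$g2_ratio * mu
  sd2 <- noise$g1_cv * mu2
  sub_upper <- mu - noise$subg1_margin_k * sd1

  gen_integrated <- function(class, n) {
    if (n == 0) return(numeric(0))
    switch(class,
      G1 = rnorm_pos(n, mu, sd1),
      G2 = rnorm_pos(n, mu2, sd2),
      S  = pmax(stats::runif(n, mu, mu2) + stats::rnorm(n, 0, sd1), 1),
      subG1 = {
        # left-truncated exponential decay below the G1 peak region:
        # density highest just under the boundary, emulating graded DNA loss
        rate <- 1 / noise$subg1_scale
        e <- stats::qexp(stats::runif(n) * stats::pexp(sub_upper - 2, rate), rate)
        sub_upper - e
      })
  }

  classes <- rep(names(counts), counts)
  integrated <- unlist(lapply(names(counts),
                              function(cl) gen_integrated(cl, counts[[cl]])),
                       use.names = FALSE)
  peak <- integrated * pmin(pmax(stats::rnorm(n_singlet, noise$peak_ratio_mean,
                                              noise$peak_ratio_sd), 0.75), 0.999)
  fsc <- rnorm_pos(n_singlet, noise$fsc_mean, noise$fsc_sd)
  ssc <- rnorm_pos(n_singlet, noise$ssc_mean, noise$ssc_sd)

  ev <- data.frame(fsc = fsc, ssc = ssc, peak_fluor = peak,
                   integrated_fluor = integrated, truth_class = classes,
                   stringsAsFactors = FALSE)

  if (n_doublet > 0) {
    if (nrow(ev) < 2) stop("cannot form doublets from fewer than 2 singlets")
    i <- sample.int(nrow(ev), n_doublet, replace = TRUE)
    j <- sample.int(nrow(ev), n_doublet, replace = TRUE)
    dbl <- data.frame(
      fsc = pmax(ev$fsc[i], ev$fsc[j]) * 1.2,
      ssc = pmax(ev$ssc[i], ev$ssc[j]) * 1.2,
      peak_fluor = pmax(ev$peak_fluor[i], ev$peak_fluor[j]),
      integrated_fluor = ev$integrated_fluor[i] + ev$integrated_fluor[j],
      truth_class = "doublet", stringsAsFactors = FALSE)
    ev <- rbind(ev, dbl)
  }
  if (n_debris > 0) {
    deb <- data.frame(
      fsc = rnorm_pos(n_debris, noise$debris_fsc_mean, noise$debris_fsc_sd, 0.5),
      ssc = rnorm_pos(n_debris, noise$debris_fsc_mean, noise$debris_fsc_sd, 0.5),
      peak_fluor = rnorm_pos(n_debris, 15, 8, 0.5),
      integrated_fluor = rnorm_pos(n_debris, 18, 9, 0.5),
      truth_class = "debris", stringsAsFactors = FALSE)
    deb$peak_fluor <- pmin(deb$peak_fluor, deb$integrated_fluor)
    ev <- rbind(ev, deb)
  }
  rownames(ev) <- NULL
  ev[sample.int(nrow(ev)), , drop = FALSE]
}

# Default true phase composition per stage. Sub-G1 levels 2/10/30 give the
# well-separated apoptotic gradient expected between growing, plateau and
# deeply atretic dominant follicles.
default_stage_profiles <- function() {
  list(growing = c(p_subG1 = 2,  p_G1 = 77, p_S = 12, p_G2 = 9),
       plateau = c(p_subG1 = 10, p_G1 = 78, p_S = 7,  p_G2 = 5),
       atretic = c(p_subG1 = 30, p_G1 = 60, p_S = 5,  p_G2 = 5))
}

#' Simulate a cohort of dominant follicles
#'
#' Generates follicle metadata (diameter, RIN) and PI-stained event tables
#' for a mixed-stage cohort with hidden true stages. Mimics a slaughterhouse
#' collection of dominant follicles (> 9 mm) where a few samples fail RNA
#' quality control.
#'
#' @param n_follicles Total number of follicles (default 27).
#' @param stage_mix Named integer vector of true-stage counts
#'   (`growing`/`plateau`/`atretic`); must sum to `n_follicles`.
#' @param diameter_range_mm Diameter sampling interval; lower bound must
#'   exceed 9 mm (dominance threshold).
#' @param rin_range RIN sampling interval for QC-passing samples.
#' @param n_low_rin Number of samples forced below the RIN threshold.
#' @param low_rin_range RIN interval used for the forced low-RIN samples.
#' @param n_events Events per follicle (default 10000).
#' @param noise [event_noise_config()] shared by all follicles.
#' @param profile_jitter_sd SD (percentage points) of the per-follicle
#'   perturbation of the stage's true phase percentages.
#' @param seed Integer seed.
#' @return A list with `samples` (data.frame: sample_id, true_stage,
#'   diameter_mm, rin, true phase percentages) and `events` (named list of
#'   event tables).
#' @export
simulate_cohort <- function(n_follicles = 27,
                            stage_mix = c(growing = 9, plateau = 9, atretic = 9),
                            diameter_range_mm = c(10, 22),
                            rin_range = c(7.0, 9.3),
                            n_low_rin = 0, low_rin_range = c(5.0, 6.9),
                            n_events = 10000,
                            noise = event_noise_config(),
                            profile_jitter_sd = 1,
                            seed = 1L) {
  if (diameter_range_mm[1] <= 9)
    stop("diameter_range_mm lower bound must exceed 9 mm (dominant follicles only)")
  if (sum(stage_mix) != n_follicles)
    stop("stage_mix counts must sum to n_follicles")
  stopifnot(n_low_rin <= n_follicles)
  set.seed(seed)

  if (n_follicles == 0) {
    return(list(samples = data.frame(sample_id = character(0),
                                     true_stage = character(0),
                                     diameter_mm = numeric(0), rin = numeric(0)),
                events = list()))
  }

  profiles <- default_stage_profiles()
  stages <- rep(names(stage_mix), stage_mix)
  ids <- sprintf("F%02d", seq_len(n_follicles))
  low_rin_idx <- if (n_low_rin > 0) sample.int(n_follicles, n_low_rin) else integer(0)

  truth_p <- t(vapply(seq_len(n_follicles), function(i) {
    p <- profiles[[stages[i]]]
    if (profile_jitter_sd > 0) {
      p <- pmax(p + stats::rnorm(4, 0, profile_jitter_sd), 0.1)
      p <- p / sum(p) * 100
    }
    p
  }, numeric(4)))
  colnames(truth_p) <- c("p_subG1", "p_G1", "p_S", "p_G2")

  samples <- data.frame(
    sample_id = ids, true_stage = stages,
    diameter_mm = stats::runif(n_follicles, diameter_range_mm[1], diameter_range_mm[2]),
    rin = stats::runif(n_follicles, rin_range[1], rin_range[2]),
    truth_p, stringsAsFactors = FALSE)
  if (length(low_rin_idx))
    samples$rin[low_rin_idx] <- stats::runif(n_low_rin, low_rin_range[1], low_rin_range[2])

  event_seeds <- sample.int(.Machine$integer.max %/% 2L, n_follicles)
  events <- lapply(seq_len(n_follicles), function(i) {
    tr <- stage_truth(stages[i], truth_p[i, 1], truth_p[i, 2],
                      truth_p[i, 3], truth_p[i, 4])
    simulate_follicle_events(tr, n_events = n_events, noise = noise,
                             seed = event_seeds[i])
  })
  names(events) <- ids
  list(samples = samples, events = events)
}
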