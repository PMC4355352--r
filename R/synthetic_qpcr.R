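# Synthetic qPCR panel: log-linear amplification model, dilution series,
# stable reference genes, optional theca-contaminated sample.

#' Default synthetic qPCR gene panel
#'
#' Two stage-independent reference genes (EIF2B2, SF3A1), stage-trending
#' targets and a theca marker (CYP17A1-like, low and flat in pure granulosa
#' samples). Quantities are in ng within the standard-curve range; slopes are
#' near the -3.32 Cq/decade of a 100%-efficient reaction.
#'
#' @return Data.frame: gene, slope, intercept, level_growing, level_plateau,
#'   level_atretic, is_reference.
#' @export
default_qpcr_genes <- function() {
  data.frame(
    gene = c("EIF2B2", "SF3A1", "VNN1", "ANGPT2", "CCNB1", "PTTG1", "STAR",
             "CYP17A1"),
    slope = c(-3.32, -3.40, -3.35, -3.30, -3.45, -3.38, -3.33, -3.36),
    intercept = c(17.5, 18.2, 18.0, 17.8, 18.5, 18.1, 17.6, 18.3),
    level_growing = c(2e-6, 1.5e-6, 5e-7, 4e-7, 4e-6, 3e-6, 8e-7, 1e-7),
    level_plateau = c(2e-6, 1.5e-6, 2e-6, 1.2e-6, 1.5e-6, 1.2e-6, 2.4e-6, 1e-7),
    level_atretic = c(2e-6, 1.5e-6, 8e-6, 4e-6, 5e-7, 4e-7, 1.2e-6, 1e-7),
    is_reference = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Simulate a qPCR panel with dilution series
#'
#' Per-well Cq values follow the log-linear amplification model
#' `Cq = intercept + slope * log10(quantity) + noise`. Each gene gets a
#' five-point, decade-spaced standard dilution series (1e-4 .. 1e-8 ng by
#' default). Sample quantities are the gene's stage level with log-normal
#' biological scatter; reference genes are stage-independent. Optionally one
#' sample carries an elevated theca-marker quantity, emulating contamination.
#'
#' @param stage_assignment Named character vector sample -> stage.
#' @param genes Gene panel as in [default_qpcr_genes()].
#' @param dilution_ng Standard-curve input quantities; must be strictly
#'   monotone (default `10^-(4:8)` ng).
#' @param cq_sd Cq measurement noise SD.
#' @param quantity_cv Biological coefficient of variation of quantities.
#' @param contaminated_sample Optional sample id whose `marker_gene` quantity
#'   is multiplied by `contamination_factor`.
#' @param marker_gene Theca marker gene (default "CYP17A1").
#' @param contamination_factor Fold elevation in the contaminated sample.
#' @param undetected Optional data.frame (gene, sample) of wells reported as
#'   undetected (Cq = NA).
#' @param seed Integer seed.
#' @return List: `panel` (gene, sample, stage, Cq), `standards` (gene,
#'   input_ng, Cq), `truth` (true quantities, panel definition).
#' @export
simulate_qpcr <- function(stage_assignment, genes = default_qpcr_genes(),
                          dilution_ng = 10^-(4:8), cq_sd = 0.15,
                          quantity_cv = 0.3,
                          contaminated_sample = NULL, marker_gene = "CYP17A1",
                          contamination_factor = 50,
                          undetected = NULL, seed = 1L) {
  d <- diff(dilution_ng)
  if (length(dilution_ng) < 2 || !(all(d > 0) || all(d < 0)))
    stop("dilution series must be strictly monotone")
  set.seed(seed)
  samples <- names(stage_assignment)

  standards <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(gene = genes$gene[i], input_ng = dilution_ng,
               Cq = genes$intercept[i] + genes$slope[i] * log10(dilution_ng) +
                 stats::rnorm(length(dilution_ng), 0, cq_sd),
               stringsAsFactors = FALSE)
  }))

  sdlog <- sqrt(log(1 + quantity_cv^2))
  qty <- matrix(NA_real_, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  for (i in seq_len(nrow(genes))) {
    lev <- vapply(seq_along(samples), function(j)
      genes[[paste0("level_", stage_assignment[[samples[j]]])]][i], numeric(1))
    qty[i, ] <- lev * stats::rlnorm(length(samples), -sdlog^2 / 2, sdlog)
  }
  if (!is.null(contaminated_sample)) {
    if (!contaminated_sample %in% samples)
      stop("contaminated_sample not in stage_assignment")
    qty[marker_gene, contaminated_sample] <-
      qty[marker_gene, contaminated_sample] * contamination_factor
  }

  panel <- expand.grid(gene = genes$gene, sample = samples,
                       stringsAsFactors = FALSE)
  panel$stage <- unname(stage_assignment[panel$sample])
  ix <- cbind(match(panel$gene, genes$gene), match(panel$sample, samples))
  q <- qty[ix]
  panel$Cq <- genes$intercept[ix[, 1]] + genes$slope[ix[, 1]] * log10(q) +
    stats::rnorm(nrow(panel), 0, cq_sd)
  if (!is.null(undetected) && nrow(undetected)) {
    drop <- paste(panel$gene, panel$sample) %in%
      paste(undetected$gene, undetected$sample)
    panel$Cq[drop] <- NA_real_
  }
  list(panel = panel, standards = standards,
       truth = list(quantity = qty, genes = genes,
                    contaminated_sample = contaminated_sample))
}
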