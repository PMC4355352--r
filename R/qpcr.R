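# Standard curves, geNORM normalization, contamination QC and the
# stage-comparison test battery.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq on log10(input quantity) over the dilution series;
#' amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (1.0 = 100% at the ideal -3.3219 Cq/decade).
#'
#' @param standards Data.frame with columns `input_ng` and `Cq` for one gene
#'   (>= 3 points, strictly monotone quantities).
#' @param gene Optional gene name carried into the result.
#' @return List of class `standard_curve`: gene, slope, intercept,
#'   efficiency, r2, n_points.
#' @export
fit_standard_curve <- function(standards, gene = standards$gene[1]) {
  stopifnot(all(c("input_ng", "Cq") %in% names(standards)))
  q <- standards$input_ng
  if (length(q) < 3) stop("need at least 3 dilution points")
  d <- diff(q)
  if (!(all(d > 0) || all(d < 0))) stop("dilution quantities must be monotone")
  fit <- stats::lm(Cq ~ log10(input_ng), data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("positive standard-curve slope (Cq must decrease with quantity)")
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((standards$Cq - mean(standards$Cq))^2)
  structure(list(gene = if (is.null(gene)) NA_character_ else gene,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r2 = r2,
                 n_points = length(q)),
            class = "standard_curve")
}

#' Quantify Cq values against standard curves
#'
#' `quantity = 10^((Cq - intercept) / slope)` per gene; undetected wells
#' (NA Cq) propagate as NA quantities, never as zeros.
#'
#' @param panel Data.frame with columns `gene`, `sample`, `Cq`.
#' @param curves Named list of [fit_standard_curve()] results, one per gene.
#' @return The panel with a `quantity` column (ng).
#' @export
quantify <- function(panel, curves) {
  missing_curves <- setdiff(unique(panel$gene), names(curves))
  if (length(missing_curves))
    stop("no standard curve for gene(s): ",
         paste(missing_curves, collapse = ", "))
  panel$quantity <- vapply(seq_len(nrow(panel)), function(i) {
    cv <- curves[[panel$gene[i]]]
    10^((panel$Cq[i] - cv$intercept) / cv$slope)
  }, numeric(1))
  panel
}

#' geNORM reference-gene normalization
#'
#' Divides each target quantity by the sample's normalization factor, the
#' geometric mean of the reference-gene quantities in that sample. The geNORM
#' stability measure M (mean SD of pairwise log2 ratios against the other
#' references, across samples) is reported for audit.
#'
#' @param panel Quantified panel (needs `gene`, `sample`, `quantity`).
#' @param reference_genes Reference gene names (default EIF2B2 and SF3A1).
#' @return List: `panel` with `normalized_quantity` column (references keep
#'   their own normalized values too), `factors` (per-sample normalization
#'   factor), `stability_M` (per reference gene).
#' @export
genorm_normalize <- function(panel, reference_genes = c("EIF2B2", "SF3A1")) {
  stopifnot(all(c("gene", "sample", "quantity") %in% names(panel)))
  samples <- unique(panel$sample)
  ref <- panel[panel$gene %in% reference_genes, ]
  refmat <- matrix(NA_real_, length(reference_genes), length(samples),
                   dimnames = list(reference_genes, samples))
  refmat[cbind(match(ref$gene, reference_genes), match(ref$sample, samples))] <-
    ref$quantity
  bad <- colnames(refmat)[colSums(!is.finite(refmat) | refmat <= 0) > 0]
  if (length(bad))
    stop("reference gene missing or unquantified in sample(s): ",
         paste(bad, collapse = ", "))
  factors <- exp(colMeans(log(refmat)))
  panel$normalized_quantity <- panel$quantity / factors[panel$sample]

  stability_M <- vapply(reference_genes, function(g) {
    others <- setdiff(reference_genes, g)
    mean(vapply(others, function(h)
      stats::sd(log2(refmat[g, ] / refmat[h, ])), numeric(1)))
  }, numeric(1))
  list(panel = panel, factors = factors, stability_M = stability_M)
}

#' Marker-based contamination QC
#'
#' Runs Bartlett's test of equal variance on a marker gene's expression
#' across groups. If variances differ (p < 0.05), each sample is assessed by
#' leave-one-out: a sample is flagged as contaminated when removing it makes
#' Bartlett's test non-significant and its marker value exceeds its group
#' median by the configured multiple.
#'
#' @param panel Quantified panel with `gene`, `sample`, `stage` and a value
#'   column.
#' @param marker_gene Marker expected flat across clean samples (e.g. a
#'   theca-specific transcript in granulosa preparations).
#' @param value_col Column used as the expression value (default
#'   `normalized_quantity` when present, else `quantity`).
#' @param fold_threshold Minimum multiple of the group median (default 5).
#' @return List: `bartlett_p`, `flagged` (data.frame of flagged samples with
#'   leave-one-out p and fold over group median), `values`.
#' @export
contamination_qc <- function(panel, marker_gene, value_col = NULL,
                             fold_threshold = 5) {
  if (is.null(value_col))
    value_col <- if ("normalized_quantity" %in% names(panel))
      "normalized_quantity" else "quantity"
  d <- panel[panel$gene == marker_gene, ]
  if (!nrow(d)) stop("marker gene not in panel: ", marker_gene)
  d <- d[is.finite(d[[value_col]]), ]
  counts <- table(d$stage)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2))
    stop("group(s) of size < 2: ", paste(names(counts)[counts < 2], collapse = ", "))

  safe_bartlett <- function(y, g) {
    if (all(tapply(y, g, stats::var) < .Machine$double.eps)) return(NA_real_)
    tryCatch(stats::bartlett.test(y, factor(g))$p.value,
             error = function(e) NA_real_)
  }
  p0 <- safe_bartlett(d[[value_col]], d$stage)
  flagged <- d[0, c("sample", "stage")]
  flagged$loo_p <- numeric(0); flagged$fold_over_median <- numeric(0)
  if (is.finite(p0) && p0 < 0.05) {
    for (i in seq_len(nrow(d))) {
      keep <- d[-i, ]
      if (any(table(keep$stage) < 2)) next
      loo_p <- safe_bartlett(keep[[value_col]], keep$stage)
      grp_med <- stats::median(d[[value_col]][d$stage == d$stage[i]])
      fold <- d[[value_col]][i] / grp_med
      if (is.finite(loo_p) && loo_p >= 0.05 && fold > fold_threshold) {
        flagged <- rbind(flagged,
                         data.frame(sample = d$sample[i], stage = d$stage[i],
                                    loo_p = loo_p, fold_over_median = fold))
      }
    }
  }
  list(bartlett_p = p0, flagged = flagged,
       values = d[, c("sample", "stage", value_col)])
}

# Variance-stabilizing transform used when Bartlett's test rejects equal
# variance: quantities (ng, << 1) are scaled by 1e12 before log10 so results
# stay positive.
log_variance_transform <- function(y) log10(y * 1e12)

# Student-Newman-Keuls step-down pairwise comparisons on group means.
# Returns the significance matrix (sorted order) and letter groupings.
snk_pairwise <- function(means, n, mse, df, alpha = 0.05) {
  ord <- order(means)
  m <- means[ord]; nn <- n[ord]; g <- length(m)
  sig <- matrix(NA, g, g)
  mark_nonsig <- function(i, j) {
    for (a in i:(j - 1)) for (b in (a + 1):j)
      if (is.na(sig[a, b])) sig[a, b] <<- FALSE
  }
  test_window <- function(i, j) {
    if (!is.na(sig[i, j])) return()
    span <- j - i + 1
    nh <- span / sum(1 / nn[i:j])          # harmonic-mean group size
    if (mse <= 0) {
      q <- if (m[j] - m[i] <= 0) 0 else Inf
    } else q <- (m[j] - m[i]) / sqrt(mse / nh)
    crit <- stats::qtukey(1 - alpha, span, df)
    if (q < crit) mark_nonsig(i, j)
    else {
      sig[i, j] <<- TRUE
      if (span > 2) { test_window(i, j - 1); test_window(i + 1, j) }
    }
  }
  test_window(1, g)
  sig[is.na(sig)] <- FALSE

  # letters: maximal contiguous runs of mutually non-significant groups
  runs <- list()
  for (i in seq_len(g)) {
    j <- i
    while (j < g && !sig[i, j + 1]) j <- j + 1
    runs[[i]] <- c(i, j)
  }
  keep <- vapply(seq_along(runs), function(k)
    !any(vapply(seq_along(runs), function(l)
      l != k && runs[[l]][1] <= runs[[k]][1] && runs[[l]][2] >= runs[[k]][2],
      logical(1))), logical(1))
  runs <- runs[keep]
  letters_sorted <- rep("", g)
  for (k in seq_along(runs))
    for (idx in runs[[k]][1]:runs[[k]][2])
      letters_sorted[idx] <- paste0(letters_sorted[idx], letters[k])
  out_letters <- character(g)
  out_letters[ord] <- letters_sorted
  names(out_letters) <- names(means)
  list(sig_sorted = sig, order = ord, letters = out_letters)
}

#' Stage-comparison statistics for a qPCR panel
#'
#' Per gene: Bartlett's test of equal variance across stages, with the
#' `Y = log10(y * 1e12)` transform applied (and Bartlett rerun) when the raw
#' test rejects at 0.05; one-tailed Welch t-tests per contrast (direction
#' supplied, e.g. from the microarray fold-change sign, or taken from the
#' observed means); one-way ANOVA with a Newman-Keuls post hoc producing
#' letter groupings; and a post-test for linear trend across the ordered
#' stages. Undetected wells are excluded pairwise and summarized as detection
#' counts; zero-variance genes are reported as untestable.
#'
#' @param panel Normalized panel with `gene`, `sample`, `stage` and a value
#'   column (default `normalized_quantity`).
#' @param stage_levels Ordered stages (default growing, plateau, atretic).
#' @param directions Optional named list gene -> named numeric vector of
#'   expected signs per contrast (`G_vs_P`, `P_vs_A`, `G_vs_A`; +1 = up in
#'   the second item).
#' @param alpha Newman-Keuls significance level (default 0.05).
#' @param value_col Value column name.
#' @return Data.frame, one row per gene: Bartlett p before/after transform,
#'   transform flag, one-tailed t p per contrast, ANOVA p, trend p,
#'   Newman-Keuls letters, detection counts, untestable flag.
#' @export
stage_stats <- function(panel, stage_levels = c("growing", "plateau", "atretic"),
                        directions = NULL, alpha = 0.05,
                        value_col = "normalized_quantity") {
  stopifnot(all(c("gene", "sample", "stage", value_col) %in% names(panel)))
  contrasts <- list(G_vs_P = stage_levels[1:2],
                    P_vs_A = stage_levels[2:3],
                    G_vs_A = stage_levels[c(1, 3)])
  if (length(unique(panel$stage)) < 2) stop("need at least 2 stages")

  one_gene <- function(d, gene) {
    y <- d[[value_col]]; st <- factor(d$stage, stage_levels)
    detected <- is.finite(y)
    det <- paste(vapply(stage_levels, function(s)
      sprintf("%s:%d/%d", s, sum(detected & st == s), sum(st == s)),
      character(1)), collapse = " ")
    y <- y[detected]; st <- droplevels(st[detected])
    row <- data.frame(gene = gene, detection = det,
                      untestable = FALSE, bartlett_p_raw = NA_real_,
                      transform_applied = FALSE, bartlett_p_used = NA_real_,
                      p_G_vs_P = NA_real_, p_P_vs_A = NA_real_,
                      p_G_vs_A = NA_real_, anova_p = NA_real_,
                      trend_p = NA_real_, letters = NA_character_,
                      stringsAsFactors = FALSE)
    if (nlevels(st) < 2 || any(table(st) < 2) || stats::var(y) < 1e-300) {
      row$untestable <- TRUE
      return(row)
    }
    vars <- tapply(y, st, stats::var)
    if (all(vars < .Machine$double.eps)) { row$untestable <- TRUE; return(row) }
    row$bartlett_p_raw <- stats::bartlett.test(y, st)$p.value
    if (is.finite(row$bartlett_p_raw) && row$bartlett_p_raw < 0.05 &&
        all(y > 0)) {
      y <- log_variance_transform(y)
      row$transform_applied <- TRUE
      row$bartlett_p_used <- stats::bartlett.test(y, st)$p.value
    } else row$bartlett_p_used <- row$bartlett_p_raw

    for (cn in names(contrasts)) {
      stg <- contrasts[[cn]]
      y1 <- y[st == stg[1]]; y2 <- y[st == stg[2]]
      if (length(y1) < 2 || length(y2) < 2) next
      dsign <- if (!is.null(directions[[gene]]) &&
                   !is.na(directions[[gene]][cn]))
        directions[[gene]][[cn]] else sign(mean(y2) - mean(y1))
      if (dsign == 0) dsign <- 1
      alt <- if (dsign > 0) "greater" else "less"
      row[[paste0("p_", cn)]] <- tryCatch(
        stats::t.test(y2, y1, alternative = alt)$p.value,
        error = function(e) NA_real_)
    }

    fit <- stats::aov(y ~ st)
    an <- stats::anova(fit)
    row$anova_p <- an[["Pr(>F)"]][1]
    mse <- an[["Mean Sq"]][2]; df_err <- an[["Df"]][2]
    means <- tapply(y, st, mean); ns <- table(st)
    snk <- snk_pairwise(means, as.numeric(ns), mse, df_err, alpha)
    row$letters <- paste(paste0(names(snk$letters), "=", snk$letters),
                         collapse = ";")
    if (nlevels(st) == length(stage_levels)) {
      cc <- seq_along(stage_levels) - mean(seq_along(stage_levels))
      Lval <- sum(cc * means)
      se <- sqrt(mse * sum(cc^2 / as.numeric(ns)))
      row$trend_p <- 2 * stats::pt(-abs(Lval / se), df_err)
    }
    row
  }

  genes <- unique(panel$gene)
  out <- do.call(rbind, lapply(genes, function(g)
    one_gene(panel[panel$gene == g, ], g)))
  rownames(out) <- NULL
  out
}
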