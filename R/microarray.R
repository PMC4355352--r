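# Two-color normalization, loop linear model, moderated statistics, DEG
# selection and the cross-contrast partition.

#' Background-correct a two-color array set
#'
#' Subtracts the background estimate from each channel's foreground with a
#' floor of 0.5 so subsequent logs stay finite.
#'
#' @param set A `loop_array_set`.
#' @param floor Minimum corrected intensity (default 0.5).
#' @return The set with corrected intensity matrices `E_R`, `E_G` added.
#' @export
background_correct <- function(set, floor = 0.5) {
  if (is.null(set$R) || is.null(set$G) || is.null(set$Rb) || is.null(set$Gb))
    stop("foreground/background matrices missing")
  if (any(set$R < 0) || any(set$G < 0))
    stop("negative raw intensities")
  set$E_R <- pmax(set$R - set$Rb, floor)
  set$E_G <- pmax(set$G - set$Gb, floor)
  set
}

#' Within-array loess normalization
#'
#' For each array, M = log2(R/G) is replaced by its residual from a loess fit
#' of M on A = (log2 R + log2 G)/2, removing intensity-dependent dye effects;
#' A is preserved.
#'
#' @param set A background-corrected `loop_array_set`.
#' @param span Loess span (default 0.3).
#' @return The set with normalized log-scale channels `logR`, `logG`.
#' @export
normalize_within_loess <- function(set, span = 0.3) {
  if (is.null(set$E_R)) stop("run background_correct first")
  n_probes <- nrow(set$E_R)
  if (n_probes < 50) stop("loess normalization needs at least 50 probes")
  logR <- log2(set$E_R); logG <- log2(set$E_G)
  for (a in seq_len(ncol(logR))) {
    A <- (logR[, a] + logG[, a]) / 2
    M <- logR[, a] - logG[, a]
    fit <- stats::loess(M ~ A, span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    Mn <- M - stats::fitted(fit)
    logR[, a] <- A + Mn / 2
    logG[, a] <- A - Mn / 2
  }
  set$logR <- logR; set$logG <- logG
  set
}

#' Between-array quantile normalization
#'
#' Forces every array channel's intensity distribution to the common
#' (column-mean) distribution: after normalization every column's sorted
#' vector is identical, with ties averaged and within-column ranks preserved.
#'
#' @param x A `loop_array_set` with log-scale channels, or a numeric matrix
#'   (rows = probes, columns = arrays/channels).
#' @return Object of the same type, quantile-normalized.
#' @export
normalize_between_quantile <- function(x) {
  if (inherits(x, "loop_array_set")) {
    if (is.null(x$logR)) stop("run normalize_within_loess first")
    n <- ncol(x$logR)
    q <- limma::normalizeQuantiles(cbind(x$logR, x$logG), ties = TRUE)
    x$logR <- q[, seq_len(n), drop = FALSE]
    x$logG <- q[, n + seq_len(n), drop = FALSE]
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 arrays")
  if (any(!is.finite(x))) stop("non-finite intensities")
  limma::normalizeQuantiles(x, ties = TRUE)
}

# --- empirical-Bayes variance moderation (moment matching on log s^2) ---

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Squeeze per-probe variances toward a common prior
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' matching the mean and variance of log sample variances to the scaled-F
#' model (the standard moment-matching empirical-Bayes approach), then
#' returns the posterior variances `(d0 s0^2 + df s^2) / (d0 + df)`.
#'
#' @param s2 Per-probe residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `d0`, `s0_2`, `s2_post`.
#' @export
squeeze_variances <- function(s2, df) {
  stopifnot(df > 0, all(is.finite(s2)))
  s2 <- pmax(s2, 0)
  # zero variances (e.g. probes pinned to one rank by quantile normalization)
  # are offset away from zero before fitting the scaled-F model
  m <- stats::median(s2)
  if (m == 0) m <- 1
  s2_fit <- pmax(s2, 1e-5 * m)
  z <- log(s2_fit)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
    s2_post <- rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

loop_design_matrix <- function(arrays) {
  ind <- function(side, st) as.numeric(arrays[[side]] == st)
  X <- cbind(plateau = ind("red_stage", "plateau") - ind("green_stage", "plateau"),
             atretic = ind("red_stage", "atretic") - ind("green_stage", "atretic"),
             dye = 1)
  if (qr(X)$rank < ncol(X)) {
    seen <- unique(c(arrays$red_stage, arrays$green_stage))
    stop("rank-deficient loop design; stages present: ",
         paste(seen, collapse = ", "))
  }
  X
}

#' Fit the loop linear model and moderated contrasts
#'
#' Per probe, M = log2(R/G) is regressed on stage coefficients (growing as
#' reference) plus a dye coefficient shared by all arrays (the dye-swap mates
#' identify it). Residual variances are moderated with
#' [squeeze_variances()] and the three loop contrasts (G vs P, P vs A,
#' G vs A; positive log2FC = up in the second item) are reported with
#' moderated t and two-sided p-values.
#'
#' @param set A normalized `loop_array_set` (log-scale channels present).
#' @return An object of class `loop_fit`: `contrasts` (list of data.frames
#'   probe/log2FC/A/t/p_value), `d0`, `s0_2`, `dye_coef`, `df_residual`.
#' @export
fit_loop_model <- function(set) {
  if (is.null(set$logR) || is.null(set$logG))
    stop("array set not normalized (no log-scale channels)")
  M <- set$logR - set$logG
  A <- rowMeans((set$logR + set$logG) / 2)
  X <- loop_design_matrix(set$arrays)
  n_arr <- nrow(X)
  df <- n_arr - ncol(X)
  if (df < 1) stop("not enough arrays for the loop model")

  fit <- stats::lm.fit(X, t(M))
  coefs <- fit$coefficients                  # 3 x probes
  s2 <- colSums(fit$residuals^2) / df
  sq <- squeeze_variances(s2, df)
  xtxinv <- chol2inv(chol(crossprod(X)))

  L <- cbind(G_vs_P = c(1, 0, 0), P_vs_A = c(-1, 1, 0), G_vs_A = c(0, 1, 0))
  df_total <- df + sq$d0
  contrasts <- lapply(colnames(L), function(cn) {
    l <- L[, cn]
    b <- drop(crossprod(l, coefs))
    u <- drop(t(l) %*% xtxinv %*% l)
    tval <- b / sqrt(sq$s2_post * u)
    p <- 2 * stats::pt(-abs(tval), df = df_total)
    data.frame(probe = set$probes, log2FC = unname(b), A = unname(A),
               t = unname(tval), p_value = unname(p),
               stringsAsFactors = FALSE)
  })
  names(contrasts) <- colnames(L)
  structure(list(contrasts = contrasts, d0 = sq$d0, s0_2 = sq$s0_2,
                 dye_coef = unname(coefs["dye", ]), df_residual = df),
            class = "loop_fit")
}

#' DEG selection criteria
#'
#' @param fc_min Symmetric raw fold-change threshold, strict (default 1.5:
#'   keep FC > 1.5 or < 1/1.5).
#' @param p_max P-value threshold, strict (default 0.05).
#' @param a_min Minimum average log2 intensity, inclusive (default 7).
#' @return A list of class `deg_criteria`.
#' @export
deg_criteria <- function(fc_min = 1.5, p_max = 0.05, a_min = 7) {
  stopifnot(fc_min > 1, p_max > 0, p_max < 1)
  structure(list(fc_min = fc_min, p_max = p_max, a_min = a_min),
            class = "deg_criteria")
}

#' Select differentially expressed probes
#'
#' Keeps probes with raw fold change strictly beyond the symmetric threshold
#' (|log2FC| > log2(fc_min)), p strictly below p_max, and average log2
#' intensity at least a_min; labels each as up or down (sign of log2FC, i.e.
#' relative to the second item of the contrast). An FDR column
#' (Benjamini-Hochberg over all tested probes) is carried along for users but
#' plays no role in selection.
#'
#' @param result One contrast's data.frame from [fit_loop_model()].
#' @param crit A [deg_criteria()].
#' @return The selected rows with added `direction` and `fdr` columns.
#' @export
select_degs <- function(result, crit = deg_criteria()) {
  stopifnot(all(c("probe", "log2FC", "A", "p_value") %in% names(result)))
  fdr <- stats::p.adjust(result$p_value, method = "BH")
  keep <- abs(result$log2FC) > log2(crit$fc_min) &
    result$p_value < crit$p_max & result$A >= crit$a_min
  out <- result[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  out$fdr <- fdr[keep]
  rownames(out) <- NULL
  out
}

#' Partition DEGs across the two stage transitions
#'
#' Classifies each gene significant in G vs P or P vs A as continuous (both
#' transitions, same direction), reversal (both transitions, opposite
#' direction) or specific to a single transition; also reports pairwise
#' intersections with the G vs A list when supplied.
#'
#' @param deg_gp,deg_pa DEG tables (from [select_degs()]) for the G vs P and
#'   P vs A transitions; need `probe` and `direction` columns.
#' @param deg_ga Optional DEG table for G vs A.
#' @return List with `table` (probe, category, directions) and `counts`
#'   (per-contrast totals, specific/continuous/reversal counts, pairwise
#'   intersections).
#' @export
partition_contrasts <- function(deg_gp, deg_pa, deg_ga = NULL) {
  check_tab <- function(tab, nm) {
    if (anyDuplicated(tab$probe))
      stop("duplicate gene ids in ", nm)
    stopifnot(all(c("probe", "direction") %in% names(tab)))
  }
  check_tab(deg_gp, "G_vs_P"); check_tab(deg_pa, "P_vs_A")
  dir_gp <- stats::setNames(deg_gp$direction, deg_gp$probe)
  dir_pa <- stats::setNames(deg_pa$direction, deg_pa$probe)
  genes <- union(deg_gp$probe, deg_pa$probe)
  in_gp <- genes %in% deg_gp$probe
  in_pa <- genes %in% deg_pa$probe
  category <- ifelse(in_gp & in_pa,
                     ifelse(dir_gp[genes] == dir_pa[genes],
                            "continuous", "reversal"),
                     ifelse(in_gp, "specific_G_vs_P", "specific_P_vs_A"))
  tab <- data.frame(probe = genes, category = unname(category),
                    dir_G_vs_P = unname(dir_gp[genes]),
                    dir_P_vs_A = unname(dir_pa[genes]),
                    stringsAsFactors = FALSE)
  counts <- list(
    total_G_vs_P = nrow(deg_gp), total_P_vs_A = nrow(deg_pa),
    shared = sum(in_gp & in_pa),
    continuous = sum(category == "continuous"),
    reversal = sum(category == "reversal"),
    specific_G_vs_P = sum(category == "specific_G_vs_P"),
    specific_P_vs_A = sum(category == "specific_P_vs_A"))
  # identity: specific + shared = total, per contrast
  stopifnot(counts$specific_G_vs_P + counts$shared == counts$total_G_vs_P,
            counts$specific_P_vs_A + counts$shared == counts$total_P_vs_A)
  if (!is.null(deg_ga)) {
    check_tab(deg_ga, "G_vs_A")
    counts$total_G_vs_A <- nrow(deg_ga)
    counts$shared_GP_GA <- length(intersect(deg_gp$probe, deg_ga$probe))
    counts$shared_PA_GA <- length(intersect(deg_pa$probe, deg_ga$probe))
  }
  list(table = tab, counts = counts)
}
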