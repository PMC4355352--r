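# QC exclusion, x-score ranking and rank-based stage assignment.

#' Staging configuration
#'
#' @param k Group size (default 7): the k highest-x samples become growing,
#'   the k lowest atretic, and k samples centered on the remaining ranks
#'   become plateau.
#' @param rin_min Minimum RNA integrity number; samples below it are excluded
#'   before ranking (default 7.0).
#' @return A list of class `staging_config`.
#' @export
staging_config <- function(k = 7, rin_min = 7.0) {
  stopifnot(k >= 1, rin_min > 0)
  structure(list(k = k, rin_min = rin_min), class = "staging_config")
}

#' Compute the follicle health score x
#'
#' `x = p_G2 + p_S + p_G1 - p_subG1`: the proportion of intact-or-cycling
#' cells minus the apoptotic sub-G1 fraction. On a normalized profile this
#' equals `100 - 2 * p_subG1`, so ranking by decreasing x is ranking by
#' increasing apoptosis.
#'
#' @param profile A normalized [phase_profile()].
#' @param allow_raw Permit scoring of unnormalized profiles (sensitivity
#'   analysis only); default `FALSE`.
#' @return The x score (percent scale).
#' @export
compute_x <- function(profile, allow_raw = FALSE) {
  if (!isTRUE(profile$normalized) && !allow_raw)
    stop("compute_x requires a normalized profile (see normalize_proportions)")
  profile$p_G2 + profile$p_S + profile$p_G1 - profile$p_subG1
}

#' Assign growth stages by x-score rank
#'
#' Samples failing RNA QC are excluded first; the remainder is ranked by x
#' in decreasing order (ties broken by sample_id, ascending). The top k ranks
#' are labeled growing, the bottom k atretic, and the k contiguous ranks
#' centered on the remaining middle block plateau; leftover samples at the
#' group boundaries are excluded from further analysis.
#'
#' @param samples Data.frame with columns `sample_id`, `rin`, `x_score`.
#' @param cfg A [staging_config()].
#' @return The input data.frame with added columns `stage` (growing /
#'   plateau / atretic / excluded_boundary / excluded_qc) and `x_rank`
#'   (rank among QC-passing samples, NA otherwise), ordered as input.
#' @export
assign_stages <- function(samples, cfg = staging_config()) {
  required <- c("sample_id", "rin", "x_score")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("samples lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id values")
  k <- cfg$k

  samples$stage <- "unassigned"
  samples$x_rank <- NA_integer_
  qc_fail <- samples$rin < cfg$rin_min
  samples$stage[qc_fail] <- "excluded_qc"

  idx <- which(!qc_fail)
  n <- length(idx)
  if (n < 3 * k)
    stop("need at least ", 3 * k, " QC-passing samples, have ", n,
         " (deficit ", 3 * k - n, ")")

  ord <- idx[order(-samples$x_score[idx], samples$sample_id[idx])]
  samples$x_rank[ord] <- seq_len(n)

  stage_of_rank <- rep("excluded_boundary", n)
  stage_of_rank[seq_len(k)] <- "growing"
  stage_of_rank[seq(n - k + 1, n)] <- "atretic"
  m <- n - 2 * k                       # middle block size
  excess <- m - k                      # boundary samples to drop
  # plateau = k ranks centered on the middle block; when the excess is odd
  # the extra exclusion falls on the growing side
  start <- k + 1 + ceiling(excess / 2)
  stage_of_rank[seq(start, start + k - 1)] <- "plateau"

  samples$stage[ord] <- stage_of_rank
  samples
}
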