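# Synthetic two-color loop-design arrays with dye swap and known effects.

loop_contrasts <- function() {
  list(G_vs_P = c("growing", "plateau"),
       P_vs_A = c("plateau", "atretic"),
       G_vs_A = c("growing", "atretic"))
}

expand_effect <- function(spec, probes) {
  eff <- stats::setNames(numeric(length(probes)), probes)
  if (!is.null(spec) && length(spec)) {
    unknown <- setdiff(names(spec), probes)
    if (length(unknown)) stop("de_config names not among probes: ",
                              paste(utils::head(unknown, 3), collapse = ", "))
    eff[names(spec)] <- spec
  }
  eff
}

#' Simulate a loop-design two-color array set
#'
#' Builds the three-contrast loop (G vs P, P vs A, G vs A). For each contrast
#' and biological replicate, one slide hybridizes the second stage in red
#' against the first in green, and a dye-swap mate inverts the assignment.
#' Log2 expression is a per-probe base level (~ Normal(9, 1.5)) plus the
#' stage effect, per-sample biological noise and per-measurement technical
#' noise; a gene-independent dye bias is added to the red channel and an
#' additive background to both.
#'
#' @param stage_assignment Named character vector mapping sample id to stage;
#'   all three stages must be present with equal replicate counts.
#' @param n_probes Number of probes (default 2000).
#' @param de_config Per-contrast true signed log2 effects: a list with
#'   elements among `G_vs_P`, `P_vs_A`, `G_vs_A`, each a named numeric vector
#'   (probe -> effect, positive = up in the second stage of the contrast).
#'   Effects are propagated around the loop (growing is the reference).
#' @param dye_bias Gene-independent log2 offset added to the red channel.
#' @param noise List: `bio_sd` (per-sample biological SD, log2), `tech_sd`
#'   (per-measurement SD, log2), `bg_mean`, `bg_sd` (additive background).
#' @param seed Integer seed.
#' @return An object of class `loop_array_set`: foreground/background
#'   matrices `R`, `G`, `Rb`, `Gb` (probes x arrays), the `arrays` design
#'   data.frame (with dye-swap mate links), `probes`, and `truth` (true
#'   per-contrast effects and per-sample stages).
#' @export
simulate_loop_arrays <- function(stage_assignment, n_probes = 2000,
                                 de_config = list(), dye_bias = 0,
                                 noise = list(bio_sd = 0.01, tech_sd = 0.1,
                                              bg_mean = 30, bg_sd = 5),
                                 seed = 1L) {
  if (n_probes < 1) stop("n_probes must be >= 1")
  stages <- c("growing", "plateau", "atretic")
  if (!all(stages %in% stage_assignment))
    stop("stage_assignment must cover all three stages")
  by_stage <- split(names(stage_assignment), factor(stage_assignment, stages))
  n_rep <- unique(lengths(by_stage))
  if (length(n_rep) != 1)
    stop("equal replicate counts per stage required for the loop design")
  set.seed(seed)

  probes <- sprintf("P%05d", seq_len(n_probes))
  eff <- list(growing = stats::setNames(numeric(n_probes), probes))
  eff$plateau <- eff$growing + expand_effect(de_config$G_vs_P, probes)
  eff$atretic <- if (!is.null(de_config$P_vs_A) || is.null(de_config$G_vs_A))
    eff$plateau + expand_effect(de_config$P_vs_A, probes)
  else
    eff$growing + expand_effect(de_config$G_vs_A, probes)

  base <- stats::rnorm(n_probes, 9, 1.5)
  samples <- names(stage_assignment)
  bio <- matrix(stats::rnorm(n_probes * length(samples), 0, noise$bio_sd),
                n_probes, dimnames = list(probes, samples))
  sample_expr <- function(s) base + eff[[stage_assignment[[s]]]] + bio[, s]

  # array design: per contrast, replicate i of each stage paired; main slide
  # red = second stage, green = first; swap mate inverts dyes
  rows <- list()
  for (cn in names(loop_contrasts())) {
    st <- loop_contrasts()[[cn]]
    for (i in seq_len(n_rep)) {
      first <- by_stage[[st[1]]][i]; second <- by_stage[[st[2]]][i]
      id <- sprintf("%s_r%d", cn, i)
      rows[[length(rows) + 1]] <- data.frame(
        array_id = id, contrast = cn, red_sample = second,
        green_sample = first, is_swap = FALSE,
        swap_mate = paste0(id, "_swap"), stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        array_id = paste0(id, "_swap"), contrast = cn, red_sample = first,
        green_sample = second, is_swap = TRUE,
        swap_mate = id, stringsAsFactors = FALSE)
    }
  }
  arrays <- do.call(rbind, rows)
  arrays$red_stage <- unname(stage_assignment[arrays$red_sample])
  arrays$green_stage <- unname(stage_assignment[arrays$green_sample])
  n_arr <- nrow(arrays)

  channel <- function(sample_ids, bias) {
    sig <- vapply(sample_ids, sample_expr, numeric(n_probes)) + bias +
      matrix(stats::rnorm(n_probes * n_arr, 0, noise$tech_sd), n_probes)
    bg <- matrix(pmax(stats::rnorm(n_probes * n_arr, noise$bg_mean, noise$bg_sd), 0),
                 n_probes)
    list(fg = 2^sig + bg, bg = bg)
  }
  red <- channel(arrays$red_sample, dye_bias)
  green <- channel(arrays$green_sample, 0)
  dn <- list(probes, arrays$array_id)
  dimnames(red$fg) <- dimnames(red$bg) <- dn
  dimnames(green$fg) <- dimnames(green$bg) <- dn

  truth_effects <- list(G_vs_P = eff$plateau - eff$growing,
                        P_vs_A = eff$atretic - eff$plateau,
                        G_vs_A = eff$atretic - eff$growing)
  structure(list(R = red$fg, G = green$fg, Rb = red$bg, Gb = green$bg,
                 probes = probes, arrays = arrays,
                 truth = list(effects = truth_effects, base = base,
                              stage_of = stage_assignment,
                              dye_bias = dye_bias)),
            class = "loop_array_set")
}

#' @export
print.loop_array_set <- function(x, ...) {
  cat(sprintf("loop_array_set: %d probes x %d arrays (%d dye-swap pairs)\n",
              length(x$probes), nrow(x$arrays), sum(!x$arrays$is_swap)))
  invisible(x)
}

#' Extract single-channel data sets from a (normalized) array set
#'
#' Each two-color array carries two data sets, one per channel; this pulls
#' one channel's log2 intensities per array, labeled by the hybridized
#' sample's stage. With four biological replicates per stage and dye-swap
#' mates this yields eight data sets per growth stage in the green channel.
#'
#' @param set A `loop_array_set` after normalization (log-scale channels
#'   present).
#' @param channel `"green"`, `"red"` or `"both"`.
#' @return A matrix probes x data sets with a `stages` attribute (stage label
#'   per column).
#' @export
extract_channel_data <- function(set, channel = c("green", "red", "both")) {
  channel <- match.arg(channel)
  if (is.null(set$logR) || is.null(set$logG))
    stop("array set has no log-scale channels; normalize it first")
  pick <- function(mat, side) {
    colnames(mat) <- paste0(set$arrays$array_id, "_", side)
    attr(mat, "stages") <- set$arrays[[paste0(side, "_stage")]]
    attr(mat, "samples") <- set$arrays[[paste0(side, "_sample")]]
    mat
  }
  if (channel == "green") return(pick(set$logG, "green"))
  if (channel == "red") return(pick(set$logR, "red"))
  g <- pick(set$logG, "green"); r <- pick(set$logR, "red")
  out <- cbind(g, r)
  attr(out, "stages") <- c(attr(g, "stages"), attr(r, "stages"))
  attr(out, "samples") <- c(attr(g, "samples"), attr(r, "samples"))
  out
}
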