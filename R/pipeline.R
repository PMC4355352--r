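# Configuration, delimited-text adapters and the end-to-end pipeline.

#' Pipeline configuration
#'
#' @param seed Master seed; every random draw in the pipeline flows from it.
#' @param n_follicles,stage_mix,n_low_rin Cohort settings (see
#'   [simulate_cohort()]).
#' @param n_events Events per follicle.
#' @param k,rin_min Staging settings (see [staging_config()]).
#' @param n_probes,n_de_per_transition,de_effect Array settings: number of
#'   probes, number of truly regulated probes per transition (half up, half
#'   down) and their |log2| effect.
#' @param dye_bias Log2 red-channel offset injected by the generator.
#' @param fc_min,p_max,a_min DEG criteria (see [deg_criteria()]).
#' @param contaminate Inject one theca-contaminated atretic sample into the
#'   qPCR panel.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_follicles = 27,
                            stage_mix = c(growing = 9, plateau = 9, atretic = 9),
                            n_low_rin = 2, n_events = 10000,
                            k = 7, rin_min = 7.0,
                            n_probes = 2000, n_de_per_transition = 100,
                            de_effect = 1.0, dye_bias = 0.3,
                            fc_min = 1.5, p_max = 0.05, a_min = 7,
                            contaminate = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly through the file.
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` returns the configuration.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$stage_mix)) vals$stage_mix <- unlist(vals$stage_mix)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  vals$stage_mix <- as.list(vals$stage_mix)
  yaml::write_yaml(vals, path)
  invisible(path)
}

# --- delimited-text adapters -------------------------------------------------

read_tsv_checked <- function(path, required, what) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  extra <- setdiff(names(tab), required)
  if (length(missing_cols))
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "),
         if (length(extra)) paste0(" (extra: ", paste(extra, collapse = ", "), ")"))
  if (length(extra))
    warning(what, " has extra column(s), preserved: ",
            paste(extra, collapse = ", "))
  tab
}

#' Delimited-text readers and writers
#'
#' Tab-delimited UTF-8 text with a header row is the canonical on-disk
#' format. Readers validate the schema strictly: missing columns are an
#' error; extra columns produce a warning and are preserved.
#'
#' @param path File path.
#' @param x Data.frame to write.
#' @return Readers return a data.frame; `write_tsv` returns the path,
#'   invisibly.
#' @export
read_event_table <- function(path)
  read_tsv_checked(path, c("fsc", "ssc", "peak_fluor", "integrated_fluor"),
                   "event table")

#' @rdname read_event_table
#' @export
read_cq_table <- function(path)
  read_tsv_checked(path, c("gene", "sample", "Cq"), "Cq table")

#' @rdname read_event_table
#' @export
read_dilution_table <- function(path)
  read_tsv_checked(path, c("gene", "input_ng", "Cq"), "dilution table")

#' @rdname read_event_table
#' @export
read_array_table <- function(path)
  read_tsv_checked(path, c("array_id", "contrast", "dye", "probe_id", "fg", "bg"),
                   "array table")

#' @rdname read_event_table
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Long-format export of a loop_array_set (array_id, contrast, dye, probe_id,
# fg, bg), the interchange layout for two-color intensities.
#' Export a loop array set as a long-format table
#'
#' @param set A `loop_array_set`.
#' @return Data.frame with one row per probe x array x dye.
#' @export
array_set_to_long <- function(set) {
  n_p <- length(set$probes); n_a <- nrow(set$arrays)
  one_dye <- function(dye, fg, bg) data.frame(
    array_id = rep(set$arrays$array_id, each = n_p),
    contrast = rep(set$arrays$contrast, each = n_p),
    dye = dye, probe_id = rep(set$probes, n_a),
    fg = as.vector(fg), bg = as.vector(bg), stringsAsFactors = FALSE)
  rbind(one_dye("red", set$R, set$Rb), one_dye("green", set$G, set$Gb))
}

# --- end-to-end pipeline -----------------------------------------------------

# Picks the hybridization subset: per stage, the n samples whose x scores
# best characterize the stage (extremes for growing/atretic, central for
# plateau).
select_hybridization_samples <- function(staged, n = 4) {
  pick <- function(stage, scorer) {
    d <- staged[staged$stage == stage, ]
    d$sample_id[order(scorer(d$x_score))][seq_len(min(n, nrow(d)))]
  }
  c(pick("growing", function(x) -x),
    pick("plateau", function(x) abs(x - stats::median(x))),
    pick("atretic", identity))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate a follicle cohort; gate events, deconvolve DNA-content
#' histograms, normalize proportions and compute x scores; assign stages;
#' simulate and analyze the loop-design arrays (background correction, loess
#' and quantile normalization, moderated loop model, DEG selection and
#' cross-contrast partition); run the between-group ordination; score a
#' truth-derived signed regulon; and run the qPCR branch (standard curves,
#' quantification, geNORM, contamination QC, stage statistics). A manifest
#' records the seed and per-stage record counts; identical configurations
#' give identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, result tables and the JSON
#'   manifest are written there.
#' @return List with the intermediate objects and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  cohort <- simulate_cohort(n_follicles = config$n_follicles,
                            stage_mix = config$stage_mix,
                            n_low_rin = config$n_low_rin,
                            n_events = config$n_events, seed = seed)

  gcfg <- gate_config(target_events = config$n_events)
  dcfg <- dna_model_config()
  samples <- cohort$samples
  samples$x_score <- NA_real_
  for (i in seq_len(nrow(samples))) {
    g <- gate_events(cohort$events[[samples$sample_id[i]]], gcfg,
                     seed = seed + i)
    prof <- normalize_proportions(fit_dna_histogram(g$events, dcfg))
    samples$x_score[i] <- compute_x(prof)
  }
  staged <- assign_stages(samples, staging_config(config$k, config$rin_min))
  staged_counts <- table(factor(staged$stage,
                                c("growing", "plateau", "atretic",
                                  "excluded_boundary", "excluded_qc")))

  hyb <- select_hybridization_samples(staged, 4)
  stage_assignment <- stats::setNames(
    staged$stage[match(hyb, staged$sample_id)], hyb)

  n_de <- config$n_de_per_transition
  de_probes <- sprintf("P%05d", seq_len(2 * n_de))
  eff <- rep(c(config$de_effect, -config$de_effect), each = n_de / 2)
  de_config <- list(
    G_vs_P = stats::setNames(eff, de_probes[seq_len(n_de)]),
    P_vs_A = stats::setNames(eff, de_probes[n_de + seq_len(n_de)]))
  arrays <- simulate_loop_arrays(stage_assignment, n_probes = config$n_probes,
                                 de_config = de_config,
                                 dye_bias = config$dye_bias,
                                 seed = seed + 1000L)
  norm <- normalize_between_quantile(
    normalize_within_loess(background_correct(arrays)))
  fit <- fit_loop_model(norm)
  crit <- deg_criteria(config$fc_min, config$p_max, config$a_min)
  degs <- lapply(fit$contrasts, select_degs, crit = crit)
  partition <- partition_contrasts(degs$G_vs_P, degs$P_vs_A, degs$G_vs_A)

  green <- extract_channel_data(norm, "green")
  bga <- between_group_analysis(green, attr(green, "stages"))
  sep <- separation_score(bga)

  # truth-derived atresia regulon: probes truly regulated in P vs A
  true_pa <- arrays$truth$effects$P_vs_A
  reg <- regulon("atresia_program",
                 sign(true_pa[true_pa != 0]))
  enr <- activation_zscore(degs$P_vs_A, reg)
  fisher_p <- fisher_enrichment(degs$P_vs_A$probe, names(true_pa[true_pa != 0]),
                                arrays$probes)

  staged_ids <- staged$sample_id[staged$stage %in%
                                   c("growing", "plateau", "atretic")]
  qpcr_assignment <- stats::setNames(
    staged$stage[match(staged_ids, staged$sample_id)], staged_ids)
  contaminated <- if (isTRUE(config$contaminate))
    staged_ids[qpcr_assignment == "atretic"][2] else NULL
  sim_q <- simulate_qpcr(qpcr_assignment,
                         contaminated_sample = contaminated,
                         seed = seed + 2000L)
  curves <- lapply(split(sim_q$standards, sim_q$standards$gene),
                   fit_standard_curve)
  qpanel <- quantify(sim_q$panel, curves)
  normed <- genorm_normalize(qpanel)
  qc <- contamination_qc(normed$panel, "CYP17A1")
  clean <- normed$panel[!normed$panel$sample %in% qc$flagged$sample, ]
  stats_tab <- stage_stats(clean[!clean$gene %in%
                                   c("EIF2B2", "SF3A1", "CYP17A1"), ])

  manifest <- list(
    seed = seed, n_follicles = config$n_follicles,
    staged = as.list(staged_counts),
    n_arrays = nrow(arrays$arrays),
    datasets_per_stage = as.list(table(attr(green, "stages"))),
    deg_counts = lapply(degs, nrow),
    partition_counts = partition$counts,
    separation_score = sep,
    regulon_call = enr$call,
    qpcr_flagged = qc$flagged$sample,
    qpcr_genes_tested = nrow(stats_tab))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(staged, file.path(out_dir, "staged_cohort.tsv"))
    for (cn in names(fit$contrasts))
      write_tsv(fit$contrasts[[cn]], file.path(out_dir, paste0("contrast_", cn, ".tsv")))
    write_tsv(partition$table, file.path(out_dir, "deg_partition.tsv"))
    write_tsv(data.frame(dataset = rownames(bga$sample_scores),
                         stage = bga$labels, bga$sample_scores),
              file.path(out_dir, "bga_scores.tsv"))
    write_tsv(stats_tab, file.path(out_dir, "qpcr_stats.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort = cohort, staged = staged, arrays = arrays, fit = fit,
       degs = degs, partition = partition, bga = bga,
       separation = sep, enrichment = enr, fisher_p = fisher_p,
       qpcr = list(curves = curves, panel = normed$panel,
                   factors = normed$factors, qc = qc, stats = stats_tab),
       manifest = manifest)
}
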