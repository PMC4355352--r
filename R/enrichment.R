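# Gene-set over-representation and signed-regulon activation scoring.

#' Fisher over-representation p-value
#'
#' One-sided hypergeometric tail probability that at least the observed
#' number of DEGs falls in the gene set, given the universe.
#'
#' @param deg_set Character vector of significant genes.
#' @param gene_set Character vector, the annotated set.
#' @param universe Character vector of all testable genes; both sets must be
#'   contained in it.
#' @return The over-representation p-value.
#' @export
fisher_enrichment <- function(deg_set, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  deg_set <- unique(deg_set); gene_set <- unique(gene_set)
  if (!all(deg_set %in% universe) || !all(gene_set %in% universe))
    stop("deg_set and gene_set must be subsets of the universe")
  k <- length(intersect(deg_set, gene_set))
  m <- length(gene_set)
  n <- length(universe) - m
  stats::phyper(k - 1, m, n, length(deg_set), lower.tail = FALSE)
}

#' Define a signed regulon
#'
#' @param regulator_id Regulator name.
#' @param members Named numeric vector gene -> expected direction (+1 or -1).
#' @param z_threshold Activation call threshold (default 2).
#' @return A list of class `regulon`.
#' @export
regulon <- function(regulator_id, members, z_threshold = 2) {
  if (!length(members)) stop("regulon members must be non-empty")
  if (!all(members %in% c(-1, 1)))
    stop("member directions must be +1 or -1")
  if (is.null(names(members))) stop("members must be named by gene")
  structure(list(regulator_id = regulator_id, members = members,
                 z_threshold = z_threshold), class = "regulon")
}

#' Activation z-score of a signed regulon
#'
#' `z = (n_consistent - n_inconsistent) / sqrt(n_overlap)`, where a DEG is
#' consistent when the sign of its log2 fold change matches the regulon's
#' expected direction. |z| at or beyond the threshold (default 2) calls the
#' regulator activated (positive) or inhibited (negative).
#'
#' @param degs Data.frame with columns `probe` (or `gene`) and `log2FC`,
#'   restricted to significant genes.
#' @param reg A [regulon()].
#' @return List of class `enrichment_result`: `z`, `call`, `n_overlap`,
#'   `n_consistent`, `zero_overlap` flag.
#' @export
activation_zscore <- function(degs, reg) {
  gene_col <- if ("gene" %in% names(degs)) "gene" else "probe"
  fc <- stats::setNames(degs$log2FC, degs[[gene_col]])
  common <- intersect(names(reg$members), names(fc))
  if (!length(common)) {
    return(structure(list(regulator_id = reg$regulator_id, z = 0,
                          call = "not_significant", n_overlap = 0L,
                          n_consistent = 0L, zero_overlap = TRUE),
                     class = "enrichment_result"))
  }
  consistent <- sign(fc[common]) == reg$members[common]
  nc <- sum(consistent); ni <- length(common) - nc
  z <- (nc - ni) / sqrt(length(common))
  call <- if (z >= reg$z_threshold) "activated"
  else if (z <= -reg$z_threshold) "inhibited"
  else "not_significant"
  structure(list(regulator_id = reg$regulator_id, z = z, call = call,
                 n_overlap = length(common), n_consistent = nc,
                 zero_overlap = FALSE),
            class = "enrichment_result")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Read signed regulons from a TSV file
#'
#' Expects columns `regulator`, `gene`, `direction` (+1/-1).
#'
#' @param path Path to the TSV.
#' @param z_threshold Threshold forwarded to [regulon()].
#' @return Named list of [regulon()] objects.
#' @export
read_regulons <- function(path, z_threshold = 2) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("regulator", "gene", "direction")
  if (!all(required %in% names(tab)))
    stop("regulon TSV needs columns: ", paste(required, collapse = ", "))
  lapply(split(tab, tab$regulator), function(d)
    regulon(d$regulator[1], stats::setNames(d$direction, d$gene), z_threshold))
}
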