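#' Quantify guide depletion as log2 fold change per line
#'
#' Each sample is scaled to reads per million after adding a pseudocount of
#' 0.5, log2-transformed and median-centered (so the unchanged majority of
#' guides defines zero). The per-line LFC is the mean over endpoint
#' replicates minus the mean over T0 replicates. Doubling every sample's
#' sequencing depth leaves the result unchanged.
#'
#' @param counts A [screen_counts()] object.
#' @return Guide x line numeric matrix of class `LfcMatrix`, with the number
#'   of endpoint replicates per line in `attr(, "n_endpoint")`.
#' @export
compute_lfc <- function(counts) {
  stopifnot(inherits(counts, "ScreenCounts"))
  des <- counts$design
  lines <- unique(des$line)
  for (ln in lines) {
    if (!any(des$line == ln & des$timepoint == "T0")) {
      stop("line '", ln, "' has no T0 sample")
    }
    if (!any(des$line == ln & des$timepoint == "TF")) {
      stop("line '", ln, "' has no endpoint sample")
    }
  }
  x <- counts$counts + 0.5
  rpm <- sweep(x, 2, colSums(x), "/") * 1e6
  lg <- log2(rpm)
  lg <- sweep(lg, 2, apply(lg, 2, median), "-")

  lfc <- matrix(NA_real_, nrow(lg), length(lines),
                dimnames = list(rownames(lg), lines))
  n_end <- setNames(integer(length(lines)), lines)
  for (ln in lines) {
    t0 <- des$sample[des$line == ln & des$timepoint == "T0"]
    tf <- des$sample[des$line == ln & des$timepoint == "TF"]
    lfc[, ln] <- rowMeans(lg[, tf, drop = FALSE]) - rowMeans(lg[, t0, drop = FALSE])
    n_end[ln] <- length(tf)
  }
  attr(lfc, "n_endpoint") <- n_end
  class(lfc) <- c("LfcMatrix", class(lfc))
  lfc
}

#' Center log fold changes on negative-control guides
#'
#' Pooled screens are compositional: when a sizeable fraction of guides
#' depletes, read-share normalization shifts every unchanged guide upward,
#' so the all-guide median is a biased zero. Re-centering each line on
#' guides targeting nonessential reference genes puts true no-effect guides
#' at zero, which keeps gene effects and the cutting-toxicity curve on a
#' consistent baseline in the downstream fit.
#'
#' @param lfc Guide x line LFC matrix (see [compute_lfc()]).
#' @param control_guides Guide ids targeting nonessential reference genes;
#'   at least 10 must be present in `lfc`.
#' @return The re-centered LFC matrix.
#' @export
center_lfc <- function(lfc, control_guides) {
  use <- intersect(control_guides, rownames(lfc))
  if (length(use) < 10) {
    stop("need >= 10 control guides present in the LFC matrix (got ",
         length(use), ")")
  }
  ctr <- apply(unclass(lfc)[use, , drop = FALSE], 2, median, na.rm = TRUE)
  out <- sweep(lfc, 2, ctr, "-")
  attr(out, "n_endpoint") <- attr(lfc, "n_endpoint")
  class(out) <- class(lfc)
  out
}

#' Naive (uncorrected) per-gene depletion
#'
#' Mean guide LFC per gene and line, with no guide-activity or copy-number
#' correction. This is the quantity a copy-number-amplified neutral gene
#' inflates and the CERES-style fit is meant to rescue.
#'
#' @param lfc Guide x line LFC matrix.
#' @param gene_of Named character vector mapping guide ids to gene symbols.
#' @return Gene x line numeric matrix.
#' @export
naive_gene_lfc <- function(lfc, gene_of) {
  g <- gene_of[rownames(lfc)]
  keep <- !is.na(g)
  rowsum(unclass(lfc)[keep, , drop = FALSE], g[keep]) /
    as.vector(table(g[keep])[sort(unique(g[keep]))])
}
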