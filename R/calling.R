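#' Dependency threshold from common-essential scores
#'
#' The threshold D is the mean plus two standard deviations of the dependency
#' scores of common-essential genes in a reference cell line. Genes scoring
#' at or below D are dependencies. The standard deviation is the sample
#' (n - 1) standard deviation; with constant scores D equals that constant.
#'
#' @param scores Named numeric vector of per-gene scores for one line.
#' @param essential_genes Character vector of common-essential gene symbols;
#'   at least two must have scores.
#' @param source_line Label of the line the scores come from.
#' @return A list of class `DependencyThreshold` with `D`, `n`, `mean`,
#'   `sigma`, `source_line`; `D == mean + 2 * sigma` exactly.
#' @export
compute_threshold <- function(scores, essential_genes, source_line = "reference") {
  use <- intersect(essential_genes, names(scores))
  vals <- scores[use]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) {
    stop("need at least 2 common-essential genes with scores (got ",
         length(vals), ")")
  }
  m <- mean(vals)
  s <- sd(vals)
  structure(list(D = m + 2 * s, n = length(vals), mean = m, sigma = s,
                 source_line = source_line),
            class = "DependencyThreshold")
}

#' @export
print.DependencyThreshold <- function(x, ...) {
  cat(sprintf("DependencyThreshold: D = %.5f (mean %.5f + 2 x sd %.5f over %d genes, line %s)\n",
              x$D, x$mean, x$sigma, x$n, x$source_line))
  invisible(x)
}

#' Integrate dependency scores across guide libraries with expression filter
#'
#' Emulates the cross-library consolidation of a reference line's scores:
#' only genes present in all contributing libraries ("concordant") are kept,
#' genes not expressed in the reference line (TPM below `tpm_min`) are
#' excluded, and survivors get the median score across libraries. Every
#' exclusion carries a reason code.
#'
#' @param score_sets List (length >= 2) of named numeric vectors, one per
#'   library, scores of the reference line.
#' @param expression Named numeric vector of reference-line TPM values.
#' @param tpm_min Minimum TPM to count as expressed.
#' @return Data frame of class `IntegratedScores` with columns `gene`,
#'   `median_score`, `libraries_present`, `expressed`, `excluded`, `reason`.
#' @export
integrate_libraries <- function(score_sets, expression, tpm_min = 1.0) {
  stopifnot(is.list(score_sets), length(score_sets) >= 2)
  universe <- sort(unique(unlist(lapply(score_sets, names))))
  present <- vapply(universe, function(g) {
    sum(vapply(score_sets, function(s) g %in% names(s) && !is.na(s[g]), TRUE))
  }, integer(1))
  tpm <- expression[universe]
  expressed <- !is.na(tpm) & tpm >= tpm_min

  reason <- rep(NA_character_, length(universe))
  reason[present < length(score_sets)] <- "not_in_all_libraries"
  reason[present == length(score_sets) & !expressed] <- "not_expressed"
  excluded <- !is.na(reason)

  med <- rep(NA_real_, length(universe))
  keep <- which(!excluded)
  if (length(keep) == 0) stop("no gene survives integration")
  med[keep] <- vapply(universe[keep], function(g) {
    median(vapply(score_sets, function(s) s[[g]], numeric(1)))
  }, numeric(1))

  for (r in c("not_in_all_libraries", "not_expressed")) {
    n <- sum(reason == r, na.rm = TRUE)
    if (n > 0) sd_log(n, " gene(s) excluded: ", r)
  }

  out <- data.frame(
    gene = universe,
    median_score = med,
    libraries_present = present,
    expressed = expressed,
    excluded = excluded,
    reason = reason,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("IntegratedScores", "data.frame")
  out
}

#' Call histotype-stratified dependencies under the 90 percent rule
#'
#' For each histotype (AD, SCLC, SCC) and each candidate gene, the fraction
#' of that histotype's lines with a score at or below the threshold D is
#' computed on exact fractions; the gene is called when the fraction reaches
#' `min_fraction`. Missing scores count as not below the threshold
#' (conservative). Lines labelled outside the three histotypes are ignored.
#'
#' @param effects A `GeneEffectMatrix` or gene x line numeric matrix.
#' @param histotypes Named character vector, line -> histotype label.
#' @param D A `DependencyThreshold` or a bare numeric threshold.
#' @param min_fraction Minimum fraction of lines at or below D (default 0.9).
#' @param candidate_genes Genes eligible for calling; defaults to all genes
#'   in `effects`. Must be a subset of the matrix's genes.
#' @return A list of class `HistotypeCallSet`: `calls` (named list of called
#'   gene sets), `fraction` (gene x histotype matrix), `n_lines`, `D`,
#'   `min_fraction`.
#' @export
call_histotype_dependencies <- function(effects, histotypes, D,
                                        min_fraction = 0.9,
                                        candidate_genes = NULL) {
  x <- if (inherits(effects, "GeneEffectMatrix")) effects$effects else as.matrix(effects)
  thr <- if (inherits(D, "DependencyThreshold")) D$D else as.numeric(D)
  if (is.null(candidate_genes)) candidate_genes <- rownames(x)
  if (!all(candidate_genes %in% rownames(x))) {
    stop("candidate_genes must be a subset of the score matrix's genes")
  }
  missing_lab <- setdiff(colnames(x), names(histotypes))
  if (length(missing_lab) > 0) {
    stop("unlabelled line(s): ", paste(utils::head(missing_lab, 5), collapse = ", "))
  }
  histos <- c("AD", "SCLC", "SCC")
  lab <- histotypes[colnames(x)]
  n_lines <- vapply(histos, function(h) sum(lab == h), integer(1))
  if (any(n_lines == 0)) {
    stop("histotype(s) with zero lines: ",
         paste(histos[n_lines == 0], collapse = ", "))
  }
  xs <- x[candidate_genes, , drop = FALSE]
  below <- !is.na(xs) & xs <= thr
  fraction <- vapply(histos, function(h) {
    rowMeans(below[, lab == h, drop = FALSE])
  }, numeric(length(candidate_genes)))
  if (length(candidate_genes) == 1L) {
    fraction <- matrix(fraction, nrow = 1,
                       dimnames = list(candidate_genes, histos))
  }
  calls <- lapply(setNames(histos, histos), function(h) {
    candidate_genes[fraction[, h] >= min_fraction]
  })
  structure(list(calls = calls, fraction = fraction, n_lines = n_lines,
                 D = thr, min_fraction = min_fraction),
            class = "HistotypeCallSet")
}

#' @export
print.HistotypeCallSet <- function(x, ...) {
  cat("HistotypeCallSet (D =", format(x$D, digits = 4),
      ", min fraction", x$min_fraction, "):\n")
  for (h in names(x$calls)) {
    cat("  ", h, ":", length(x$calls[[h]]), "genes over", x$n_lines[[h]], "lines\n")
  }
  invisible(x)
}

#' Partition three histotype call sets into the seven Venn regions
#'
#' @param calls A `HistotypeCallSet` (or named list with AD, SCLC, SCC gene
#'   sets).
#' @return A list of class `VennPartition`: `regions` (seven disjoint gene
#'   sets: `AD_only`, `SCLC_only`, `SCC_only`, `AD_SCLC`, `AD_SCC`,
#'   `SCLC_SCC`, `core`) and `sizes`.
#' @export
venn_partition <- function(calls) {
  sets <- if (inherits(calls, "HistotypeCallSet")) calls$calls else calls
  stopifnot(setequal(names(sets), c("AD", "SCLC", "SCC")))
  ad <- sets$AD; sc <- sets$SCLC; sq <- sets$SCC
  regions <- list(
    AD_only = setdiff(ad, union(sc, sq)),
    SCLC_only = setdiff(sc, union(ad, sq)),
    SCC_only = setdiff(sq, union(ad, sc)),
    AD_SCLC = setdiff(intersect(ad, sc), sq),
    AD_SCC = setdiff(intersect(ad, sq), sc),
    SCLC_SCC = setdiff(intersect(sc, sq), ad),
    core = intersect(intersect(ad, sc), sq)
  )
  regions <- lapply(regions, sort)
  structure(list(regions = regions, sizes = lengths(regions)),
            class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition:", paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
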