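#' Configuration for the copy-number-corrected dependency fit
#'
#' @param lambda Ridge penalty on gene effects. The default 0.681 is the
#'   value recommended for GeCKO-library screens.
#' @param max_iter Maximum alternating iterations.
#' @param rel_tol Relative objective-change convergence tolerance.
#' @param knots Cut-number knots of the piecewise-linear cutting-toxicity
#'   curve; strictly increasing and containing 2 (the diploid anchor where
#'   toxicity is defined to be zero).
#' @param fit_activity If `FALSE`, guide activities stay fixed at 1.
#' @param fit_toxicity If `FALSE`, the toxicity curve stays fixed at 0 (pure
#'   ridge regression of gene effects).
#' @param fit_intercept If `TRUE`, a free per-line intercept is fitted along
#'   with the other terms. Off by default: with per-gene-per-line free
#'   effects the intercept is only weakly identified, and the compositional
#'   offset of pooled screens is better removed by negative-control
#'   centering ([center_lfc()]) before fitting.
#' @return A list of class `ceres_config`.
#' @export
ceres_config <- function(lambda = 0.681, max_iter = 100L, rel_tol = 1e-6,
                         knots = c(0, 2, 4, 8, 16, 32),
                         fit_activity = TRUE, fit_toxicity = TRUE,
                         fit_intercept = FALSE) {
  stopifnot(lambda > 0, max_iter >= 1, rel_tol > 0)
  if (is.unsorted(knots, strictly = TRUE) || !(2 %in% knots)) {
    stop("knots must be strictly increasing and contain 2")
  }
  structure(list(lambda = lambda, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, knots = knots,
                 fit_activity = fit_activity, fit_toxicity = fit_toxicity,
                 fit_intercept = fit_intercept),
            class = "ceres_config")
}

# Linear interpolation basis: rows = observations (kappa values), columns =
# knots; kappa outside the knot range is clamped to the end knots.
interp_basis <- function(kappa, knots) {
  K <- length(knots)
  kappa <- pmin(pmax(kappa, knots[1]), knots[K])
  seg <- findInterval(kappa, knots, rightmost.closed = TRUE)
  w <- (kappa - knots[seg]) / (knots[pmin(seg + 1L, K)] - knots[seg])
  w[seg == K] <- 0
  Matrix::sparseMatrix(
    i = c(seq_along(kappa), seq_along(kappa)),
    j = c(seg, pmin(seg + 1L, K)),
    x = c(1 - w, w),
    dims = c(length(kappa), K)
  )
}

# Signed cumulative map from non-negative segment increments to knot values
# anchored at the knot equal to 2: monotone non-increasing by construction.
increment_map <- function(knots) {
  K <- length(knots)
  i0 <- which(knots == 2)
  M <- matrix(0, K, K - 1L)
  for (j in seq_len(K)) {
    if (j < i0) M[j, j:(i0 - 1L)] <- 1
    if (j > i0) M[j, i0:(j - 1L)] <- -1
  }
  M
}

#' Fit the joint gene-effect / guide-activity / cutting-toxicity model
#'
#' Separates true gene essentiality from copy-number-driven cutting toxicity
#' by minimizing
#' \deqn{\sum_{g,c} \big(y_{gc} - a_g\,(\textstyle\sum_{t \in T(g)} d_{tc} +
#'   q_c(\kappa_{gc}))\big)^2 + \lambda \sum_{t,c} d_{tc}^2}
#' over gene effects \eqn{d}, guide activities \eqn{a \in [0,1]} and per-line
#' monotone non-increasing piecewise-linear toxicity curves \eqn{q_c}
#' anchored at \eqn{q_c(2) = 0}, where \eqn{y} is the guide-level LFC and
#' \eqn{\kappa_{gc}} the cut number (copy number summed over the guide's
#' target loci). Alternating updates: gene effects by per-line closed-form
#' ridge regression, activities by clipped 1-D least squares, toxicity by
#' non-negative coordinate descent on the curve increments. Each block update
#' is an exact or descent step, so the objective never increases.
#'
#' Missing LFC entries are dropped from the objective, not imputed.
#'
#' @param lfc Guide x line LFC matrix (see [compute_lfc()]).
#' @param guide_map A [map_guides()] result (or data frame with `guide_id`,
#'   `gene_symbol`).
#' @param copy_number Gene x line numeric matrix covering every target gene
#'   and every line in `lfc`.
#' @param config A [ceres_config()].
#' @return A list of class `CeresFit`: `gene_effect` (GeneEffectMatrix),
#'   `guide_activity`, `toxicity` (knot x line matrix), `knots`, `objective`
#'   (per-iteration trace), `converged`, `n_iter`, `unfit_guides`.
#' @export
fit_ceres <- function(lfc, guide_map, copy_number, config = ceres_config()) {
  stopifnot(inherits(config, "ceres_config"))
  lfc <- unclass(lfc)
  targets <- guide_targets(guide_map)
  fitted_guides <- intersect(rownames(lfc), names(targets))
  unfit <- setdiff(rownames(lfc), fitted_guides)
  if (length(unfit) > 0) {
    sd_log(length(unfit), " guide(s) without mapping dropped from fit")
  }
  if (length(fitted_guides) == 0) stop("no mapped guides to fit")
  y <- lfc[fitted_guides, , drop = FALSE]
  targets <- targets[fitted_guides]
  genes <- sort(unique(unlist(targets)))
  lines <- colnames(y)
  if (!all(genes %in% rownames(copy_number))) {
    stop("copy number missing for gene(s): ",
         paste(utils::head(setdiff(genes, rownames(copy_number)), 5), collapse = ", "))
  }
  if (!all(lines %in% colnames(copy_number))) {
    stop("copy number missing for line(s): ",
         paste(utils::head(setdiff(lines, colnames(copy_number)), 5), collapse = ", "))
  }
  nG <- length(fitted_guides); nT <- length(genes); nL <- length(lines)
  knots <- config$knots; K <- length(knots)
  lambda <- config$lambda

  # guide -> target incidence (without activity)
  Tmat <- Matrix::sparseMatrix(
    i = rep(seq_len(nG), lengths(targets)),
    j = match(unlist(targets), genes),
    x = 1, dims = c(nG, nT)
  )
  # cut number per guide and line: total cuts across target loci
  kappa <- as.matrix(Tmat %*% copy_number[genes, lines, drop = FALSE])
  Bline <- lapply(seq_len(nL), function(c) interp_basis(kappa[, c], knots))
  Mmap <- increment_map(knots)

  a <- setNames(rep(1, nG), fitted_guides)
  d <- matrix(0, nT, nL, dimnames = list(genes, lines))
  qk <- matrix(0, K, nL, dimnames = list(paste0("cut", knots), lines))
  cc <- setNames(rep(0, nL), lines)
  obs <- !is.na(y)
  y0 <- y; y0[!obs] <- 0

  qval <- function() {
    out <- matrix(0, nG, nL)
    for (c in seq_len(nL)) out[, c] <- as.vector(Bline[[c]] %*% qk[, c])
    out
  }
  objective <- function(qv) {
    fit <- sweep((as.matrix(Tmat %*% d) + qv) * a, 2, cc, "+")
    sum(((y0 - fit)[obs])^2) + lambda * sum(d^2)
  }

  trace <- numeric(0)
  qv <- qval()
  obj_prev <- objective(qv)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L

    ## (1) gene effects: per-line closed-form ridge
    Xa <- Tmat * a  # row-scaled incidence
    yc <- sweep(y0, 2, cc, "-")
    full <- all(obs)
    if (full) {
      Mn <- Matrix::crossprod(Xa) + lambda * Matrix::Diagonal(nT)
      d[] <- as.matrix(Matrix::solve(Mn, Matrix::crossprod(Xa, yc - a * qv)))
    } else {
      for (c in seq_len(nL)) {
        rows <- which(obs[, c])
        Xc <- Xa[rows, , drop = FALSE]
        Mn <- Matrix::crossprod(Xc) + lambda * Matrix::Diagonal(nT)
        rhs <- Matrix::crossprod(Xc, yc[rows, c] - a[rows] * qv[rows, c])
        d[, c] <- as.vector(Matrix::solve(Mn, rhs))
      }
    }

    ## (2) guide activities: clipped 1-D least squares
    if (config$fit_activity) {
      m <- as.matrix(Tmat %*% d) + qv
      m[!obs] <- 0
      num <- rowSums(yc * obs * m)
      den <- rowSums(m^2)
      upd <- den > 1e-12
      a[upd] <- pmin(pmax(num[upd] / den[upd], 0), 1)
    }

    ## (3) toxicity curves: non-negative coordinate descent on increments
    if (config$fit_toxicity) {
      dsum <- as.matrix(Tmat %*% d)
      for (c in seq_len(nL)) {
        rows <- which(obs[, c])
        A <- (a * Bline[[c]])[rows, , drop = FALSE] %*% Mmap
        A <- as.matrix(A)
        delta <- -diff(qk[, c])  # non-negative by invariant
        resid <- y0[rows, c] - cc[c] - a[rows] * dsum[rows, c] - A %*% delta
        den <- colSums(A^2)
        for (pass in 1:10) {
          for (mseg in which(den > 1e-12)) {
            old <- delta[mseg]
            prop <- old + sum(A[, mseg] * resid) / den[mseg]
            new <- max(0, prop)
            if (new != old) {
              resid <- resid - A[, mseg] * (new - old)
              delta[mseg] <- new
            }
          }
        }
        qk[, c] <- as.vector(Mmap %*% delta)
      }
      qv <- qval()
    }

    ## (4) per-line intercept: exact least-squares mean of residuals
    if (config$fit_intercept) {
      pred <- (as.matrix(Tmat %*% d) + qv) * a
      for (c in seq_len(nL)) {
        rows <- which(obs[, c])
        cc[c] <- mean(y0[rows, c] - pred[rows, c])
      }
    }

    obj <- objective(qv)
    trace <- c(trace, obj)
    if (abs(obj_prev - obj) <= config$rel_tol * max(abs(obj_prev), 1e-12)) {
      converged <- TRUE
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  if (!converged) {
    warning("fit_ceres did not converge in ", config$max_iter,
            " iterations; returning best iterate")
  }

  structure(list(
    gene_effect = gene_effect_matrix(d, provenance = "ceres_fit"),
    guide_activity = a,
    intercept = cc,
    toxicity = qk,
    knots = knots,
    objective = trace,
    converged = converged,
    n_iter = it,
    unfit_guides = unfit,
    config = config
  ), class = "CeresFit")
}

#' @export
print.CeresFit <- function(x, ...) {
  cat("CeresFit:", nrow(x$gene_effect$effects), "genes x",
      ncol(x$gene_effect$effects), "lines;",
      x$n_iter, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Normalize gene effects to the common-essential / nonessential scale
#'
#' Per line, an affine map sends the median score of the nonessential
#' reference genes to 0 and the median of the common-essential reference
#' genes to -1 -- the conventional dependency-score scale on which the
#' downstream threshold is defined.
#'
#' @param fit A `CeresFit` or `GeneEffectMatrix`.
#' @param essential_ref,nonessential_ref Reference gene sets; each must share
#'   at least 10 genes with the fitted matrix.
#' @return A `GeneEffectMatrix` of normalized scores.
#' @export
normalize_scores <- function(fit, essential_ref, nonessential_ref) {
  gem <- if (inherits(fit, "CeresFit")) fit$gene_effect else fit
  stopifnot(inherits(gem, "GeneEffectMatrix"))
  x <- gem$effects
  ess <- intersect(essential_ref, rownames(x))
  non <- intersect(nonessential_ref, rownames(x))
  if (length(ess) < 10 || length(non) < 10) {
    stop("need >= 10 reference genes of each kind among fitted genes (got ",
         length(ess), " essential, ", length(non), " nonessential)")
  }
  out <- x
  for (c in seq_len(ncol(x))) {
    m1 <- median(x[ess, c], na.rm = TRUE)
    m0 <- median(x[non, c], na.rm = TRUE)
    if (isTRUE(all.equal(m0, m1))) {
      stop("degenerate normalization in line '", colnames(x)[c],
           "': reference medians coincide")
    }
    out[, c] <- -(x[, c] - m0) / (m1 - m0)
  }
  gene_effect_matrix(out, entrez = gem$entrez, histotype = gem$histotype,
                     provenance = paste0(gem$provenance, "+normalized"))
}
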