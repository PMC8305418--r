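# Minimal guide map for hand-built fits: one row per guide, single target.
simple_map <- function(guides, genes) {
  data.frame(guide_id = guides, gene_symbol = genes, cds_index = 1L,
             offset = 0L, strand = "+", stringsAsFactors = FALSE)
}

ridge_mode <- function(...) {
  ceres_config(fit_activity = FALSE, fit_toxicity = FALSE, ...)
}

test_that("single-gene noiseless case matches the closed-form ridge solution", {
  lfc <- matrix(-1, 4, 1, dimnames = list(paste0("g", 1:4), "L1"))
  cn <- matrix(2, 1, 1, dimnames = list("GENE1", "L1"))
  fit <- fit_ceres(lfc, simple_map(rownames(lfc), rep("GENE1", 4)), cn,
                   ridge_mode())
  expect_equal(unname(fit$gene_effect$effects["GENE1", "L1"]),
               -4 / 4.681, tolerance = 1e-6)
  expect_equal(-4 / 4.681, -0.8545, tolerance = 1e-4)
})

test_that("ridge mode matches the closed form on random noiseless instances", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    genes <- paste0("G", 1:10)
    lines <- paste0("L", 1:3)
    d_true <- matrix(rnorm(30, -0.3, 0.5), 10, 3, dimnames = list(genes, lines))
    n_guides <- sample(2:5, 10, replace = TRUE)
    gmap <- simple_map(paste0("gu", seq_len(sum(n_guides))),
                       rep(genes, n_guides))
    lfc <- d_true[gmap$gene_symbol, , drop = FALSE]
    rownames(lfc) <- gmap$guide_id
    cn <- matrix(2, 10, 3, dimnames = list(genes, lines))
    fit <- fit_ceres(lfc, gmap, cn, ridge_mode())
    oracle <- d_true * (n_guides / (n_guides + 0.681))
    expect_equal(fit$gene_effect$effects[genes, lines], oracle,
                 tolerance = 1e-6)
  }
})

test_that("all-zero LFC is a fixed point with zero objective", {
  lfc <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), c("L1", "L2")))
  cn <- matrix(2, 3, 2, dimnames = list(c("A", "B", "C"), c("L1", "L2")))
  fit <- fit_ceres(lfc, simple_map(rownames(lfc), rep(c("A", "B", "C"), 2)),
                   cn, ceres_config())
  expect_equal(max(abs(fit$gene_effect$effects)), 0)
  expect_equal(max(abs(fit$toxicity)), 0)
  expect_equal(fit$objective[length(fit$objective)], 0)
})

test_that("fit invariants hold on a realistic simulated screen", {
  sim <- tiny_sim()
  map <- map_guides(sim$library, sim$catalog)
  lfc <- center_lfc(compute_lfc(sim$counts),
                    sim$library$guide_id[sim$library$declared_gene %in%
                                           sim$truth$nonessential_genes])
  fit <- fit_ceres(lfc, map, sim$truth$copy_number, ceres_config())
  # objective never increases across alternating iterations
  expect_true(all(diff(fit$objective) <= 1e-8 * abs(fit$objective[1])))
  # activities clipped to [0, 1]
  expect_true(all(fit$guide_activity >= 0 & fit$guide_activity <= 1))
  # toxicity curves monotone non-increasing, anchored at cut number 2
  expect_true(all(apply(fit$toxicity, 2, function(q) all(diff(q) <= 1e-12))))
  expect_equal(unname(fit$toxicity["cut2", ]),
               rep(0, ncol(fit$toxicity)))
})

test_that("estimates are invariant to guide and line permutations", {
  sim <- tiny_sim()
  map <- map_guides(sim$library, sim$catalog)
  lfc <- compute_lfc(sim$counts)
  cn <- sim$truth$copy_number
  fit1 <- suppressWarnings(fit_ceres(lfc, map, cn, ceres_config(max_iter = 30)))
  set.seed(1)
  gp <- sample(nrow(lfc)); lp <- sample(ncol(lfc))
  lfc2 <- unclass(lfc)[gp, lp]
  fit2 <- suppressWarnings(fit_ceres(lfc2, map[sample(nrow(map)), ], cn,
                                     ceres_config(max_iter = 30)))
  g <- rownames(fit1$gene_effect$effects); l <- colnames(fit1$gene_effect$effects)
  expect_equal(fit1$gene_effect$effects,
               fit2$gene_effect$effects[g, l], tolerance = 1e-6)
  expect_equal(fit1$guide_activity[names(fit1$guide_activity)],
               fit2$guide_activity[names(fit1$guide_activity)], tolerance = 1e-6)
})

test_that("missing LFC entries are dropped, not imputed", {
  lfc <- matrix(-1, 4, 2, dimnames = list(paste0("g", 1:4), c("L1", "L2")))
  lfc[3:4, 2] <- NA
  cn <- matrix(2, 1, 2, dimnames = list("GENE1", c("L1", "L2")))
  fit <- fit_ceres(lfc, simple_map(rownames(lfc), rep("GENE1", 4)), cn,
                   ridge_mode())
  expect_equal(unname(fit$gene_effect$effects["GENE1", ]),
               c(-4 / 4.681, -2 / 2.681), tolerance = 1e-6)
})

test_that("normalization maps reference medians to 0 and -1 and is affine-invariant", {
  set.seed(8)
  genes <- c(paste0("E", 1:12), paste0("N", 1:12))
  m <- rbind(matrix(rnorm(24, -1, 0.05), 12), matrix(rnorm(24, 0, 0.05), 12))
  dimnames(m) <- list(genes, c("L1", "L2"))
  gem <- gene_effect_matrix(m)
  ess <- paste0("E", 1:12); non <- paste0("N", 1:12)
  norm1 <- normalize_scores(gem, ess, non)
  for (c in 1:2) {
    expect_equal(median(norm1$effects[ess, c]), -1)
    expect_equal(median(norm1$effects[non, c]), 0)
  }
  # already-normalized input with medians exactly (0, -1) is unchanged
  norm2 <- normalize_scores(norm1, ess, non)
  expect_equal(norm2$effects, norm1$effects)
  # uniform scaling is undone
  doubled <- gene_effect_matrix(m * 2)
  expect_equal(normalize_scores(doubled, ess, non)$effects, norm1$effects)
  # degenerate reference separation errors
  flat <- gene_effect_matrix(matrix(0.3, 24, 2, dimnames = dimnames(m)))
  expect_error(normalize_scores(flat, ess, non), "degenerate")
  expect_error(normalize_scores(gem, ess[1:5], non), ">= 10")
})
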