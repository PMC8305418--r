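test_that("threshold statistic follows the mean-plus-two-sd rule exactly", {
  scores <- c(A = -1.0, B = -0.9, C = -1.1, D = -1.0, X = 5)
  thr <- compute_threshold(scores, c("A", "B", "C", "D"))
  expect_equal(thr$mean, -1.0)
  expect_equal(thr$sigma, sd(c(-1.0, -0.9, -1.1, -1.0)))
  expect_equal(thr$D, thr$mean + 2 * thr$sigma)  # machine-precision invariant
  expect_equal(thr$D, -0.83670, tolerance = 1e-5)
  expect_equal(thr$n, 4L)

  const <- compute_threshold(c(g1 = -0.7, g2 = -0.7, g3 = -0.7), paste0("g", 1:3))
  expect_equal(const$D, -0.7)
  expect_error(compute_threshold(c(g1 = -1), "g1"), "at least 2")
})

test_that("library integration applies concordance and expression rules", {
  sets <- list(
    lib1 = c(g1 = -0.5, g2 = -0.2, g3 = -1.0, g4 = -0.8),
    lib2 = c(g1 = -0.4, g2 = -0.3, g3 = -0.9, g4 = -0.7),
    lib3 = c(g1 = -0.6, g2 = -0.1, g4 = -0.9)
  )
  tpm <- c(g1 = 10, g2 = 0, g3 = 50, g4 = 3)
  res <- integrate_libraries(sets, tpm, tpm_min = 1)
  expect_equal(res$median_score[res$gene == "g1"], -0.5)
  expect_equal(res$reason[res$gene == "g2"], "not_expressed")
  expect_equal(res$reason[res$gene == "g3"], "not_in_all_libraries")
  expect_equal(res$median_score[res$gene == "g4"], -0.8)
  expect_error(integrate_libraries(sets[1], tpm), "length")
  expect_error(
    integrate_libraries(list(a = c(g2 = -1), b = c(g2 = -1)), tpm),
    "no gene survives")
})

test_that("the 90 percent boundary is inclusive and missing scores never count", {
  mat <- matrix(0, 3, 12, dimnames = list(c("gA", "gB", "gC"), paste0("L", 1:12)))
  histos <- setNames(c(rep("AD", 10), "SCLC", "SCC"), colnames(mat))
  mat["gA", 1:9] <- -1    # 9/10 AD lines below: fraction 0.9, called
  mat["gB", 1:8] <- -1    # 8/10: fraction 0.8, not called
  mat["gC", 1:9] <- -1
  mat["gC", 9] <- NA      # 8 below + 1 missing: missing is not below
  calls <- call_histotype_dependencies(mat, histos, D = -0.3)
  expect_true("gA" %in% calls$calls$AD)
  expect_false("gB" %in% calls$calls$AD)
  expect_false("gC" %in% calls$calls$AD)
  expect_equal(unname(calls$fraction["gA", "AD"]), 0.9)
})

test_that("calling matches an independent brute-force oracle on random matrices", {
  set.seed(77)
  for (i in 1:40) {
    genes <- paste0("g", 1:50)
    lines <- paste0("L", 1:12)
    # labels with at least one line per histotype; scores on a lattice so
    # exact threshold ties occur
    labs <- setNames(c("AD", "SCLC", "SCC",
                       sample(c("AD", "SCLC", "SCC"), 9, replace = TRUE)), lines)
    mat <- matrix(sample(seq(-1, 0.2, by = 0.3), 600, replace = TRUE), 50, 12,
                  dimnames = list(genes, lines))
    mat[sample(600, 20)] <- NA
    D <- sample(c(-0.4, -0.7, -1), 1)
    frac <- sample(c(0.5, 0.9, 1), 1)
    cand <- sample(genes, 35)
    got <- call_histotype_dependencies(mat, labs, D, frac, cand)
    want <- brute_force_calls(mat, labs, D, frac, cand)
    for (h in c("AD", "SCLC", "SCC")) {
      expect_setequal(got$calls[[h]], want[[h]])
    }
  }
})

test_that("calling is monotone in the threshold and in the fraction", {
  set.seed(5)
  mat <- matrix(rnorm(300, -0.4, 0.4), 25, 12,
                dimnames = list(paste0("g", 1:25), paste0("L", 1:12)))
  labs <- setNames(rep(c("AD", "SCLC", "SCC"), each = 4), colnames(mat))
  base <- call_histotype_dependencies(mat, labs, D = -0.3, min_fraction = 0.75)
  lower_D <- call_histotype_dependencies(mat, labs, D = -0.5, min_fraction = 0.75)
  higher_frac <- call_histotype_dependencies(mat, labs, D = -0.3, min_fraction = 0.9)
  for (h in c("AD", "SCLC", "SCC")) {
    expect_true(all(lower_D$calls[[h]] %in% base$calls[[h]]))
    expect_true(all(higher_frac$calls[[h]] %in% base$calls[[h]]))
  }
})

test_that("calling rejects bad inputs", {
  mat <- matrix(-1, 2, 2, dimnames = list(c("g1", "g2"), c("L1", "L2")))
  expect_error(
    call_histotype_dependencies(mat, c(L1 = "AD", L2 = "AD"), -0.3),
    "zero lines")
  expect_error(
    call_histotype_dependencies(mat, c(L1 = "AD"), -0.3),
    "unlabelled")
  expect_error(
    call_histotype_dependencies(mat, c(L1 = "AD", L2 = "SCLC"), -0.3,
                                candidate_genes = "nope"),
    "subset")
})

test_that("venn partition is a disjoint cover with correct set algebra", {
  vp <- venn_partition(list(AD = c("a", "b"), SCLC = c("b", "c"), SCC = "b"))
  expect_equal(vp$regions$core, "b")
  expect_equal(vp$regions$AD_only, "a")
  expect_equal(vp$regions$SCLC_only, "c")
  expect_equal(sum(vp$sizes), 3)

  same <- venn_partition(list(AD = c("x", "y"), SCLC = c("x", "y"), SCC = c("y", "x")))
  expect_setequal(same$regions$core, c("x", "y"))
  expect_equal(sum(same$sizes) - length(same$regions$core), 0)

  set.seed(21)
  for (i in 1:20) {
    sets <- lapply(setNames(1:3, c("AD", "SCLC", "SCC")), function(j) {
      sample(paste0("g", 1:30), sample(0:20, 1))
    })
    vp <- venn_partition(sets)
    all_regions <- unlist(vp$regions)
    expect_equal(length(all_regions), length(unique(all_regions)))
    expect_setequal(all_regions, unique(unlist(sets)))
    # brute-force membership check per gene
    for (g in unique(unlist(sets))) {
      key <- paste(c("AD", "SCLC", "SCC")[vapply(sets, function(s) g %in% s, TRUE)],
                   collapse = "_")
      region <- switch(key, AD = "AD_only", SCLC = "SCLC_only", SCC = "SCC_only",
                       AD_SCLC = "AD_SCLC", AD_SCC = "AD_SCC",
                       SCLC_SCC = "SCLC_SCC", AD_SCLC_SCC = "core")
      expect_true(g %in% vp$regions[[region]])
    }
  }
})
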