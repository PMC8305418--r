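test_that("config validation rejects degenerate designs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, lines_per_histotype = c(AD = 2, SCLC = 0, SCC = 2)),
               "at least one cell line")
  expect_error(sim_config(seed = 1, guides_per_gene = 3), "evenly")
  expect_error(sim_config(seed = 1, cn_toxicity_slope = 0.1), "<= 0")
})

test_that("same seed regenerates bit-identical counts and truth", {
  s1 <- simulate_screen(tiny_config(seed = 42))
  s2 <- simulate_screen(tiny_config(seed = 42))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$library, s2$library)
  s3 <- simulate_screen(tiny_config(seed = 43))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("ground truth honours its structural invariants", {
  sim <- tiny_sim()
  tr <- sim$truth
  expect_true(all(tr$true_guide_activity >= 0 & tr$true_guide_activity <= 1))
  expect_true(all(tr$copy_number >= 0))
  expect_true(all(tr$expression_tpm[tr$unexpressed_genes, ] == 0))
  # histotype-specific genes: strong inside, near zero outside
  for (h in names(tr$specific_genes)) {
    own <- names(tr$histotype_labels)[tr$histotype_labels == h]
    other <- setdiff(names(tr$histotype_labels), own)
    eff <- tr$true_gene_effect[tr$specific_genes[[h]], , drop = FALSE]
    expect_true(all(rowMeans(eff[, own, drop = FALSE]) <= -0.7))
    expect_true(all(rowMeans(eff[, other, drop = FALSE]) >= -0.15))
  }
  # semi-library split exhausts guides per gene
  split_tab <- table(sim$library$declared_gene, sim$library$semi_library)
  expect_true(all(split_tab == 1))  # tiny config: 1 guide per semi-library
})

test_that("null screen (no effects, no toxicity) has per-gene LFC near zero", {
  cfg <- tiny_config(seed = 7,
                     essential_effect_mean = 0, essential_effect_sd = 1e-9,
                     specific_effect = 0, offtarget_sd = 0,
                     cn_toxicity_slope = 0)
  sim <- simulate_screen(cfg)
  lfc <- compute_lfc(sim$counts)
  gm <- naive_gene_lfc(lfc, setNames(sim$library$declared_gene, sim$library$guide_id))
  se <- apply(gm, 1, sd) / sqrt(ncol(gm))
  # per-gene mean LFC across lines within 3 SE of zero for almost all genes
  z <- abs(rowMeans(gm)) / pmax(se, 1e-6)
  expect_gt(mean(z <= 3), 0.95)
  expect_lt(abs(mean(gm)), 0.05)
})

test_that("amplification never increases expected endpoint representation", {
  sim <- tiny_sim()
  tr <- sim$truth
  counts <- sim$counts$counts
  des <- sim$counts$design
  tf <- des$sample[des$timepoint == "TF"]
  t0 <- des$sample[des$timepoint == "T0"]
  ratios <- sapply(unique(des$line), function(ln) {
    rowMeans(counts[, intersect(tf, des$sample[des$line == ln]), drop = FALSE]) /
      pmax(rowMeans(counts[, intersect(t0, des$sample[des$line == ln]), drop = FALSE]), 1)
  })
  rownames(ratios) <- rownames(counts)
  # aggregate TF/T0 ratio of amplified-neutral guides: amplified lines lower
  amp_ratio <- dip_ratio <- numeric(0)
  for (g in tr$amplified_genes) {
    gids <- sim$library$guide_id[sim$library$declared_gene == g]
    amp_in <- tr$amplified_lines[[g]]
    dip_in <- setdiff(unique(des$line), amp_in)
    amp_ratio <- c(amp_ratio, as.vector(ratios[gids, amp_in]))
    dip_ratio <- c(dip_ratio, as.vector(ratios[gids, dip_in]))
  }
  expect_lt(mean(amp_ratio), mean(dip_ratio))
})

test_that("drug table is reproducible and its filter truth is correct", {
  tr <- tiny_sim()$truth
  d1 <- simulate_drug_table(tr, seed = 5)
  d2 <- simulate_drug_table(tr, seed = 5)
  expect_identical(d1, d2)
  modes_kept <- c("inhibitor", "antagonist", "modulator")
  expect_identical(d1$kept_rows, d1$table$interaction_type %in% modes_kept)
  expect_setequal(d1$druggable_genes,
                  unique(d1$table$gene_symbol[d1$kept_rows]))
  # a gene with only non-druggable modes must not be in the druggable truth
  only_agonist <- setdiff(unique(d1$table$gene_symbol), d1$druggable_genes)
  if (length(only_agonist) > 0) {
    rows <- d1$table[d1$table$gene_symbol %in% only_agonist, ]
    expect_true(all(!rows$interaction_type %in% modes_kept))
  }
  expect_true(all(d1$table$category %in% drug_categories()))
})
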