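demo_table <- function() {
  data.frame(
    gene_symbol = c("g1", "g1", "g2", "g3"),
    drug_name = c("d1", "d2", "d3", "d4"),
    interaction_type = c("inhibitor", "agonist", "modulator", "antagonist"),
    category = NA_character_, source = "test",
    stringsAsFactors = FALSE
  )
}

test_that("mode-of-action filter keeps only druggable rows for queried genes", {
  res <- filter_druggable(demo_table(), c("g1", "g2"))
  expect_equal(nrow(res$interactions), 2)
  expect_setequal(res$druggable_genes, c("g1", "g2"))
  expect_false("agonist" %in% res$interactions$interaction_type)
  # g3 is druggable by mode but not queried
  expect_false("g3" %in% res$druggable_genes)
  # empty query -> empty output
  empty <- filter_druggable(demo_table(), character(0))
  expect_equal(nrow(empty$interactions), 0)
  expect_length(empty$druggable_genes, 0)
})

test_that("filter is invariant to row order and interaction-type case", {
  tab <- demo_table()
  tab$interaction_type <- c("Inhibitor", "AGONIST", "Modulator", "antagonist")
  shuffled <- tab[c(3, 1, 4, 2), ]
  r1 <- filter_druggable(tab, c("g1", "g2", "g3"))
  r2 <- filter_druggable(shuffled, c("g1", "g2", "g3"))
  expect_setequal(r1$druggable_genes, r2$druggable_genes)
  expect_setequal(r1$interactions$drug_name, r2$interactions$drug_name)
  # vocabulary is configurable
  r3 <- filter_druggable(tab, c("g1", "g2", "g3"), modes = "agonist")
  expect_equal(r3$interactions$drug_name, "d2")
})

test_that("filtered simulated drug table matches generator truth exactly", {
  tr <- tiny_sim()$truth
  drug <- simulate_drug_table(tr, seed = 13)
  res <- filter_druggable(drug$table, names(tr$gene_class))
  expect_identical(res$interactions, drug$table[drug$kept_rows, ],
                   ignore_attr = "row.names")
  expect_identical(res$druggable_genes, drug$druggable_genes)
})

test_that("hypergeometric p matches direct enumeration, including the worked case", {
  universe <- paste0("u", 1:20)
  query <- universe[1:5]
  pw <- list(hit = universe[1:5], half = universe[3:12], none = universe[6:10])
  res <- enrich(query, pw, universe)
  p_hit <- res$p_value[res$pathway == "hit"]
  expect_equal(p_hit, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(p_hit, hyper_tail_enum(5, 5, 20, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$pathway == "half"],
               hyper_tail_enum(3, 10, 20, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$pathway == "none"],
               hyper_tail_enum(0, 5, 20, 5), tolerance = 1e-12)
  # the pathway identical to the query is the most significant
  expect_equal(res$pathway[1], "hit")
})

test_that("enrichment matches enumeration and naive BH on random fixtures", {
  set.seed(99)
  universe <- paste0("g", 1:60)
  for (rep in 1:4) {
    query <- sample(universe, 12)
    pw <- lapply(1:25, function(i) sample(universe, sample(3:20, 1)))
    names(pw) <- sprintf("P%02d", 1:25)
    res <- enrich(query, pw, universe)
    res <- res[match(names(pw), res$pathway), ]
    p_oracle <- vapply(names(pw), function(id) {
      k <- length(intersect(pw[[id]], query))
      hyper_tail_enum(k, length(pw[[id]]), 60, 12)
    }, numeric(1))
    expect_equal(unname(res$p_value), unname(p_oracle), tolerance = 1e-12)
    expect_equal(unname(res$p_adjusted), unname(bh_naive(p_oracle)),
                 tolerance = 1e-12)
    expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
    expect_identical(res$significant, res$p_adjusted <= 0.05)
  }
})

test_that("query genes outside the universe are dropped with a warning", {
  universe <- paste0("g", 1:10)
  pw <- list(A = universe[1:4])
  expect_warning(res <- enrich(c("g1", "g2", "alien"), pw, universe),
                 "outside the universe")
  expect_equal(res$overlap, 2)
  expect_error(enrich("g1", pw, character(0)), "universe")
})
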