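#' Configuration for the synthetic pooled CRISPR-KO screen generator
#'
#' Builds the parameter set that [simulate_screen()] consumes. Defaults emulate
#' a two-semi-library knockout screen across a panel of lung cancer cell lines
#' of three histotypes (adenocarcinoma AD, small-cell SCLC, squamous-cell SCC),
#' with a common-essential core, histotype-specific dependencies, neutral
#' genes, and copy-number-amplified neutral genes that deplete through Cas9
#' cutting toxicity rather than essentiality.
#'
#' @param seed Integer master seed. Mandatory: all randomness flows from it
#'   through one derived stream per generated component, so regenerating with
#'   the same seed is bit-identical.
#' @param lines_per_histotype Named integer vector, lines per histotype.
#' @param n_common_essential Number of genes essential in every line. Their
#'   true effects are drawn once per gene from Normal(mean -1, sd 0.283): a
#'   gene-specific strength, constant across lines. The spread is calibrated
#'   so that the common-essential mean-plus-two-sd threshold lands near -0.3
#'   on the normalized score scale, as observed in real dependency data.
#' @param n_histotype_specific Genes per histotype with true effect -0.8 in
#'   their own histotype and Normal(0, sd 0.05) elsewhere.
#' @param n_nonessential Neutral genes (effect 0 everywhere).
#' @param n_amplified_neutral Neutral genes amplified (copy number drawn
#'   uniformly from 6..12) in a random half of the lines; they deplete via
#'   cutting toxicity only and are the false positives copy-number correction
#'   must rescue.
#' @param guides_per_gene Guides per gene, split evenly across semi-libraries
#'   A and B (must be even).
#' @param count_depth_mean Mean sequencing reads per guide at T0.
#' @param nb_dispersion Negative-binomial size parameter of the marginal count
#'   distribution. Overdispersion is modelled as a library-composition skew per
#'   guide and line, shared between the T0 and endpoint samples of that line
#'   (the endpoint pool grew out of the T0 pool), with Poisson sequencing
#'   noise per replicate on top. `Inf` gives pure Poisson counts.
#' @param doublings Scale factor on phenotypic effects (screen duration in
#'   population doublings).
#' @param cn_toxicity_slope Log2 depletion per Cas9 cut beyond the diploid
#'   two, non-positive; the toxicity is floored at `cn_toxicity_floor`.
#' @param cn_toxicity_floor Lower bound of the cutting-toxicity effect.
#' @param frac_unexpressed Fraction of nonessential genes with TPM exactly 0
#'   in every line.
#' @param t0_replicates,tf_replicates Sequencing replicates per line at T0 and
#'   at the endpoint.
#' @param essential_effect_mean,essential_effect_sd,specific_effect,offtarget_sd
#'   Effect-size parameters of the ground truth (see above for defaults).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       lines_per_histotype = c(AD = 8L, SCLC = 6L, SCC = 6L),
                       n_common_essential = 60L,
                       n_histotype_specific = 30L,
                       n_nonessential = 150L,
                       n_amplified_neutral = 30L,
                       guides_per_gene = 4L,
                       count_depth_mean = 400,
                       nb_dispersion = 8,
                       doublings = 1.0,
                       cn_toxicity_slope = -0.15,
                       cn_toxicity_floor = -1.5,
                       frac_unexpressed = 0.05,
                       t0_replicates = 2L,
                       tf_replicates = 2L,
                       essential_effect_mean = -1,
                       essential_effect_sd = sqrt(0.08),
                       specific_effect = -0.8,
                       offtarget_sd = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory: the generator has no implicit randomness")
  cfg <- list(
    seed = seed,
    lines_per_histotype = lines_per_histotype,
    n_common_essential = as.integer(n_common_essential),
    n_histotype_specific = as.integer(n_histotype_specific),
    n_nonessential = as.integer(n_nonessential),
    n_amplified_neutral = as.integer(n_amplified_neutral),
    guides_per_gene = as.integer(guides_per_gene),
    count_depth_mean = count_depth_mean,
    nb_dispersion = nb_dispersion,
    doublings = doublings,
    cn_toxicity_slope = cn_toxicity_slope,
    cn_toxicity_floor = cn_toxicity_floor,
    frac_unexpressed = frac_unexpressed,
    t0_replicates = as.integer(t0_replicates),
    tf_replicates = as.integer(tf_replicates),
    essential_effect_mean = essential_effect_mean,
    essential_effect_sd = essential_effect_sd,
    specific_effect = specific_effect,
    offtarget_sd = offtarget_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$lines_per_histotype)) ||
      !all(c("AD", "SCLC", "SCC") %in% names(cfg$lines_per_histotype))) {
    stop("lines_per_histotype must name AD, SCLC and SCC")
  }
  if (any(cfg$lines_per_histotype < 1)) {
    stop("every histotype needs at least one cell line")
  }
  for (f in c("n_common_essential", "n_histotype_specific", "n_nonessential",
              "n_amplified_neutral", "guides_per_gene", "t0_replicates",
              "tf_replicates")) {
    if (!is_count(cfg[[f]])) stop("`", f, "` must be a positive integer")
  }
  if (cfg$guides_per_gene %% 2L != 0L) {
    stop("guides_per_gene must split evenly across semi-libraries A and B")
  }
  if (cfg$cn_toxicity_slope > 0) stop("cn_toxicity_slope must be <= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$frac_unexpressed < 0 || cfg$frac_unexpressed > 1) {
    stop("frac_unexpressed must lie in [0, 1]")
  }
  invisible(cfg)
}

# True cutting-toxicity curve: log2 effect of kappa cuts, anchored at the
# diploid two cuts, floored.
toxicity_true <- function(kappa, slope, floor) {
  pmax(slope * (kappa - 2), floor)
}

#' Simulate a two-semi-library pooled CRISPR knockout screen
#'
#' Generates guide-level read counts for T0 and endpoint samples across a
#' panel of cell lines, together with the guide library, a coding-sequence
#' catalog in which every guide has an exact match, per-gene copy-number and
#' expression matrices, histotype labels, and the full ground truth.
#'
#' The expected endpoint count of guide g in line c is the T0 mean times
#' `2^mu`, with `mu = doublings * a_g * (d_{gene(g),c} + q(kappa_{g,c}))`:
#' `a_g` the guide activity (Beta(6,2)), `d` the true gene effect, and
#' `q(kappa) = max(slope * (kappa - 2), floor)` the copy-number cutting
#' toxicity at cut number kappa (the gene's copy number). The same gene
#' effects drive both semi-libraries through distinct guides and noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `screen_sim` with elements `counts`
#'   ([screen_counts()]), `library` (guide library data frame), `catalog`
#'   (CDS catalog data frame), and `truth` (ground-truth list).
#' @export
simulate_screen <- function(config) {
  validate_sim_config(config)
  cfg <- config

  histos <- c("AD", "SCLC", "SCC")
  n_lines <- sum(cfg$lines_per_histotype[histos])
  lines <- unlist(lapply(histos, function(h) {
    sprintf("%s%02d", h, seq_len(cfg$lines_per_histotype[[h]]))
  }))
  histotype <- setNames(rep(histos, cfg$lines_per_histotype[histos]), lines)

  gene_class <- c(
    setNames(rep("common_essential", cfg$n_common_essential),
             sprintf("ESS%03d", seq_len(cfg$n_common_essential))),
    unlist(lapply(histos, function(h) {
      setNames(rep(paste0("specific_", h), cfg$n_histotype_specific),
               sprintf("SP%s%03d", h, seq_len(cfg$n_histotype_specific)))
    })),
    setNames(rep("nonessential", cfg$n_nonessential),
             sprintf("NEU%03d", seq_len(cfg$n_nonessential))),
    setNames(rep("amplified_neutral", cfg$n_amplified_neutral),
             sprintf("AMP%03d", seq_len(cfg$n_amplified_neutral)))
  )
  genes <- names(gene_class)
  n_genes <- length(genes)

  ## true gene effects (stream 1)
  effect <- matrix(0, n_genes, n_lines, dimnames = list(genes, lines))
  with_stream(cfg$seed, 1L, {
    ess <- gene_class == "common_essential"
    effect[ess, ] <- matrix(
      rnorm(sum(ess), cfg$essential_effect_mean, cfg$essential_effect_sd),
      sum(ess), n_lines
    )
    for (h in histos) {
      sp <- gene_class == paste0("specific_", h)
      own <- histotype == h
      effect[sp, own] <- cfg$specific_effect
      effect[sp, !own] <- rnorm(sum(sp) * sum(!own), 0, cfg$offtarget_sd)
    }
  })

  ## copy number (stream 3): diploid baseline, amplification in half the lines
  cn <- matrix(2, n_genes, n_lines, dimnames = list(genes, lines))
  amp_lines_of <- list()
  with_stream(cfg$seed, 3L, {
    for (g in genes[gene_class == "amplified_neutral"]) {
      amp_in <- sample(lines, max(1L, floor(n_lines / 2)))
      cn[g, amp_in] <- sample(6:12, length(amp_in), replace = TRUE)
      amp_lines_of[[g]] <- sort(amp_in)
    }
  })

  ## expression (stream 4): signal genes well expressed; a fraction of the
  ## nonessential genes silent everywhere
  tpm <- matrix(0, n_genes, n_lines, dimnames = list(genes, lines))
  unexpressed <- character(0)
  with_stream(cfg$seed, 4L, {
    signal <- gene_class != "nonessential"
    base <- numeric(n_genes)
    base[signal] <- 5 + rlnorm(sum(signal), log(30), 1)
    base[!signal] <- rlnorm(sum(!signal), log(20), 1.2)
    neu <- genes[gene_class == "nonessential"]
    n_off <- round(cfg$frac_unexpressed * length(neu))
    unexpressed <- if (n_off > 0) sample(neu, n_off) else character(0)
    base[match(unexpressed, genes)] <- 0
    tpm[] <- base * exp(matrix(rnorm(n_genes * n_lines, 0, 0.2), n_genes))
    tpm[base == 0, ] <- 0
  })

  ## guide library + activities (streams 2, 6)
  gpg <- cfg$guides_per_gene
  guide_id <- as.vector(t(outer(genes, seq_len(gpg), function(g, k) sprintf("%s_g%d", g, k))))
  guide_gene <- rep(genes, each = gpg)
  semi <- rep(rep(c("A", "B"), each = gpg / 2L), n_genes)
  activity <- with_stream(cfg$seed, 2L, setNames(rbeta(length(guide_id), 6, 2), guide_id))

  seqs <- with_stream(cfg$seed, 6L, make_guide_and_cds_sequences(genes, gpg))
  library_df <- data.frame(
    guide_id = guide_id,
    sequence = seqs$guide_seq,
    declared_gene = guide_gene,
    semi_library = semi,
    stringsAsFactors = FALSE
  )

  ## counts (stream 5)
  design <- expand.grid(
    replicate = seq_len(max(cfg$t0_replicates, cfg$tf_replicates)),
    timepoint = c("T0", "TF"),
    line = lines,
    stringsAsFactors = FALSE
  )
  design <- design[(design$timepoint == "T0" & design$replicate <= cfg$t0_replicates) |
                     (design$timepoint == "TF" & design$replicate <= cfg$tf_replicates), ]
  design$sample <- sprintf("%s_%s_r%d", design$line, design$timepoint, design$replicate)
  design <- design[, c("sample", "line", "timepoint", "replicate")]
  rownames(design) <- NULL

  qk <- toxicity_true(cn, cfg$cn_toxicity_slope, cfg$cn_toxicity_floor)
  mu <- cfg$doublings * activity[guide_id] *
    (effect[guide_gene, , drop = FALSE] + qk[guide_gene, , drop = FALSE])
  rownames(mu) <- guide_id

  counts <- matrix(0L, length(guide_id), nrow(design),
                   dimnames = list(guide_id, design$sample))
  with_stream(cfg$seed, 5L, {
    for (ln in lines) {
      skew <- if (is.finite(cfg$nb_dispersion)) {
        rgamma(length(guide_id), shape = cfg$nb_dispersion, rate = cfg$nb_dispersion)
      } else {
        rep(1, length(guide_id))
      }
      lam0 <- cfg$count_depth_mean * skew
      for (i in which(design$line == ln)) {
        lam <- if (design$timepoint[i] == "T0") lam0 else lam0 * 2^mu[, ln]
        counts[, design$sample[i]] <- rpois(length(lam), lam)
      }
    }
  })

  truth <- list(
    gene_class = gene_class,
    true_gene_effect = effect,
    true_guide_activity = activity,
    copy_number = cn,
    expression_tpm = tpm,
    histotype_labels = histotype,
    unexpressed_genes = sort(unexpressed),
    amplified_lines = amp_lines_of,
    specific_genes = lapply(setNames(histos, histos), function(h) {
      names(gene_class)[gene_class == paste0("specific_", h)]
    }),
    essential_genes = names(gene_class)[gene_class == "common_essential"],
    nonessential_genes = names(gene_class)[gene_class == "nonessential"],
    amplified_genes = names(gene_class)[gene_class == "amplified_neutral"]
  )

  structure(
    list(
      counts = screen_counts(counts, design),
      library = library_df,
      catalog = seqs$catalog,
      truth = truth,
      config = cfg
    ),
    class = "screen_sim"
  )
}

# Random unique 20-mers embedded in random CDS backgrounds; odd-numbered
# guides go in on the plus strand, even-numbered as reverse complements.
make_guide_and_cds_sequences <- function(genes, gpg) {
  bases <- c("A", "C", "G", "T")
  n_guides <- length(genes) * gpg
  repeat {
    gseq <- vapply(seq_len(n_guides), function(i) {
      paste(sample(bases, 20, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(gseq)) break
  }
  offsets <- 10L + (seq_len(gpg) - 1L) * 40L
  cds_len <- max(offsets) + 20L + 10L
  cds <- character(length(genes))
  strand_of <- rep(c("+", "-"), length.out = gpg)
  for (j in seq_along(genes)) {
    body <- sample(bases, cds_len, replace = TRUE)
    for (k in seq_len(gpg)) {
      gs <- gseq[(j - 1L) * gpg + k]
      ins <- if (strand_of[k] == "+") gs else revcomp_chr(gs)
      body[offsets[k] + 0:19] <- strsplit(ins, "")[[1]]
    }
    cds[j] <- paste(body, collapse = "")
  }
  catalog <- data.frame(
    gene_symbol = genes,
    entrez_id = seq_along(genes) + 100000L,
    cds_index = 1L,
    chromosome = "chr1",
    start = (seq_along(genes) - 1L) * (cds_len + 100L),
    end = (seq_along(genes) - 1L) * (cds_len + 100L) + cds_len,
    strand = "+",
    sequence = cds,
    stringsAsFactors = FALSE
  )
  list(guide_seq = gseq, catalog = catalog)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate a drug-gene interaction table with known filter truth
#'
#' Emulates a DGIdb-style export: about 30 percent of the genes in the ground
#' truth receive one to three drug interactions, with mode-of-action labels
#' drawn from inhibitor, antagonist, modulator, agonist and binder, and a
#' manual-curation category from the five-value vocabulary. The returned
#' truth records exactly which rows (and hence genes) survive the
#' inhibitor/antagonist/modulator mode filter.
#'
#' @param truth Ground truth from [simulate_screen()] (the `truth` element).
#' @param seed Integer seed.
#' @return List with `table` (the interaction data frame), `kept_rows`
#'   (logical, rows surviving the mode filter) and `druggable_genes`
#'   (genes with at least one surviving row).
#' @export
simulate_drug_table <- function(truth, seed) {
  genes <- names(truth$gene_class)
  modes <- c("inhibitor", "antagonist", "modulator", "agonist", "binder")
  tab <- with_stream(seed, 7L, {
    with_drug <- sort(sample(genes, round(0.3 * length(genes))))
    rows <- lapply(with_drug, function(g) {
      k <- sample(1:3, 1)
      data.frame(
        gene_symbol = g,
        drug_name = sprintf("DRUG_%s_%d", g, seq_len(k)),
        interaction_type = sample(modes, k, replace = TRUE),
        category = sample(drug_categories(), k, replace = TRUE),
        source = "synthetic",
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  kept <- tab$interaction_type %in% c("inhibitor", "antagonist", "modulator")
  list(
    table = tab,
    kept_rows = kept,
    druggable_genes = sort(unique(tab$gene_symbol[kept]))
  )
}

#' The five manual drug-curation categories
#'
#' Closed vocabulary used by the druggability annotation stage.
#' @return Character vector of length five.
#' @export
drug_categories <- function() {
  c("approved for lung cancer",
    "approved for other cancer conditions",
    "in clinical trials for cancer conditions",
    "approved or in clinical trials for non-cancer conditions",
    "pre-clinical data on target")
}

#' Build a small pathway collection from simulation ground truth
#'
#' Pathways mirror the generated gene groups (the common-essential core and
#' each histotype-specific set) plus random decoy pathways, so enrichment has
#' known positives. The universe is the full simulated gene set.
#'
#' @param truth Ground truth from [simulate_screen()].
#' @param seed Integer seed.
#' @param n_random Number of random decoy pathways.
#' @param random_size Genes per decoy pathway.
#' @return List with `pathways` (named list of gene vectors) and `universe`.
#' @export
simulate_pathways <- function(truth, seed, n_random = 10, random_size = 20) {
  genes <- names(truth$gene_class)
  pw <- c(
    list(CORE_ESSENTIAL_MACHINERY = truth$essential_genes),
    setNames(truth$specific_genes, paste0("HISTOTYPE_PROGRAM_", names(truth$specific_genes)))
  )
  decoys <- with_stream(seed, 8L, {
    lapply(seq_len(n_random), function(i) sort(sample(genes, random_size)))
  })
  names(decoys) <- sprintf("RANDOM_SET_%02d", seq_len(n_random))
  list(pathways = c(pw, decoys), universe = genes)
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Synthetic CRISPR screen\n")
  cat("  guides:", nrow(x$library), " genes:", nrow(x$catalog),
      " lines:", length(x$truth$histotype_labels), "\n")
  cat("  samples:", nrow(x$counts$design), "\n")
  invisible(x)
}
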