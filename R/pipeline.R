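#' Pipeline run configuration
#'
#' Assembles defaults and overrides for the full analysis flow
#' (simulate -> fit -> call -> annotate). Defaults carry the study constants:
#' ridge penalty 0.681, threshold rule mean + 2 sd, 90 percent-of-lines
#' calling, BH-adjusted p <= 0.05, mode vocabulary
#' inhibitor/antagonist/modulator.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Master seed for the simulation stage.
#' @param sim Named list of [sim_config()] overrides.
#' @param ceres Named list of [ceres_config()] overrides.
#' @param tpm_min Expression filter threshold (TPM) in the reference line.
#' @param min_fraction Histotype calling fraction.
#' @param modes Druggable mode-of-action vocabulary.
#' @param alpha Enrichment significance level (BH-adjusted).
#' @param reference_line Reference line for integration and the threshold;
#'   defaults to the first AD line.
#' @param gene_effects Optional path (or vector of paths) to external
#'   gene-effect CSVs in DepMap dialect; when supplied, `cmd_call()` skips
#'   the fit stage and consumes these directly.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, seed, sim = list(), ceres = list(),
                       tpm_min = 1.0, min_fraction = 0.9,
                       modes = c("inhibitor", "antagonist", "modulator"),
                       alpha = 0.05, reference_line = NULL,
                       gene_effects = NULL) {
  structure(list(outdir = outdir, seed = seed, sim = sim, ceres = ceres,
                 tpm_min = tpm_min, min_fraction = min_fraction,
                 modes = modes, alpha = alpha,
                 reference_line = reference_line,
                 gene_effects = gene_effects),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields
#'   (`outdir` and `seed` required).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$outdir), !is.null(y$seed))
  cfg <- run_config(outdir = y$outdir, seed = y$seed)
  for (f in intersect(names(y), names(cfg))) cfg[[f]] <- y[[f]]
  if (!is.null(cfg$modes)) cfg$modes <- as.character(cfg$modes)
  cfg
}

out_path <- function(cfg, ...) file.path(cfg$outdir, ...)

require_artifact <- function(cfg, file, producer) {
  p <- out_path(cfg, file)
  if (!file.exists(p)) {
    stop("missing artifact '", file, "': run ", producer,
         " first (or supply it externally)")
  }
  p
}

#' Pipeline stages
#'
#' `cmd_simulate()` generates the synthetic screen and writes every input
#' file; `cmd_fit()` maps guides, quantifies depletion and fits the
#' copy-number-corrected model per semi-library and for the combined guide
#' set; `cmd_call()` integrates libraries, computes the dependency threshold
#' and calls histotype dependencies; `cmd_annotate()` produces druggability
#' and enrichment tables; `cmd_run_all()` chains all stages and writes a run
#' manifest. All stages are deterministic given the configuration seed, and
#' rerunning reproduces byte-identical primary outputs.
#'
#' @param cfg A [run_config()].
#' @return Each stage returns its primary results invisibly; see details.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  sim <- simulate_screen(scfg)
  drug <- simulate_drug_table(sim$truth, cfg$seed)
  pw <- simulate_pathways(sim$truth, cfg$seed)

  write_counts_tsv(sim$counts, out_path(cfg, "counts.tsv"),
                   gene_symbol = setNames(sim$library$declared_gene,
                                          sim$library$guide_id))
  write.table(sim$library, out_path(cfg, "library.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(setNames(sim$library$sequence, sim$library$guide_id),
              out_path(cfg, "library.fasta"))
  write_fasta(setNames(sim$catalog$sequence, sim$catalog$gene_symbol),
              out_path(cfg, "cds.fasta"))
  write.table(sim$catalog[, setdiff(names(sim$catalog), "sequence")],
              out_path(cfg, "cds_catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gene_matrix_csv(sim$truth$copy_number, out_path(cfg, "copy_number.csv"))
  write_gene_matrix_csv(sim$truth$expression_tpm, out_path(cfg, "tpm.csv"))
  write_sample_info(sim$truth$histotype_labels, out_path(cfg, "sample_info.csv"))
  write_interactions_tsv(drug$table, out_path(cfg, "interactions.tsv"))
  write_gmt(pw$pathways, out_path(cfg, "pathways.gmt"))
  writeLines(sim$truth$essential_genes, out_path(cfg, "essential_ref.txt"))
  writeLines(sim$truth$nonessential_genes, out_path(cfg, "nonessential_ref.txt"))
  jsonlite::write_json(
    list(gene_class = as.list(sim$truth$gene_class),
         histotype_labels = as.list(sim$truth$histotype_labels),
         unexpressed_genes = sim$truth$unexpressed_genes,
         specific_genes = sim$truth$specific_genes,
         essential_genes = sim$truth$essential_genes,
         nonessential_genes = sim$truth$nonessential_genes,
         amplified_genes = sim$truth$amplified_genes,
         amplified_lines = sim$truth$amplified_lines,
         druggable_genes = drug$druggable_genes),
    out_path(cfg, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(sim = sim, drug = drug, pathways = pw))
}

#' @rdname pipeline
#' @export
cmd_fit <- function(cfg) {
  counts <- read_counts_tsv(require_artifact(cfg, "counts.tsv", "cmd_simulate"))
  lib <- read.delim(require_artifact(cfg, "library.tsv", "cmd_simulate"),
                    stringsAsFactors = FALSE)
  catalog <- read.delim(require_artifact(cfg, "cds_catalog.tsv", "cmd_simulate"),
                        stringsAsFactors = FALSE)
  catalog$sequence <- unname(read_fasta(
    require_artifact(cfg, "cds.fasta", "cmd_simulate"))[catalog$gene_symbol])
  cn <- read_gene_matrix_csv(require_artifact(cfg, "copy_number.csv", "cmd_simulate"))
  ess <- readLines(require_artifact(cfg, "essential_ref.txt", "cmd_simulate"))
  non <- readLines(require_artifact(cfg, "nonessential_ref.txt", "cmd_simulate"))

  ccfg <- do.call(ceres_config, cfg$ceres)
  map <- map_guides(lib, catalog)

  subsets <- list(A = lib$guide_id[lib$semi_library == "A"],
                  B = lib$guide_id[lib$semi_library == "B"],
                  combined = lib$guide_id)
  fits <- list()
  for (nm in names(subsets)) {
    sub <- screen_counts(counts$counts[subsets[[nm]], , drop = FALSE],
                         counts$design)
    lfc <- compute_lfc(sub)
    ctrl <- lib$guide_id[lib$declared_gene %in% non &
                           lib$guide_id %in% subsets[[nm]]]
    lfc <- center_lfc(lfc, ctrl)
    fit <- fit_ceres(lfc, map[map$guide_id %in% subsets[[nm]], ], cn, ccfg)
    scores <- normalize_scores(fit, ess, non)
    scores$provenance <- paste0("semi_library_", nm)
    write_gene_effect_csv(scores, out_path(cfg, paste0("gene_effect_", nm, ".csv")))
    fits[[nm]] <- list(fit = fit, scores = scores)
  }
  jsonlite::write_json(
    lapply(fits, function(f) list(
      n_iter = f$fit$n_iter, converged = f$fit$converged,
      objective_first = f$fit$objective[1],
      objective_last = f$fit$objective[length(f$fit$objective)],
      n_genes = nrow(f$fit$gene_effect$effects),
      n_unfit_guides = length(f$fit$unfit_guides)
    )),
    out_path(cfg, "fit_diagnostics.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(fits)
}

#' @rdname pipeline
#' @export
cmd_call <- function(cfg) {
  if (!is.null(cfg$gene_effects)) {
    paths <- cfg$gene_effects
    score_mats <- lapply(paths, read_gene_effect_csv)
    primary <- score_mats[[length(score_mats)]]
  } else {
    paths <- vapply(c("A", "B", "combined"), function(nm) {
      require_artifact(cfg, paste0("gene_effect_", nm, ".csv"), "cmd_fit")
    }, character(1))
    score_mats <- lapply(paths, read_gene_effect_csv)
    primary <- score_mats[["combined"]]
  }
  histotypes <- read_sample_info(require_artifact(cfg, "sample_info.csv",
                                                  "cmd_simulate"))
  tpm_path <- out_path(cfg, "tpm.csv")
  tpm <- if (file.exists(tpm_path)) read_gene_matrix_csv(tpm_path) else NULL
  ess <- readLines(require_artifact(cfg, "essential_ref.txt", "cmd_simulate"))

  ref <- cfg$reference_line %||%
    colnames(primary$effects)[histotypes[colnames(primary$effects)] == "AD"][1]
  if (is.na(ref)) ref <- colnames(primary$effects)[1]

  ref_scores <- lapply(score_mats, function(m) {
    if (!ref %in% colnames(m$effects)) {
      stop("reference line '", ref, "' absent from ", m$provenance)
    }
    m$effects[, ref]
  })
  expression <- if (!is.null(tpm)) tpm[, ref] else NULL

  if (length(ref_scores) >= 2) {
    integrated <- integrate_libraries(ref_scores, expression %||%
                                        setNames(rep(Inf, nrow(primary$effects)),
                                                 rownames(primary$effects)),
                                      tpm_min = cfg$tpm_min)
  } else {
    s <- ref_scores[[1]]
    expr <- if (is.null(expression)) rep(TRUE, length(s)) else {
      !is.na(expression[names(s)]) & expression[names(s)] >= cfg$tpm_min
    }
    integrated <- data.frame(gene = names(s), median_score = unname(s),
                             libraries_present = 1L, expressed = expr,
                             excluded = !expr,
                             reason = ifelse(expr, NA_character_, "not_expressed"),
                             stringsAsFactors = FALSE)
    integrated$median_score[integrated$excluded] <- NA_real_
    class(integrated) <- c("IntegratedScores", "data.frame")
  }

  med <- setNames(integrated$median_score, integrated$gene)
  thr <- compute_threshold(med[!is.na(med)], ess, source_line = ref)
  candidates <- integrated$gene[!integrated$excluded]
  ref_dependencies <- integrated$gene[!integrated$excluded &
                                        integrated$median_score <= thr$D]

  calls <- call_histotype_dependencies(primary, histotypes, thr,
                                       min_fraction = cfg$min_fraction,
                                       candidate_genes = candidates)
  venn <- venn_partition(calls)

  write.table(as.data.frame(integrated), out_path(cfg, "integrated.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(thr), out_path(cfg, "threshold.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(ref_dependencies, out_path(cfg, "dependency_genes_reference.txt"))
  for (h in names(calls$calls)) {
    df <- data.frame(gene = rownames(calls$fraction),
                     fraction_below_D = calls$fraction[, h],
                     n_lines = calls$n_lines[[h]],
                     called = rownames(calls$fraction) %in% calls$calls[[h]])
    write.table(df[order(-df$fraction_below_D, df$gene), ],
                out_path(cfg, paste0("calls_", h, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(c(venn$regions, list(sizes = as.list(venn$sizes))),
                       out_path(cfg, "venn.json"), pretty = TRUE)
  invisible(list(integrated = integrated, threshold = thr, calls = calls,
                 venn = venn, reference_line = ref,
                 reference_dependencies = ref_dependencies))
}

#' @rdname pipeline
#' @export
cmd_annotate <- function(cfg) {
  interactions <- read_interactions_tsv(
    require_artifact(cfg, "interactions.tsv", "cmd_simulate"))
  pathways <- read_gmt(require_artifact(cfg, "pathways.gmt", "cmd_simulate"))
  integrated <- read.delim(require_artifact(cfg, "integrated.tsv", "cmd_call"),
                           stringsAsFactors = FALSE)
  universe <- integrated$gene[!integrated$excluded]

  call_sets <- lapply(setNames(c("AD", "SCLC", "SCC"), c("AD", "SCLC", "SCC")),
                      function(h) {
    df <- read.delim(require_artifact(cfg, paste0("calls_", h, ".tsv"), "cmd_call"),
                     stringsAsFactors = FALSE)
    df$gene[df$called]
  })
  called_union <- sort(unique(unlist(call_sets)))

  drug <- filter_druggable(interactions, called_union, modes = cfg$modes)
  write_interactions_tsv(drug$interactions, out_path(cfg, "druggable.tsv"))
  writeLines(drug$druggable_genes, out_path(cfg, "druggable_genes.txt"))

  enr <- lapply(names(call_sets), function(h) {
    e <- enrich(call_sets[[h]], pathways, universe, alpha = cfg$alpha)
    write.table(as.data.frame(e), out_path(cfg, paste0("enrichment_", h, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    e
  })
  names(enr) <- names(call_sets)
  invisible(list(druggable = drug, enrichment = enr, called_union = called_union))
}

#' @rdname pipeline
#' @export
cmd_run_all <- function(cfg) {
  t_all <- Sys.time()
  timing <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- expr
    timing[[stage]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }
  simres <- tick("simulate", cmd_simulate(cfg))
  fits <- tick("fit", cmd_fit(cfg))
  callres <- tick("call", cmd_call(cfg))
  annres <- tick("annotate", cmd_annotate(cfg))

  n_genes <- length(simres$sim$truth$gene_class)
  integrated <- callres$integrated
  n_excl <- function(r) sum(integrated$reason == r, na.rm = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("screendep")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outdir")],
    timings_sec = timing,
    total_sec = round(as.numeric(difftime(Sys.time(), t_all, units = "secs")), 3),
    input_checksums = as.list(tools::md5sum(out_path(cfg, c(
      "counts.tsv", "library.tsv", "copy_number.csv", "tpm.csv",
      "sample_info.csv", "interactions.tsv", "pathways.gmt")))),
    gene_accounting = list(
      simulated = n_genes,
      fitted = nrow(fits$combined$scores$effects),
      integration_universe = nrow(integrated),
      excluded_not_in_all_libraries = n_excl("not_in_all_libraries"),
      excluded_not_expressed = n_excl("not_expressed"),
      candidates = sum(!integrated$excluded),
      reference_dependencies = length(callres$reference_dependencies),
      called_AD = length(callres$calls$calls$AD),
      called_SCLC = length(callres$calls$calls$SCLC),
      called_SCC = length(callres$calls$calls$SCC),
      called_union = length(annres$called_union),
      druggable = length(annres$druggable$druggable_genes)
    ),
    threshold = unclass(callres$threshold)
  )
  jsonlite::write_json(manifest, out_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = simres, fits = fits, call = callres,
                 annotate = annres, manifest = manifest))
}
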