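#' Guide-level screen counts with sample design
#'
#' Container for a guide x sample matrix of non-negative integer read counts
#' plus the sample design (line, timepoint T0/TF, replicate).
#'
#' @param counts Integer matrix, guides in rows, samples in columns.
#' @param design Data frame with columns `sample`, `line`, `timepoint`
#'   (`"T0"` or `"TF"`) and `replicate`.
#' @return A list of class `ScreenCounts`.
#' @export
screen_counts <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have guide ids as rownames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be non-negative integers; first offender: guide '",
         rownames(counts)[bad[1, 1]], "', sample '", colnames(counts)[bad[1, 2]],
         "' = ", counts[bad[1, , drop = FALSE]])
  }
  stopifnot(all(c("sample", "line", "timepoint", "replicate") %in% names(design)))
  if (!setequal(design$sample, colnames(counts))) {
    stop("design samples and count columns disagree")
  }
  if (!all(design$timepoint %in% c("T0", "TF"))) {
    stop("timepoint must be 'T0' or 'TF'")
  }
  design <- design[match(colnames(counts), design$sample), ]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "ScreenCounts")
}

#' @export
print.ScreenCounts <- function(x, ...) {
  cat("ScreenCounts:", nrow(x$counts), "guides x", ncol(x$counts), "samples (",
      length(unique(x$design$line)), "lines )\n")
  invisible(x)
}

# Parse "<line>_T0_r1" / "TF_rep2" style sample names into a design table.
parse_sample_names <- function(samples) {
  m <- regmatches(samples, regexec("^(?:(.*)_)?(T0|TF)_(?:rep|r)?([0-9]+)$", samples))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("cannot parse sample name(s): ", paste(samples[bad], collapse = ", "),
         " (expected <line>_T0_r<k> / <line>_TF_r<k>)")
  }
  data.frame(
    sample = samples,
    line = ifelse(vapply(m, `[`, "", 2L) == "", "line1", vapply(m, `[`, "", 2L)),
    timepoint = vapply(m, `[`, "", 3L),
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Read and write guide-count tables
#'
#' Tab-separated, columns `guide_id`, `gene_symbol`, then one column per
#' sample named `<line>_<T0|TF>_r<replicate>` (a missing line prefix denotes a
#' single-line screen). Counts must be non-negative integers; violations are
#' rejected with the offending address.
#'
#' @param path File path.
#' @return [read_counts_tsv()] returns a `ScreenCounts`; the writer returns
#'   `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("guide_id", "gene_symbol") %in% names(df)))
  samp <- setdiff(names(df), c("guide_id", "gene_symbol"))
  counts <- as.matrix(df[, samp, drop = FALSE])
  rownames(counts) <- df$guide_id
  if (!is.numeric(counts)) {
    nonnum <- which(!vapply(df[samp], is.numeric, TRUE))
    stop("non-numeric counts in column(s): ", paste(samp[nonnum], collapse = ", "))
  }
  sc <- screen_counts(counts, parse_sample_names(samp))
  attr(sc, "gene_symbol") <- setNames(df$gene_symbol, df$guide_id)
  sc
}

#' @rdname read_counts_tsv
#' @param counts A `ScreenCounts`.
#' @param gene_symbol Named character vector mapping guide ids to gene
#'   symbols (optional; defaults to the attribute carried by the object).
#' @export
write_counts_tsv <- function(counts, path, gene_symbol = NULL) {
  stopifnot(inherits(counts, "ScreenCounts"))
  gene_symbol <- gene_symbol %||% attr(counts, "gene_symbol") %||%
    setNames(rep(NA_character_, nrow(counts$counts)), rownames(counts$counts))
  df <- data.frame(
    guide_id = rownames(counts$counts),
    gene_symbol = unname(gene_symbol[rownames(counts$counts)]),
    counts$counts,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene-effect matrices in DepMap dialect
#'
#' The on-disk layout follows DepMap gene-effect exports: rows are cell
#' lines, the first column holds the line identifier, and gene columns are
#' headed `"SYMBOL (ENTREZ)"` (plain `"SYMBOL"` is accepted). Internally the
#' matrix is genes x lines. Missing cells are preserved as `NA`.
#'
#' @param path File path.
#' @return [read_gene_effect_csv()] returns a list of class
#'   `GeneEffectMatrix` with elements `effects` (genes x lines numeric
#'   matrix), `entrez` (named vector, `NA` where the header had no id) and
#'   `provenance`.
#' @export
read_gene_effect_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lines <- df[[1]]
  gcols <- names(df)[-1]
  parsed <- parse_gene_headers(gcols)
  if (anyDuplicated(parsed$symbol)) {
    dups <- unique(parsed$symbol[duplicated(parsed$symbol)])
    stop("duplicate gene column(s): ", paste(dups, collapse = ", "))
  }
  mat <- matrix(NA_real_, length(gcols), length(lines),
                dimnames = list(parsed$symbol, lines))
  for (j in seq_along(gcols)) {
    v <- df[[j + 1L]]
    if (!is.numeric(v) && !is.logical(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "" & toupper(v) != "NA")
      if (length(bad) > 0) {
        stop("non-numeric gene-effect cell at row ", bad[1],
             " (line '", lines[bad[1]], "'), column '", gcols[j], "'")
      }
      v <- vn
    }
    mat[j, ] <- as.numeric(v)
  }
  gene_effect_matrix(mat, entrez = setNames(parsed$entrez, parsed$symbol),
                     provenance = basename(path))
}

parse_gene_headers <- function(headers) {
  m <- regmatches(headers, regexec("^(.+?) \\(([0-9]+)\\)$", headers))
  symbol <- vapply(seq_along(headers), function(i) {
    if (length(m[[i]]) == 3L) m[[i]][2L] else headers[i]
  }, character(1))
  entrez <- vapply(seq_along(headers), function(i) {
    if (length(m[[i]]) == 3L) as.integer(m[[i]][3L]) else NA_integer_
  }, integer(1))
  list(symbol = symbol, entrez = entrez)
}

#' Construct a gene-effect matrix container
#'
#' @param effects Numeric genes x lines matrix.
#' @param entrez Optional named integer vector of Entrez ids.
#' @param histotype Optional named character vector of per-line histotypes.
#' @param provenance Free-text label (library/release).
#' @return A list of class `GeneEffectMatrix`.
#' @export
gene_effect_matrix <- function(effects, entrez = NULL, histotype = NULL,
                               provenance = "unspecified") {
  effects <- as.matrix(effects)
  if (is.null(rownames(effects)) || is.null(colnames(effects))) {
    stop("effects needs gene rownames and line colnames")
  }
  if (anyDuplicated(rownames(effects))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(effects))) stop("duplicate line identifiers")
  if (any(is.infinite(effects))) stop("effects must be finite (NA allowed)")
  structure(list(effects = effects, entrez = entrez, histotype = histotype,
                 provenance = provenance),
            class = "GeneEffectMatrix")
}

#' @export
print.GeneEffectMatrix <- function(x, ...) {
  cat("GeneEffectMatrix:", nrow(x$effects), "genes x", ncol(x$effects),
      "lines [", x$provenance, "]\n")
  invisible(x)
}

#' @rdname read_gene_effect_csv
#' @param x A `GeneEffectMatrix`.
#' @export
write_gene_effect_csv <- function(x, path) {
  stopifnot(inherits(x, "GeneEffectMatrix"))
  headers <- rownames(x$effects)
  if (!is.null(x$entrez)) {
    ent <- x$entrez[headers]
    headers <- ifelse(is.na(ent), headers, sprintf("%s (%d)", headers, ent))
  }
  df <- data.frame(line = colnames(x$effects), t(x$effects),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("line", headers)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings that return plain named character vectors.
#' Line-wrapped records are concatenated; an empty file is an error.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path)
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a DGIdb-style drug-gene interaction table
#'
#' Tab-separated with columns `gene_symbol` (or `gene`), `drug_name` (or
#' `drug`), `interaction_type`, optionally `category` and `source`.
#' Interaction modes are lower-cased on ingest; rows missing the gene or the
#' drug are skipped with a warning. Categories, when present, must come from
#' the closed five-value curation vocabulary (see [drug_categories()]).
#'
#' @param path File path.
#' @return Data frame of class `DrugGeneTable`.
#' @export
read_interactions_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "gene"] <- "gene_symbol"
  names(df)[names(df) == "drug"] <- "drug_name"
  stopifnot(all(c("gene_symbol", "drug_name", "interaction_type") %in% names(df)))
  if (!"category" %in% names(df)) df$category <- NA_character_
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$interaction_type <- tolower(df$interaction_type)
  df$category[df$category == ""] <- NA_character_
  incomplete <- is.na(df$gene_symbol) | df$gene_symbol == "" |
    is.na(df$drug_name) | df$drug_name == ""
  if (any(incomplete)) {
    warning(sum(incomplete), " interaction row(s) missing gene or drug; skipped")
    df <- df[!incomplete, ]
  }
  bad_cat <- !is.na(df$category) & !(df$category %in% drug_categories())
  if (any(bad_cat)) {
    stop("unknown drug category: ", paste(unique(df$category[bad_cat]), collapse = "; "))
  }
  rownames(df) <- NULL
  class(df) <- c("DrugGeneTable", "data.frame")
  df
}

#' @rdname read_interactions_tsv
#' @param table A `DrugGeneTable` data frame.
#' @export
write_interactions_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell-line histotype annotations
#'
#' CSV with columns `line` and `histotype`. Labels outside AD/SCLC/SCC are
#' retained (they pass through to the output map) but trigger a warning and
#' are excluded from histotype calling downstream.
#'
#' @param path File path.
#' @return Named character vector: line -> histotype.
#' @export
read_sample_info <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "histotype") %in% names(df)))
  unknown <- setdiff(unique(df$histotype), c("AD", "SCLC", "SCC"))
  if (length(unknown) > 0) {
    warning("unknown histotype label(s) retained but not callable: ",
            paste(unknown, collapse = ", "))
  }
  setNames(df$histotype, df$line)
}

#' @rdname read_sample_info
#' @param histotypes Named character vector.
#' @export
write_sample_info <- function(histotypes, path) {
  utils::write.csv(
    data.frame(line = names(histotypes), histotype = unname(histotypes)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write gene x line numeric matrices (copy number, TPM)
#'
#' Plain CSV, genes in rows (first column `gene`), lines in columns.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_gene_matrix_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric values in ", path)
  rownames(mat) <- df[[1]]
  mat
}

#' @rdname read_gene_matrix_csv
#' @param mat Numeric matrix, genes x lines.
#' @export
write_gene_matrix_csv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GMT pathway collections
#'
#' Standard GMT: one pathway per line, tab-separated `id`, `description`,
#' member genes. Empty pathways are rejected.
#'
#' @param path File path.
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  members <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(members) == 0)) {
    stop("empty pathway in GMT: ", paste(ids[lengths(members) == 0], collapse = ", "))
  }
  setNames(members, ids)
}

#' @rdname read_gmt
#' @param pathways Named list of gene vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, id, pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
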