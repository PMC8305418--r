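#' Map guides to coding sequences by exact 20-mer matching
#'
#' A guide maps to a CDS record if and only if its 20-mer occurs exactly in
#' the CDS sequence (strand `+`) or its reverse complement does (strand `-`).
#' All occurrences are recorded; a guide may hit several genes and is then
#' treated as multi-target downstream. Guides with zero hits are flagged
#' unmapped (a state, not an error) and excluded from fitting.
#'
#' Offsets are 0-based into the CDS sequence.
#'
#' @param library Guide library data frame with columns `guide_id`,
#'   `sequence` (20-nt uppercase ACGT), `declared_gene`, `semi_library`.
#' @param catalog CDS catalog data frame with columns `gene_symbol`,
#'   `cds_index`, `sequence` (one row per CDS record).
#' @return A data frame of class `GuideMap` with columns `guide_id`,
#'   `gene_symbol`, `cds_index`, `offset`, `strand`; unmapped guide ids are
#'   carried in `attr(, "unmapped")`.
#' @export
map_guides <- function(library, catalog) {
  stopifnot(nrow(library) > 0, nrow(catalog) > 0)
  if (anyDuplicated(library$guide_id)) stop("guide_id must be unique")
  if (!all(grepl("^[ACGT]{20}$", library$sequence))) {
    stop("guide sequences must be 20-nt uppercase ACGT")
  }
  guides <- Biostrings::DNAStringSet(setNames(library$sequence, library$guide_id))
  pd_fwd <- Biostrings::PDict(guides)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(guides))

  hits <- vector("list", nrow(catalog) * 2L)
  for (j in seq_len(nrow(catalog))) {
    subj <- Biostrings::DNAString(catalog$sequence[j])
    for (dir in 1:2) {
      m <- Biostrings::matchPDict(if (dir == 1) pd_fwd else pd_rev, subj)
      starts <- Biostrings::startIndex(m)
      hit <- which(lengths(starts) > 0)
      if (length(hit) > 0) {
        hits[[(j - 1L) * 2L + dir]] <- data.frame(
          guide_id = rep(library$guide_id[hit], lengths(starts)[hit]),
          gene_symbol = catalog$gene_symbol[j],
          cds_index = catalog$cds_index[j] %||% 1L,
          offset = unlist(starts[hit]) - 1L,
          strand = if (dir == 1) "+" else "-",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  map <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(map)) {
    map <- data.frame(guide_id = character(0), gene_symbol = character(0),
                      cds_index = integer(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  }
  map <- map[order(map$guide_id, map$gene_symbol, map$offset), ]
  rownames(map) <- NULL
  unmapped <- setdiff(library$guide_id, map$guide_id)
  if (length(unmapped) > 0) {
    sd_log(length(unmapped), " guide(s) unmapped; excluded from fitting")
  }
  attr(map, "unmapped") <- unmapped
  class(map) <- c("GuideMap", "data.frame")
  map
}

# guide -> unique target gene sets (one entry per mapped guide)
guide_targets <- function(map) {
  split(map$gene_symbol, map$guide_id) |> lapply(unique)
}
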