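## Assembly of drug-target and disease-target gene sets, their common
## intersection, pathway labelling, and the compound display-alias scheme.

#' Drug target set from compound-target associations
#'
#' Keeps genes with at least one association probability strictly greater
#' than `minProbability` (applied per association, not per aggregated
#' gene).
#'
#' @param assocs `data.frame` with columns `gene` and `probability`.
#' @param minProbability Inclusion threshold (default 0.8, strict).
#' @return Sorted character vector of unique gene symbols.
#' @export
drugTargets <- function(assocs, minProbability = 0.8) {
  if (!nrow(assocs)) return(character())
  if (any(assocs$probability < 0 | assocs$probability > 1, na.rm = TRUE))
    stop("association probabilities must lie in [0, 1]")
  keep <- assocs$probability > minProbability
  sort(unique(canonicalizeSymbols(assocs$gene[keep])))
}

#' Disease target set from scored database records
#'
#' GeneCards-style records are stably sorted by score (descending, ties by
#' gene symbol ascending) and the top `ceiling(fraction * N)` genes kept;
#' the result is unioned with every DisGeNET-style record.
#'
#' @param records `data.frame` with columns `gene`, `score`, `source`
#'   (values `"genecards"` or `"disgenet"`).
#' @param genecardsTopFraction Fraction of the score-ranked GeneCards list
#'   to keep, in (0, 1\] (default 0.5).
#' @return Sorted character vector of unique gene symbols.
#' @export
diseaseTargets <- function(records, genecardsTopFraction = 0.5) {
  if (genecardsTopFraction <= 0 || genecardsTopFraction > 1)
    stop("genecardsTopFraction must lie in (0, 1]")
  records$gene <- canonicalizeSymbols(records$gene)
  gc <- records[records$source == "genecards", , drop = FALSE]
  dg <- records[records$source == "disgenet", , drop = FALSE]
  kept <- character()
  if (nrow(gc)) {
    gc <- gc[order(-gc$score, gc$gene), , drop = FALSE]
    kept <- gc$gene[seq_len(ceiling(genecardsTopFraction * nrow(gc)))]
  }
  sort(unique(c(kept, dg$gene)))
}

#' Common targets of drug and disease
#'
#' @param drug,disease Character vectors of gene symbols.
#' @return Sorted intersection; an empty intersection raises a warning
#'   (downstream network stages then have nothing to work on).
#' @export
commonTargets <- function(drug, disease) {
  common <- sort(intersect(canonicalizeSymbols(drug),
                           canonicalizeSymbols(disease)))
  if (!length(common))
    warning("drug and disease target sets are disjoint")
  common
}

#' Label common targets with their pathway memberships
#'
#' @param common Character vector of genes.
#' @param pathways List of [GeneSet-class] objects.
#' @return List with `labels` (named list mapping every common gene to the
#'   character vector of pathway ids containing it, possibly empty) and
#'   `counts` (named integer vector of per-pathway member counts among
#'   `common`).
#' @export
labelPathwayMembers <- function(common, pathways) {
  common <- canonicalizeSymbols(common)
  ids <- vapply(pathways, function(p) p@id, "")
  labels <- lapply(common, function(g)
    ids[vapply(pathways, function(p) g %in% p@genes, FALSE)])
  names(labels) <- common
  counts <- vapply(pathways, function(p)
    length(intersect(common, p@genes)), 0L)
  names(counts) <- ids
  list(labels = labels, counts = counts)
}

#' Assign display aliases to compounds
#'
#' Compounds occurring in two or more herbs receive single capital letters
#' A, B, C, ... assigned in order of descending herb count then compound id;
#' herb-unique compounds receive the herb abbreviation plus a 1-based index
#' in compound-id order within each herb.
#'
#' @param compounds `data.frame` with columns `compound_id` and `herb_ids`
#'   (semicolon-separated herb codes).
#' @param herbCodes Optional named character vector mapping herb codes to
#'   display abbreviations; defaults to the codes themselves.
#' @param extendLetters Allow double letters (AA, AB, ...) when more than
#'   26 shared compounds exist (default `FALSE`, which errors instead).
#' @return `data.frame` with columns `compound_id`, `label`, `n_herbs`.
#' @export
assignAliases <- function(compounds, herbCodes = NULL,
                          extendLetters = FALSE) {
  herbs <- strsplit(compounds$herb_ids, ";", fixed = TRUE)
  herbs <- lapply(herbs, function(h) unique(trimws(h)))
  if (any(vapply(herbs, length, 0L) == 0))
    stop("compound without herb membership")
  allHerbs <- sort(unique(unlist(herbs)))
  if (is.null(herbCodes))
    herbCodes <- stats::setNames(allHerbs, allHerbs)
  miss <- setdiff(allHerbs, names(herbCodes))
  if (length(miss))
    stop("no abbreviation for herb(s): ", paste(miss, collapse = ", "))
  nHerbs <- vapply(herbs, length, 0L)
  shared <- which(nHerbs >= 2)
  shared <- shared[order(-nHerbs[shared], compounds$compound_id[shared])]
  if (length(shared) > 26 && !extendLetters)
    stop("more than 26 shared compounds; enable extendLetters")
  letterPool <- c(LETTERS,
                  as.vector(t(outer(LETTERS, LETTERS, paste0))))
  label <- character(nrow(compounds))
  label[shared] <- letterPool[seq_along(shared)]
  for (h in allHerbs) {
    uniq <- which(nHerbs == 1 & vapply(herbs, `[`, "", 1) == h)
    uniq <- uniq[order(compounds$compound_id[uniq])]
    label[uniq] <- paste0(herbCodes[[h]], seq_along(uniq))
  }
  if (anyDuplicated(label))
    stop("alias labels are not unique; check herb abbreviations")
  data.frame(compound_id = compounds$compound_id, label = label,
             n_herbs = nHerbs, stringsAsFactors = FALSE)
}
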