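## Rule-based ADMET screen: oral potential (oral bioavailability or
## Lipinski's rule of five) plus Caco-2 permeability, drug-likeness and
## half-life, all strict inequalities. Toxicity labels are consumed as a
## prediction table and summarized, never filtered on.

.requireColumns <- function(compounds, cols) {
  missing <- setdiff(cols, names(compounds))
  if (length(missing))
    stop("missing descriptor(s): ", paste(missing, collapse = ", "))
  for (col in cols)
    if (any(is.na(compounds[[col]])))
      stop("missing values in descriptor '", col, "'")
}

#' Lipinski rule-of-five compliance
#'
#' Counts violations among MW > 500 Da, AlogP > 5, H-bond donors > 5 and
#' H-bond acceptors > 10. By the original convention a compound complies
#' when it has at most one violation; set `maxViolations = 0` for the
#' strict variant.
#'
#' @param compounds `data.frame` with columns `mw`, `alogp`, `h_donors`,
#'   `h_acceptors` (one row per compound).
#' @param maxViolations Maximum tolerated violation count (default 1).
#' @return Logical vector, one element per row.
#' @export
#' @examples
#' passesRo5(data.frame(mw = 400, alogp = 3, h_donors = 2, h_acceptors = 5))
passesRo5 <- function(compounds, maxViolations = 1) {
  .requireColumns(compounds, c("mw", "alogp", "h_donors", "h_acceptors"))
  v <- (compounds$mw > 500) + (compounds$alogp > 5) +
    (compounds$h_donors > 5) + (compounds$h_acceptors > 10)
  v <= maxViolations
}

#' Oral-potential and drug-likeness screen
#'
#' A compound passes when it has oral potential (oral bioavailability
#' strictly above `obCutoff` percent, or rule-of-five compliant) and
#' additionally Caco-2 permeability > `caco2Cutoff`, drug-likeness >
#' `dlCutoff` and half-life > `halfLifeCutoff` hours. All comparisons are
#' strict.
#'
#' @param compounds `data.frame` with columns `ob`, `caco2`, `dl`,
#'   `half_life` plus the rule-of-five descriptors.
#' @param obCutoff,caco2Cutoff,dlCutoff,halfLifeCutoff Screen thresholds
#'   (defaults 30, 0.4, 0.18, 3).
#' @param maxViolations Passed to [passesRo5()].
#' @return Logical vector, one element per row.
#' @export
passesScreen <- function(compounds, obCutoff = 30, caco2Cutoff = 0.4,
                         dlCutoff = 0.18, halfLifeCutoff = 3,
                         maxViolations = 1) {
  .requireColumns(compounds, c("ob", "caco2", "dl", "half_life"))
  oral <- compounds$ob > obCutoff | passesRo5(compounds, maxViolations)
  oral & compounds$caco2 > caco2Cutoff & compounds$dl > dlCutoff &
    compounds$half_life > halfLifeCutoff
}

#' Screen a compound table
#'
#' Applies [passesScreen()] and reports, per criterion, how many compounds
#' failed it (a compound failing several criteria is counted once in each).
#'
#' @inheritParams passesScreen
#' @return List with `kept` (the passing rows, input order preserved) and
#'   `report` (named integer vector of per-criterion failure counts:
#'   `oral_potential`, `caco2`, `dl`, `half_life`).
#' @export
screenCompounds <- function(compounds, obCutoff = 30, caco2Cutoff = 0.4,
                            dlCutoff = 0.18, halfLifeCutoff = 3,
                            maxViolations = 1) {
  if (!nrow(compounds))
    return(list(kept = compounds,
                report = c(oral_potential = 0L, caco2 = 0L, dl = 0L,
                           half_life = 0L)))
  keep <- passesScreen(compounds, obCutoff, caco2Cutoff, dlCutoff,
                       halfLifeCutoff, maxViolations)
  oral <- compounds$ob > obCutoff | passesRo5(compounds, maxViolations)
  report <- c(oral_potential = sum(!oral),
              caco2 = sum(!(compounds$caco2 > caco2Cutoff)),
              dl = sum(!(compounds$dl > dlCutoff)),
              half_life = sum(!(compounds$half_life > halfLifeCutoff)))
  list(kept = compounds[keep, , drop = FALSE],
       report = vapply(report, as.integer, 0L))
}

#' Count active toxicity predictions per endpoint
#'
#' @param compounds `data.frame` with one column per toxicity endpoint
#'   (hepatotoxicity, carcinogenicity, immunotoxicity, mutagenicity,
#'   cytotoxicity, cardiotoxicity) holding `"active"` / `"inactive"`
#'   labels. Absent endpoint columns are reported as zero.
#' @return `data.frame` with columns `endpoint` and `n_active`; every
#'   endpoint always present.
#' @export
summarizeToxicity <- function(compounds) {
  counts <- integer(length(.toxEndpoints))
  names(counts) <- .toxEndpoints
  for (ep in .toxEndpoints) {
    if (!ep %in% names(compounds)) next
    lab <- compounds[[ep]]
    bad <- setdiff(unique(lab[!is.na(lab)]), c("active", "inactive"))
    if (length(bad))
      stop("unknown toxicity label(s) for ", ep, ": ",
           paste(bad, collapse = ", "))
    counts[ep] <- sum(lab == "active", na.rm = TRUE)
  }
  data.frame(endpoint = .toxEndpoints, n_active = unname(counts),
             stringsAsFactors = FALSE)
}
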