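## Post-processing of molecular docking records: the binding-energy to
## inhibition-constant conversion and range/per-receptor summaries. No
## docking is executed here; records arrive as a table.

#' Inhibition constant from binding free energy
#'
#' `Ki = exp(dG / (R T))` with the gas constant in calorie units
#' (R = 1.98720 cal mol^-1 K^-1) and `dG` in kcal/mol, the AutoDock
#' reporting convention; the molar result is returned on the micromolar
#' scale. Strictly increasing in `dG`: stronger (more negative) binding
#' gives a smaller constant.
#'
#' @param deltaG Binding free energy in kcal/mol (vectorized).
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @return Inhibition constant in micromoles per litre.
#' @export
#' @examples
#' kiFromEnergy(-8.26)  # about 0.88
kiFromEnergy <- function(deltaG, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive")
  R <- 1.98720  # cal / (mol K)
  1e6 * exp(deltaG * 1000 / (R * temperature))
}

#' Read a docking-record table
#'
#' @param path Tab-separated file with columns `receptor`, `ligand`,
#'   `delta_g` (kcal/mol) and optionally `ki_reported`.
#' @param temperature Passed to [kiFromEnergy()].
#' @return `data.frame` with a computed `ki` column (micromolar) added.
#' @export
readDockingTable <- function(path, temperature = 298.15) {
  schema <- tableSchema("docking",
                        c(receptor = "text", ligand = "text",
                          delta_g = "number"))
  df <- readTable(path, schema)
  df$receptor <- canonicalizeSymbols(df$receptor)
  df$ki <- kiFromEnergy(df$delta_g, temperature)
  df
}

#' Summarize docking records
#'
#' Reports the binding-energy and inhibition-constant extrema, flags
#' stable dockings (binding free energy below `stableCutoff`, default
#' -5 kcal/mol), and identifies the best (lowest-energy) ligand per
#' receptor.
#'
#' @param records `data.frame` with columns `receptor`, `ligand`,
#'   `delta_g`, and optionally `ki` (computed when absent).
#' @param stableCutoff Stability threshold on `delta_g` (strict `<`).
#' @param temperature Passed to [kiFromEnergy()] when `ki` is absent.
#' @return List with `min_delta_g`, `max_delta_g`, `min_ki`, `max_ki`,
#'   `n_stable`, `records` (input plus `stable` flag) and
#'   `best_per_receptor`.
#' @export
summarizeDocking <- function(records, stableCutoff = -5,
                             temperature = 298.15) {
  if (!nrow(records)) stop("no docking records")
  if (!"ki" %in% names(records))
    records$ki <- kiFromEnergy(records$delta_g, temperature)
  records$stable <- records$delta_g < stableCutoff
  best <- do.call(rbind, lapply(split(records, records$receptor),
                                function(d) d[which.min(d$delta_g), ]))
  best <- best[order(best$delta_g), , drop = FALSE]
  rownames(best) <- NULL
  list(min_delta_g = min(records$delta_g),
       max_delta_g = max(records$delta_g),
       min_ki = min(records$ki), max_ki = max(records$ki),
       n_stable = sum(records$stable),
       records = records, best_per_receptor = best)
}
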