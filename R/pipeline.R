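## End-to-end orchestration: one YAML config drives every stage in the
## fixed order screen -> targets -> networks -> complexes / diffusion /
## proximity / enrichment -> docking summary, writing a JSON manifest that
## records the parameters and seed behind every artifact.

.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    output_dir = "netpharm_out",
    simulate = list(),     # syntheticConfig() overrides; NULL disables
    inputs = NULL,         # alternative: named file paths
    screen = list(ob = 30, caco2 = 0.4, dl = 0.18, half_life = 3,
                  max_ro5_violations = 1),
    targets = list(min_probability = 0.8, genecards_top_fraction = 0.5),
    network = list(min_confidence = 0.4),
    mcode = list(degree_cutoff = 2, node_score_cutoff = 0.2, k_core = 2,
                 haircut = TRUE, fluff = FALSE),
    rwr = list(restart = 0.7, top_k = 10),
    proximity = list(null_groups = 50),
    enrichment = list(p_cutoff = 0.005),
    cluster = list(n_clusters = 4),
    docking = list(temperature = 298.15, table = NULL)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.loadConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .mergeConfig(.defaultPipelineConfig(), config)
}

#' Validate a pipeline configuration
#'
#' @param config Path to a YAML config file, or a config list.
#' @return Character vector of problems; empty when the config is
#'   runnable.
#' @export
validateConfig <- function(config) {
  cfg <- .loadConfig(config)
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
        cfg$seed == round(cfg$seed), "seed: must be a single integer")
  chk(is.character(cfg$output_dir) && nzchar(cfg$output_dir),
      "output_dir: must be a non-empty path")
  r <- cfg$rwr$restart
  chk(is.numeric(r) && r > 0 && r <= 1,
      "rwr.restart: must lie in (0, 1]")
  chk(cfg$rwr$top_k >= 1, "rwr.top_k: must be >= 1")
  f <- cfg$targets$genecards_top_fraction
  chk(is.numeric(f) && f > 0 && f <= 1,
      "targets.genecards_top_fraction: must lie in (0, 1]")
  p <- cfg$targets$min_probability
  chk(is.numeric(p) && p >= 0 && p <= 1,
      "targets.min_probability: must lie in [0, 1]")
  mc <- cfg$network$min_confidence
  chk(is.numeric(mc) && mc >= 0 && mc < 1,
      "network.min_confidence: must lie in [0, 1)")
  chk(cfg$mcode$degree_cutoff >= 2, "mcode.degree_cutoff: must be >= 2")
  nsc <- cfg$mcode$node_score_cutoff
  chk(is.numeric(nsc) && nsc >= 0 && nsc <= 1,
      "mcode.node_score_cutoff: must lie in [0, 1]")
  pc <- cfg$enrichment$p_cutoff
  chk(is.numeric(pc) && pc > 0 && pc <= 1,
      "enrichment.p_cutoff: must lie in (0, 1]")
  chk(cfg$proximity$null_groups >= 1,
      "proximity.null_groups: must be >= 1")
  chk(cfg$cluster$n_clusters >= 1, "cluster.n_clusters: must be >= 1")
  chk(cfg$docking$temperature > 0,
      "docking.temperature: must be positive")
  if (is.null(cfg$simulate)) {
    needed <- c("compound_table", "associations", "disease_genes",
                "edge_list")
    if (is.null(cfg$inputs)) {
      problems <- c(problems,
                    "inputs: required when simulation is disabled")
    } else {
      for (nm in needed) {
        path <- cfg$inputs[[nm]]
        if (is.null(path))
          problems <- c(problems, paste0("inputs.", nm, ": missing"))
        else if (!file.exists(path))
          problems <- c(problems,
                        paste0("inputs.", nm, ": file not found (", path,
                               ")"))
      }
    }
  }
  if (!is.null(cfg$docking$table) && !file.exists(cfg$docking$table))
    problems <- c(problems, "docking.table: file not found")
  problems
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order on either simulated inputs
#' (default) or user-supplied tables, writing all artifacts under
#' `output_dir` along with a `manifest.json` recording the seed, the stage
#' parameters, and an MD5 checksum of every file produced. Re-running with
#' an identical config reproduces every artifact.
#'
#' @param config Path to a YAML config, or a config list; see
#'   [validateConfig()] for the recognised fields. A minimal call
#'   `runPipeline(list(output_dir = tempdir()))` simulates everything.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  cfg <- .loadConfig(config)
  seed <- as.integer(cfg$seed)
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message("[netpharm] ", ...)
  artifacts <- character()
  keep <- function(path) artifacts <<- c(artifacts, path)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    note(name, " (", format(Sys.time() - t0, digits = 2), ")")
    res
  }

  ## ---- inputs -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    syn <- do.call(syntheticConfig, c(list(seed = seed), cfg$simulate))
    inputs <- stage("simulate", {
      compounds <- genCompoundTable(syn)
      ppi <- genPPI(syn)
      list(compounds = compounds, ppi = ppi,
           assocs = genTargetAssociations(syn),
           disease = genDiseaseGenes(syn),
           regulations = genRegulationTable(syn), syn = syn)
    })
    indir <- file.path(outdir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    keep(.writeTSV(inputs$compounds, file.path(indir, "compounds.tsv")))
    keep(.writeTSV(edgeTable(inputs$ppi$network),
                   file.path(indir, "ppi_edges.tsv")))
    keep(.writeTSV(inputs$assocs, file.path(indir, "associations.tsv")))
    keep(.writeTSV(inputs$disease,
                   file.path(indir, "disease_genes.tsv")))
    keep(.writeTSV(inputs$regulations,
                   file.path(indir, "regulations.tsv")))
    fullNetwork <- inputs$ppi$network
    edges <- edgeTable(fullNetwork)
    names(edges) <- c("node_a", "node_b", "confidence")
  } else {
    inputs <- stage("read inputs", {
      list(compounds = utils::read.delim(cfg$inputs$compound_table,
                                         stringsAsFactors = FALSE),
           assocs = utils::read.delim(cfg$inputs$associations,
                                      stringsAsFactors = FALSE),
           disease = utils::read.delim(cfg$inputs$disease_genes,
                                       stringsAsFactors = FALSE),
           regulations = if (!is.null(cfg$inputs$regulations))
             utils::read.delim(cfg$inputs$regulations,
                               stringsAsFactors = FALSE))
    })
    edges <- readEdgeList(cfg$inputs$edge_list)
    fullNetwork <- buildNetwork(edges,
                                minConfidence = cfg$network$min_confidence)
  }

  ## ---- screen -------------------------------------------------------
  scr <- stage("screen", screenCompounds(
    inputs$compounds, obCutoff = cfg$screen$ob,
    caco2Cutoff = cfg$screen$caco2, dlCutoff = cfg$screen$dl,
    halfLifeCutoff = cfg$screen$half_life,
    maxViolations = cfg$screen$max_ro5_violations))
  keep(.writeTSV(scr$kept, file.path(outdir, "compounds_kept.tsv")))
  keep(.writeJSON(list(fail_counts = as.list(scr$report),
                       n_in = nrow(inputs$compounds),
                       n_kept = nrow(scr$kept)),
                  file.path(outdir, "screen_report.json")))
  tox <- summarizeToxicity(scr$kept)
  keep(.writeTSV(tox, file.path(outdir, "toxicity_summary.tsv")))

  ## ---- targets ------------------------------------------------------
  assocKept <- inputs$assocs[
    inputs$assocs$compound_id %in% scr$kept$compound_id, , drop = FALSE]
  drug <- stage("drug targets",
                drugTargets(assocKept, cfg$targets$min_probability))
  disease <- stage("disease targets",
                   diseaseTargets(inputs$disease,
                                  cfg$targets$genecards_top_fraction))
  common <- commonTargets(drug, disease)
  keep(.writeTSV(data.frame(gene = drug),
                 file.path(outdir, "drug_targets.tsv")))
  keep(.writeTSV(data.frame(gene = disease),
                 file.path(outdir, "disease_targets.tsv")))
  keep(.writeTSV(data.frame(gene = common),
                 file.path(outdir, "common_targets.tsv")))
  aliases <- assignAliases(scr$kept)
  keep(.writeTSV(aliases, file.path(outdir, "compound_aliases.tsv")))
  ranking <- compoundDegreeRanking(assocKept[
    assocKept$probability > cfg$targets$min_probability, , drop = FALSE],
    common, aliases)
  keep(.writeTSV(ranking, file.path(outdir, "compound_degrees.tsv")))

  ## ---- network topology --------------------------------------------
  net <- stage("network", {
    n <- buildNetwork(edges, minConfidence = cfg$network$min_confidence)
    keep(writeGraphFile(n, file.path(outdir, "network.graphml")))
    n
  })
  commonNet <- buildNetwork(edges,
                            minConfidence = cfg$network$min_confidence,
                            restrictTo = common)
  statsNet <- if (numEdges(commonNet) > 0) commonNet else net
  cent <- centralities(statsNet)
  keep(.writeTSV(cent, file.path(outdir, "centralities.tsv")))
  key <- keyTargets(cent)
  keep(.writeTSV(data.frame(gene = key),
                 file.path(outdir, "key_targets.tsv")))
  keep(.writeJSON(list(n_nodes = numNodes(statsNet),
                       n_edges = numEdges(statsNet),
                       average_degree = averageDegree(statsNet),
                       average_clustering = averageClustering(statsNet),
                       n_key_targets = length(key)),
                  file.path(outdir, "network_stats.json")))

  if (!is.null(inputs$regulations) && length(common)) {
    tf <- tfSubnetwork(inputs$regulations, common)
    keep(.writeTSV(tf$edges, file.path(outdir, "tf_subnetwork.tsv")))
  }

  ## ---- MCODE --------------------------------------------------------
  cx <- stage("mcode", mcodeFindComplexes(
    net, degreeCutoff = cfg$mcode$degree_cutoff,
    nodeScoreCutoff = cfg$mcode$node_score_cutoff,
    kCore = cfg$mcode$k_core, haircut = cfg$mcode$haircut,
    fluff = cfg$mcode$fluff))
  cxdf <- if (length(cx)) {
    data.frame(rank = seq_along(cx),
               seed = vapply(cx, function(x) x@seed, ""),
               score = vapply(cx, function(x) x@score, 0),
               n_members = vapply(cx, function(x) length(x@members), 0L),
               members = vapply(cx, function(x)
                 paste(x@members, collapse = ";"), ""))
  } else {
    data.frame(rank = integer(), seed = character(), score = numeric(),
               n_members = integer(), members = character())
  }
  keep(.writeTSV(cxdf, file.path(outdir, "mcode_complexes.tsv")))

  ## ---- diffusion ----------------------------------------------------
  seeds <- intersect(common, networkNodes(net))
  if (length(seeds)) {
    dres <- stage("rwr", rwr(net, seeds, restart = cfg$rwr$restart))
    sc <- scores(dres)
    keep(.writeTSV(data.frame(gene = names(sc), score = unname(sc)),
                   file.path(outdir, "rwr_scores.tsv")))
    cand <- topCandidates(dres, k = cfg$rwr$top_k)
    keep(.writeTSV(cand, file.path(outdir, "rwr_candidates.tsv")))
  } else {
    cand <- NULL
  }

  ## ---- proximity ----------------------------------------------------
  setA <- intersect(drug, networkNodes(net))
  setB <- intersect(disease, networkNodes(net))
  if (length(setA) >= 2 && length(setB) >= 2) {
    prox <- stage("proximity", proximityWithNull(
      net, setA, setB, nGroups = cfg$proximity$null_groups,
      seed = seed + 1L, onUnreachable = "drop"))
    keep(.writeJSON(list(s_ab = prox@s_ab, d_ab = prox@d_ab,
                         d_aa = prox@d_aa, d_bb = prox@d_bb,
                         null_mean = prox@null_mean,
                         null_sd = prox@null_sd, n_null = prox@n_null),
                    file.path(outdir, "proximity.json")))
  }

  ## ---- enrichment ---------------------------------------------------
  if (!is.null(cfg$simulate)) {
    gs <- genGeneSets(inputs$syn, query = common)
    terms <- gs$sets
  } else if (!is.null(cfg$inputs$gene_sets)) {
    terms <- readGMT(cfg$inputs$gene_sets)
  } else {
    terms <- NULL
  }
  if (!is.null(terms) && length(common)) {
    enrUniverse <- if (!is.null(cfg$simulate)) networkNodes(net)
    enr <- stage("enrichment",
                 enrich(common, terms, universe = enrUniverse,
                        pCutoff = cfg$enrichment$p_cutoff))
    keep(.writeTSV(enr, file.path(outdir, "enrichment.tsv")))
  }

  ## ---- correlation clustering --------------------------------------
  if (!is.null(cand) && nrow(cand) >= cfg$cluster$n_clusters &&
      !is.null(cfg$simulate)) {
    cm <- genCorrelationMatrix(inputs$syn, cand$gene)
    cl <- correlationClusters(cm, nClusters = cfg$cluster$n_clusters)
    keep(.writeTSV(data.frame(gene = names(cl), cluster = unname(cl)),
                   file.path(outdir, "gene_clusters.tsv")))
  }

  ## ---- docking summary ---------------------------------------------
  dockPath <- cfg$docking$table
  if (is.null(dockPath))
    dockPath <- system.file("extdata", "docking_records.tsv",
                            package = "netpharm")
  if (nzchar(dockPath) && file.exists(dockPath)) {
    dock <- readDockingTable(dockPath,
                             temperature = cfg$docking$temperature)
    ds <- stage("docking", summarizeDocking(
      dock, temperature = cfg$docking$temperature))
    keep(.writeTSV(ds$records, file.path(outdir, "docking_ki.tsv")))
    keep(.writeJSON(list(min_delta_g = ds$min_delta_g,
                         max_delta_g = ds$max_delta_g,
                         min_ki = ds$min_ki, max_ki = ds$max_ki,
                         n_stable = ds$n_stable,
                         n_records = nrow(ds$records)),
                    file.path(outdir, "docking_summary.json")))
  }

  ## ---- manifest -----------------------------------------------------
  manifest <- list(
    seed = seed,
    parameters = cfg[setdiff(names(cfg), c("inputs", "output_dir"))],
    artifacts = lapply(artifacts, function(p)
      list(file = basename(p),
           md5 = unname(tools::md5sum(p)))))
  .writeJSON(manifest, file.path(outdir, "manifest.json"))
  note("wrote ", length(artifacts), " artifacts to ", outdir)
  invisible(manifest)
}
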