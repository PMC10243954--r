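## Synthetic-data generators. Every pipeline input can be simulated with
## planted structure (dense clique, proximal gene-set pair, enriched term,
## correlation blocks) so downstream stages have a known ground truth.

#' Configuration for the synthetic-data generators
#'
#' @slot seed Integer master seed; every generator derives a fixed child
#'   seed from it, so the whole fixture is reproducible from one number.
#' @slot n_compounds,n_herbs,n_genes Counts of simulated entities.
#' @slot pass_fraction Fraction of compounds built to satisfy the ADMET
#'   screen (per-compound Bernoulli; exactly all/none at 1/0).
#' @slot n_edges_per_node Preferential-attachment edges added per node.
#' @slot clique_size Size of the dense clique planted on low-degree nodes.
#' @slot proximal_set_size Size of the planted gene sets A, B_near, B_far.
#' @slot n_terms,term_size_min,term_size_max Gene-set collection shape.
#' @slot enrichment_strength Sampling weight multiplier for query genes in
#'   the single planted enriched term (1 = no planting).
#' @slot correlation_blocks,block_correlation Block structure of the
#'   simulated co-expression correlation matrix.
#' @slot n_correlation_samples Observations drawn per gene when simulating
#'   the correlation matrix.
#' @slot n_disease_genes,n_associations,n_regulations Table sizes for the
#'   disease-gene, compound-target and transcription-regulation generators.
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", n_compounds = "integer",
                 pass_fraction = "numeric", n_herbs = "integer",
                 n_genes = "integer", n_edges_per_node = "integer",
                 clique_size = "integer", proximal_set_size = "integer",
                 n_terms = "integer", term_size_min = "integer",
                 term_size_max = "integer", enrichment_strength = "numeric",
                 correlation_blocks = "integer",
                 block_correlation = "numeric",
                 n_correlation_samples = "integer",
                 n_disease_genes = "integer", n_associations = "integer",
                 n_regulations = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  counts <- c(n_compounds = object@n_compounds, n_herbs = object@n_herbs,
              n_genes = object@n_genes,
              n_edges_per_node = object@n_edges_per_node,
              n_terms = object@n_terms,
              term_size_min = object@term_size_min,
              correlation_blocks = object@correlation_blocks,
              n_correlation_samples = object@n_correlation_samples,
              n_disease_genes = object@n_disease_genes,
              n_associations = object@n_associations,
              n_regulations = object@n_regulations)
  if (any(counts < 1))
    msg <- c(msg, paste("counts must be positive:",
                        paste(names(counts)[counts < 1], collapse = ", ")))
  if (object@clique_size < 3) msg <- c(msg, "clique_size must be >= 3")
  if (object@proximal_set_size < 2)
    msg <- c(msg, "proximal_set_size must be >= 2")
  if (object@pass_fraction < 0 || object@pass_fraction > 1)
    msg <- c(msg, "pass_fraction must lie in [0, 1]")
  if (object@enrichment_strength < 1)
    msg <- c(msg, "enrichment_strength must be >= 1")
  if (object@block_correlation <= 0 || object@block_correlation >= 1)
    msg <- c(msg, "block_correlation must lie in (0, 1)")
  if (object@term_size_max < object@term_size_min)
    msg <- c(msg, "term_size_max < term_size_min")
  if (object@n_genes < object@clique_size + 2 * object@proximal_set_size + 10)
    msg <- c(msg, "n_genes too small for the planted structure")
  if (length(msg)) msg else TRUE
})

#' Build a synthetic-data configuration
#'
#' Defaults describe a small but structured study: 60 candidate compounds
#' across 5 herbs with 60% passing the ADMET screen, a 200-gene scale-free
#' interaction network with a planted 5-clique and a planted proximal pair
#' of 6-gene sets, 30 gene sets of 10-40 genes with one term enriched at
#' strength 8, and a 4-block correlation matrix at within-block correlation
#' 0.8.
#'
#' @param seed Master seed (integer).
#' @param n_compounds,pass_fraction,n_herbs Compound-table shape.
#' @param n_genes,n_edges_per_node,clique_size,proximal_set_size Network
#'   shape and planted structure.
#' @param n_terms,term_size_min,term_size_max,enrichment_strength Gene-set
#'   collection shape.
#' @param correlation_blocks,block_correlation,n_correlation_samples
#'   Correlation-matrix shape.
#' @param n_disease_genes,n_associations,n_regulations Table sizes.
#' @return A validated [SyntheticConfig-class].
#' @export
#' @examples
#' cfg <- syntheticConfig(seed = 1)
#' ppi <- genPPI(cfg)
#' ppi$network
syntheticConfig <- function(seed = 1L, n_compounds = 60L,
                            pass_fraction = 0.6, n_herbs = 5L,
                            n_genes = 200L, n_edges_per_node = 2L,
                            clique_size = 5L, proximal_set_size = 6L,
                            n_terms = 30L, term_size_min = 10L,
                            term_size_max = 40L, enrichment_strength = 8,
                            correlation_blocks = 4L,
                            block_correlation = 0.8,
                            n_correlation_samples = 100L,
                            n_disease_genes = 120L,
                            n_associations = 600L,
                            n_regulations = 200L) {
  new("SyntheticConfig", seed = as.integer(seed),
      n_compounds = as.integer(n_compounds),
      pass_fraction = as.numeric(pass_fraction),
      n_herbs = as.integer(n_herbs), n_genes = as.integer(n_genes),
      n_edges_per_node = as.integer(n_edges_per_node),
      clique_size = as.integer(clique_size),
      proximal_set_size = as.integer(proximal_set_size),
      n_terms = as.integer(n_terms),
      term_size_min = as.integer(term_size_min),
      term_size_max = as.integer(term_size_max),
      enrichment_strength = as.numeric(enrichment_strength),
      correlation_blocks = as.integer(correlation_blocks),
      block_correlation = as.numeric(block_correlation),
      n_correlation_samples = as.integer(n_correlation_samples),
      n_disease_genes = as.integer(n_disease_genes),
      n_associations = as.integer(n_associations),
      n_regulations = as.integer(n_regulations))
}

## deterministic child seed per generator, kept below 2^31
.childSeed <- function(seed, tag) {
  offs <- c(compounds = 11L, ppi = 23L, genesets = 37L, corr = 41L,
            disease = 53L, assoc = 67L, regulation = 79L, null = 97L)
  (abs(as.integer(seed)) %% 20000000L) * 100L + offs[[tag]]
}

.geneUniverse <- function(config) sprintf("G%04d", seq_len(config@n_genes))

.herbCodes <- function(config) {
  ## two-letter herb abbreviations: HA, HB, ...
  stats::setNames(paste0("H", LETTERS[seq_len(config@n_herbs)]),
                  paste0("herb_", seq_len(config@n_herbs)))
}

.toxEndpoints <- c("hepatotoxicity", "carcinogenicity", "immunotoxicity",
                   "mutagenicity", "cytotoxicity", "cardiotoxicity")
## active-label probability per endpoint (hepatotoxicity rare, the rest
## moderately common, as in rule-based toxicity panels)
.toxActiveProb <- c(hepatotoxicity = 0.05, carcinogenicity = 0.15,
                    immunotoxicity = 0.25, mutagenicity = 0.20,
                    cytotoxicity = 0.25, cardiotoxicity = 0.15)

#' Generate a synthetic compound property table
#'
#' Each compound carries the ADMET descriptors the screen consumes (MW,
#' AlogP, H-bond donors/acceptors, oral bioavailability, Caco-2,
#' drug-likeness, half-life), 1-3 herb memberships with a controlled shared
#' subset, per-endpoint toxicity labels with probabilities, and an LD50.
#' A compound is built to pass the full screen with probability
#' `pass_fraction`; failing compounds violate at least one criterion.
#'
#' @param config A [SyntheticConfig-class].
#' @return `data.frame` with one row per compound; `herb_ids` is a
#'   semicolon-separated herb-code list; toxicity endpoints appear as paired
#'   `<endpoint>` / `<endpoint>_prob` columns.
#' @export
genCompoundTable <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.childSeed(config@seed, "compounds"))
  n <- config@n_compounds
  herbs <- .herbCodes(config)
  pass <- stats::runif(n) < config@pass_fraction

  ## passing draws: all criteria comfortably satisfied, zero RO5 violations
  mw <- stats::runif(n, 200, 480)
  alogp <- stats::runif(n, 0, 4.5)
  hd <- sample(0:4, n, replace = TRUE)
  ha <- sample(0:8, n, replace = TRUE)
  ob <- stats::runif(n, 35, 80)
  caco2 <- stats::runif(n, 0.45, 1.6)
  dl <- stats::runif(n, 0.2, 0.9)
  hl <- stats::runif(n, 3.5, 24)

  for (i in which(!pass)) {
    ## break a random non-empty subset of the four screen criteria
    broken <- sample(c("oral", "caco2", "dl", "half_life"),
                     sample(1:3, 1))
    if ("oral" %in% broken) {
      ob[i] <- stats::runif(1, 5, 25)
      mw[i] <- stats::runif(1, 550, 900)   # >= 2 RO5 violations
      alogp[i] <- stats::runif(1, 5.5, 9)
    }
    if ("caco2" %in% broken) caco2[i] <- stats::runif(1, -0.5, 0.35)
    if ("dl" %in% broken) dl[i] <- stats::runif(1, 0.01, 0.15)
    if ("half_life" %in% broken) hl[i] <- stats::runif(1, 0.2, 2.5)
  }

  ## herb membership: ~25% of compounds shared by 2-3 herbs
  n_herb <- ifelse(stats::runif(n) < 0.25,
                   sample(2:min(3, config@n_herbs), n, replace = TRUE), 1L)
  n_herb <- pmin(n_herb, config@n_herbs)
  herb_ids <- vapply(n_herb, function(k)
    paste(sort(sample(unname(herbs), k)), collapse = ";"), "")

  df <- data.frame(
    compound_id = sprintf("C%03d", seq_len(n)),
    name = sprintf("compound_%03d", seq_len(n)),
    herb_ids = herb_ids, mw = mw, alogp = alogp, h_donors = hd,
    h_acceptors = ha, ob = ob, caco2 = caco2, dl = dl, half_life = hl,
    ld50 = round(stats::rlnorm(n, log(800), 1)),
    stringsAsFactors = FALSE)
  for (ep in .toxEndpoints) {
    active <- stats::runif(n) < .toxActiveProb[[ep]]
    df[[ep]] <- ifelse(active, "active", "inactive")
    df[[paste0(ep, "_prob")]] <- round(ifelse(
      active, stats::runif(n, 0.5, 1), stats::runif(n, 0.5, 1)), 3)
  }
  df
}

#' Generate a synthetic PPI network with planted structure
#'
#' A preferential-attachment (scale-free) base graph mimics the degree
#' heterogeneity of protein interaction networks. Onto it are planted: a
#' clique of `clique_size` otherwise low-degree nodes (ground truth for
#' MCODE), a gene set A, a set B_near sampled from A's 1-hop neighbourhood
#' and a set B_far at graph distance >= 3 from A (ground truth for the
#' proximity index). Edge confidences are Uniform(0.41, 1), so a 0.4
#' confidence filter keeps every edge.
#'
#' @param config A [SyntheticConfig-class].
#' @return List with elements `network` ([Network-class]), `clique`,
#'   `set_a`, `set_b_near`, `set_b_far` (character vectors).
#' @export
genPPI <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.childSeed(config@seed, "ppi"))
  n <- config@n_genes
  genes <- .geneUniverse(config)
  g <- igraph::sample_pa(n, m = config@n_edges_per_node, directed = FALSE)
  igraph::V(g)$name <- genes

  ## plant the clique on the lowest-degree nodes (late arrivals)
  deg <- igraph::degree(g)
  clique <- genes[order(deg, seq_len(n))][seq_len(config@clique_size)]
  pairs <- utils::combn(clique, 2)
  for (j in seq_len(ncol(pairs))) {
    if (!igraph::are_adjacent(g, pairs[1, j], pairs[2, j]))
      g <- igraph::add_edges(g, pairs[, j])
  }

  ## planted proximal pair: A away from the clique, B_near from A's 1-hop
  ## neighbourhood, B_far at distance >= 3 from A
  k <- config@proximal_set_size
  eligible <- setdiff(genes, clique)
  set_a <- sample(eligible, k)
  nb <- setdiff(unique(unlist(lapply(
    igraph::adjacent_vertices(g, set_a), names))), c(set_a, clique))
  if (length(nb) < k)
    stop("1-hop neighbourhood of set A too small; increase n_genes")
  set_b_near <- sample(nb, k)
  d_from_a <- igraph::distances(g, v = set_a, weights = NA)
  min_d <- apply(d_from_a, 2, min)
  far <- setdiff(genes[min_d >= 3], clique)
  if (length(far) < k)
    stop("too few nodes at distance >= 3 from set A; ",
         "increase n_genes or lower n_edges_per_node")
  set_b_far <- sample(far, k)

  el <- igraph::as_edgelist(g, names = TRUE)
  net <- Network(nodes = genes,
                 edges = data.frame(from = el[, 1], to = el[, 2],
                                    confidence = stats::runif(
                                      nrow(el), 0.41, 1.0)))
  list(network = net, clique = sort(clique), set_a = sort(set_a),
       set_b_near = sort(set_b_near), set_b_far = sort(set_b_far))
}

#' Generate a synthetic gene-set collection with one planted enriched term
#'
#' All terms draw their genes from the configured universe; exactly one
#' term samples query genes with weight `enrichment_strength` (so strength
#' 1 degenerates to uniform sampling and plants nothing).
#'
#' @param config A [SyntheticConfig-class].
#' @param query Character vector of query genes (non-empty; the set whose
#'   enrichment is planted).
#' @return List with `sets` (list of [GeneSet-class]) and `planted` (the id
#'   of the planted term).
#' @export
genGeneSets <- function(config, query) {
  stopifnot(is(config, "SyntheticConfig"))
  query <- unique(canonicalizeSymbols(query))
  if (!length(query)) stop("query gene set is empty")
  set.seed(.childSeed(config@seed, "genesets"))
  universe <- .geneUniverse(config)
  sizes <- sample(config@term_size_min:config@term_size_max,
                  config@n_terms, replace = TRUE)
  planted_idx <- sample(config@n_terms, 1)
  w <- ifelse(universe %in% query, config@enrichment_strength, 1)
  sets <- vector("list", config@n_terms)
  for (i in seq_len(config@n_terms)) {
    id <- sprintf("T%03d", i)
    if (i == planted_idx) {
      genes <- sample(universe, sizes[i], prob = w)
    } else {
      genes <- sample(universe, sizes[i])
    }
    sets[[i]] <- GeneSet(id = id, name = paste("synthetic term", i),
                         genes = genes)
  }
  list(sets = sets, planted = sprintf("T%03d", planted_idx))
}

#' Generate a block-structured correlation matrix
#'
#' Genes are split into `correlation_blocks` contiguous blocks; each block
#' shares a latent factor so that within-block correlations concentrate
#' around `block_correlation` and between-block correlations around zero.
#' The matrix is an empirical correlation of simulated observations, hence
#' exactly symmetric with a unit diagonal.
#'
#' @param config A [SyntheticConfig-class].
#' @param genes Character vector of gene names (matrix dimnames).
#' @return Correlation matrix with a `blocks` attribute (named integer
#'   block assignment).
#' @export
genCorrelationMatrix <- function(config, genes) {
  stopifnot(is(config, "SyntheticConfig"))
  p <- length(genes)
  B <- config@correlation_blocks
  if (p < B) stop("fewer genes than correlation blocks")
  set.seed(.childSeed(config@seed, "corr"))
  blocks <- sort(rep_len(seq_len(B), p))
  nobs <- config@n_correlation_samples
  rho <- config@block_correlation
  f <- matrix(stats::rnorm(nobs * B), nobs, B)
  x <- sqrt(rho) * f[, blocks, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(nobs * p), nobs, p)
  m <- stats::cor(x)
  dimnames(m) <- list(genes, genes)
  attr(m, "blocks") <- stats::setNames(blocks, genes)
  m
}

#' Generate a synthetic disease-gene table
#'
#' Relevance scores are heavy-tailed (log-normal), emulating the skewed
#' score distributions of disease-gene databases; each record carries a
#' source label (`genecards` or `disgenet`) and (gene, source) pairs are
#' unique.
#'
#' @param config A [SyntheticConfig-class].
#' @return `data.frame` with columns `gene`, `score`, `source`.
#' @export
genDiseaseGenes <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.childSeed(config@seed, "disease"))
  universe <- .geneUniverse(config)
  n <- min(config@n_disease_genes, 2L * config@n_genes)
  src <- sample(c("genecards", "disgenet"), n, replace = TRUE,
                prob = c(0.7, 0.3))
  gene <- character(n)
  for (s in unique(src)) {
    idx <- which(src == s)
    gene[idx] <- sample(universe, length(idx))
  }
  data.frame(gene = gene, score = stats::rlnorm(n, meanlog = 1, sdlog = 1),
             source = src, stringsAsFactors = FALSE)
}

#' Generate synthetic compound-target associations
#'
#' Association probabilities are Uniform(0, 1), so roughly one fifth exceed
#' the conventional 0.8 inclusion threshold. Duplicate (compound, gene)
#' pairs keep the maximum probability.
#'
#' @param config A [SyntheticConfig-class].
#' @return `data.frame` with columns `compound_id`, `gene`, `probability`,
#'   `source`.
#' @export
genTargetAssociations <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.childSeed(config@seed, "assoc"))
  n <- config@n_associations
  df <- data.frame(
    compound_id = sample(sprintf("C%03d", seq_len(config@n_compounds)),
                         n, replace = TRUE),
    gene = sample(.geneUniverse(config), n, replace = TRUE),
    probability = stats::runif(n),
    source = sample(c("swisstarget", "targetnet", "drugbank"), n,
                    replace = TRUE),
    stringsAsFactors = FALSE)
  key <- paste(df$compound_id, df$gene)
  keep <- order(df$probability, decreasing = TRUE)
  df <- df[keep, ][!duplicated(key[keep]), ]
  df <- df[order(df$compound_id, df$gene), ]
  rownames(df) <- NULL
  df
}

#' Generate a synthetic transcription-regulation table
#'
#' A small pool of the universe acts as regulators; modes are drawn from
#' activation / repression / unknown.
#'
#' @param config A [SyntheticConfig-class].
#' @return `data.frame` with columns `regulator`, `target`, `mode`.
#' @export
genRegulationTable <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.childSeed(config@seed, "regulation"))
  universe <- .geneUniverse(config)
  tfs <- sample(universe, max(3L, config@n_genes %/% 20L))
  n <- config@n_regulations
  df <- data.frame(
    regulator = sample(tfs, n, replace = TRUE),
    target = sample(universe, n, replace = TRUE),
    mode = sample(c("activation", "repression", "unknown"), n,
                  replace = TRUE, prob = c(0.4, 0.3, 0.3)),
    stringsAsFactors = FALSE)
  df <- df[df$regulator != df$target, ]
  df <- df[!duplicated(paste(df$regulator, df$target)), ]
  rownames(df) <- NULL
  df
}
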