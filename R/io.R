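## Readers/writers for the tabular and graph formats the pipeline touches.
## All gene symbols pass through canonicalizeSymbols() on the way in.

#' Describe the expected layout of a delimited table
#'
#' @param name Schema name, used in error messages.
#' @param columns Named character vector mapping required column names to a
#'   value kind: one of `"text"`, `"number"`, `"integer"`, `"probability"`.
#' @param delimiter Field delimiter (default tab).
#' @return A `tableSchema` object.
#' @export
#' @examples
#' tableSchema("edges", c(from = "text", to = "text", score = "number"))
tableSchema <- function(name, columns, delimiter = "\t") {
  stopifnot(is.character(columns), length(columns) > 0)
  if (is.null(names(columns)) || any(!nzchar(names(columns))))
    stop("every schema column must be named")
  if (anyDuplicated(names(columns)))
    stop("schema column names must be unique")
  bad <- setdiff(columns, c("text", "number", "integer", "probability"))
  if (length(bad))
    stop("unknown value kind: ", paste(bad, collapse = ", "))
  structure(list(name = name, columns = columns, delimiter = delimiter),
            class = "tableSchema")
}

#' Read and validate a delimited table against a schema
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [tableSchema()] describing required columns.
#' @return `data.frame` with all file columns, required columns coerced to
#'   their declared kind; row order preserved.
#' @export
readTable <- function(path, schema) {
  stopifnot(inherits(schema, "tableSchema"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = schema$delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(schema$columns), names(df))
  if (length(missing))
    stop("schema '", schema$name, "': missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in ", path)
  for (col in names(schema$columns)) {
    kind <- schema$columns[[col]]
    if (kind == "text") {
      df[[col]] <- as.character(df[[col]])
      next
    }
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("schema '", schema$name, "': column '", col,
           "' not parseable as ", kind, " at row ", bad[1])
    if (kind == "integer" && any(v != round(v), na.rm = TRUE))
      stop("schema '", schema$name, "': column '", col,
           "' contains non-integer values")
    if (kind == "probability" && any(v < 0 | v > 1, na.rm = TRUE))
      stop("schema '", schema$name, "': column '", col,
           "' outside [0, 1]")
    df[[col]] <- v
  }
  df
}

#' Read a STRING-style edge list
#'
#' Three delimited columns: node, node, score. Scores are normalized to the
#' unit interval: with `scoreScale = "auto"` the file is treated as
#' thousand-scaled (STRING combined scores) whenever any score exceeds 1,
#' otherwise as already unit-scaled. Duplicate undirected edges collapse to
#' the maximum confidence; self-loops are dropped with a warning (or raise
#' an error).
#'
#' @param path Path to the edge file (header optional, detected from the
#'   third field of the first line).
#' @param scoreScale `"auto"`, `"unit"` or `"thousand"`.
#' @param selfLoops `"drop"` (default, with warning) or `"error"`.
#' @return `data.frame` with columns `node_a`, `node_b`, `confidence`.
#' @export
readEdgeList <- function(path, scoreScale = c("auto", "unit", "thousand"),
                         selfLoops = c("drop", "error")) {
  scoreScale <- match.arg(scoreScale)
  selfLoops <- match.arg(selfLoops)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "[\t,]")[[1]]
  header <- length(fields) >= 3 &&
    is.na(suppressWarnings(as.numeric(fields[3])))
  df <- utils::read.delim(path, header = header, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    df <- utils::read.delim(path, header = header,
                            stringsAsFactors = FALSE)
  }
  if (ncol(df) < 3) stop("edge list needs 3 columns (a, b, score)")
  df <- df[, 1:3]
  names(df) <- c("node_a", "node_b", "score")
  df$score <- as.numeric(df$score)
  if (any(is.na(df$score))) stop("unparseable score in edge list")
  if (any(df$score < 0)) stop("negative confidence score")
  if (any(df$score > 1000)) stop("confidence score exceeds 1000")
  scale1000 <- switch(scoreScale,
                      unit = FALSE,
                      thousand = TRUE,
                      auto = any(df$score > 1))
  conf <- if (scale1000) df$score / 1000 else df$score
  a <- canonicalizeSymbols(df$node_a)
  b <- canonicalizeSymbols(df$node_b)
  loop <- a == b
  if (any(loop)) {
    if (selfLoops == "error")
      stop("self-loop on ", paste(unique(a[loop]), collapse = ", "))
    warning("dropping ", sum(loop), " self-loop(s)")
    a <- a[!loop]; b <- b[!loop]; conf <- conf[!loop]
  }
  if (!length(a))
    return(data.frame(node_a = character(), node_b = character(),
                      confidence = numeric()))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  conf <- tapply(conf, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1),
                    node_b = vapply(parts, `[`, "", 2),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a tab-separated GMT file (id, description, genes...).
#' @return List of [GeneSet-class] objects in file order.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(trimws(genes))]
    if (!length(genes)) stop("GMT line ", i, " has an empty gene list")
    out[[i]] <- GeneSet(id = f[1], name = f[2], genes = genes)
  }
  out
}

#' Write a GMT gene-set collection
#'
#' @param sets List of [GeneSet-class] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s@id, s@name, s@genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a network to disk
#'
#' Two formats: GraphML (single file, readable by Cytoscape and igraph) and
#' a two-file node/edge table pair (`<path>_nodes.tsv`, `<path>_edges.tsv`)
#' as used for Cytoscape table import. Round-tripping through
#' [readGraphFile()] recovers node set, edge set and confidences.
#'
#' @param network A [Network-class] object.
#' @param path Output path (prefix for `node_edge_tables`).
#' @param format `"graphml"` or `"node_edge_tables"`.
#' @return Invisibly, the path(s) written.
#' @export
writeGraphFile <- function(network, path,
                           format = c("graphml", "node_edge_tables")) {
  format <- match.arg(format)
  stopifnot(is(network, "Network"))
  if (format == "graphml") {
    g <- asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  npath <- paste0(path, "_nodes.tsv")
  epath <- paste0(path, "_edges.tsv")
  utils::write.table(data.frame(node = networkNodes(network)), npath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  e <- edgeTable(network)
  e$confidence <- formatC(e$confidence, digits = 6, format = "f")
  utils::write.table(e, epath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(npath, epath))
}

#' Read a network written by [writeGraphFile()]
#'
#' @param path Path (or prefix for `node_edge_tables`).
#' @param format `"graphml"` or `"node_edge_tables"`.
#' @return A [Network-class] object.
#' @export
readGraphFile <- function(path, format = c("graphml", "node_edge_tables")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    if (igraph::ecount(g) == 0)
      return(Network(nodes = nodes))
    el <- igraph::as_edgelist(g, names = TRUE)
    conf <- igraph::E(g)$confidence
    if (is.null(conf)) conf <- rep(1, nrow(el))
    return(Network(nodes = nodes,
                   edges = data.frame(from = el[, 1], to = el[, 2],
                                      confidence = conf)))
  }
  ndf <- utils::read.delim(paste0(path, "_nodes.tsv"),
                           stringsAsFactors = FALSE)
  edf <- utils::read.delim(paste0(path, "_edges.tsv"),
                           stringsAsFactors = FALSE)
  Network(nodes = ndf$node, edges = edf)
}
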