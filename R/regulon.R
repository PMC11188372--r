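# TRRUST-dialect ingestion, cross-species symbol mapping, MIE network
# construction, and SIF/GraphML export.

.modes <- c("Activation", "Repression", "Unknown")

#' Read a TRRUST-dialect regulatory table
#'
#' Parses a tab-separated file with four columns (TF, target, mode,
#' references). Exact duplicate (tf, target, mode) rows are collapsed;
#' (tf, target) pairs carrying conflicting modes are collapsed to a single
#' edge with mode `Unknown`, with a warning. Malformed rows or unknown mode
#' strings are an error citing the line number.
#'
#' @param path path to the TSV (no header).
#' @return data.frame with columns `tf`, `target`, `mode`, `references`.
#' @export
readRegulatoryTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) != 4L)
      stopf("line %d: expected 4 tab-separated fields, found %d", i, length(f))
    if (!f[3] %in% .modes)
      stopf("line %d: unknown interaction mode '%s'", i, f[3])
    if (!nzchar(f[1]) || !nzchar(f[2]))
      stopf("line %d: empty TF or target symbol", i)
  }
  df <- data.frame(tf = vapply(parts, `[`, "", 1L),
                   target = vapply(parts, `[`, "", 2L),
                   mode = vapply(parts, `[`, "", 3L),
                   references = vapply(parts, `[`, "", 4L),
                   stringsAsFactors = FALSE)
  collapseEdges(df)
}

# Collapse duplicate rows; conflicting modes for a (tf, target) pair become
# a single Unknown edge (warning).
collapseEdges <- function(df) {
  df <- unique(df[, c("tf", "target", "mode", "references")])
  key <- paste(df$tf, df$target, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    warnf("%d TF-target pair(s) with conflicting modes collapsed to Unknown",
          length(dup))
    keep <- !key %in% dup
    merged <- do.call(rbind, lapply(dup, function(k) {
      rows <- df[key == k, ]
      data.frame(tf = rows$tf[1], target = rows$target[1], mode = "Unknown",
                 references = paste(unique(rows$references), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    df <- rbind(df[keep, ], merged)
  }
  rownames(df) <- NULL
  df[order(df$tf, df$target), ]
}

#' Map edge symbols across species
#'
#' Replaces TF and target symbols using a source-to-destination mapping
#' table. One-to-many entries produce one edge per destination symbol.
#' Symbols absent from the mapping fall back to title-case conversion
#' (all-caps human style to capitalised rodent style, e.g. `ABCC3` to
#' `Abcc3`) and are listed in the report as fallback-mapped. With an empty
#' mapping the operation is idempotent on already-converted symbols.
#'
#' @param edges data.frame as from [readRegulatoryTable()].
#' @param mapping data.frame with columns `source_symbol`,
#'   `destination_symbol` (one row per pair), or NULL for fallback-only.
#' @return list with `edges` (mapped, duplicates collapsed) and `report`
#'   (data.frame `symbol`, `status` in mapped/fallback/one_to_many,
#'   `destinations`).
#' @export
mapSymbols <- function(edges, mapping = NULL) {
  if (is.null(mapping))
    mapping <- data.frame(source_symbol = character(),
                          destination_symbol = character())
  stopifnot(all(c("source_symbol", "destination_symbol") %in% names(mapping)))
  map <- split(mapping$destination_symbol, mapping$source_symbol)
  syms <- unique(c(edges$tf, edges$target))
  dest <- lapply(syms, function(s) {
    if (s %in% names(map)) map[[s]] else titleCaseSymbol(s)
  })
  names(dest) <- syms
  status <- vapply(syms, function(s) {
    if (!s %in% names(map)) "fallback"
    else if (length(map[[s]]) > 1L) "one_to_many"
    else "mapped"
  }, character(1))
  report <- data.frame(
    symbol = syms, status = status,
    destinations = vapply(dest, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    expand.grid(tf = dest[[edges$tf[i]]], target = dest[[edges$target[i]]],
                stringsAsFactors = FALSE)
  })
  n <- vapply(rows, nrow, 0L)
  out <- do.call(rbind, rows)
  out$mode <- rep(edges$mode, n)
  out$references <- rep(edges$references, n)
  list(edges = collapseEdges(out), report = report)
}

#' Read an MIE list TSV
#'
#' Two tab-separated columns with header: `name` (the TF symbol to match in
#' the regulon table) and `sources` (comma-separated subset of
#' target_prediction, aop_database, literature_review).
#'
#' @param path file path.
#' @return data.frame with `name` and `sources`.
#' @export
readMIEList <- function(path) {
  df <- readTSV(path)
  if (!all(c("name", "sources") %in% names(df)))
    stopf("MIE list needs 'name' and 'sources' columns")
  if (any(!nzchar(df$sources)))
    stopf("every MIE needs a non-empty sources tag")
  df
}

#' Read a symbol mapping TSV
#'
#' @param path TSV with header columns `source_symbol`,
#'   `destination_symbol`.
#' @return The mapping data.frame.
#' @export
readMappingTable <- function(path) {
  df <- readTSV(path)
  if (!all(c("source_symbol", "destination_symbol") %in% names(df)))
    stopf("mapping needs 'source_symbol' and 'destination_symbol' columns")
  df
}

#' Build the MIE-to-target network
#'
#' Restricts regulatory edges to TFs whose symbol matches an MIE name
#' (case-insensitive exact match; alias resolution such as GR vs NR3C1 is
#' the responsibility of the input MIE list, which carries the TF symbol to
#' match). MIEs with no matching edges are retained with zero counts and a
#' warning — in real TRRUST ingestions a fraction of MIEs routinely fails
#' to map. Per-MIE counts are distinct targets (`n_targets`) and distinct
#' targets present in the expression gene set (`n_mapped`).
#'
#' @param edges regulatory edge table (`tf`, `target`, `mode`).
#' @param mies data.frame with `name` (and optionally `sources`).
#' @param expressionGenes character vector of genes present in the
#'   expression data.
#' @return An [MIENetwork-class].
#' @export
buildMIENetwork <- function(edges, mies, expressionGenes) {
  stopifnot(is.data.frame(mies), "name" %in% names(mies))
  if (!"sources" %in% names(mies)) mies$sources <- "unspecified"
  hit <- match(toupper(edges$tf), toupper(mies$name))
  sub <- edges[!is.na(hit), , drop = FALSE]
  sub$mie <- mies$name[hit[!is.na(hit)]]
  netEdges <- unique(sub[, c("mie", "target", "mode")])
  rownames(netEdges) <- NULL
  counts <- do.call(rbind, lapply(mies$name, function(m) {
    tg <- unique(netEdges$target[netEdges$mie == m])
    data.frame(mie = m, n_targets = length(tg),
               n_mapped = length(intersect(tg, expressionGenes)),
               stringsAsFactors = FALSE)
  }))
  unmatched <- counts$mie[counts$n_targets == 0]
  if (length(unmatched))
    warnf("%d MIE(s) have no edge in the regulatory table: %s",
          length(unmatched), paste(unmatched, collapse = ", "))
  new("MIENetwork", mies = mies[, c("name", "sources")], edges = netEdges,
      counts = counts)
}

# Sign and dysregulation classes for node colouring.
nodeClasses <- function(fc, upThr = 0.6, downThr = -0.6) {
  sign_class <- ifelse(is.na(fc) | fc == 0, "neutral",
                       ifelse(fc > 0, "up", "down"))
  dys <- ifelse(!is.na(fc) & fc >= upThr, "up",
                ifelse(!is.na(fc) & fc <= downThr, "down", "none"))
  data.frame(log2fc = fc, sign_class = sign_class, dysreg_class = dys,
             stringsAsFactors = FALSE)
}

#' Export an MIE network with condition colouring
#'
#' Writes the network in SIF (`MIE<TAB>regulates<TAB>target`) or GraphML
#' format, plus a node attribute table carrying each node's log2 fold
#' change, sign class (`up` if fc > 0, `down` if fc < 0, `neutral` at
#' exactly 0 or when missing) and dysregulation class at the +/-0.6
#' threshold. Targets absent from `fc` are neutral.
#'
#' @param network an [MIENetwork-class].
#' @param fc named numeric of per-gene log2 fold changes for one condition.
#' @param format `"sif"` or `"graphml"`.
#' @param file output path for the network file.
#' @param attrFile optional path for the node attribute TSV.
#' @param upThr,downThr dysregulation thresholds.
#' @return Invisibly, the node attribute data.frame.
#' @export
exportNetwork <- function(network, fc = numeric(), format = c("sif", "graphml"),
                          file, attrFile = NULL, upThr = 0.6, downThr = -0.6) {
  stopifnot(is(network, "MIENetwork"))
  if (!is.character(format) || !format[1] %in% c("sif", "graphml"))
    stopf("unknown network format '%s'", format[1])
  format <- format[1]
  ed <- mieEdges(network)
  nodes <- unique(c(ed$mie, ed$target))
  attrs <- cbind(
    data.frame(node = nodes,
               type = ifelse(nodes %in% ed$mie, "MIE", "target"),
               stringsAsFactors = FALSE),
    nodeClasses(unname(fc[match(nodes, names(fc))]), upThr, downThr))
  if (format == "sif") {
    writeLines(sprintf("%s\tregulates\t%s", ed$mie, ed$target), file)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$mie, to = ed$target, mode = ed$mode),
      directed = TRUE,
      vertices = data.frame(
        name = attrs$node, type = attrs$type,
        log2fc = ifelse(is.na(attrs$log2fc), 0, attrs$log2fc),
        sign_class = attrs$sign_class, dysreg_class = attrs$dysreg_class))
    igraph::write_graph(g, file, format = "graphml")
  }
  if (!is.null(attrFile)) writeTSV(attrs, attrFile)
  invisible(attrs)
}

#' Re-import a GraphML network export
#'
#' Round-trip companion to [exportNetwork()]: returns the edge list and
#' node attributes stored in a GraphML file.
#'
#' @param file GraphML path.
#' @return list with `edges` (from, to, mode) and `nodes` (attribute
#'   data.frame).
#' @export
importGraphML <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  nd <- igraph::as_data_frame(g, what = "vertices")
  list(edges = ed, nodes = nd)
}
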