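# Interactome input/output: PSI-MITAB 2.5 and plain 2-column edge lists in,
# cleaned undirected igraph out, GEXF/GraphML export for visualization.

#' Read an interactome edge list
#'
#' Parses a protein-protein interaction file into one record per interaction.
#' Two dialects are supported: PSI-MITAB 2.5 (tab-separated, >= 15 columns;
#' the first \code{uniprotkb:}-prefixed accession of columns 1 and 2 is
#' taken as the interactor identifier) and a minimal 2-column TSV of
#' identifier pairs (header optional). Lines without two parseable
#' identifiers are skipped and counted, never silently kept.
#'
#' @param path Path to the interaction file.
#' @param dialect \code{"auto"} (default; sniffed from the first line),
#'   \code{"mitab"}, or \code{"tsv2col"}.
#' @return A data frame of class \code{interaction_records} with columns
#'   \code{interactor_a}, \code{interactor_b} and \code{source_line}
#'   (1-based line number), plus attributes \code{n_skipped} and
#'   \code{dialect}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC", "A\tB"), f)
#' read_interactome(f)
#' @export
read_interactome <- function(path, dialect = c("auto", "mitab", "tsv2col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interactome file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty interactome file: ", path, call. = FALSE)

  if (dialect == "auto") {
    probe <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    dialect <- if (length(probe) >= 15L || any(grepl("^uniprotkb:", probe)))
      "mitab" else "tsv2col"
  }

  n <- length(lines)
  a <- character(n); b <- character(n); src <- integer(n)
  kept <- 0L; skipped <- 0L
  first_uniprot <- function(field) {
    toks <- strsplit(field, "|", fixed = TRUE)[[1]]
    hit <- grep("^uniprotkb:", toks, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub("^uniprotkb:", "", hit[1])
  }

  for (i in seq_len(n)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) { next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (dialect == "mitab") {
      if (i == 1L && grepl("ID\\(s\\) interactor", ln)) next  # header
      if (length(f) < 2L) { skipped <- skipped + 1L; next }
      ia <- first_uniprot(f[1]); ib <- first_uniprot(f[2])
    } else {
      if (i == 1L && length(f) >= 2L &&
          any(tolower(f[1:2]) %in% c("interactor_a", "interactor_b",
                                     "protein_a", "protein_b", "gene_a",
                                     "gene_b", "source", "target"))) next
      ia <- if (length(f) >= 1L && nzchar(f[1])) f[1] else NA_character_
      ib <- if (length(f) >= 2L && nzchar(f[2])) f[2] else NA_character_
    }
    if (is.na(ia) || is.na(ib) || !nzchar(ia) || !nzchar(ib)) {
      skipped <- skipped + 1L
      next
    }
    kept <- kept + 1L
    a[kept] <- ia; b[kept] <- ib; src[kept] <- i
  }

  if (kept == 0L) {
    stop("no parseable interaction records in ", path,
         " (dialect '", dialect, "'; try dialect = 'mitab' or 'tsv2col')",
         call. = FALSE)
  }
  if (skipped > 0L) {
    message("read_interactome: skipped ", skipped, " unparseable line(s)")
  }
  out <- data.frame(interactor_a = a[seq_len(kept)],
                    interactor_b = b[seq_len(kept)],
                    source_line = src[seq_len(kept)],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  attr(out, "dialect") <- dialect
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Read an identifier mapping table
#'
#' Two-column TSV of \code{(external_id, canonical_id)}; the mapping may be
#' many-to-one. Used to translate e.g. UniProt accessions to gene symbols
#' before building the network. No network lookups are ever performed.
#'
#' @param path Path to the TSV.
#' @return Named character vector: names are external ids, values canonical.
#' @export
read_id_map <- function(path) {
  df <- read_two_col(path, "canonical_id")
  df$canonical_id <- as.character(df$canonical_id)
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    stop("id map assigns multiple canonical ids to: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  stats::setNames(df$canonical_id, df$gene_id)
}

#' Build a cleaned interaction network
#'
#' Turns interaction records into a simple undirected \pkg{igraph} graph:
#' identifiers are canonicalized when \code{id_map} is given (records with
#' any unmapped endpoint are dropped and counted), self-loops are removed
#' and duplicate edges in either orientation are collapsed, so vertex degree
#' means "number of distinct interaction partners".
#'
#' @param records Data frame from \code{\link{read_interactome}} (or any
#'   data frame whose first two columns are interactor identifiers).
#' @param id_map Optional named character vector (external -> canonical),
#'   e.g. from \code{\link{read_id_map}}.
#' @return An undirected simple \code{igraph} graph with a graph attribute
#'   \code{cleaning}: list with \code{n_self_loops}, \code{n_duplicates},
#'   \code{n_unmapped}.
#' @examples
#' recs <- data.frame(interactor_a = c("A", "B", "A", "B"),
#'                    interactor_b = c("B", "A", "A", "C"))
#' g <- build_network(recs)
#' igraph::ecount(g)  # 2: A-B collapsed, A-A dropped
#' @export
build_network <- function(records, id_map = NULL) {
  if (NROW(records) == 0L) stop("no interaction records supplied", call. = FALSE)
  a <- as.character(records[[1]])
  b <- as.character(records[[2]])
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    ma <- unname(id_map[a]); mb <- unname(id_map[b])
    bad <- is.na(ma) | is.na(mb)
    n_unmapped <- sum(bad)
    if (n_unmapped > 0L) {
      lost <- unique(c(a[is.na(ma)], b[is.na(mb)]))
      message("build_network: dropped ", n_unmapped,
              " record(s) with unmapped identifiers (e.g. ",
              paste(head(lost, 5), collapse = ", "), ")")
    }
    a <- ma[!bad]; b <- mb[!bad]
    if (length(a) == 0L) {
      stop("all interaction records dropped by identifier mapping", call. = FALSE)
    }
  }
  loops <- a == b
  n_loops <- sum(loops)
  a2 <- a[!loops]; b2 <- b[!loops]
  # canonical unordered orientation, then collapse duplicates
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  verts <- sort(unique(c(a, b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (any(!dup)) {
    g <- igraph::add_edges(g, rbind(lo[!dup], hi[!dup]))
  }
  g <- igraph::set_graph_attr(g, "cleaning",
                              list(n_self_loops = n_loops,
                                   n_duplicates = n_dup,
                                   n_unmapped = n_unmapped))
  g
}

#' Export a network for visualization
#'
#' Writes GEXF 1.2 or GraphML readable by Gephi/Cytoscape. Every vertex
#' carries its degree, an optional regulation label, and a visual size
#' proportional to degree (hub maps read by node size).
#'
#' @param net An \code{igraph} graph.
#' @param path Output file path.
#' @param format \code{"gexf"} or \code{"graphml"}.
#' @param annotations Optional data frame with column \code{gene_id} plus
#'   per-vertex attribute columns (e.g. \code{label}); \code{gene_id} values
#'   must all be vertices of \code{net}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("gexf", "graphml"),
                           annotations = NULL) {
  format <- match.arg(format)
  vnames <- igraph::V(net)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(net)))
  deg <- igraph::degree(net)
  label <- rep(NA_character_, length(vnames))
  if (!is.null(annotations) && NROW(annotations) > 0L) {
    ann_id <- as.character(annotations$gene_id)
    if (!all(ann_id %in% vnames)) {
      stop("annotation gene ids absent from the network: ",
           paste(head(setdiff(ann_id, vnames), 5), collapse = ", "),
           call. = FALSE)
    }
    if ("label" %in% names(annotations)) {
      label[match(ann_id, vnames)] <- as.character(annotations$label)
    }
  }
  g <- net
  igraph::V(g)$degree <- deg
  igraph::V(g)$regulation <- ifelse(is.na(label), "", label)
  igraph::V(g)$size <- 1 + deg  # node size proportional to degree

  if (format == "graphml") {
    ok <- try(igraph::write_graph(g, path, format = "graphml"), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write ", path, call. = FALSE)
    return(invisible(path))
  }
  write_gexf(g, path)
  invisible(path)
}

# Minimal GEXF 1.2 writer (undirected, static; node attributes degree,
# regulation; viz size proportional to degree).
write_gexf <- function(g, path) {
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(g)))
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                               defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "degree",
                      type = "integer")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "regulation",
                      type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  deg <- igraph::V(g)$degree
  reg <- igraph::V(g)$regulation
  for (i in seq_along(vnames)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[i], label = vnames[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = as.character(deg[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "1", value = reg[i])
    xml2::xml_add_child(nd, "size", value = as.character(1 + deg[i]))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(g, names = TRUE)
  for (i in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                        source = el[i, 1], target = el[i, 2])
  }
  ok <- try(xml2::write_xml(doc, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

# Read back a GEXF file written by write_gexf (round-trip checks, CLI).
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_el <- xml2::xml_find_all(doc, ".//g:node", ns)
  ids <- xml2::xml_attr(node_el, "id")
  reg <- vapply(node_el, function(nd) {
    av <- xml2::xml_find_first(nd, ".//g:attvalue[@for='1']", ns)
    if (inherits(av, "xml_missing")) "" else xml2::xml_attr(av, "value")
  }, character(1))
  edge_el <- xml2::xml_find_all(doc, ".//g:edge", ns)
  src <- xml2::xml_attr(edge_el, "source")
  tgt <- xml2::xml_attr(edge_el, "target")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(src)) g <- igraph::add_edges(g, rbind(src, tgt))
  igraph::V(g)$regulation <- reg
  g
}
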