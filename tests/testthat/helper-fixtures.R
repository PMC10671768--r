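# Shared fixtures: tiny named graphs, a brute-force betweenness oracle and
# minimal expression profiles, all built in code.

named_graph <- function(edges, isolated = character(0)) {
  # edges: character vector like c("a-b", "b-c")
  pairs <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
  verts <- sort(unique(c(pairs, isolated)))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]))
}

star_s4 <- function() named_graph(c("c-l1", "c-l2", "c-l3", "c-l4"))
triangle <- function() named_graph(c("A-B", "B-C", "A-C"))
path4 <- function() named_graph(c("a-b", "b-c", "c-d"))

# Brute-force betweenness: enumerate every simple path between every vertex
# pair by depth-first recursion over the adjacency matrix (base R only),
# keep the shortest, and count those passing through each vertex. Only
# feasible for very small graphs; deliberately independent of igraph's
# Brandes implementation.
brute_betweenness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  verts <- rownames(A)
  all_paths <- function(from, to) {
    found <- list()
    recurse <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        found[[length(found) + 1L]] <<- path
        return()
      }
      for (nxt in which(A[last, ] == 1)) {
        if (!(nxt %in% path)) recurse(c(path, nxt))
      }
    }
    recurse(from)
    found
  }
  btw <- stats::setNames(numeric(n), verts)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      len <- vapply(paths, length, integer(1))
      shortest <- paths[len == min(len)]
      sigma <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        cnt <- table(inner)
        idx <- as.integer(names(cnt))
        btw[idx] <- btw[idx] + as.numeric(cnt) / sigma
      }
    }
  }
  btw
}

# Random connected G(n, p) graph with named vertices.
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    g <- igraph::set_vertex_attr(g, "name",
                                 value = sprintf("v%02d", seq_len(n)))
    if (igraph::is_connected(g)) return(g)
  }
}

# Minimal normalized profiles straight from rpkm values (for differential).
profile_from_rpkm <- function(gene_id, rpkm_values) {
  data.frame(gene_id = gene_id, rpkm = rpkm_values, stringsAsFactors = FALSE)
}

# Regulation-calls stand-in for targeting tests that only need id + label.
fake_calls <- function(gene_id, label, z = NULL) {
  df <- data.frame(gene_id = gene_id, label = label,
                   z = if (is.null(z)) rep(NA_real_, length(gene_id)) else z,
                   stringsAsFactors = FALSE)
  class(df) <- c("regulation_calls", "data.frame")
  df
}

# Run the full file-based pipeline on a written fixture directory.
run_pipeline_from_dir <- function(dir, ...) {
  diagnose(interactome = file.path(dir, "interactome.tsv"),
           tumor = file.path(dir, "tumor_counts.tsv"),
           control = file.path(dir, "control_counts.tsv"),
           lengths = file.path(dir, "lengths.tsv"), ...)
}
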