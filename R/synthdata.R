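# Seeded synthetic interactomes (preferential attachment) with planted
# up-regulated hubs and paired tumor/control count profiles, so the whole
# pipeline can be exercised without any download.

#' Generate a scale-free interactome
#'
#' Barabasi-Albert preferential attachment: the graph starts from a complete
#' clique on \code{m + 1} vertices; each subsequent vertex attaches
#' \code{m} edges to distinct existing vertices chosen with probability
#' proportional to their current degree. Deterministic for a given seed.
#' Vertices are named \code{g0001, g0002, ...} in order of arrival, so
#' low-numbered genes tend to be the hubs.
#'
#' @param n Number of vertices.
#' @param m Edges attached by each new vertex; \code{1 <= m < n}.
#' @param seed RNG seed.
#' @return An undirected simple named \code{igraph} graph.
#' @examples
#' g <- gen_network(10, 1, seed = 1)
#' igraph::ecount(g)  # m = 1 gives a tree: n - 1 edges
#' @export
gen_network <- function(n, m, seed = 1) {
  if (!(m >= 1 && m < n)) stop("need 1 <= m < n", call. = FALSE)
  n <- as.integer(n); m <- as.integer(m)
  edges_a <- integer(0); edges_b <- integer(0)
  # seed clique on m + 1 vertices
  clq <- utils::combn(seq_len(m + 1L), 2L)
  edges_a <- clq[1, ]; edges_b <- clq[2, ]
  # multiset of edge endpoints: sampling from it is degree-proportional
  stubs <- c(edges_a, edges_b)
  with_seed(seed, {
    if (n > m + 1L) {
      for (v in (m + 2L):n) {
        chosen <- integer(0)
        while (length(chosen) < m) {
          cand <- stubs[sample.int(length(stubs), m - length(chosen),
                                   replace = TRUE)]
          chosen <- unique(c(chosen, cand))
        }
        chosen <- chosen[seq_len(m)]
        edges_a <- c(edges_a, rep.int(v, m))
        edges_b <- c(edges_b, chosen)
        stubs <- c(stubs, rep.int(v, m), chosen)
      }
    }
  })
  width <- max(4L, nchar(as.character(n)))
  vnames <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  igraph::add_edges(g, rbind(vnames[edges_a], vnames[edges_b]))
}

#' Generate paired tumor/control expression profiles with planted hubs
#'
#' Control counts are drawn per gene from a log-normal model around
#' \code{base_mean} (sdlog \code{noise_sd}) and rounded to integers; tumor
#' counts come from the identical model except that the planted genes' means
#' are multiplied by \code{fold}. Because non-planted genes share one mean
#' model with independent noise in the two samples, their tumor - control
#' RPKM differences are symmetric about zero by construction. CDS lengths
#' are uniform integers in [300, 10000] bp.
#'
#' @param net Interactome from \code{\link{gen_network}}; its vertex names
#'   are the gene universe.
#' @param planted_up Either a character vector of gene ids to up-regulate or
#'   an integer count; a count selects the highest-degree vertices (ties by
#'   name) so that "up-regulated" and "hub" coincide, unless
#'   \code{planted_random = TRUE}, which plants uniformly random genes (the
#'   negative control: no degree/expression association).
#' @param fold Mean multiplier for planted genes; must exceed 1.
#' @param base_mean Log-normal median of control counts.
#' @param noise_sd sdlog of the count noise.
#' @param seed RNG seed; all randomness (lengths, counts, planting) flows
#'   from it.
#' @param planted_random Plant random-degree genes instead of top hubs.
#' @return List of class \code{synthetic_dataset}: \code{network},
#'   \code{control_counts}, \code{tumor_counts} (data frames
#'   \code{gene_id}/\code{count}), \code{lengths}
#'   (\code{gene_id}/\code{length_bp}), \code{planted_up}, \code{params}.
#' @export
gen_expression <- function(net, planted_up = 5, fold = 8, base_mean = 500,
                           noise_sd = 0.1, seed = 1, planted_random = FALSE) {
  stopifnot(fold > 1)
  genes <- igraph::V(net)$name
  n <- length(genes)
  with_seed(seed, {
    if (is.numeric(planted_up) && length(planted_up) == 1L) {
      k <- as.integer(planted_up)
      if (k >= n) stop("planted count must be smaller than the gene universe",
                       call. = FALSE)
      planted <- if (k == 0L) {
        character(0)
      } else if (planted_random) {
        sort(sample(genes, k))
      } else {
        deg <- igraph::degree(net)
        genes[order(-deg, genes)][seq_len(k)]
      }
    } else {
      planted <- as.character(planted_up)
      if (!all(planted %in% genes)) {
        stop("planted genes absent from the network: ",
             paste(setdiff(planted, genes), collapse = ", "), call. = FALSE)
      }
    }
    lengths_bp <- sample(300:10000, n, replace = TRUE)
    mu <- rep(base_mean, n)
    mu_t <- ifelse(genes %in% planted, mu * fold, mu)
    control <- as.integer(round(rlnorm(n, meanlog = log(mu), sdlog = noise_sd)))
    tumor <- as.integer(round(rlnorm(n, meanlog = log(mu_t), sdlog = noise_sd)))
  })
  structure(list(
    network = net,
    control_counts = data.frame(gene_id = genes, count = control,
                                stringsAsFactors = FALSE),
    tumor_counts = data.frame(gene_id = genes, count = tumor,
                              stringsAsFactors = FALSE),
    lengths = data.frame(gene_id = genes, length_bp = lengths_bp,
                         stringsAsFactors = FALSE),
    planted_up = planted,
    params = list(n_genes = n, fold = fold, base_mean = base_mean,
                  noise_sd = noise_sd, seed = seed,
                  planted_random = planted_random)),
    class = "synthetic_dataset")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: \code{\link{gen_network}} then
#' \code{\link{gen_expression}} under one seed.
#'
#' @inheritParams gen_network
#' @inheritParams gen_expression
#' @param m Preferential-attachment edges per new vertex.
#' @return A \code{synthetic_dataset} (see \code{\link{gen_expression}}).
#' @export
gen_dataset <- function(n = 2000, m = 3, planted_up = 5, fold = 8,
                        base_mean = 500, noise_sd = 0.1, seed = 1,
                        planted_random = FALSE) {
  net <- gen_network(n, m, seed = seed)
  ds <- gen_expression(net, planted_up = planted_up, fold = fold,
                       base_mean = base_mean, noise_sd = noise_sd,
                       seed = seed + 1L, planted_random = planted_random)
  ds$params$m_attach <- m
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic dataset: %d genes, %d interactions, %d planted hub(s)\n",
              p$n_genes, igraph::ecount(x$network), length(x$planted_up)))
  cat(sprintf("  fold %.3g, base mean %.3g, noise sd %.3g, seed %d\n",
              p$fold, p$base_mean, p$noise_sd, p$seed))
  if (length(x$planted_up)) {
    cat("  planted:", paste(x$planted_up, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a synthetic dataset as pipeline-ready fixture files
#'
#' Writes \code{interactome.tsv} (2-column edge list),
#' \code{tumor_counts.tsv}, \code{control_counts.tsv}, \code{lengths.tsv}
#' and \code{truth.json} (planted set and generator parameters) in exactly
#' the dialects the pipeline readers consume.
#'
#' @param ds A \code{synthetic_dataset}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory ", dir, call. = FALSE)
  }
  el <- igraph::as_edgelist(ds$network, names = TRUE)
  write_tsv(data.frame(interactor_a = el[, 1], interactor_b = el[, 2],
                       stringsAsFactors = FALSE),
            file.path(dir, "interactome.tsv"))
  write_tsv(ds$tumor_counts, file.path(dir, "tumor_counts.tsv"))
  write_tsv(ds$control_counts, file.path(dir, "control_counts.tsv"))
  write_tsv(ds$lengths, file.path(dir, "lengths.tsv"))
  jsonlite::write_json(list(planted_up = ds$planted_up, params = ds$params),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
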