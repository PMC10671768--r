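# Degree, betweenness, Shannon network entropy and vertex-removal
# (attack) trajectories.

#' Vertex degrees
#'
#' @param net An \code{igraph} graph.
#' @return Named integer vector of degrees; isolated vertices have degree 0.
#' @export
net_degree <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' Betweenness centrality
#'
#' Raw (unnormalized) betweenness over unordered vertex pairs with endpoints
#' excluded: \eqn{C_B(v) = \sum_{s \ne v \ne t} \sigma(s,t|v)/\sigma(s,t)},
#' where \eqn{\sigma(s,t)} counts shortest paths between \eqn{s} and
#' \eqn{t} and \eqn{\sigma(s,t|v)} those passing through \eqn{v}.
#' Disconnected pairs contribute 0.
#'
#' @param net An \code{igraph} graph.
#' @return Named numeric vector of centralities.
#' @export
net_betweenness <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Shannon network entropy
#'
#' Two variants of \eqn{H = -\sum_v p(v) \log p(v)} over the connectivity
#' distribution, both excluding degree-0 vertices (whose probability would
#' be undefined):
#' \describe{
#'   \item{\code{vertex}}{\eqn{p(v) = deg(v) / \sum_u deg(u)} over vertices
#'     with positive degree; maximal (\eqn{\log n_+}) exactly for regular
#'     graphs.}
#'   \item{\code{degree_class}}{\eqn{p(k) = n_k / n_+} over observed degree
#'     classes \eqn{k \ge 1}, where \eqn{n_k} counts vertices of degree
#'     \eqn{k} and \eqn{n_+} those of positive degree; 0 for regular graphs.}
#' }
#' A network with no edges has entropy 0 by convention.
#'
#' @param net An \code{igraph} graph.
#' @param variant \code{"vertex"} or \code{"degree_class"}.
#' @param log_base 2 (default, bits), \code{exp(1)} or 10.
#' @return An object of class \code{entropy_result}: list with \code{value},
#'   \code{variant}, \code{log_base}, \code{n_vertices}, \code{n_edges}.
#' @examples
#' s4 <- igraph::make_star(5, mode = "undirected")
#' net_entropy(s4)$value                      # 2 bits
#' net_entropy(s4, "degree_class")$value      # ~0.722 bits
#' @export
net_entropy <- function(net, variant = c("vertex", "degree_class"),
                        log_base = 2) {
  variant <- match.arg(variant)
  stopifnot(log_base > 0, log_base != 1)
  deg <- igraph::degree(net, loops = FALSE)
  pos <- deg[deg > 0]
  value <- if (length(pos) == 0L) {
    0
  } else if (variant == "vertex") {
    p <- pos / sum(pos)
    -sum(p * log(p)) / log(log_base)
  } else {
    nk <- table(pos)
    p <- as.numeric(nk) / length(pos)
    -sum(p * log(p)) / log(log_base)
  }
  structure(list(value = value, variant = variant, log_base = log_base,
                 n_vertices = igraph::vcount(net),
                 n_edges = igraph::ecount(net)),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  base_lab <- if (isTRUE(all.equal(x$log_base, exp(1)))) "e" else x$log_base
  cat(sprintf("Network Shannon entropy (%s variant, log base %s): %.6f\n",
              x$variant, base_lab, x$value))
  cat(sprintf("  %d vertices, %d edges\n", x$n_vertices, x$n_edges))
  invisible(x)
}

#' Entropy per node
#'
#' Network entropy divided by the number of vertices; the per-node scale on
#' which drug-sensitivity comparisons between cell-line networks are made.
#'
#' @inheritParams net_entropy
#' @return A single non-negative number.
#' @export
entropy_per_node <- function(net, variant = c("vertex", "degree_class"),
                             log_base = 2) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("entropy per node undefined for an empty network", call. = FALSE)
  net_entropy(net, variant, log_base)$value / n
}

#' Entropy trajectory under vertex removal (network attack)
#'
#' Removes vertices one at a time and records the network entropy after each
#' removal. Targets are either an explicit ordered vertex list or chosen by
#' strategy: \code{targeted_static} ranks all vertices by degree once
#' (descending, ties broken by name for determinism), \code{targeted_adaptive}
#' re-ranks after every removal, \code{random} draws uniformly without
#' replacement under \code{seed}. The input network is not modified.
#'
#' @param net An \code{igraph} graph.
#' @param targets Optional ordered character vector of vertices to remove;
#'   overrides \code{strategy}.
#' @param strategy Removal strategy when \code{targets} is missing.
#' @param k Number of removals (ignored when \code{targets} given).
#' @param seed RNG seed for \code{strategy = "random"}.
#' @inheritParams net_entropy
#' @return Object of class \code{attack_result}: data frame with columns
#'   \code{step}, \code{removed}, \code{entropy}, plus attributes
#'   \code{strategy}, \code{seed}, \code{variant}, \code{log_base},
#'   \code{initial_entropy}.
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::V(tri)$name <- c("A", "B", "C")
#' net_attack(tri, targets = "A")$entropy  # path of 2 vertices -> 1 bit
#' @export
net_attack <- function(net, targets = NULL,
                       strategy = c("targeted_static", "targeted_adaptive",
                                    "random"),
                       k = NULL, seed = NULL,
                       variant = c("vertex", "degree_class"), log_base = 2) {
  variant <- match.arg(variant)
  vnames <- igraph::V(net)$name
  if (is.null(vnames)) stop("network vertices must be named", call. = FALSE)

  rank_by_degree <- function(g) {
    d <- igraph::degree(g)
    nm <- igraph::V(g)$name
    nm[order(-d, nm)]
  }

  if (!is.null(targets)) {
    strategy <- "explicit"
    missing_v <- setdiff(targets, vnames)
    if (length(missing_v) > 0L) {
      stop("attack target(s) not in network: ",
           paste(missing_v, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(targets)) stop("duplicate attack targets", call. = FALSE)
    order_fixed <- as.character(targets)
    k <- length(order_fixed)
  } else {
    strategy <- match.arg(strategy)
    if (is.null(k)) stop("supply either targets or k", call. = FALSE)
    if (k > igraph::vcount(net)) stop("k exceeds vertex count", call. = FALSE)
    order_fixed <- switch(strategy,
      targeted_static = rank_by_degree(net)[seq_len(k)],
      random = with_seed(seed, sample(vnames, k)),
      targeted_adaptive = NULL)
  }

  g <- net
  removed <- character(k)
  entropy <- numeric(k)
  for (i in seq_len(k)) {
    v <- if (is.null(order_fixed)) rank_by_degree(g)[1] else order_fixed[i]
    g <- igraph::delete_vertices(g, v)
    removed[i] <- v
    entropy[i] <- net_entropy(g, variant, log_base)$value
  }
  out <- data.frame(step = seq_len(k), removed = removed, entropy = entropy,
                    stringsAsFactors = FALSE)
  structure(out,
            strategy = strategy, seed = seed, variant = variant,
            log_base = log_base,
            initial_entropy = net_entropy(net, variant, log_base)$value,
            class = c("attack_result", "data.frame"))
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("Network attack (%s strategy, %s entropy, base %s)\n",
              attr(x, "strategy"), attr(x, "variant"),
              format(attr(x, "log_base"))))
  cat(sprintf("  initial entropy %.6f; %d removal(s), final %.6f\n",
              attr(x, "initial_entropy"), nrow(x),
              if (nrow(x)) x$entropy[nrow(x)] else attr(x, "initial_entropy")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot an attack entropy trajectory
#'
#' @param x An \code{attack_result}.
#' @param ... Passed to \code{plot.default}.
#' @importFrom graphics plot lines abline
#' @export
plot.attack_result <- function(x, ...) {
  plot(c(0, x$step), c(attr(x, "initial_entropy"), x$entropy),
       type = "b", xlab = "vertices removed",
       ylab = sprintf("entropy (%s, base %s)", attr(x, "variant"),
                      format(attr(x, "log_base"))),
       main = sprintf("Entropy under %s attack", attr(x, "strategy")), ...)
  invisible(x)
}
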