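# Up-regulated subnetwork construction, hub ranking, entropy contributions
# and pathway-weighted up-regulation scores.

#' Induced subnetwork of up-regulated genes
#'
#' @param net Full interactome (\code{igraph}).
#' @param calls \code{regulation_calls} from \code{\link{differential}}.
#' @return Induced subgraph on the up-labeled genes present in \code{net}.
#'   Up-genes absent from the interactome are reported via a message.
#' @export
up_subnetwork <- function(net, calls) {
  up <- calls$gene_id[calls$label == "up"]
  if (length(up) == 0L) stop("no genes labeled 'up'", call. = FALSE)
  vnames <- igraph::V(net)$name
  absent <- setdiff(up, vnames)
  if (length(absent) == length(up)) {
    stop("none of the up-regulated genes occur in the network", call. = FALSE)
  }
  if (length(absent) > 0L) {
    message("up_subnetwork: ", length(absent),
            " up-regulated gene(s) absent from the interactome (e.g. ",
            paste(head(absent, 5), collapse = ", "), ")")
  }
  igraph::induced_subgraph(net, intersect(up, vnames))
}

#' Rank up-regulated hub candidates
#'
#' Orders up-regulated genes by connectivity: degree in the chosen scope
#' descending (\code{"sub"}: degree inside the up-regulated subnetwork,
#' the default; \code{"full"}: degree in the whole interactome), ties broken
#' by betweenness in the full network descending, then lexicographic gene id.
#' The order is a deterministic total order.
#'
#' @param net Full interactome.
#' @param sub Up-regulated subnetwork from \code{\link{up_subnetwork}}.
#' @param calls \code{regulation_calls}; supplies z-scores for the report.
#' @param degree_scope \code{"sub"} or \code{"full"}.
#' @return Object of class \code{target_ranking}: data frame with columns
#'   \code{rank}, \code{gene_id}, \code{degree_sub}, \code{degree_full},
#'   \code{betweenness}, \code{z}; attribute \code{degree_scope}.
#' @export
rank_hubs <- function(net, sub, calls, degree_scope = c("sub", "full")) {
  degree_scope <- match.arg(degree_scope)
  genes <- igraph::V(sub)$name
  if (length(genes) == 0L) stop("empty up-regulated subnetwork", call. = FALSE)
  deg_sub <- igraph::degree(sub)[genes]
  deg_full <- igraph::degree(net)[genes]
  btw <- igraph::betweenness(net, v = genes, directed = FALSE,
                             normalized = FALSE)
  z <- calls$z[match(genes, calls$gene_id)]
  key_deg <- if (degree_scope == "sub") deg_sub else deg_full
  ord <- order(-key_deg, -btw, genes)
  out <- data.frame(rank = seq_along(genes),
                    gene_id = genes[ord],
                    degree_sub = unname(deg_sub[ord]),
                    degree_full = unname(deg_full[ord]),
                    betweenness = unname(btw[ord]),
                    z = z[ord],
                    stringsAsFactors = FALSE)
  attr(out, "degree_scope") <- degree_scope
  class(out) <- c("target_ranking", "data.frame")
  out
}

#' @export
print.target_ranking <- function(x, ...) {
  cat(sprintf("Hub target ranking (%d candidate(s), degree scope '%s')\n",
              nrow(x), attr(x, "degree_scope")))
  print.data.frame(head(x, 10), row.names = FALSE, ...)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more\n")
  invisible(x)
}

#' Top-n hub targets
#'
#' @param ranking A \code{target_ranking}.
#' @param n Number of targets (default 5, the conventional top-five cut).
#' @return The first \code{min(n, nrow(ranking))} rows; warns when fewer
#'   than \code{n} candidates exist.
#' @export
top_n_targets <- function(ranking, n = 5) {
  stopifnot(n >= 1)
  if (nrow(ranking) < n) {
    warning("only ", nrow(ranking), " candidate target(s) available (asked for ",
            n, ")")
  }
  out <- ranking[seq_len(min(n, nrow(ranking))), , drop = FALSE]
  attr(out, "degree_scope") <- attr(ranking, "degree_scope")
  class(out) <- class(ranking)
  out
}

#' Entropy contribution of candidate targets
#'
#' Quantifies how much network entropy each target accounts for.
#' \code{mode = "individual"}: for each target \eqn{t}, the drop
#' \eqn{H(net) - H(net - t)} computed from the intact network.
#' \code{mode = "cumulative"} (default): the entropy trajectory as targets
#' are removed in order; the entropy after removing all of them is the
#' net entropy — the residual disorder the inhibition cannot reach.
#' Individual contributions need not sum to the cumulative drop.
#'
#' @param net An \code{igraph} graph.
#' @param targets Character vector of vertices (e.g.
#'   \code{top_n_targets(...)$gene_id}).
#' @param mode \code{"cumulative"} or \code{"individual"}.
#' @inheritParams net_entropy
#' @return List with \code{contributions} (named numeric; cumulative mode:
#'   successive entropy drops in removal order), \code{net_entropy} (entropy
#'   after removing all targets in cumulative mode; the intact entropy minus
#'   the summed individual contributions in individual mode),
#'   \code{initial_entropy}, \code{mode}, \code{variant}, \code{log_base},
#'   and \code{trajectory} (an \code{attack_result}, cumulative mode only).
#' @export
entropy_contribution <- function(net, targets,
                                 mode = c("cumulative", "individual"),
                                 variant = c("vertex", "degree_class"),
                                 log_base = 2) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  vnames <- igraph::V(net)$name
  unknown <- setdiff(targets, vnames)
  if (length(unknown) > 0L) {
    stop("unknown target(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  h0 <- net_entropy(net, variant, log_base)$value
  if (mode == "individual") {
    contrib <- vapply(targets, function(t) {
      h0 - net_entropy(igraph::delete_vertices(net, t), variant,
                       log_base)$value
    }, numeric(1))
    return(list(contributions = contrib, net_entropy = h0 - sum(contrib),
                initial_entropy = h0, mode = mode, variant = variant,
                log_base = log_base, trajectory = NULL))
  }
  traj <- net_attack(net, targets = targets, variant = variant,
                     log_base = log_base)
  h_after <- traj$entropy
  contrib <- -diff(c(h0, h_after))
  names(contrib) <- targets
  list(contributions = contrib,
       net_entropy = h_after[length(h_after)],
       initial_entropy = h0, mode = mode, variant = variant,
       log_base = log_base, trajectory = traj)
}

#' Pathway-weighted up-regulation score
#'
#' Connectivity-weighted relative frequency of up-regulated genes in a gene
#' set: the summed full-interactome degree of up-regulated set members over
#' the summed degree of all set members present in the interactome. A cheap
#' proxy for the entropy burden a pathway contributes; 1 when every
#' connected member is up-regulated, 0 when none is.
#'
#' @param net Full interactome.
#' @param calls \code{regulation_calls}.
#' @param gene_set Character vector of gene ids (e.g. a WNT-pathway set).
#' @param set_name Optional label carried into the result.
#' @return One-row data frame: \code{set_name}, \code{score},
#'   \code{n_up_in_set}, \code{n_set}.
#' @export
pathway_score <- function(net, calls, gene_set, set_name = "set") {
  vnames <- igraph::V(net)$name
  present <- intersect(unique(gene_set), vnames)
  if (length(present) == 0L) {
    stop("gene set entirely absent from the network", call. = FALSE)
  }
  deg <- igraph::degree(net)[present]
  up <- calls$gene_id[calls$label == "up"]
  num <- sum(deg[present %in% up])
  den <- sum(deg)
  score <- if (den == 0) 0 else num / den
  data.frame(set_name = set_name, score = score,
             n_up_in_set = sum(present %in% up),
             n_set = length(present), stringsAsFactors = FALSE)
}

#' Read pathway gene sets
#'
#' Accepts GMT (set name, description, members per line) or 2-column TSV
#' \code{(set_name, gene_id)}.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(fields) >= 3L)) {  # GMT
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[`, character(1), 1L)
    return(sets)
  }
  df <- do.call(rbind, lapply(fields, function(f) f[1:2]))
  if (identical(tolower(df[1, 1]), "set_name")) df <- df[-1, , drop = FALSE]
  split(df[, 2], df[, 1])
}
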