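# End-to-end orchestration: files in, ranked targets + entropy report +
# survival prediction out.

#' Hub-based diagnosis pipeline
#'
#' Runs the full workflow: read and clean the interactome, RPKM-normalize
#' tumor and control counts, call up-regulated genes on the signed-log
#' difference distribution, build the up-regulated subnetwork, rank hubs,
#' take the top \code{top_n}, compute their cumulative entropy contribution,
#' and translate entropy into a predicted 5-year overall survival and the
#' number of hubs to inhibit for \code{survival_goal}. All outputs are
#' deterministic for a given configuration and seed.
#'
#' When \code{out_dir} is given, writes \code{targets.tsv},
#' \code{regulation_calls.tsv}, \code{entropy_report.json},
#' \code{run_report.json} and (optionally) \code{subnetwork.gexf}. On error,
#' partial outputs in \code{out_dir} are removed.
#'
#' @param interactome Path to a PSI-MITAB or 2-column TSV edge list.
#' @param tumor,control Paths to count TSVs (\code{gene_id}, \code{count}).
#' @param lengths Path to the CDS length TSV (\code{gene_id},
#'   \code{length_bp}).
#' @param id_map Optional path to an identifier-mapping TSV.
#' @param alpha Two-tailed significance level for the differential call.
#' @param variant,log_base Entropy variant and logarithm base. The default
#'   is \code{"degree_class"}: it is the variant whose entropy falls under
#'   targeted hub removal (the vertex variant rises toward its regular-graph
#'   maximum as hubs disappear), hence the one on which inhibition can lower
#'   entropy toward a survival threshold.
#' @param degree_scope Hub-ranking degree scope (\code{"sub"} or
#'   \code{"full"}).
#' @param top_n Number of hub targets to report.
#' @param calibration A \code{survline}, a built-in calibration name (see
#'   \code{\link{hub_calibration}}), or a path to a calibration-points TSV
#'   (orthogonally refit).
#' @param survival_goal Target 5-year OS in percent.
#' @param allow_mismatch Allow an entropy variant differing from the
#'   calibration's declared one.
#' @param seed Seed recorded in the run report (the pipeline itself is
#'   deterministic; the seed feeds any downstream randomized follow-up).
#' @param out_dir Optional output directory.
#' @param gexf Also export the up-regulated subnetwork as GEXF.
#' @return Object of class \code{hub_diagnosis}: list with \code{network},
#'   \code{calls}, \code{subnetwork}, \code{ranking}, \code{targets},
#'   \code{entropy} (intact-network \code{entropy_result}),
#'   \code{contribution} (cumulative entropy contribution of the targets),
#'   \code{net_entropy}, \code{survival_pred} (predicted 5-year OS at the
#'   net entropy), \code{targets_needed}, \code{config}, \code{warnings}.
#' @export
diagnose <- function(interactome, tumor, control, lengths, id_map = NULL,
                     alpha = 0.05, variant = c("degree_class", "vertex"),
                     log_base = 2, degree_scope = c("sub", "full"),
                     top_n = 5, calibration = "pancancer-2019",
                     survival_goal = 100, allow_mismatch = FALSE, seed = 1,
                     out_dir = NULL, gexf = FALSE) {
  variant <- match.arg(variant)
  degree_scope <- match.arg(degree_scope)
  warnings_seen <- character(0)
  stage <- "config"
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  cleanup_outputs <- function() {
    if (is.null(out_dir)) return()
    for (f in c("targets.tsv", "regulation_calls.tsv", "entropy_report.json",
                "run_report.json", "subnetwork.gexf")) {
      p <- file.path(out_dir, f)
      if (file.exists(p)) unlink(p)
    }
  }
  run <- function(stage_name, expr) {
    stage <<- stage_name
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen,
                          paste0(stage_name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  res <- tryCatch({
    line <- run("survival.calibration", {
      if (inherits(calibration, "survline")) calibration
      else if (is.character(calibration) &&
               calibration %in% hub_calibration()) hub_calibration(calibration)
      else if (is.character(calibration) && file.exists(calibration))
        fit_survline(read_calibration_points(calibration), method = "tls")
      else stop("calibration must be a survline, a built-in name, or a file")
    })
    recs <- run("graphio.read_interactome", read_interactome(interactome))
    map <- if (!is.null(id_map)) run("graphio.read_id_map", read_id_map(id_map))
    net <- run("graphio.build_network", build_network(recs, id_map = map))

    tum <- run("expression.rpkm", {
      rpkm(read_two_col(tumor, "count", integer = TRUE),
           read_two_col(lengths, "length_bp", integer = TRUE))
    })
    ctl <- run("expression.rpkm", {
      rpkm(read_two_col(control, "count", integer = TRUE),
           read_two_col(lengths, "length_bp", integer = TRUE))
    })
    calls <- run("expression.differential", differential(tum, ctl, alpha = alpha))

    n_up <- sum(calls$label == "up")
    if (n_up == 0L) {
      out <- structure(list(network = net, calls = calls, subnetwork = NULL,
                            ranking = NULL, targets = NULL,
                            entropy = net_entropy(net, variant, log_base),
                            contribution = NULL, net_entropy = NA_real_,
                            survival_pred = NA_real_, targets_needed = NULL,
                            no_targets = TRUE,
                            config = diagnose_config(
                              interactome, tumor, control, lengths, id_map,
                              alpha, variant, log_base, degree_scope, top_n,
                              line, survival_goal, seed),
                            warnings = warnings_seen),
                       class = "hub_diagnosis")
      if (!is.null(out_dir)) write_diagnosis(out, out_dir, gexf = FALSE)
      return(out)
    }

    sub <- run("targeting.up_subnetwork", up_subnetwork(net, calls))
    ranking <- run("targeting.rank_hubs",
                   rank_hubs(net, sub, calls, degree_scope = degree_scope))
    targets <- run("targeting.top_n", top_n_targets(ranking, n = top_n))
    contrib <- run("targeting.entropy_contribution",
                   entropy_contribution(net, targets$gene_id,
                                        mode = "cumulative",
                                        variant = variant,
                                        log_base = log_base))
    h <- net_entropy(net, variant, log_base)
    surv_pred <- run("survival.predict",
                     predict(line, contrib$net_entropy,
                             cap_at_100 = FALSE))
    tn <- run("survival.targets_needed",
              targets_needed(net, ranking, line,
                             survival_goal = survival_goal, variant = variant,
                             log_base = log_base,
                             allow_mismatch = allow_mismatch))
    out <- structure(list(network = net, calls = calls, subnetwork = sub,
                          ranking = ranking, targets = targets, entropy = h,
                          contribution = contrib,
                          net_entropy = contrib$net_entropy,
                          survival_pred = surv_pred, targets_needed = tn,
                          no_targets = FALSE,
                          config = diagnose_config(
                            interactome, tumor, control, lengths, id_map,
                            alpha, variant, log_base, degree_scope, top_n,
                            line, survival_goal, seed),
                          warnings = warnings_seen),
                     class = "hub_diagnosis")
    if (!is.null(out_dir)) write_diagnosis(out, out_dir, gexf = gexf)
    out
  }, error = function(e) {
    cleanup_outputs()
    stop("diagnose failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

diagnose_config <- function(interactome, tumor, control, lengths, id_map,
                            alpha, variant, log_base, degree_scope, top_n,
                            line, survival_goal, seed) {
  list(interactome = interactome, tumor = tumor, control = control,
       lengths = lengths, id_map = id_map, alpha = alpha,
       entropy_variant = variant, log_base = log_base,
       degree_scope = degree_scope, top_n = top_n,
       calibration = list(slope = line$slope, intercept = line$intercept,
                          method = line$method,
                          entropy_variant = line$entropy_variant),
       survival_goal = survival_goal, seed = seed)
}

write_diagnosis <- function(x, out_dir, gexf = FALSE) {
  cfg <- x$config
  if (!isTRUE(x$no_targets)) {
    tg <- x$targets
    tg$entropy_contribution <- unname(x$contribution$contributions)
    write_tsv(tg, file.path(out_dir, "targets.tsv"))
  } else {
    write_tsv(data.frame(rank = integer(0), gene_id = character(0)),
              file.path(out_dir, "targets.tsv"))
  }
  write_tsv(as.data.frame(x$calls), file.path(out_dir, "regulation_calls.tsv"))
  entropy_report <- list(
    entropy_variant = cfg$entropy_variant, log_base = cfg$log_base,
    network = list(n_vertices = x$entropy$n_vertices,
                   n_edges = x$entropy$n_edges,
                   entropy = x$entropy$value),
    net_entropy_after_targets = if (isTRUE(x$no_targets)) NULL else x$net_entropy,
    predicted_survival_pct = if (isTRUE(x$no_targets)) NULL else x$survival_pred,
    targets_needed = if (isTRUE(x$no_targets)) NULL else list(
      survival_goal = x$targets_needed$survival_goal,
      threshold = x$targets_needed$threshold,
      count = x$targets_needed$count,
      reachable = x$targets_needed$reachable,
      final_entropy = x$targets_needed$final_entropy))
  jsonlite::write_json(entropy_report, file.path(out_dir, "entropy_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  run_report <- list(
    tool = "hubdiag",
    version = as.character(utils::packageVersion("hubdiag")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    no_targets = isTRUE(x$no_targets),
    warnings = x$warnings,
    cleaning = igraph::graph_attr(x$network, "cleaning"))
  jsonlite::write_json(run_report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (gexf && !isTRUE(x$no_targets)) {
    ann <- data.frame(gene_id = x$calls$gene_id, label = x$calls$label,
                      stringsAsFactors = FALSE)
    ann <- ann[ann$gene_id %in% igraph::V(x$subnetwork)$name, , drop = FALSE]
    export_network(x$subnetwork, file.path(out_dir, "subnetwork.gexf"),
                   format = "gexf", annotations = ann)
  }
  invisible(out_dir)
}

#' @export
print.hub_diagnosis <- function(x, ...) {
  cat("Hub-based diagnosis\n")
  cat(sprintf("  interactome: %d vertices, %d edges; entropy %.6f (%s, base %s)\n",
              x$entropy$n_vertices, x$entropy$n_edges, x$entropy$value,
              x$entropy$variant, format(x$entropy$log_base)))
  tab <- table(factor(x$calls$label, levels = c("up", "down", "unchanged")))
  cat(sprintf("  regulation calls: %d up, %d down, %d unchanged\n",
              tab[["up"]], tab[["down"]], tab[["unchanged"]]))
  if (isTRUE(x$no_targets)) {
    cat("  no up-regulated genes: no targets to report\n")
    return(invisible(x))
  }
  cat(sprintf("  top %d hub target(s): %s\n", nrow(x$targets),
              paste(x$targets$gene_id, collapse = ", ")))
  cat(sprintf("  net entropy after inhibition: %.6f -> predicted 5-year OS %.2f%%\n",
              x$net_entropy, x$survival_pred))
  tn <- x$targets_needed
  cat(sprintf("  hubs needed for %.6g%% OS: %s\n", tn$survival_goal,
              if (tn$reachable) tn$count else "unreachable"))
  invisible(x)
}
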