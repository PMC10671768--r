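# Linear calibration between network entropy and 5-year overall survival:
# fitting (orthogonal or ordinary least squares), prediction, threshold
# inversion, and the hubs-to-remove estimator.

#' Fit the entropy vs 5-year-survival calibration line
#'
#' Fits \eqn{y = a + b x} with \eqn{x} = 5-year overall survival (percent)
#' and \eqn{y} = network entropy. The default method \code{"tls"} is
#' orthogonal (total least squares) regression on the raw, unstandardized
#' axes — the closed-form principal-axis solution of the 2x2 scatter matrix
#' — appropriate because both axes are measured, not designed.
#' \code{"ols"} minimizes vertical residuals via \code{\link[stats]{lm}}.
#'
#' @param survival_pct Numeric vector of 5-year OS values (percent), or a
#'   data frame with columns \code{survival_pct} and \code{entropy}.
#' @param entropy Numeric vector of network entropies (ignored when a data
#'   frame is supplied).
#' @param method \code{"tls"} (orthogonal, default) or \code{"ols"}.
#' @param entropy_variant,log_base Optional declaration of the entropy
#'   variant/base the calibration entropies were computed under; recorded on
#'   the object and checked by \code{\link{targets_needed}}. Use
#'   \code{"unspecified"} (default) when unknown.
#' @return Object of class \code{survline}: list with \code{slope} (entropy
#'   per percent survival), \code{intercept} (entropy), \code{method},
#'   \code{n_points}, \code{points}, \code{entropy_variant}, \code{log_base}.
#' @examples
#' fit <- fit_survline(c(0, 1, 2), c(1, 3, 5))
#' coef(fit)  # intercept 1, slope 2 (exact for collinear points)
#' @export
fit_survline <- function(survival_pct, entropy = NULL,
                         method = c("tls", "ols"),
                         entropy_variant = "unspecified", log_base = NA) {
  method <- match.arg(method)
  if (is.data.frame(survival_pct)) {
    entropy <- survival_pct$entropy
    survival_pct <- survival_pct$survival_pct
  }
  x <- as.numeric(survival_pct); y <- as.numeric(entropy)
  if (length(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 calibration points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite calibration values", call. = FALSE)
  if (max(x) == min(x)) stop("degenerate calibration: all survival values equal", call. = FALSE)

  if (method == "ols") {
    cf <- coef(lm(y ~ x))
    intercept <- unname(cf[1]); slope <- unname(cf[2])
  } else {
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
    sxy <- sum((x - mx) * (y - my))
    if (sxy == 0) {
      # principal axis is axis-aligned; pick the direction of larger scatter
      slope <- if (sxx >= syy) 0 else stop(
        "orthogonal fit is a vertical line; entropy does not depend on survival",
        call. = FALSE)
    } else {
      slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    }
    intercept <- my - slope * mx
  }
  structure(list(slope = slope, intercept = intercept, method = method,
                 n_points = length(x),
                 points = data.frame(survival_pct = x, entropy = y),
                 entropy_variant = entropy_variant, log_base = log_base),
            class = "survline")
}

#' Construct a calibration line from known coefficients
#'
#' For published lines whose underlying points are not available; the line
#' is taken as-is, never re-fit.
#'
#' @param slope,intercept Line coefficients (entropy = slope * survival +
#'   intercept).
#' @inheritParams fit_survline
#' @return A \code{survline} with \code{method = "given"}.
#' @export
survline <- function(slope, intercept, entropy_variant = "unspecified",
                     log_base = NA) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, method = "given",
                 n_points = 0L, points = NULL,
                 entropy_variant = entropy_variant, log_base = log_base),
            class = "survline")
}

#' Built-in survival calibrations
#'
#' Two published entropy/5-year-OS calibrations, each tagged with entropy
#' variant \code{"unspecified"} because the source does not state the
#' variant or logarithm base its entropies were computed under:
#' \describe{
#'   \item{\code{breast-cell-lines-2020}}{Orthogonal fit through the average
#'     network entropies of triple-negative (11.4332400), luminal
#'     (11.4294941) and control (11.4150921) breast cell lines against
#'     5-year OS of 70, 90 and 100 percent.}
#'   \item{\code{pancancer-2019}}{The published pan-cancer line
#'     \eqn{y = -0.004 x + 2.507} relating per-cancer-type mean entropy of
#'     up-regulated subnetworks to 5-year OS; coefficients taken as given
#'     (the underlying points are not published).}
#' }
#'
#' @param name Calibration name; with no argument, lists available names.
#' @return A \code{survline}, or a character vector of names.
#' @export
hub_calibration <- function(name = NULL) {
  if (is.null(name)) return(names(.calibrations))
  if (!name %in% names(.calibrations)) {
    stop("unknown calibration '", name, "'; available: ",
         paste(names(.calibrations), collapse = ", "), call. = FALSE)
  }
  .calibrations[[name]]()
}

.calibrations <- list(
  "breast-cell-lines-2020" = function() {
    fit_survline(c(70, 90, 100), c(11.4332400, 11.4294941, 11.4150921),
                 method = "tls")
  },
  "pancancer-2019" = function() survline(-0.004, 2.507)
)

#' @export
print.survline <- function(x, digits = 12, ...) {
  cat(sprintf("Entropy ~ 5-year-OS calibration (%s)\n", x$method))
  cat(sprintf("  entropy = %s * survival_pct + %s\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits)))
  if (x$n_points > 0) cat(sprintf("  fitted on %d points\n", x$n_points))
  cat(sprintf("  entropy variant: %s\n", x$entropy_variant))
  invisible(x)
}

#' @export
coef.survline <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict 5-year survival from network entropy
#'
#' Inverts the calibration line: \eqn{survival = (H - intercept)/slope}.
#' Predictions above 100 percent are reported as-is by default (read as
#' benefit beyond the 5-year horizon); \code{cap_at_100} clips them.
#'
#' @param object A \code{survline}.
#' @param entropy Numeric vector of network entropies.
#' @param cap_at_100 Clip predictions to at most 100.
#' @param ... Unused.
#' @return Predicted 5-year OS (percent), same length as \code{entropy}.
#' @export
predict.survline <- function(object, entropy, cap_at_100 = FALSE, ...) {
  if (object$slope == 0) stop("calibration slope is zero; cannot invert", call. = FALSE)
  out <- (entropy - object$intercept) / object$slope
  if (cap_at_100) out <- pmin(out, 100)
  out
}

#' @importFrom graphics points
#' @export
plot.survline <- function(x, ...) {
  pts <- x$points
  xs <- if (!is.null(pts)) range(pts$survival_pct) else c(0, 100)
  xx <- seq(xs[1], xs[2], length.out = 50)
  plot(xx, x$slope * xx + x$intercept, type = "l",
       xlab = "5-year overall survival (%)", ylab = "network entropy",
       main = sprintf("Entropy/survival calibration (%s)", x$method), ...)
  if (!is.null(pts)) points(pts$survival_pct, pts$entropy, pch = 19)
  invisible(x)
}

#' Entropy threshold for a survival goal
#'
#' The entropy at which the calibration line predicts the given survival:
#' \code{slope * survival_goal + intercept}.
#'
#' @param line A \code{survline}.
#' @param survival_goal Target 5-year OS in percent (default 100).
#' @return Entropy threshold (same units as the calibration entropies).
#' @export
entropy_threshold <- function(line, survival_goal = 100) {
  stopifnot(inherits(line, "survline"))
  line$slope * survival_goal + line$intercept
}

#' Number of hubs to remove to reach a survival goal
#'
#' Removes ranked hub targets cumulatively from the network until its
#' entropy falls to or below the calibration threshold for
#' \code{survival_goal}, and reports the minimal number of removals plus the
#' full entropy trajectory. When the ranking is exhausted above the
#' threshold the result is flagged unreachable rather than raising an error.
#' The entropy variant/base must match the calibration's declared variant
#' (lines tagged \code{"unspecified"} are accepted with no check); pass
#' \code{allow_mismatch = TRUE} to override.
#'
#' @param net Interactome (\code{igraph}) whose entropy is being lowered.
#' @param ranking A \code{target_ranking} (or character vector of vertex
#'   names in removal order).
#' @param line A \code{survline} calibration.
#' @param survival_goal Target 5-year OS in percent.
#' @param allow_mismatch Permit an entropy variant/base differing from the
#'   calibration's declaration.
#' @inheritParams net_entropy
#' @return List of class \code{targets_needed}: \code{count},
#'   \code{reachable}, \code{threshold}, \code{initial_entropy},
#'   \code{final_entropy}, \code{survival_goal}, \code{trajectory}
#'   (an \code{attack_result}).
#' @export
targets_needed <- function(net, ranking, line, survival_goal = 100,
                           variant = c("vertex", "degree_class"),
                           log_base = 2, allow_mismatch = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(line, "survline"))
  declared <- line$entropy_variant
  if (!allow_mismatch && !identical(declared, "unspecified") &&
      (!identical(declared, variant) ||
       (!is.na(line$log_base) && !isTRUE(all.equal(line$log_base, log_base))))) {
    stop("entropy variant/base (", variant, ", base ", format(log_base),
         ") differs from the calibration's declaration (", declared,
         if (!is.na(line$log_base)) paste0(", base ", format(line$log_base)),
         "); pass allow_mismatch = TRUE to override", call. = FALSE)
  }
  targets <- if (is.data.frame(ranking)) ranking$gene_id else as.character(ranking)
  if (length(targets) == 0L) stop("empty target ranking", call. = FALSE)
  thr <- entropy_threshold(line, survival_goal)
  h0 <- net_entropy(net, variant, log_base)$value
  if (h0 <= thr) {
    traj <- net_attack(net, targets = character(0), variant = variant,
                       log_base = log_base)
    return(structure(list(count = 0L, reachable = TRUE, threshold = thr,
                          initial_entropy = h0, final_entropy = h0,
                          survival_goal = survival_goal, trajectory = traj),
                     class = "targets_needed"))
  }
  traj <- net_attack(net, targets = targets, variant = variant,
                     log_base = log_base)
  below <- which(traj$entropy <= thr)
  if (length(below) == 0L) {
    structure(list(count = length(targets), reachable = FALSE, threshold = thr,
                   initial_entropy = h0,
                   final_entropy = traj$entropy[nrow(traj)],
                   survival_goal = survival_goal, trajectory = traj),
              class = "targets_needed")
  } else {
    k <- below[1]
    structure(list(count = as.integer(k), reachable = TRUE, threshold = thr,
                   initial_entropy = h0, final_entropy = traj$entropy[k],
                   survival_goal = survival_goal, trajectory = traj),
              class = "targets_needed")
  }
}

`%||%` <- function(a, b) if (length(a)) a else b

#' @export
print.targets_needed <- function(x, ...) {
  cat(sprintf("Hubs to inhibit for %.6g%% 5-year OS: %s\n", x$survival_goal,
              if (x$reachable) x$count else
                sprintf("unreachable (all %d ranked hubs removed)", x$count)))
  cat(sprintf("  entropy threshold %.6f; initial %.6f -> final %.6f\n",
              x$threshold, x$initial_entropy, x$final_entropy))
  invisible(x)
}

#' Read calibration points from a TSV
#'
#' Two columns: \code{survival_pct}, \code{entropy}; header optional.
#'
#' @param path File path.
#' @return Data frame with columns \code{survival_pct}, \code{entropy}.
#' @export
read_calibration_points <- function(path) {
  df <- read_two_col(path, "entropy", integer = TRUE)
  names(df) <- c("survival_pct", "entropy")
  df$survival_pct <- suppressWarnings(as.numeric(df$survival_pct))
  if (anyNA(df$survival_pct) || anyNA(df$entropy)) {
    stop("non-numeric calibration values in ", path, call. = FALSE)
  }
  df
}

#' Serialize / deserialize a calibration line as JSON
#'
#' @param line A \code{survline}.
#' @param path JSON file path.
#' @return \code{write_survline}: \code{path} invisibly;
#'   \code{read_survline}: a \code{survline}.
#' @export
write_survline <- function(line, path) {
  stopifnot(inherits(line, "survline"))
  jsonlite::write_json(
    list(slope = line$slope, intercept = line$intercept,
         method = line$method, n_points = line$n_points,
         entropy_variant = line$entropy_variant,
         log_base = if (is.na(line$log_base)) NULL else line$log_base),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_survline
#' @export
read_survline <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- survline(j$slope, j$intercept,
                  entropy_variant = j$entropy_variant %||% "unspecified",
                  log_base = if (is.null(j$log_base)) NA else j$log_base)
  out$method <- j$method %||% "given"
  out$n_points <- j$n_points %||% 0L
  out
}
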