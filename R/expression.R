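# RPKM normalization and the population-level differential-expression call
# on tumor - control profile differences.

#' RPKM normalization
#'
#' Reads per kilobase of coding sequence per million mapped reads:
#' \deqn{RPKM_g = 10^9 C_g / (N L_g)}
#' with \eqn{C_g} the read count of gene \eqn{g}, \eqn{L_g} its CDS length in
#' base pairs, and \eqn{N} the total mapped reads.
#'
#' @param counts Data frame with columns \code{gene_id}, \code{count}
#'   (non-negative; gene ids unique).
#' @param lengths Data frame with columns \code{gene_id}, \code{length_bp}
#'   (positive integers). Every counted gene needs a length.
#' @param library_size Total mappable reads \eqn{N}; defaults to
#'   \code{sum(counts$count)} (reads mapped onto the supplied gene set).
#' @return Data frame with columns \code{gene_id}, \code{count},
#'   \code{length_bp}, \code{rpkm}; attribute \code{library_size}.
#' @examples
#' rpkm(data.frame(gene_id = "g", count = 10),
#'      data.frame(gene_id = "g", length_bp = 1000),
#'      library_size = 1e6)  # rpkm = 10
#' @export
rpkm <- function(counts, lengths, library_size = NULL) {
  stopifnot(all(c("gene_id", "count") %in% names(counts)),
            all(c("gene_id", "length_bp") %in% names(lengths)))
  if (anyDuplicated(counts$gene_id)) stop("duplicate gene ids in counts", call. = FALSE)
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  miss <- setdiff(counts$gene_id, lengths$gene_id)
  if (length(miss) > 0L) {
    stop("no CDS length for gene(s): ", paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10),
         call. = FALSE)
  }
  L <- lengths$length_bp[match(counts$gene_id, lengths$gene_id)]
  if (any(L < 1)) stop("CDS lengths must be >= 1 bp", call. = FALSE)
  N <- as.numeric(if (is.null(library_size)) sum(as.numeric(counts$count))
                  else library_size)
  if (N <= 0) stop("library size must be positive", call. = FALSE)
  if (!is.null(library_size) && library_size < sum(counts$count)) {
    stop("library_size smaller than the sum of counts", call. = FALSE)
  }
  out <- data.frame(gene_id = as.character(counts$gene_id),
                    count = counts$count,
                    length_bp = L,
                    rpkm = 1e9 * counts$count / (N * L),
                    stringsAsFactors = FALSE)
  attr(out, "library_size") <- N
  out
}

#' Signed log10 transform
#'
#' Odd, strictly increasing extension of \code{log10(x + 1)} to the whole
#' real line: \code{sign(x) * log10(abs(x) + 1)}. Applied to tumor - control
#' expression differences, which are symmetric about zero, it yields an
#' approximately normal distribution suitable for a z-score cut.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
signed_log10 <- function(x) sign(x) * log10(abs(x) + 1)

#' Population-level differential-expression call
#'
#' Implements the profile-difference test: per gene,
#' \eqn{d_g = RPKM_{tumor,g} - RPKM_{control,g}};
#' \eqn{s_g = sign(d_g) \log_{10}(|d_g| + 1)}; a normal distribution is
#' fitted to all \eqn{s_g} (moment fit, or median/MAD when
#' \code{robust = TRUE}) and genes are labeled \code{up} / \code{down} when
#' their z-score exceeds the two-tailed standard-normal quantile at
#' \code{alpha}, \code{unchanged} otherwise. This is a population-level cut
#' on the whole difference distribution, not a per-gene replicate test.
#'
#' @param tumor,control Normalized profiles from \code{\link{rpkm}} (data
#'   frames with \code{gene_id} and \code{rpkm}). Gene sets should match;
#'   otherwise the intersection is used with a warning.
#' @param alpha Two-tailed significance level in (0,1). Default 0.05; pass
#'   \code{5e-4} to cut at a literal 0.05\% p-value.
#' @param robust Use median/MAD instead of mean/sd for the normal fit.
#' @return Object of class \code{regulation_calls}: data frame with columns
#'   \code{gene_id}, \code{d}, \code{s}, \code{z}, \code{label}; attributes
#'   \code{fit_mean}, \code{fit_sd}, \code{alpha}, \code{cutoff},
#'   \code{robust}.
#' @export
differential <- function(tumor, control, alpha = 0.05, robust = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  common <- intersect(tumor$gene_id, control$gene_id)
  if (length(common) < length(tumor$gene_id) ||
      length(common) < length(control$gene_id)) {
    warning("tumor and control gene sets differ; using the ",
            length(common), "-gene intersection")
  }
  if (length(common) < 3L) stop("need at least 3 shared genes", call. = FALSE)
  d <- tumor$rpkm[match(common, tumor$gene_id)] -
       control$rpkm[match(common, control$gene_id)]
  s <- signed_log10(d)
  if (robust) {
    mu <- median(s); sigma <- mad(s)
  } else {
    mu <- mean(s); sigma <- sd(s)
  }
  if (!is.finite(sigma) || sigma == 0) {
    if (all(d == 0)) {
      # exact self-comparison: nothing is differential by definition
      sigma <- NA_real_
      z <- rep(0, length(s))
    } else {
      stop("degenerate profiles: fitted sd of signed-log differences is 0",
           call. = FALSE)
    }
  } else {
    z <- (s - mu) / sigma
  }
  q <- qnorm(1 - alpha / 2)
  label <- ifelse(z > q, "up", ifelse(z < -q, "down", "unchanged"))
  out <- data.frame(gene_id = common, d = d, s = s, z = z, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "fit_mean") <- mu
  attr(out, "fit_sd") <- sigma
  attr(out, "alpha") <- alpha
  attr(out, "cutoff") <- q
  attr(out, "robust") <- robust
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' @export
print.regulation_calls <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("up", "down", "unchanged")))
  cat(sprintf(paste0("Regulation calls on %d genes (two-tailed alpha = %s,",
                     " |z| cutoff %.4f%s)\n"),
              nrow(x), format(attr(x, "alpha")), attr(x, "cutoff"),
              if (isTRUE(attr(x, "robust"))) ", robust fit" else ""))
  cat(sprintf("  up: %d  down: %d  unchanged: %d\n",
              tab[["up"]], tab[["down"]], tab[["unchanged"]]))
  cat(sprintf("  normal fit of signed-log differences: mean %.4g, sd %.4g\n",
              attr(x, "fit_mean"), attr(x, "fit_sd")))
  invisible(x)
}

#' Summary statistics of a set of regulation calls
#'
#' Label counts plus skewness and excess kurtosis of the signed-log
#' difference distribution — diagnostics for the approximate-normality
#' assumption behind the z-score cut.
#'
#' @param calls A \code{regulation_calls} object.
#' @return One-row data frame: \code{n}, \code{n_up}, \code{n_down},
#'   \code{n_unchanged}, \code{skewness}, \code{excess_kurtosis}.
#' @export
population_summary <- function(calls) {
  s <- calls$s
  m <- mean(s); v <- mean((s - m)^2)
  skew <- if (v > 0) mean((s - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((s - m)^4) / v^2 - 3 else 0
  tab <- table(factor(calls$label, levels = c("up", "down", "unchanged")))
  data.frame(n = nrow(calls),
             n_up = as.integer(tab[["up"]]),
             n_down = as.integer(tab[["down"]]),
             n_unchanged = as.integer(tab[["unchanged"]]),
             skewness = skew,
             excess_kurtosis = kurt)
}
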