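# Internal helpers shared across modules.

#' @importFrom stats qnorm sd rlnorm runif coef lm median mad
#' @importFrom utils read.delim write.table head
NULL

# Run `expr` under a deterministic RNG state without touching the caller's
# global stream. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Read a 2-column TSV of (gene_id, value); header optional and sniffed.
read_two_col <- function(path, value_name, integer = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 2L && is.na(suppressWarnings(as.numeric(fields[2])))
  df <- if (has_header) {
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("gene_id", value_name))
  }
  names(df)[1:2] <- c("gene_id", value_name)
  df$gene_id <- as.character(df$gene_id)
  v <- df[[value_name]]
  if (integer) {
    vi <- suppressWarnings(as.numeric(v))
    if (anyNA(vi)) stop("non-numeric values in column 2 of ", path, call. = FALSE)
    df[[value_name]] <- vi
  }
  df[, c("gene_id", value_name)]
}

# Deterministic TSV writer (no quoting, no row names, "." decimal).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
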