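# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ipnet <- function(...) stop(..., call. = FALSE)

# matrix coercion that preserves dimnames and checks numeric content
as_numeric_matrix <- function(x, what = "input") {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop_ipnet(what, " must be numeric")
  m
}

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_ipnet("`", nm, "` must be TRUE or FALSE")
  }
  x
}

check_count <- function(x, nm, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_ipnet("`", nm, "` must be a single integer >= ", min)
  }
  as.integer(x)
}

check_number <- function(x, nm, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_ipnet("`", nm, "` must be a single number in [", min, ", ", max, "]")
  }
  as.numeric(x)
}

# canonical undirected edge keys ("a|b" with a < b)
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by
#' every table this package writes: tab separator, header row, no factor
#' conversion, `""` treated as missing.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x data.frame or matrix.
#' @param path file path.
#' @param rownames_as column name under which to emit row names as a first
#'   column, or `NULL` to drop them.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, rownames_as = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        rownames_as),
               x)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
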