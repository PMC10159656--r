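# Three-way count containers and their long-format serialization.

#' Construct a three-way count tensor
#'
#' Bundles an \code{N x r x p} array of non-negative integer counts with axis
#' labels. Units index the first axis (e.g. genes), occasions the second
#' (e.g. time points or replicates) and variables the third (e.g. conditions),
#' so each unit contributes one \code{r x p} count matrix.
#'
#' @param counts numeric array with dimensions \code{c(N, r, p)}; all entries
#'   must be non-negative integers.
#' @param unit_ids,occasion_labels,variable_labels optional character labels
#'   for the three axes; defaults are generated.
#' @return An object of class \code{count_tensor}: a list with elements
#'   \code{counts}, \code{unit_ids}, \code{occasion_labels},
#'   \code{variable_labels}.
#' @examples
#' ct <- count_tensor(array(rpois(24, 5), c(4, 2, 3)))
#' dim(ct$counts)
#' @export
count_tensor <- function(counts, unit_ids = NULL, occasion_labels = NULL,
                         variable_labels = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop_validation("counts must be a 3-dimensional array (N x r x p)")
  if (!is_count(counts))
    stop_validation("counts must be finite non-negative integers")
  d <- dim(counts)
  if (any(d < 1L)) stop_validation("all tensor dimensions must be >= 1")
  if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(d[1]))
  if (is.null(occasion_labels)) occasion_labels <- paste0("occ", seq_len(d[2]))
  if (is.null(variable_labels)) variable_labels <- paste0("var", seq_len(d[3]))
  if (length(unit_ids) != d[1] || length(occasion_labels) != d[2] ||
      length(variable_labels) != d[3])
    stop_validation("label lengths must match the tensor dimensions")
  structure(list(counts = counts,
                 unit_ids = as.character(unit_ids),
                 occasion_labels = as.character(occasion_labels),
                 variable_labels = as.character(variable_labels)),
            class = "count_tensor")
}

#' @export
print.count_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("count_tensor: %d units x %d occasions x %d variables\n",
              d[1], d[2], d[3]))
  cat("counts range:", paste(range(x$counts), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.count_tensor <- function(x) dim(x$counts)

tensor_dims <- function(tensor) {
  d <- dim(tensor$counts)
  list(N = d[1], r = d[2], p = d[3])
}

#' All-ones offset matrix for a tensor
#'
#' Library-size offsets enter the model as fixed positive constants added on
#' the log scale to the Poisson rate; all-ones offsets correspond to equal
#' sequencing depth across the \code{r x p} samples.
#'
#' @param tensor a \code{count_tensor}.
#' @return An \code{r x p} matrix of ones.
#' @export
ones_offsets <- function(tensor) {
  d <- tensor_dims(tensor)
  matrix(1, d$r, d$p)
}

validate_offsets <- function(offsets, tensor) {
  d <- tensor_dims(tensor)
  if (is.null(offsets)) return(ones_offsets(tensor))
  if (!is.matrix(offsets) || nrow(offsets) != d$r || ncol(offsets) != d$p)
    stop_validation("offsets must be an r x p matrix matching the tensor")
  if (!all(is.finite(offsets)) || any(offsets <= 0))
    stop_validation("all offsets must be strictly positive")
  offsets
}

#' Read a count tensor from long-format delimited text
#'
#' The canonical interchange format is a delimited table with header columns
#' \code{unit}, \code{occasion}, \code{variable}, \code{count}: one row per
#' cell of the tensor. Axis order is the order of first appearance in the
#' file; every (unit, occasion, variable) triple must appear exactly once --
#' missing triples are an error, there are no implicit zeros.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @return A \code{count_tensor}.
#' @seealso [write_count_tensor()]
#' @export
read_count_tensor <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_validation("input file not found: ", path)
  df <- utils::read.delim(path, sep = delimiter, stringsAsFactors = FALSE)
  need <- c("unit", "occasion", "variable", "count")
  if (!all(need %in% names(df)))
    stop_validation("long-format table must have columns: ",
                    paste(need, collapse = ", "))
  if (!is_count(df$count))
    stop_validation("counts must be non-negative integers")
  units <- unique(as.character(df$unit))
  occs <- unique(as.character(df$occasion))
  vars <- unique(as.character(df$variable))
  key <- paste(df$unit, df$occasion, df$variable, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stop_validation(sprintf("duplicate triple (%s, %s, %s)",
                            first$unit, first$occasion, first$variable))
  }
  N <- length(units); r <- length(occs); p <- length(vars)
  if (nrow(df) != N * r * p)
    stop_validation(sprintf(
      "table is ragged: expected %d rows for %d x %d x %d, got %d",
      N * r * p, N, r, p, nrow(df)))
  arr <- array(NA_real_, c(N, r, p))
  ii <- cbind(match(as.character(df$unit), units),
              match(as.character(df$occasion), occs),
              match(as.character(df$variable), vars))
  arr[ii] <- df$count
  if (anyNA(arr)) stop_validation("table is ragged: missing triples")
  count_tensor(arr, units, occs, vars)
}

#' Write a count tensor as long-format delimited text
#'
#' @param tensor a \code{count_tensor}.
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @return Invisibly, \code{path}.
#' @seealso [read_count_tensor()]
#' @export
write_count_tensor <- function(tensor, path, delimiter = "\t") {
  d <- tensor_dims(tensor)
  idx <- expand.grid(occ = seq_len(d$r), var = seq_len(d$p),
                     unit = seq_len(d$N))
  df <- data.frame(unit = tensor$unit_ids[idx$unit],
                   occasion = tensor$occasion_labels[idx$occ],
                   variable = tensor$variable_labels[idx$var],
                   count = tensor$counts[cbind(idx$unit, idx$occ, idx$var)])
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Flatten to an N x (r*p) matrix, sample j = (i-1)*p + k (row-major cells),
# matching the vec-transpose convention used throughout.
flatten_tensor <- function(tensor) {
  d <- tensor_dims(tensor)
  out <- matrix(aperm(tensor$counts, c(3, 2, 1)), nrow = d$N,
                ncol = d$r * d$p, byrow = TRUE)
  colnames(out) <- as.vector(t(outer(tensor$occasion_labels,
                                     tensor$variable_labels, paste,
                                     sep = "__")))
  out
}
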