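#' Construct a typed variables-by-samples data matrix
#'
#' A \code{data_matrix} is the basic unit of a multi-modal data set (MMDS):
#' one data type's measurements, variables in rows and samples in columns,
#' tagged with the data type it carries (e.g. \code{"mRNA"}, \code{"miRNA"},
#' \code{"meth_beta"}, \code{"covariate"}).
#'
#' @param values numeric matrix, \code{p_k} variables by \code{n} samples.
#'   All entries must be finite.
#' @param variable_ids character vector of unique row identifiers. Defaults
#'   to the rownames of \code{values}.
#' @param sample_ids character vector of unique, ordered column identifiers.
#'   Defaults to the colnames of \code{values}.
#' @param dtype_tag single string naming the data type.
#' @return An object of class \code{"data_matrix"}: a list with elements
#'   \code{values}, \code{variable_ids}, \code{sample_ids}, \code{dtype_tag}.
#' @examples
#' m <- data_matrix(matrix(rnorm(6), 3, 2,
#'                         dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'                  dtype_tag = "mRNA")
#' m
#' @export
data_matrix <- function(values, variable_ids = rownames(values),
                        sample_ids = colnames(values), dtype_tag = "data") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(variable_ids))
    variable_ids <- paste0("v", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(ncol(values)))
  variable_ids <- as.character(variable_ids)
  sample_ids <- as.character(sample_ids)
  if (length(variable_ids) != nrow(values))
    stop("length of 'variable_ids' (", length(variable_ids),
         ") does not match nrow(values) (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' (", length(sample_ids),
         ") does not match ncol(values) (", ncol(values), ")")
  if (anyDuplicated(variable_ids))
    stop("duplicate variable IDs: ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(values) < 1L) stop("need at least one variable (row)")
  if (ncol(values) < 2L) stop("need at least two samples (columns)")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop("non-finite value at row '", variable_ids[i[1L]], "', column '",
         sample_ids[i[2L]], "' (", length(bad), " non-finite cells in total)")
  }
  dimnames(values) <- list(variable_ids, sample_ids)
  structure(list(values = values, variable_ids = variable_ids,
                 sample_ids = sample_ids, dtype_tag = as.character(dtype_tag)[1L]),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix [%s]: %d variables x %d samples\n",
              x$dtype_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' @export
as.matrix.data_matrix <- function(x, ...) x$values

#' Read a typed data matrix from a TSV file
#'
#' Expects a tab-separated file whose header row holds the sample IDs, whose
#' first column holds the variable IDs, and whose body is numeric. Missing or
#' non-numeric cells are an error (use \code{impute = TRUE} for row-median
#' imputation of NA cells).
#'
#' @param path path to the TSV file.
#' @param dtype_tag data type tag to attach.
#' @param impute if \code{TRUE}, NA cells are replaced by their row median
#'   (rows that are entirely NA remain an error). Default \code{FALSE}.
#' @return A [data_matrix].
#' @export
read_data_matrix <- function(path, dtype_tag = "data", impute = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("matrix TSV needs an ID column and >= 2 sample columns: ", path)
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    x <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(x) & !is.na(body[[j]]) &
                   !(body[[j]] %in% c("NA", "NaN", "")))
    if (length(bad))
      stop("non-numeric cell at row '", ids[bad[1L]], "', column '",
           colnames(body)[j], "' in ", path, ": '", body[[j]][bad[1L]], "'")
    vals[, j] <- x
  }
  if (anyNA(vals)) {
    if (impute) {
      vals <- impute_row_median(vals, ids)
    } else {
      i <- arrayInd(which(is.na(vals))[1L], dim(vals))
      stop("missing value at row '", ids[i[1L]], "', column '",
           colnames(body)[i[2L]], "' in ", path,
           " (set impute = TRUE for row-median imputation)")
    }
  }
  dimnames(vals) <- list(ids, colnames(body))
  data_matrix(vals, dtype_tag = dtype_tag)
}

impute_row_median <- function(vals, ids) {
  for (i in seq_len(nrow(vals))) {
    na <- is.na(vals[i, ])
    if (all(na)) stop("row '", ids[i], "' is entirely missing; cannot impute")
    if (any(na)) vals[i, na] <- stats::median(vals[i, !na])
  }
  vals
}

#' Write a data matrix to TSV
#'
#' Inverse of [read_data_matrix()]: header row of sample IDs, first column of
#' variable IDs, full-precision numeric body.
#'
#' @param m a [data_matrix].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_data_matrix <- function(m, path) {
  stopifnot(inherits(m, "data_matrix"))
  df <- data.frame(id = m$variable_ids,
                   format(m$values, digits = 17, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Reads a TSV with columns \code{sample_id}, \code{time}, \code{censored}
#' (0 = event observed, 1 = censored). Times must be positive.
#'
#' @param path path to the TSV file.
#' @return A data frame with columns \code{sample_id} (character),
#'   \code{time} (positive numeric) and \code{censored} (0/1 integer).
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "censored")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("survival table lacks columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in survival table")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop("survival times must be finite and positive")
  if (!all(df$censored %in% c(0, 1)))
    stop("'censored' must be 0 (event) or 1 (censored)")
  df[need]
}
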