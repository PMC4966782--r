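#' Stack a multi-modal data set into a super-matrix
#'
#' Vertically concatenates the per-type matrices of an MMDS along their shared
#' sample axis. All blocks must carry identical sample IDs in identical order;
#' with \code{reorder = TRUE} later blocks are permuted to the column order of
#' the first block by ID.
#'
#' @param mmds a list of [data_matrix] objects (or a single one).
#' @param reorder permit reordering of columns by sample ID. Default
#'   \code{FALSE}: any order mismatch is an error.
#' @param scale if \code{TRUE} (default \code{FALSE}), the stacked matrix is
#'   immediately scaled by its Frobenius norm (see [frobenius_scale()]).
#' @param scale_blocks if \code{TRUE}, each block is divided by its own
#'   Frobenius norm before stacking. Off by default: the standard convention
#'   scales only the stacked matrix.
#' @return An object of class \code{"super_matrix"}: a list with
#'   \code{values} (p x n matrix), \code{block_map} (data frame with
#'   \code{dtype_tag}, \code{row_start}, \code{row_end}; half-open 0-based
#'   ranges), \code{variable_ids}, \code{sample_ids}, and
#'   \code{frobenius_applied}.
#' @examples
#' a <- data_matrix(matrix(1:6, 3, 2), paste0("g", 1:3), c("s1", "s2"), "mRNA")
#' b <- data_matrix(matrix(1:4, 2, 2), paste0("m", 1:2), c("s1", "s2"), "miRNA")
#' sm <- stack_mmds(list(a, b))
#' sm$block_map
#' @export
stack_mmds <- function(mmds, reorder = FALSE, scale = FALSE,
                       scale_blocks = FALSE) {
  if (inherits(mmds, "data_matrix")) mmds <- list(mmds)
  stopifnot(length(mmds) >= 1L, all(vapply(mmds, inherits, TRUE, "data_matrix")))
  ref <- mmds[[1L]]$sample_ids
  mats <- vector("list", length(mmds))
  for (k in seq_along(mmds)) {
    m <- mmds[[k]]
    if (!setequal(m$sample_ids, ref) || length(m$sample_ids) != length(ref)) {
      off <- c(setdiff(ref, m$sample_ids), setdiff(m$sample_ids, ref))
      stop("block ", k, " ('", m$dtype_tag, "') sample IDs differ from block 1: ",
           paste(utils::head(off, 10L), collapse = ", "))
    }
    if (!identical(m$sample_ids, ref)) {
      if (!reorder)
        stop("block ", k, " ('", m$dtype_tag, "') sample order differs from ",
             "block 1; pass reorder = TRUE to align by ID")
      m$values <- m$values[, match(ref, m$sample_ids), drop = FALSE]
      m$sample_ids <- ref
    }
    v <- m$values
    if (scale_blocks) {
      fn <- sqrt(sum(v^2))
      if (fn == 0) stop("block ", k, " is all zero; cannot scale")
      v <- v / fn
    }
    mats[[k]] <- v
  }
  p_k <- vapply(mats, nrow, 0L)
  ends <- cumsum(p_k)
  block_map <- data.frame(
    dtype_tag = vapply(mmds, function(m) m$dtype_tag, ""),
    row_start = c(0L, ends[-length(ends)]),
    row_end = ends,
    stringsAsFactors = FALSE)
  vid <- unlist(lapply(mmds, function(m) m$variable_ids), use.names = FALSE)
  if (anyDuplicated(paste(rep(block_map$dtype_tag, p_k), vid)))
    stop("duplicate (dtype_tag, variable_id) pairs across blocks")
  sm <- structure(list(values = do.call(rbind, mats), block_map = block_map,
                       variable_ids = vid, sample_ids = ref,
                       frobenius_applied = FALSE),
                  class = "super_matrix")
  if (scale) sm <- frobenius_scale(sm) else sm
}

#' Scale a super-matrix by its Frobenius norm
#'
#' Divides all entries by the Frobenius norm so the scaled matrix has unit
#' norm; this puts blocks with different row counts and dynamic ranges on a
#' common scale before the penalized rank-1 fit.
#'
#' @param sm a \code{"super_matrix"}.
#' @return The scaled \code{"super_matrix"} with \code{frobenius_applied}
#'   set.
#' @export
frobenius_scale <- function(sm) {
  stopifnot(inherits(sm, "super_matrix"))
  fn <- sqrt(sum(sm$values^2))
  if (fn == 0) stop("zero matrix: Frobenius norm is 0, cannot scale")
  sm$values <- sm$values / fn
  sm$frobenius_applied <- TRUE
  sm
}

#' Extract one block of a super-matrix as a data_matrix
#'
#' @param sm a \code{"super_matrix"}.
#' @param k block index (row of \code{sm$block_map}).
#' @return The k-th block as a [data_matrix].
#' @export
block_slice <- function(sm, k) {
  stopifnot(inherits(sm, "super_matrix"), k >= 1L, k <= nrow(sm$block_map))
  b <- sm$block_map[k, ]
  idx <- (b$row_start + 1L):b$row_end
  data_matrix(sm$values[idx, , drop = FALSE], sm$variable_ids[idx],
              sm$sample_ids, b$dtype_tag)
}

# block index (1..K) for each of the p rows
block_of_rows <- function(sm) {
  rep.int(seq_len(nrow(sm$block_map)),
          sm$block_map$row_end - sm$block_map$row_start)
}

#' @export
print.super_matrix <- function(x, ...) {
  cat(sprintf("super_matrix: %d rows x %d samples, %d block(s)%s\n",
              nrow(x$values), ncol(x$values), nrow(x$block_map),
              if (x$frobenius_applied) ", Frobenius-scaled" else ""))
  for (k in seq_len(nrow(x$block_map)))
    cat(sprintf("  %s: rows [%d, %d)\n", x$block_map$dtype_tag[k],
                x$block_map$row_start[k], x$block_map$row_end[k]))
  invisible(x)
}

#' @export
dim.super_matrix <- function(x) dim(x$values)

#' @export
as.matrix.super_matrix <- function(x, ...) x$values

# Coerce matrix / data_matrix / list-of-data_matrix input to a scaled
# super_matrix. Used by the fitting front ends.
as_super_matrix <- function(x, scale = TRUE) {
  if (inherits(x, "super_matrix")) {
    if (scale && !x$frobenius_applied) x <- frobenius_scale(x)
    return(x)
  }
  if (inherits(x, "data_matrix")) return(stack_mmds(list(x), scale = scale))
  if (is.list(x)) return(stack_mmds(x, scale = scale))
  if (is.matrix(x)) return(stack_mmds(list(data_matrix(x)), scale = scale))
  stop("cannot interpret input of class '", paste(class(x), collapse = "/"),
       "' as a super-matrix")
}
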