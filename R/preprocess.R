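#' Log2 or generalized-log2 transform
#'
#' With \code{glog_c = 0} this is the plain elementwise \code{log2(x)} and all
#' values must be positive. With \code{glog_c > 0} the generalized log2
#' \deqn{glog2(x) = log2((x + sqrt(x^2 + c)) / 2)}
#' is applied, which is defined for all real \code{x} (including values driven
#' negative by background subtraction) and converges to \code{log2(x)} as
#' \code{c} tends to zero.
#'
#' @param m a [data_matrix].
#' @param glog_c non-negative regularization constant \code{c}; 0 gives the
#'   plain log2.
#' @return A transformed [data_matrix].
#' @export
log2_transform <- function(m, glog_c = 0) {
  stopifnot(inherits(m, "data_matrix"), glog_c >= 0)
  x <- m$values
  if (glog_c == 0) {
    if (any(x <= 0)) {
      i <- arrayInd(which(x <= 0)[1L], dim(x))
      stop("non-positive entry at row '", m$variable_ids[i[1L]],
           "', column '", m$sample_ids[i[2L]],
           "'; use glog_c > 0 for a transform defined on all reals")
    }
    x <- log2(x)
  } else {
    x <- log2((x + sqrt(x^2 + glog_c)) / 2)
  }
  data_matrix(x, m$variable_ids, m$sample_ids, m$dtype_tag)
}

#' Quantile-normalize the columns of a data matrix
#'
#' Forces every column to share the same marginal distribution: the value at
#' each rank is replaced by the cross-column mean of that rank's values, ties
#' receiving the mean of their ranks' reference values. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param m a [data_matrix].
#' @return A quantile-normalized [data_matrix].
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "data_matrix"))
  x <- limma::normalizeQuantiles(m$values, ties = TRUE)
  data_matrix(x, m$variable_ids, m$sample_ids, m$dtype_tag)
}

#' Convert methylation Beta-values to M-values
#'
#' Applies the logit-type transform \code{M = log2(beta / (1 - beta))} after
#' clipping Beta to \code{[eps, 1 - eps]} so that boundary values stay finite.
#'
#' @param m a [data_matrix] with all values in \code{[0, 1]}.
#' @param eps clipping margin, default \code{1e-6}.
#' @return A [data_matrix] of M-values.
#' @export
beta_to_m <- function(m, eps = 1e-6) {
  stopifnot(inherits(m, "data_matrix"), eps > 0, eps < 0.5)
  x <- m$values
  if (any(x < 0 | x > 1)) {
    i <- arrayInd(which(x < 0 | x > 1)[1L], dim(x))
    stop("Beta-value outside [0, 1] at row '", m$variable_ids[i[1L]],
         "', column '", m$sample_ids[i[2L]], "'")
  }
  x <- pmin(pmax(x, eps), 1 - eps)
  data_matrix(log2(x / (1 - x)), m$variable_ids, m$sample_ids, m$dtype_tag)
}

#' Invert the Beta-to-M transform
#'
#' @param m a [data_matrix] of M-values.
#' @return A [data_matrix] of Beta-values, \code{beta = 2^M / (1 + 2^M)}.
#' @export
m_to_beta <- function(m) {
  stopifnot(inherits(m, "data_matrix"))
  x <- 2^m$values
  data_matrix(x / (1 + x), m$variable_ids, m$sample_ids, m$dtype_tag)
}

#' Center each row of a data matrix at zero
#'
#' @param m a [data_matrix] with at least two samples.
#' @return A [data_matrix] whose rows each have mean zero. Idempotent.
#' @export
row_center <- function(m) {
  stopifnot(inherits(m, "data_matrix"))
  x <- m$values - rowMeans(m$values)
  data_matrix(x, m$variable_ids, m$sample_ids, m$dtype_tag)
}
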