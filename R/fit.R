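#' Best rank-1 approximation by the SVD
#'
#' Returns the leading singular triplet in the orientation used throughout
#' the package: \code{u0} is the unit left singular vector with its
#' largest-magnitude entry made positive, \code{v0 = sigma * v1} carries the
#' singular value, so \code{u0 \%*\% t(v0)} is the Eckart-Young best rank-1
#' approximation of \code{D}.
#'
#' @param D numeric matrix (or \code{super_matrix} / [data_matrix]).
#' @return A list with \code{u0} (unit norm), \code{v0} (\code{= sigma *}
#'   unit right singular vector) and \code{sigma}.
#' @export
svd_rank1 <- function(D) {
  D <- raw_values(D)
  if (all(D == 0)) stop("zero matrix has no rank-1 approximation")
  # for tall-thin matrices the n x n eigenproblem of crossprod(D) is much
  # cheaper than svd(D); fall back to svd() for wide matrices
  if (nrow(D) >= ncol(D)) {
    e <- eigen(crossprod(D), symmetric = TRUE)
    sigma <- sqrt(max(e$values[1L], 0))
    v <- e$vectors[, 1L]
    u <- unname(drop(D %*% v))
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("degenerate leading singular vector")
    u <- u / nu
    sigma <- nu
  } else {
    s <- svd(D, nu = 1L, nv = 1L)
    sigma <- s$d[1L]
    u <- drop(s$u)
    v <- drop(s$v)
  }
  if (u[which.max(abs(u))] < 0) {
    u <- -u
    v <- -v
  }
  list(u0 = u, v0 = sigma * v, sigma = sigma)
}

raw_values <- function(x) {
  if (inherits(x, c("super_matrix", "data_matrix"))) x$values
  else as.matrix(x)
}

#' Penalized eigen-array update (row-wise soft threshold)
#'
#' The exact minimizer of \eqn{\|D - u v^T\|_F^2 + \lambda \|u\|_1} over
#' \code{u} for a fixed eigen-signal \code{v}: with \eqn{z_i = d_i \cdot v}
#' (row \code{i} of \code{D} dotted with \code{v}),
#' \deqn{u_i = sign(z_i) max(|z_i| - \lambda/2, 0) / \|v\|^2.}
#'
#' @param D numeric matrix (p x n).
#' @param v numeric vector of length n with positive norm.
#' @param lam non-negative l1 penalty.
#' @return The minimizing vector \code{u} of length p.
#' @export
sparse_u_update <- function(D, v, lam) {
  D <- raw_values(D)
  stopifnot(length(v) == ncol(D), lam >= 0)
  nv2 <- sum(v^2)
  if (nv2 == 0) stop("'v' must be nonzero")
  z <- drop(D %*% v)
  sign(z) * pmax(abs(z) - lam / 2, 0) / nv2
}

#' Sparse rank-1 fit of a super-matrix
#'
#' Fits the penalized rank-1 model
#' \deqn{min_{u,v} \|D - u v^T\|_F^2 + \lambda \|u\|_1, \quad v = D^T u,}
#' by alternating the exact soft-threshold update of the sparse eigen-array
#' \code{u} with the eigen-signal update \code{v = D^T v}-direction, starting
#' from the SVD rank-1 initialization. The nonzero entries of \code{u} define
#' the multi-modal signature; \code{v} is the per-sample signal they jointly
#' model.
#'
#' Internally \code{v} is kept at unit norm for fixed-point stability. On
#' exit the penalty's role is model selection only: the returned
#' eigen-array carries the unpenalized least-squares weights on the
#' selected support (relaxed-lasso debiasing), normalized to unit l2 norm
#' and sign-fixed so its largest entry is positive, and \code{v = D^T u} is
#' recomputed. The returned outer product \code{u v^T = u u^T D} is then
#' the best rank-1 approximation of \code{D} in the fitted sparse
#' direction, so deflating it removes the detected component cleanly; at
#' \code{lambda = 0} it equals the SVD truncation exactly.
#'
#' @param x input matrix: a \code{super_matrix}, a [data_matrix], a list of
#'   them (stacked and Frobenius-scaled automatically), or a plain matrix.
#' @param lambda non-negative l1 penalty; interpreted on the
#'   Frobenius-scaled super-matrix.
#' @param tol convergence tolerance on the relative l2 change of both
#'   factors, default \code{1e-6}.
#' @param max_iter iteration cap, default 500.
#' @param scale Frobenius-scale the input if not already scaled (default
#'   \code{TRUE}; plain matrices passed as-is set this to keep their scale
#'   with \code{scale = FALSE}).
#' @param init optional precomputed [svd_rank1()] initialization.
#' @return An object of class \code{"jammit"}: list with the sparse unit
#'   eigen-array \code{u}, eigen-signal \code{v} (\code{= D^T u}), penalty
#'   \code{lambda}, signature size \code{s} (nonzeros of \code{u}),
#'   \code{n_iter}, \code{converged}, \code{objective_trace} (internal
#'   penalized objective after each u-update; non-increasing), the
#'   \code{signature} (see [jammit_signature()]) and the scaled input
#'   \code{super_matrix}.
#' @examples
#' sim <- simulate_mmds(simulation_config(p_choices = 200, n = 20, seed = 1))
#' fit <- jammit(sim$blocks, lambda = 0.2 * lambda_grid(stack_mmds(sim$blocks,
#'                scale = TRUE), L = 3)$lambdas[3])
#' print(fit)
#' @export
jammit <- function(x, lambda, tol = 1e-6, max_iter = 500L, scale = TRUE,
                   init = NULL) {
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1L)
  sm <- as_super_matrix(x, scale = scale)
  D <- sm$values
  if (all(D == 0)) stop("zero super-matrix")
  if (is.null(init)) init <- svd_rank1(D)
  v <- init$v0 / sqrt(sum(init$v0^2))  # unit-norm internal eigen-signal
  u <- init$u0
  obj <- numeric(0L)
  d2 <- sum(D^2)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    z <- drop(D %*% v)
    u_new <- sign(z) * pmax(abs(z) - lambda / 2, 0)  # ||v|| = 1
    if (any(!is.finite(u_new)))
      stop("non-finite eigen-array at iteration ", iter)
    # E(u, v) with unit v, evaluated right after the u-update
    obj <- c(obj, d2 - 2 * sum(u_new * z) + sum(u_new^2) +
               lambda * sum(abs(u_new)))
    if (all(u_new == 0)) {  # fully shrunk: empty fit
      u <- u_new
      v <- rep(0, ncol(D))
      converged <- TRUE
      break
    }
    v_raw <- drop(crossprod(D, u_new))
    nv <- sqrt(sum(v_raw^2))
    if (!is.finite(nv) || nv == 0)
      stop("degenerate eigen-signal at iteration ", iter)
    v_new <- v_raw / nv
    du <- rel_change(u_new, u)
    dv <- rel_change(v_new, v)
    u <- u_new
    v <- v_new
    if (du < tol && dv < tol) {
      converged <- TRUE
      break
    }
  }
  s <- sum(u != 0)
  if (s > 0) {
    # debiased exit: the penalty decides which rows enter; the returned
    # loadings are the unpenalized least-squares weights on that support
    # (relaxed-lasso style), so deflating u v^T removes the detected
    # component without leaving a shrinkage-sized slice of signal behind
    z <- drop(D %*% v)
    u <- ifelse(u != 0, z, 0)
    u <- u / sqrt(sum(u^2))
    if (u[which.max(abs(u))] < 0) u <- -u
    v <- drop(crossprod(D, u))
  } else {
    u <- rep(0, nrow(D))
    v <- rep(0, ncol(D))
  }
  names(u) <- sm$variable_ids
  names(v) <- sm$sample_ids
  fit <- structure(list(u = u, v = v, lambda = lambda, s = s,
                        n_iter = iter, converged = converged,
                        objective_trace = obj, super_matrix = sm),
                   class = "jammit")
  fit$signature <- jammit_signature(fit, sm)
  fit
}

rel_change <- function(a, b) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(if (all(a == 0)) 0 else Inf)
  sqrt(sum((a - b)^2)) / nb
}

#' Parse a fitted eigen-array into a multi-modal signature
#'
#' Maps the nonzero entries of the sparse eigen-array back to variable IDs
#' and data-type tags by the stacking order of the super-matrix, and counts
#' the selected variables per block.
#'
#' @param fit a \code{"jammit"} fit.
#' @param sm the \code{"super_matrix"} the fit was computed on (defaults to
#'   the one stored in the fit).
#' @return An object of class \code{"jammit_signature"}: list with
#'   \code{entries} (data frame \code{variable_id}, \code{dtype_tag},
#'   \code{weight}, \code{row}) and \code{per_block_counts} (named integer
#'   vector, one per block, summing to \code{fit$s}).
#' @export
jammit_signature <- function(fit, sm = fit$super_matrix) {
  stopifnot(inherits(fit, "jammit"), inherits(sm, "super_matrix"))
  if (length(fit$u) != nrow(sm$values))
    stop("eigen-array length ", length(fit$u),
         " does not match super-matrix rows ", nrow(sm$values))
  nz <- which(fit$u != 0)
  blk <- block_of_rows(sm)
  tags <- sm$block_map$dtype_tag
  counts <- integer(length(tags))
  if (length(nz)) counts <- tabulate(blk[nz], nbins = length(tags))
  names(counts) <- tags
  entries <- data.frame(variable_id = sm$variable_ids[nz],
                        dtype_tag = tags[blk[nz]],
                        weight = unname(fit$u[nz]),
                        row = nz,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, per_block_counts = counts),
            class = "jammit_signature")
}

#' @export
print.jammit_signature <- function(x, ...) {
  cat(sprintf("multi-modal signature: %d variable(s)\n", nrow(x$entries)))
  for (k in seq_along(x$per_block_counts))
    cat(sprintf("  %s: %d\n", names(x$per_block_counts)[k],
                x$per_block_counts[k]))
  invisible(x)
}

#' Deflate a matrix by a fitted rank-1 component
#'
#' Subtracts the fitted outer product, \code{D' = D - u v^T}, exposing weaker
#' signals for a further fit.
#'
#' @param D matrix or \code{super_matrix} of the same shape the fit was
#'   computed on.
#' @param fit a \code{"jammit"} fit.
#' @return An object of the same kind as \code{D} holding the residual.
#' @export
residualize <- function(D, fit) {
  stopifnot(inherits(fit, "jammit"))
  vals <- raw_values(D)
  if (nrow(vals) != length(fit$u) || ncol(vals) != length(fit$v))
    stop("shape mismatch: matrix is ", nrow(vals), " x ", ncol(vals),
         ", fit is ", length(fit$u), " x ", length(fit$v))
  res <- vals - tcrossprod(fit$u, fit$v)
  if (inherits(D, "super_matrix")) {
    D$values <- res
    D
  } else if (inherits(D, "data_matrix")) {
    data_matrix(res, D$variable_ids, D$sample_ids, D$dtype_tag)
  } else res
}

#' @export
print.jammit <- function(x, ...) {
  cat(sprintf(
    "jammit fit: lambda = %.6g, signature size s = %d of %d rows\n",
    x$lambda, x$s, length(x$u)))
  cat(sprintf("  %d iteration(s), %sconverged\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  if (x$s > 0) {
    pb <- x$signature$per_block_counts
    cat("  per block:", paste(sprintf("%s = %d", names(pb), pb),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.jammit <- function(object, ...) {
  out <- list(lambda = object$lambda, s = object$s,
              per_block_counts = object$signature$per_block_counts,
              n_iter = object$n_iter, converged = object$converged,
              final_objective = utils::tail(object$objective_trace, 1L),
              explained = explained_fraction(object))
  class(out) <- "summary.jammit"
  out
}

explained_fraction <- function(fit) {
  d2 <- sum(fit$super_matrix$values^2)
  if (d2 == 0 || fit$s == 0) return(0)
  sum(fit$v^2) / d2  # ||u u^T D||_F^2 = ||D^T u||_F^2 for unit u
}

#' @export
print.summary.jammit <- function(x, ...) {
  cat(sprintf("Sparse rank-1 fit (lambda = %.6g)\n", x$lambda))
  cat(sprintf("  signature size: %d (%s)\n", x$s,
              paste(sprintf("%s = %d", names(x$per_block_counts),
                            x$per_block_counts), collapse = ", ")))
  cat(sprintf("  iterations: %d (%sconverged)\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  cat(sprintf("  penalized objective: %.6g\n", x$final_objective))
  cat(sprintf("  variance explained by fitted component: %.3f\n",
              x$explained))
  invisible(x)
}

#' @export
coef.jammit <- function(object, sparse = TRUE, ...) {
  if (sparse) {
    w <- object$u[object$u != 0]
    w
  } else object$u
}

#' @export
fitted.jammit <- function(object, ...) tcrossprod(object$u, object$v)

#' @export
residuals.jammit <- function(object, ...) {
  object$super_matrix$values - fitted(object)
}

#' Project new samples onto a fitted eigen-array
#'
#' Computes eigen-signal scores \code{t(D_new) \%*\% u} for new sample
#' columns measured on the same stacked variables.
#'
#' @param object a \code{"jammit"} fit.
#' @param newdata matrix (or \code{super_matrix}) with the same rows as the
#'   training super-matrix; columns are new samples. Missing: returns the
#'   training eigen-signal.
#' @param ... unused.
#' @return Numeric vector of per-sample scores.
#' @export
predict.jammit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$v)
  vals <- raw_values(newdata)
  if (nrow(vals) != length(object$u))
    stop("newdata has ", nrow(vals), " rows; fit expects ", length(object$u))
  drop(crossprod(vals, object$u))
}

#' @export
plot.jammit <- function(x, which = c("eigen-signal", "eigen-array"), ...) {
  which <- match.arg(which)
  if (which == "eigen-signal") {
    plot(seq_along(x$v), x$v, type = "h", xlab = "sample",
         ylab = "eigen-signal score",
         main = sprintf("Eigen-signal (lambda = %.4g, s = %d)", x$lambda,
                        x$s), ...)
  } else {
    plot(seq_along(x$u), x$u, type = "h", xlab = "super-matrix row",
         ylab = "eigen-array loading",
         main = sprintf("Sparse eigen-array (s = %d)", x$s), ...)
    abline(h = 0, col = "grey60")
  }
  invisible(x)
}
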