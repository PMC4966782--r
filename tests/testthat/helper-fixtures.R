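# shared fixture builders; everything is generated in code at test time

rand_dm <- function(p, n, seed = 1L, tag = "mRNA") {
  set.seed(seed)
  data_matrix(matrix(rnorm(p * n), p, n), sprintf("v%03d", seq_len(p)),
              sprintf("s%02d", seq_len(n)), tag)
}

# tiny two-block MMDS with a single planted step signal on known rows
planted_mmds <- function(p = 100L, n = 20L, n_sup = 5L, amp = 3,
                         seed = 1L) {
  set.seed(seed)
  sig <- make_step_signal(n)
  blocks <- lapply(1:2, function(k) {
    x <- matrix(rnorm(p * n), p, n)
    rows <- seq_len(n_sup) + (k - 1L)  # deterministic, distinct per block
    x[rows, ] <- x[rows, ] + amp * rep(1, n_sup) %o% sig
    data_matrix(x, sprintf("b%d_v%03d", k, seq_len(p)),
                sprintf("s%02d", seq_len(n)), paste0("type", k))
  })
  sup <- rep(FALSE, 2L * p)
  sup[seq_len(n_sup)] <- TRUE
  sup[p + seq_len(n_sup) + 1L] <- TRUE
  list(blocks = blocks, support = sup, signal = sig)
}

sig_rows <- function(fit) fit$signature$entries$row

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# minimal fdr_profile stub for exercising the selection rule on fixed values
fdr_stub <- function(fdr) {
  L <- length(fdr)
  structure(list(grid = structure(list(lambdas = seq(0, 1, length.out = L),
                                       L = L, lambda_sup = 1),
                                  class = "lambda_grid"),
                 s_obs = rep(1L, L), fdr_joint = fdr,
                 fdr_per_block = matrix(fdr, L, 1), B = 1L, seed = 1L),
            class = "fdr_profile")
}
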