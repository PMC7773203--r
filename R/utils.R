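# Shared internals: seeded evaluation and the exact/approximate
# Mann-Whitney machinery used by both the signal and composition modules.

# Evaluate `expr` under a temporary RNG state; restores (or clears) the
# caller's state afterwards so seeded helpers never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct sub-stream seed from a base seed and a small stream
# index.  Documented scheme: (seed * 101 + 7919 * stream) mod 2^31 - 1.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 101 + 7919 * stream) %% 2147483647)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' The U statistic for `x` with an exact permutation null (full enumeration
#' of all `choose(nx + ny, nx)` labelings, ties handled naturally) when
#' `nx + ny <= exact_limit`, and a tie-corrected normal approximation with
#' continuity correction otherwise.  The two-sided exact p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Numeric vectors.
#' @param exact_limit Enumerate exactly up to this combined size
#'   (default 20).
#' @return List with `U` (for `x`), `p`, and `method`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 20L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_limit) {
    sets <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}
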