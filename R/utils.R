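# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers behave as pure functions of their inputs.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Smallest highly-composite FFT size >= n.
fft_size <- function(n) stats::nextn(n, factors = c(2, 3, 5))

#' 2-D linear convolution via FFT
#'
#' Computes `out[y] = sum_x A[x] * K[y - x]` where `K` is a kernel array with
#' odd dimensions and its origin at the centre element. Output has the
#' dimensions of `A`; values of `A` outside its support are treated as zero.
#'
#' @param A numeric matrix.
#' @param K numeric kernel matrix with odd dimensions.
#' @param K_fft optional precomputed `fft` of the zero-padded kernel, as
#'   returned by [conv2_plan()]; avoids recomputation in iterative solvers.
#' @return numeric matrix with `dim(A)`.
#' @keywords internal
conv2_fft <- function(A, K = NULL, K_fft = NULL) {
  nr <- nrow(A); nc <- ncol(A)
  if (is.null(K_fft)) K_fft <- conv2_plan(dim(A), K)
  pr <- K_fft$pr; pc <- K_fft$pc
  Ap <- matrix(0, pr, pc)
  Ap[seq_len(nr), seq_len(nc)] <- A
  full <- Re(stats::fft(stats::fft(Ap) * K_fft$Kf, inverse = TRUE)) / (pr * pc)
  # kernel centre offset: first valid output row is at index kr2 + 1
  full[K_fft$kr2 + seq_len(nr), K_fft$kc2 + seq_len(nc)]
}

# Precompute the padded-kernel FFT for repeated convolutions with fixed K.
conv2_plan <- function(dimA, K) {
  kr <- nrow(K); kc <- ncol(K)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- fft_size(dimA[1] + kr - 1)
  pc <- fft_size(dimA[2] + kc - 1)
  Kp <- matrix(0, pr, pc)
  Kp[seq_len(kr), seq_len(kc)] <- K
  list(Kf = stats::fft(Kp), pr = pr, pc = pc,
       kr2 = (kr - 1L) %/% 2L, kc2 = (kc - 1L) %/% 2L)
}

# Ordinary least-squares slope of y on x (two vectors, no intercept report).
ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}
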