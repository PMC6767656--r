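#' @importFrom stats rnorm runif setNames approx
#' @importFrom utils head tail modifyList write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' master seed and a stage name, so that changing e.g. the training seed does
#' not perturb phantom generation.
#'
#' @param master_seed integer master seed.
#' @param name character stage name, e.g. `"generate"` or `"train/1"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, name) {
  h <- rlang::hash(list(as.integer(master_seed), as.character(name)))
  # fold the 128-bit hex digest into a 31-bit integer
  v <- strtoi(substring(h, seq(1, 25, by = 6), seq(6, 30, by = 6)), base = 16L)
  as.integer(sum(v * c(1, 3, 7, 31, 127)) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_csinet <- function(...) stop(sprintf(...), call. = FALSE)

# squared Frobenius norm of a complex vector/matrix
cnorm2 <- function(x) sum(Re(x)^2 + Im(x)^2)

# conjugate-linear-in-first-argument inner product
cdot <- function(a, b) sum(Conj(a) * b)
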