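#' @importFrom stats rnorm rlnorm rnbinom runif median p.adjust pnorm pt sd
#' @importFrom stats var
#'   cor kmeans quantile fisher.test setNames complete.cases
#' @importFrom utils read.table write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Hashes a root seed together with an arbitrary list of string labels into a
#' 31-bit integer seed. Used so that every simulated object (one track, one
#' count matrix) draws from its own stream: adding or reordering objects never
#' perturbs the others.
#'
#' @param root integer root seed.
#' @param ... character/numeric labels identifying the substream.
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(root, ...) {
  labels <- paste(c(as.character(root), vapply(list(...), as.character, "")),
                  collapse = "\x1f")
  bytes <- utf8ToInt(labels)
  # Polynomial hash mod the Mersenne prime 2^31 - 1. The multiplier 48271
  # (the MINSTD Lehmer constant) keeps every intermediate product below
  # 2^53, so the arithmetic stays exact in double precision.
  p <- 2147483647
  h <- 2166136261 %% p
  for (b in bytes) {
    h <- (h * 48271 + b) %% p
  }
  as.integer(h %% (p - 1) + 1)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions up to renaming).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## internal: run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
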