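# Internal helpers shared across modules.

IUPAC_ALPHABET <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N", "-")
BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_resolved <- function(x) x %in% BASES

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible sub-stream seed
#'
#' All stochastic routines accept a single integer seed; independent
#' sub-streams (replicates, bootstrap draws, generator stages) derive their
#' own seeds from it so that one top-level seed fixes the whole analysis.
#'
#' @param seed Integer master seed.
#' @param i Integer sub-stream index.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, i) {
  # Weyl-style mixing; stays inside 32-bit signed range via modulus
  a <- (as.double(seed) %% 2147483647) + 1
  ((a * 48271 + as.double(i) * 16807) %% 2147483647)
}

# Simple union-find used by threshold clustering and partition consolidation
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

stop_input <- function(...) stop(..., call. = FALSE)

# Seed the RNG for this call only: the caller's stream is restored on exit
# so seeded routines do not silently couple their caller's simulations.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    do.call(on.exit,
            list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
                 add = TRUE),
            envir = envir)
  }
  set.seed(seed)
  invisible(NULL)
}
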