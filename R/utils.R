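#' Derive a named substream seed from a root seed
#'
#' All randomised stages (simulation, HMM initialisation, k-means restarts)
#' draw their seeds from one root seed through named substreams, so each
#' stage is individually reproducible and stages do not share streams.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. `"simulate"`, `"hmm-init"`).
#' @param index optional integer (e.g. region or restart index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substreamSeed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps results in integer range
  s <- (as.double(seed) %% m) * 48271 %% m
  s <- (s + h * 69621 + as.double(index) * 16807) %% m
  as.integer(s)
}

#' Evaluate an expression with a local RNG state
#'
#' Seeds the generator for the duration of `expr` and restores the caller's
#' RNG state afterwards, so package functions never disturb the session RNG.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Hungarian-matched label agreement
#'
#' Best accuracy between two labelings over all permutations of the label
#' alphabet of `pred`. With k small (here k = 3) exhaustive enumeration of
#' the k! permutations is the assignment solver.
#'
#' @param truth,pred integer/factor vectors of equal length.
#' @return list with `agreement` (fraction correct under best matching) and
#'   `permutation` (the relabelling applied to `pred`).
#' @export
matchLabels <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tl <- sort(unique(truth))
  pl <- sort(unique(pred))
  k <- max(length(tl), length(pl))
  if (k > 8L) stop("matchLabels enumerates permutations; k > 8 unsupported")
  # confusion counts, padded square
  conf <- matrix(0L, k, k)
  for (i in seq_along(tl)) for (j in seq_along(pl)) {
    conf[i, j] <- sum(truth == tl[i] & pred == pl[j])
  }
  perms <- permutations(k)
  best <- -1L
  bestp <- perms[1L, ]
  for (r in seq_len(nrow(perms))) {
    acc <- sum(conf[cbind(perms[r, ], seq_len(k))])
    if (acc > best) {
      best <- acc
      bestp <- perms[r, ]
    }
  }
  list(agreement = best / length(truth), permutation = bestp)
}

# all permutations of 1..n as rows
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# maximal runs of 1s in a 0/1 vector -> matrix(start, end) in sample indices
runsOfOnes <- function(x) {
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  cbind(start = starts[keep], end = ends[keep])
}

# Jaccard index of two 0/1 vectors
jaccardIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a > 0 | b > 0)
  if (u == 0) return(NA_real_)
  sum(a > 0 & b > 0) / u
}
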