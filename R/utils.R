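# Internal helpers shared across modules.

#' Canonical key for an unordered gene pair
#'
#' Endpoints are sorted lexicographically and joined with \code{"|"}, so the
#' key is independent of argument order. Gene identifiers must not contain
#' \code{"|"}.
#'
#' @param a,b character vectors of gene identifiers (recycled together).
#' @return character vector of pair keys.
#' @export
pairKey <- function(a, b) {
  swap <- a > b
  unname(ifelse(swap, paste(b, a, sep = "|"), paste(a, b, sep = "|")))
}

# Sort each row's endpoints lexicographically, drop self pairs and duplicates,
# and order rows; returns an n x 2 character matrix.
canonicalPairs <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  a <- pmin(m[, 1L], m[, 2L])
  b <- pmax(m[, 1L], m[, 2L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(a, b, sep = "|")
  ord <- order(key)
  a <- a[ord]; b <- b[ord]; key <- key[ord]
  dup <- duplicated(key)
  cbind(a = a[!dup], b = b[!dup])
}

#' Derive a child seed from a master seed
#'
#' Stages of the pipeline (and bootstrap replicates within a stage) consume
#' independent child seeds derived arithmetically from the master seed, so a
#' stage can be rerun, or the replicate count changed, without reshuffling the
#' random stream of any other stage.
#'
#' @param master integer master seed.
#' @param stage integer stage index.
#' @param index integer replicate index within the stage (default 0).
#' @return an integer seed in [1, 2^31 - 20].
#' @export
childSeed <- function(master, stage, index = 0L) {
  # all intermediates < 2^53, so double arithmetic is exact
  x <- (as.numeric(master) %% 2147483647) * 7919 +
    as.numeric(stage) * 104729 + as.numeric(index) * 7907
  as.integer(x %% 2147483629) + 1L
}

# all unordered pairs over a character vector, lexicographic rows;
# returns n*(n-1)/2 x 2 matrix
allPairs <- function(genes) {
  genes <- sort(genes)
  n <- length(genes)
  if (n < 2L) {
    return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(a = genes[idx[, 1L]], b = genes[idx[, 2L]])
}

# number of unordered pairs over n nodes, exact in double precision
#' Number of candidate gene pairs
#'
#' @param n number of genes (nodes).
#' @return n*(n-1)/2 as a double (exact for any realistic atlas size).
#' @export
nGenePairs <- function(n) {
  stopifnot(length(n) == 1L, n >= 0)
  n * (n - 1) / 2
}
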