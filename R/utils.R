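# Internal helpers shared across modules.

#' Convert haplotype strings to an integer matrix
#'
#' Haplotypes are represented throughout as character strings over `{0,1}`
#' (one character per variant). This converts a vector of such strings into
#' an integer matrix with one row per haplotype.
#'
#' @param haps character vector of equal-length strings over `{0,1}`.
#' @return integer matrix (haplotypes x positions).
#' @keywords internal
haps_to_matrix <- function(haps) {
  if (length(haps) == 0L) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  k <- nchar(haps[1L])
  if (any(nchar(haps) != k)) stop("haplotype strings must have equal length")
  m <- matrix(utf8ToInt("0"), nrow = length(haps), ncol = k)
  for (i in seq_along(haps)) m[i, ] <- utf8ToInt(haps[i])
  m <- m - utf8ToInt("0")
  if (any(m != 0L & m != 1L)) stop("haplotype strings must be over {0,1}")
  storage.mode(m) <- "integer"
  m
}

#' @keywords internal
matrix_to_haps <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, function(r) paste(r, collapse = ""))
}

#' @keywords internal
str_to_int <- function(h) {
  v <- utf8ToInt(h) - utf8ToInt("0")
  storage.mode(v) <- "integer"
  v
}

# deterministic largest-remainder apportionment of `total` across cells in
# proportion to `weights`, honouring per-cell integer capacities
#' @keywords internal
apportion <- function(total, weights, capacity) {
  stopifnot(length(weights) == length(capacity), total <= sum(capacity))
  w <- weights
  w[capacity == 0L] <- 0
  if (sum(w) == 0) w <- as.numeric(capacity)
  quota <- total * w / sum(w)
  out <- pmin(floor(quota), capacity)
  rem <- total - sum(out)
  while (rem > 0L) {
    frac <- quota - floor(quota)
    frac[out >= capacity] <- -Inf
    i <- which.max(frac)
    if (!is.finite(frac[i])) { # all preferred cells full: spill anywhere
      i <- which(out < capacity)[1L]
    }
    out[i] <- out[i] + 1L
    quota[i] <- floor(quota[i]) # consume the fraction
    rem <- rem - 1L
  }
  as.integer(out)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
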