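`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the binary raster from a supported container
#'
#' Accepts a plain 0/1 matrix (neurons x bins), a [trial_ensemble] or an
#' [analysis_dataset] and returns the underlying integer raster.
#'
#' @param x matrix, `trial_ensemble` or `analysis_dataset`.
#' @return integer matrix, neurons in rows, 1-ms bins in columns.
#' @export
as_raster <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (inherits(x, c("trial_ensemble", "analysis_dataset"))) return(x$raster)
  stop("cannot extract a raster from an object of class ",
       paste(class(x), collapse = "/"))
}

## Euclidean cross-distance matrix between rows of A and rows of B.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

## Deterministic sub-seed derivation; keeps results below .Machine$integer.max
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed)
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483629
  as.integer(s)
}
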