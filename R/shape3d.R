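#' 12-moment molecular shape descriptor (USR)
#'
#' Computes the ultrafast-shape-recognition signature of a conformer: for
#' each of four reference points -- the centroid, the atom closest to the
#' centroid, the atom farthest from the centroid, and the atom farthest
#' from that atom -- the distances from every atom to the reference point
#' are summarised by their arithmetic mean, population standard deviation
#' and the signed cube root of the population third central moment. The
#' twelve values are returned in that reference-point order. The
#' descriptor is invariant under rigid motion (rotation + translation) of
#' the coordinates. Reference-atom ties are broken by lowest atom index.
#'
#' @param coords Numeric n x 3 matrix of atom coordinates (Angstrom),
#'   n >= 1, all finite. All atoms present in the record are used.
#' @return Numeric vector of length 12.
#' @examples
#' usrDescriptor(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
usrDescriptor <- function(coords) {
  coords <- .asCoords(coords)
  n <- nrow(coords)
  ctd <- colMeans(coords)
  dctd <- .distTo(coords, ctd)
  cst <- coords[which.min(dctd), ]          # closest to centroid (ties: lowest index)
  fct <- coords[which.max(dctd), ]          # farthest from centroid
  dfct <- .distTo(coords, fct)
  ftf <- coords[which.max(dfct), ]          # farthest from the farthest
  c(.moments3(dctd), .moments3(.distTo(coords, cst)),
    .moments3(dfct), .moments3(.distTo(coords, ftf)))
}

.asCoords <- function(coords) {
  if (is.null(dim(coords)) && length(coords) == 3L)
    coords <- matrix(coords, nrow = 1L)
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L || ncol(coords) != 3L)
    clStop("coordinates must be a non-empty n x 3 matrix",
           class = "ChemLinker_invalid_input")
  if (!all(is.finite(coords)))
    clStop("coordinates must all be finite",
           class = "ChemLinker_invalid_input")
  storage.mode(coords) <- "double"
  coords
}

.distTo <- function(coords, p) {
  sqrt(rowSums(sweep(coords, 2L, p)^2))
}

# mean, population sd, signed cube root of the population third central
# moment -- population (divide by n) so small-fixture values are exact.
.moments3 <- function(d) {
  n <- length(d)
  m <- mean(d)
  ctr <- d - m
  v <- sum(ctr^2) / n
  m3 <- sum(ctr^3) / n
  c(m, sqrt(v), sign(m3) * abs(m3)^(1 / 3))
}

#' Euclidean distance between two shape descriptors
#'
#' @param d1,d2 Numeric vectors of length 12 (see [usrDescriptor()]).
#' @return Non-negative L2 distance; 0 iff the vectors are equal.
#' @export
shapeDistance <- function(d1, d2) {
  if (length(d1) != 12L || length(d2) != 12L)
    clStop("shape descriptors must have exactly 12 values",
           class = "ChemLinker_invalid_input")
  sqrt(sum((as.numeric(d1) - as.numeric(d2))^2))
}

#' k-nearest-neighbour 3D shape search
#'
#' Ranks the store's conformers by Euclidean distance between their
#' precomputed 12-moment descriptors and the descriptor of the query
#' conformer, ascending; ties are broken by compound id ascending.
#'
#' @param query Query conformer: numeric n x 3 coordinate matrix.
#' @param store A [DataStore-class] (its \code{shapes} slot is used), or a
#'   bare named list of coordinate matrices.
#' @param k Number of neighbours to return (capped at the store size).
#' @return Data frame with columns \code{compound_id}, \code{distance},
#'   ascending distance. Empty when the store holds no conformers.
#' @export
search3D <- function(query, store, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    clStop("k must be a positive integer", class = "ChemLinker_invalid_input")
  shapes <- if (is(store, "DataStore")) store@shapes
            else vapply(store, usrDescriptor, numeric(12))
  if (length(shapes) == 0L || ncol(shapes) == 0L)
    return(data.frame(compound_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  qd <- usrDescriptor(query)
  d <- sqrt(colSums((shapes - qd)^2))
  ids <- colnames(shapes)
  o <- order(d, ids, method = "radix")
  o <- o[seq_len(min(as.integer(k), length(o)))]
  data.frame(compound_id = ids[o], distance = as.numeric(d[o]),
             stringsAsFactors = FALSE)
}
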