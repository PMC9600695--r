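# Internal morphology and image primitives shared by the plate and wrinkle modules.

#' @importFrom EBImage erode dilate
NULL

#' Disc structuring element
#'
#' Binary disc kernel of the given pixel radius. A pixel offset (dr, dc)
#' belongs to the disc when dr^2 + dc^2 <= radius^2, the same membership rule
#' used everywhere else in the package for circles on the pixel lattice.
#'
#' @param radius_px disc radius in pixels (>= 1)
#' @return a (2*radius+1) x (2*radius+1) 0/1 matrix
#' @keywords internal
disc_kernel <- function(radius_px) {
  stopifnot(is.numeric(radius_px), length(radius_px) == 1L, radius_px >= 1)
  r <- as.integer(radius_px)
  d <- -r:r
  k <- outer(d^2, d^2, `+`) <= radius_px^2
  storage.mode(k) <- "double"
  k
}

# Grayscale morphological opening (erosion then dilation) with a flat kernel.
# Out-of-image neighbours are ignored (min/max over in-image pixels only).
gray_opening <- function(x, kernel) {
  if (nrow(x) < nrow(kernel) || ncol(x) < ncol(kernel)) {
    stop("image (", nrow(x), "x", ncol(x), ") is smaller than the structuring element (",
         nrow(kernel), "x", ncol(kernel), ")")
  }
  out <- EBImage::dilate(EBImage::erode(x, kernel), kernel)
  matrix(as.numeric(out), nrow(x), ncol(x))
}

#' Label connected components of a binary mask
#'
#' 8-connectivity (edge or corner adjacency) by default, 4-connectivity
#' optionally. Background is 0; foreground components are numbered from 1.
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 8 (default) or 4
#' @return integer matrix of component labels, same shape as `mask`
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  fg <- which(mask != 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  # offsets to forward neighbours: S, E (+ SE, SW for 8-connectivity)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  for (o in offs) {
    r2 <- rr + o[1L]
    c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(id[fg][ok][hit], nb[hit])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # renumber components in first-pixel order for determinism
  memb <- match(memb, unique(memb))
  lab[fg] <- memb
  lab
}

# Otsu threshold (maximal between-class variance) on a [0,1] grayscale matrix.
otsu_level <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(n_bins, floor(x * n_bins) + 1L), nbins = n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
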