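# Independent brute-force oracles for the image pipeline. These implement the
# defining formulas directly (min/max over every structuring-element offset,
# flood-fill labeling, exhaustive circle counting) and share no code with the
# package implementation.

pim <- function(m, mm_per_px = 0.1) plate_image(m, mm_per_px)

disc_offsets <- function(radius_px) {
  r <- as.integer(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

# erosion/dilation by definition: extremum over all in-image disc offsets
oracle_extremum <- function(x, radius_px, op) {
  off <- disc_offsets(radius_px)
  nr <- nrow(x); nc <- ncol(x)
  acc <- matrix(if (identical(op, pmin)) Inf else -Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    dr <- off$dr[k]; dc <- off$dc[k]
    rs <- max(1, 1 - dr):min(nr, nr - dr)   # rows whose neighbour is in-image
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    acc[rs, cs] <- op(acc[rs, cs], x[rs + dr, cs + dc])
  }
  acc
}

oracle_opening <- function(x, radius_px) {
  oracle_extremum(oracle_extremum(x, radius_px, pmin), radius_px, pmax)
}

# flood-fill connected-component labeling (8- or 4-connectivity)
oracle_label <- function(bw, connectivity = 8) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!bw[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1L] + nb[k, 1L]; c2 <- p[2L] + nb[k, 2L]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            bw[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# full wrinkle-mask pipeline built on the oracles above
oracle_mask <- function(x, params) {
  bg <- oracle_opening(x, params$disk_radius_px)
  resid <- pmax(x - bg, 0)
  q <- stats::quantile(resid, params$stretch_percentiles / 100, names = FALSE)
  stretched <- if (q[2L] > q[1L]) {
    s <- (resid - q[1L]) / (q[2L] - q[1L])
    s[s < 0] <- 0; s[s > 1] <- 1
    s
  } else matrix(0, nrow(x), ncol(x))
  bw <- stretched > params$binarize_level
  lab <- oracle_label(bw, params$connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    for (comp in which(sizes < params$min_component_px)) bw[lab == comp] <- FALSE
  }
  bw
}

# exhaustive W(r): loop over every pixel, test the squared distance
oracle_circle_count <- function(bw, center, r) {
  n <- 0L
  for (j in seq_len(ncol(bw))) for (i in seq_len(nrow(bw))) {
    if (bw[i, j] && (i - center[1L])^2 + (j - center[2L])^2 <= r^2) n <- n + 1L
  }
  n
}

# draw a filled disc of given intensity onto a matrix
draw_disc <- function(m, center, radius, value) {
  d2 <- outer((seq_len(nrow(m)) - center[1L])^2,
              (seq_len(ncol(m)) - center[2L])^2, `+`)
  m[d2 <= radius^2] <- value
  m
}
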