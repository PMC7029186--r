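# Binary morphology on logical matrices (TRUE = foreground). No image
# package in the dependency stack provides these, so they are implemented
# here with vectorized shifts; frames are small (~1e4-1e5 px).

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 3x3 (8-neighbourhood) binary dilation.
mask_dilate <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | shift_mat(m, dr, dc)
  out
}

# Fill interior holes: background connected to the border (4-connectivity,
# iterative geodesic propagation) stays background; the rest is filled.
mask_fill_holes <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(m)] <- bg[, ncol(m)]
  repeat {
    grown <- reach
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      grown <- grown | shift_mat(reach, d[1], d[2])
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

# Largest 8-connected foreground component, via an igraph over foreground
# pixels.
mask_largest_component <- function(m) {
  idx <- which(m)
  if (length(idx) == 0) return(m)
  nr <- nrow(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    sh <- shift_mat(m, d[1], d[2])
    both <- which(m & sh)
    if (length(both)) {
      nb <- both - d[1] - d[2] * nr
      edges <- c(edges, rbind(lab[both], lab[nb]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- idx[comp$membership == which.max(comp$csize)]
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[keep] <- TRUE
  out
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton, vectorized over
# the whole frame per subiteration.
skeletonize <- function(m) {
  m <- m * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, 1, 0, 0); p6 <- shift_mat(m, -1, 0, 0)   # N, S
      p4 <- shift_mat(m, 0, -1, 0); p8 <- shift_mat(m, 0, 1, 0)   # E, W
      p3 <- shift_mat(m, 1, -1, 0); p5 <- shift_mat(m, -1, -1, 0) # NE, SE
      p7 <- shift_mat(m, -1, 1, 0); p9 <- shift_mat(m, 1, 1, 0)   # SW, NW
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}
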