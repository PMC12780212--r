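# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# brute-force center-to-center Euclidean distance to the nearest on-pixel
brute_force_distance <- function(mask_matrix, pixel_size = 30) {
  on <- which(mask_matrix != 0, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask_matrix), ncol(mask_matrix))
  for (i in seq_len(nrow(mask_matrix))) {
    for (j in seq_len(ncol(mask_matrix))) {
      out[i, j] <- min(sqrt((on[, 1] - i)^2 + (on[, 2] - j)^2)) * pixel_size
    }
  }
  out
}

# flood-fill component sizes (recursive queue, independent of the C++ path)
flood_fill_sizes <- function(mask_matrix, connectivity = 8) {
  nr <- nrow(mask_matrix); nc <- ncol(mask_matrix)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (connectivity == 8)
    expand.grid(di = -1:1, dj = -1:1)[-5, ]
  else data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  sizes <- integer()
  for (start in which(mask_matrix != 0 & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      i <- ((k - 1) %% nr) + 1; j <- ((k - 1) %/% nr) + 1
      for (m in seq_len(nrow(nbr))) {
        ii <- i + nbr$di[m]; jj <- j + nbr$dj[m]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        kk <- (jj - 1) * nr + ii
        if (mask_matrix[kk] != 0 && !seen[kk]) {
          seen[kk] <- TRUE
          queue <- c(queue, kk)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# textbook shortest-path travel time via igraph on the rook-lattice graph
igraph_travel_time <- function(cost_matrix, source_matrix) {
  nr <- nrow(cost_matrix); nc <- ncol(cost_matrix)
  idx <- function(i, j) (j - 1) * nr + i
  from <- integer(); to <- integer(); w <- numeric()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (i < nr) {
      from <- c(from, idx(i, j)); to <- c(to, idx(i + 1, j))
      w <- c(w, (cost_matrix[i, j] + cost_matrix[i + 1, j]) / 2)
    }
    if (j < nc) {
      from <- c(from, idx(i, j)); to <- c(to, idx(i, j + 1))
      w <- c(w, (cost_matrix[i, j] + cost_matrix[i, j + 1]) / 2)
    }
  }
  keep <- !is.na(w)
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  sources <- which(source_matrix != 0)
  d <- igraph::distances(g, v = sources, weights = w[keep])
  matrix(apply(d, 2, min), nr, nc)
}

# rule-by-rule speed expectation for a single pixel (mirrors the stated
# precedence independently of the vectorized implementation)
oracle_speed <- function(lulc, slope, elev, road, waterway, coast) {
  if (road == 1) return(60)
  if (road == 2) return(40)
  if (road == 3) return(30)
  if (coast != 0) return(20)
  if (waterway != 0) {
    si <- findInterval(slope, c(5, 10, 15, 25)) + 1
    ei <- findInterval(elev, c(450, 700, 1800, 2800)) + 1
    m <- rbind(c(15, 7.5, 3.8, 1.9, 1.4),
               c(7.5, 3.9, 2.7, 1.9, 1.4),
               c(3.8, 2.7, 2.0, 1.7, 1.4),
               c(1.9, 1.9, 1.7, 1.4, 1.3),
               c(1.4, 1.4, 1.4, 1.3, 1.2))
    return(m[ei, si])
  }
  s <- max(slope, 1)
  if (lulc %in% 4:7) return(10.560326 * s^-0.199553)
  if (lulc == 2) return(max((-0.975931 * log(s) + 6.761258) / 2, 0.1))
  if (lulc %in% c(1, 3)) return(max(-0.975931 * log(s) + 6.761258, 0.1))
  NA_real_  # water off-network: barrier
}

# small random binary mask with guaranteed on-pixels
random_mask <- function(nr, nc, p = 0.1) {
  m <- matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
  if (!any(m != 0)) m[sample(nr * nc, 1)] <- 1
  m
}

# a tiny landscape for fast end-to-end tests
small_landscape <- function(seed = 42, n = 120) {
  generate_landscape(seed, grid_spec(n, n))
}
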