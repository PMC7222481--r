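# Shared fixtures and independent oracles, built in code at test time.

# rasterized disc of radius r centered in a (2r + 2pad + 1)^2 frame
make_disc <- function(r, pad = 4, value = 1L) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix(0L, n, n)
  m[(idx$row - c0)^2 + (idx$col - c0)^2 <= r^2] <- value
  m
}

# binary mask of two discs with given center separation (centers on one row)
make_two_discs <- function(r, sep, pad = 6) {
  nr <- 2 * r + 2 * pad + 1
  nc <- 2 * r + 2 * pad + 1 + sep
  c1 <- c(r + pad + 1, r + pad + 1)
  c2 <- c(r + pad + 1, r + pad + 1 + sep)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  m <- matrix(0L, nr, nc)
  d1 <- (idx$row - c1[1])^2 + (idx$col - c1[2])^2
  d2 <- (idx$row - c2[1])^2 + (idx$col - c2[2])^2
  m[d1 <= r^2 | d2 <= r^2] <- 1L
  attr(m, "centers") <- rbind(c1, c2)
  m
}

# exhaustive between-class-variance scan over all candidate thresholds
oracle_otsu <- function(img) {
  v <- sort(unique(as.numeric(img)))
  best <- -Inf
  best_t <- v[1]
  x <- as.numeric(img)
  for (t in v[-length(v)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    sb <- (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  best_t
}

# multi-source shortest-path labelling via igraph on the pixel graph;
# ties (within tol) go to the lowest seed id.  Independent of the package's
# Dijkstra (different library, different traversal).
oracle_propagate <- function(intensity, seeds, mask, lambda, tol = 1e-9) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  rng <- range(intensity)
  norm <- if (diff(rng) > 0) (intensity - rng[1]) / diff(rng) else intensity * 0
  ok <- mask > 0 | seeds > 0
  idx <- which(ok)
  id_of <- match(seq_len(nr * nc), idx)          # pixel -> vertex id
  edges <- integer(0); w <- numeric(0)
  offs <- list(c(1, 0, 1), c(0, 1, 1), c(1, 1, 2), c(1, -1, 2))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; st2 <- o[3]
    rr <- seq_len(nr - abs(dr)); cc <- seq_len(nc - abs(dc))
    r1 <- if (dr >= 0) rr else rr + abs(dr)
    c1 <- if (dc >= 0) cc else cc + abs(dc)
    a <- outer(r1, (c1 - 1) * nr, "+")
    b <- outer(r1 + dr, (c1 + dc - 1) * nr, "+")
    keep <- ok[a] & ok[b] & !(seeds[a] > 0 & seeds[b] > 0)
    # growth into a seed pixel is forbidden (seeds keep their label); edges
    # from seed to non-seed or between free pixels only
    keep <- keep & !(seeds[b] > 0)
    dI <- norm[a] - norm[b]
    edges <- c(edges, rbind(id_of[a[keep]], id_of[b[keep]]))
    w <- c(w, sqrt(dI[keep]^2 + lambda * st2))
    # reverse direction with its own seed rule
    keep2 <- ok[a] & ok[b] & !(seeds[a] > 0 & seeds[b] > 0) & !(seeds[a] > 0)
    edges <- c(edges, rbind(id_of[b[keep2]], id_of[a[keep2]]))
    w <- c(w, sqrt(dI[keep2]^2 + lambda * st2))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = TRUE)
  sid <- sort(unique(seeds[seeds > 0]))
  cost <- matrix(Inf, length(sid), length(idx))
  for (i in seq_along(sid)) {
    src <- id_of[which(seeds == sid[i])]
    d <- igraph::distances(g, v = src, mode = "out", weights = w)
    cost[i, ] <- apply(d, 2, min)
  }
  lab <- matrix(0L, nr, nc)
  best <- apply(cost, 2, min)
  pick <- apply(cost, 2, function(cl) {
    b <- min(cl)
    if (!is.finite(b)) return(0L)
    sid[min(which(cl <= b + tol))]
  })
  lab[idx] <- pick
  tiecnt <- apply(cost, 2, function(cl) sum(cl <= min(cl) + tol))
  attr(lab, "tied") <- {
    t2 <- matrix(FALSE, nr, nc); t2[idx] <- tiecnt > 1; t2
  }
  lab
}

# two-sample KS oracle: brute-force double-ECDF scan and the asymptotic
# Kolmogorov series
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  D <- max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  t <- sqrt(n_eff) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(D = D, p = min(max(p, 0), 1))
}

# measure ground-truth label masks of a scene (no segmentation), as cell records
measure_truth <- function(sc, image_id, condition) {
  measure_image(sc$truth$cell_labels, sc$pair, sc$truth$nucleus_labels,
                image_id = image_id, condition = condition)
}

two_seed_fixture <- function(kind, nr = 40, nc = 64) {
  intensity <- switch(kind,
    uniform = matrix(120, nr, nc),
    ridge = {
      m <- matrix(100, nr, nc)
      m[, 30:34] <- 250                       # sharp bright ridge between seeds
      m
    },
    gradient = matrix(rep(seq(0, 255, length.out = nc), each = nr), nr, nc))
  seeds <- matrix(0L, nr, nc)
  seeds[nr %/% 2, 10] <- 1L
  seeds[nr %/% 2, nc - 9] <- 2L
  mask <- matrix(1L, nr, nc)
  list(intensity = intensity, seeds = seeds, mask = mask)
}

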