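# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# central finite difference of a scalar function
num_grad <- function(f, x, eps = 1e-3) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# binary cross-entropy over a grid of scores, elementwise loop
oracle_bce <- function(scores, target, eps = 1e-7) {
  s <- 0
  for (v in as.numeric(scores)) {
    v <- min(max(v, eps), 1 - eps)
    s <- s + if (target == 1) -log(v) else -log(1 - v)
  }
  s / length(scores)
}

# axis-sum projection by explicit triple loop; axis in {"z","y","x"},
# flattening row-major over the remaining axes (later axis fastest)
oracle_project <- function(mask, axis) {
  d <- dim(mask)
  if (axis == "z") {
    out <- numeric(d[2] * d[3]); k <- 0
    for (y in 1:d[2]) for (x in 1:d[3]) {
      k <- k + 1
      for (z in 1:d[1]) out[k] <- out[k] + mask[z, y, x]
    }
  } else if (axis == "y") {
    out <- numeric(d[1] * d[3]); k <- 0
    for (z in 1:d[1]) for (x in 1:d[3]) {
      k <- k + 1
      for (y in 1:d[2]) out[k] <- out[k] + mask[z, y, x]
    }
  } else {
    out <- numeric(d[1] * d[2]); k <- 0
    for (z in 1:d[1]) for (y in 1:d[2]) {
      k <- k + 1
      for (x in 1:d[3]) out[k] <- out[k] + mask[z, y, x]
    }
  }
  out
}

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

oracle_ps_loss <- function(X, Y) {
  1 - mean(sapply(c("x", "y", "z"), function(ax)
    oracle_cosine(oracle_project(X, ax), oracle_project(Y, ax))))
}

oracle_dice_loss <- function(X, Y, eps = 1e-5) {
  1 - (2 * sum(X * Y) + eps) / (sum(X) + sum(Y) + eps)
}

# patch starts by literal enumeration of the top-to-bottom rule
oracle_patch_starts <- function(depth, P, stride) {
  s <- integer(0); k <- 0
  while (k + P <= depth) { s <- c(s, k); k <- k + stride }
  as.integer(sort(unique(c(s, depth - P))))
}

# 6-neighbourhood erosion of a binary 3D mask
erode6 <- function(m) {
  d <- dim(m)
  pad <- array(0, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  keep <- pad[i, j, k] * pad[i - 1, j, k] * pad[i + 1, j, k] *
    pad[i, j - 1, k] * pad[i, j + 1, k] * pad[i, j, k - 1] * pad[i, j, k + 1]
  array(keep, d)
}

# erosions until nothing remains (thickness oracle: ~ max inscribed radius)
erosion_depth <- function(m, max_iter = 20) {
  for (i in seq_len(max_iter)) {
    m <- erode6(m)
    if (sum(m) == 0) return(i)
  }
  max_iter
}

# connected components of a binary mask (6-neighbourhood BFS)
n_components <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  idx <- which(m == 1)
  comp <- 0L
  for (start in idx) {
    if (lab[start] > 0) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      z <- (cur - 1) %% d[1] + 1
      y <- ((cur - 1) %/% d[1]) %% d[2] + 1
      x <- (cur - 1) %/% (d[1] * d[2]) + 1
      for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
        zz <- z + off[1]; yy <- y + off[2]; xx <- x + off[3]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 ||
            xx > d[3]) next
        ii <- zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1)
        if (m[ii] == 1 && lab[ii] == 0) { lab[ii] <- comp; queue <- c(queue, ii) }
      }
    }
  }
  comp
}
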