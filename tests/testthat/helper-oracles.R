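# Independent brute-force oracles used to validate the image operations.
# These deliberately use naive algorithms (double loops, per-level BFS,
# exhaustive enumeration) so they share no code with the implementations.

# elementwise max over z, looping
oracle_max_project <- function(vox) {
  d <- dim(vox)
  out <- matrix(-Inf, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (vox[y, x, z] > out[y, x]) out[y, x] <- vox[y, x, z]
  }
  out
}

# grayscale opening with spherical-cap element: explicit min-then-max loops
oracle_rolling_ball_background <- function(m, r) {
  ny <- nrow(m); nx <- ncol(m)
  offs <- list()
  for (dy in -r:r) for (dx in -r:r) {
    if (dy^2 + dx^2 <= r^2) {
      offs[[length(offs) + 1]] <- c(dy, dx, sqrt(r^2 - dy^2 - dx^2))
    }
  }
  ero <- matrix(Inf, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    for (o in offs) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
        v <- m[yy, xx] - o[3]
        if (v < ero[y, x]) ero[y, x] <- v
      }
    }
  }
  dil <- matrix(-Inf, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    for (o in offs) {
      yy <- y - o[1]; xx <- x - o[2]
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
        v <- ero[yy, xx] + o[3]
        if (v > dil[y, x]) dil[y, x] <- v
      }
    }
  }
  dil
}

# 8-connected component of {m >= thr} containing (y0, x0), stack-based flood
cc_at_threshold <- function(m, thr, y0, x0) {
  ny <- nrow(m); nx <- ncol(m)
  seen <- matrix(FALSE, ny, nx)
  if (m[y0, x0] < thr) return(seen)
  stack <- integer(ny * nx)
  stack[1] <- (x0 - 1) * ny + y0
  top <- 1L
  seen[y0, x0] <- TRUE
  while (top > 0L) {
    i <- stack[top]; top <- top - 1L
    y <- (i - 1L) %% ny + 1L; x <- (i - 1L) %/% ny + 1L
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx &&
          !seen[yy, xx] && m[yy, xx] >= thr) {
        seen[yy, xx] <- TRUE
        top <- top + 1L
        stack[top] <- (xx - 1L) * ny + yy
      }
    }
  }
  seen
}

# regional-maximum plateaus: connected equal-value regions with no higher
# neighbour; representative = centroid rounded half-down, snapped to the
# nearest member (ties toward smaller y then x)
oracle_regional_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  visited <- matrix(FALSE, ny, nx)
  out <- list()
  for (y0 in 1:ny) for (x0 in 1:nx) {
    if (visited[y0, x0]) next
    val <- m[y0, x0]
    comp <- cc_at_threshold(ifelse(m == val, val, -Inf), val, y0, x0)
    idx <- which(comp, arr.ind = TRUE)
    visited[comp] <- TRUE
    higher <- FALSE
    for (k in seq_len(nrow(idx))) {
      for (dy in -1:1) for (dx in -1:1) {
        yy <- idx[k, 1] + dy; xx <- idx[k, 2] + dx
        if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx && m[yy, xx] > val) {
          higher <- TRUE
        }
      }
    }
    if (higher) next
    half_down <- function(s, n) floor((2 * s + n - 1) / (2 * n))
    cy <- half_down(sum(idx[, 1] - 1), nrow(idx))
    cx <- half_down(sum(idx[, 2] - 1), nrow(idx))
    d2 <- (idx[, 1] - 1 - cy)^2 + (idx[, 2] - 1 - cx)^2
    best <- which(d2 == min(d2))
    best <- best[order(idx[best, 1], idx[best, 2])][1]
    out[[length(out) + 1]] <- list(y = idx[best, 1] - 1, x = idx[best, 2] - 1,
                                   peak = val)
  }
  out
}

# topographic prominence by explicit threshold descent
oracle_find_maxima <- function(m, prominence) {
  maxima <- oracle_regional_maxima(m)
  if (length(maxima) == 0 || max(m) == min(m)) {
    return(data.frame(y = integer(0), x = integer(0),
                      peak_value = numeric(0), prominence_value = numeric(0)))
  }
  levels <- sort(unique(as.vector(m)), decreasing = TRUE)
  res <- lapply(maxima, function(mx) {
    saddle <- NA_real_
    for (t in levels[levels <= mx$peak]) {
      comp <- cc_at_threshold(m, t, mx$y + 1, mx$x + 1)
      if (any(m[comp] > mx$peak)) {
        saddle <- t
        break
      }
    }
    prom <- if (is.na(saddle)) mx$peak - min(m) else mx$peak - saddle
    data.frame(y = mx$y, x = mx$x, peak_value = mx$peak,
               prominence_value = prom, is_global = is.na(saddle))
  })
  res <- do.call(rbind, res)
  res <- res[res$prominence_value >= prominence | res$is_global, , drop = FALSE]
  res[order(-res$peak_value, res$y, res$x), c("y", "x", "peak_value",
                                              "prominence_value")]
}

# best ungapped Hamming alignment by sliding substring comparison
oracle_best_hamming <- function(query, subjects) {
  L <- nchar(query)
  qs <- strsplit(query, NULL)[[1]]
  best <- L + 1L
  for (s in subjects) {
    if (nchar(s) < L) next
    sc <- strsplit(s, NULL)[[1]]
    for (p in 1:(nchar(s) - L + 1)) {
      mm <- sum(sc[p:(p + L - 1)] != qs)
      if (mm < best) best <- mm
    }
  }
  if (best > L) NA_integer_ else as.integer(best)
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, NULL)[[1]])), collapse = "")
}

# one-way ANOVA F from definitional sums of squares
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# exhaustive maximum-cardinality one-to-one matching within max_dist (n <= 10)
oracle_max_matching <- function(ay, ax, by, bx, max_dist) {
  na <- length(ay); nb <- length(by)
  ok <- outer(ay, by, "-")^2 + outer(ax, bx, "-")^2 <= max_dist^2
  best <- 0L
  recurse <- function(a, used_b, count) {
    if (a > na) {
      best <<- max(best, count)
      return(invisible())
    }
    if (count + (na - a + 1) <= best) return(invisible())  # bound
    for (b in seq_len(nb)) {
      if (!used_b[b] && ok[a, b]) {
        used_b[b] <- TRUE
        recurse(a + 1, used_b, count + 1L)
        used_b[b] <- FALSE
      }
    }
    recurse(a + 1, used_b, count)
  }
  recurse(1L, rep(FALSE, nb), 0L)
  best
}

# barycentric point-in-convex-polygon (fan triangulation), vertices ccw or cw
oracle_in_convex_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    signs <- vapply(seq_len(n), function(k) {
      k2 <- if (k == n) 1L else k + 1L
      (vx[k2] - vx[k]) * (py[i] - vy[k]) - (vy[k2] - vy[k]) * (px[i] - vx[k])
    }, numeric(1))
    all(signs > 0) || all(signs < 0)
  }, logical(1))
}

# deterministic random test image with well-spaced values
random_test_image <- function(ny = 16, nx = 16) {
  matrix(runif(ny * nx), ny, nx)
}

# strip fish_image attributes down to a plain matrix for exact comparison
plain_matrix <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}
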