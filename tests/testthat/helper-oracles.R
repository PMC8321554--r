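# Shared fixtures and independent oracles used across test files.

# A small, fast synthetic spec: one bouton, short movie.
tiny_spec <- function(n_frames = 60, ...) {
  synthetic_spec(n_boutons = 1, bouton_radius_um = 1.5, margin_um = 0.6,
                 n_frames = n_frames, ...)
}

# Brute-force minimum cross-entropy threshold: exhaustive scan over all
# histogram cut points (the iterative implementation must agree within
# one bin, or sit on an equal-criterion plateau).
li_criterion <- function(values, t, n_bins = 256L) {
  h <- actinpatches:::build_histogram(values, n_bins)
  shift <- if (min(h$centers) <= 0) h$width - min(h$centers) else 0
  g <- h$centers + shift
  w <- h$counts
  below <- g <= t + shift
  if (!sum(w[below]) || !sum(w[!below])) return(Inf)
  mb <- sum(w[below] * g[below]) / sum(w[below])
  ma <- sum(w[!below] * g[!below]) / sum(w[!below])
  -(sum(w[below] * g[below]) * log(mb) + sum(w[!below] * g[!below]) * log(ma))
}

li_brute_force <- function(values, n_bins = 256L) {
  h <- actinpatches:::build_histogram(values, n_bins)
  edges <- h$centers + h$width / 2
  crit <- vapply(edges[-n_bins], function(e) li_criterion(values, e, n_bins),
                 numeric(1))
  list(threshold = edges[which.min(crit)], min_crit = min(crit),
       bin_width = h$width)
}

# Independent moment-preservation oracle: representative levels via
# polyroot on the moment system, then percentile lookup.
moments_brute_force <- function(values, n_bins = 256L) {
  h <- actinpatches:::build_histogram(values, n_bins)
  p <- h$counts / sum(h$counts)
  g <- h$centers
  m1 <- sum(p * g); m2 <- sum(p * g^2); m3 <- sum(p * g^3)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z <- sort(Re(polyroot(c(c0, c1, 1))))
  p0 <- (z[2] - m1) / (z[2] - z[1])
  cum <- cumsum(p)
  k <- which.min(abs(cum - p0))
  g[k] + h$width / 2
}

# Exhaustive optimal partial matching between two small point sets
# (cost = squared distance, links beyond max_dist forbidden, unmatched
# points cost max_dist^2 each) -- the oracle for the LAP linker.
brute_force_match_cost <- function(ax, ay, bx, by, max_dist) {
  n1 <- length(ax); n2 <- length(bx)
  d2 <- outer(ax, bx, function(p, q) (p - q)^2) +
    outer(ay, by, function(p, q) (p - q)^2)
  feasible <- d2 <= max_dist^2
  b <- max_dist^2
  best <- Inf
  # enumerate all injective partial maps a -> b
  assign_next <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n1) {
      total <- cost + b * sum(!used) # unmatched b's
      if (total < best) best <<- total
      return()
    }
    assign_next(i + 1L, used, cost + b)  # leave a_i unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && feasible[i, j]) {
        u <- used; u[j] <- TRUE
        assign_next(i + 1L, u, cost + d2[i, j])
      }
    }
  }
  assign_next(1L, rep(FALSE, n2), 0)
  best
}

# Cost of the matching actually chosen by the package linker, in the
# same convention (unmatched points on either side cost max_dist^2).
linker_match_cost <- function(ax, ay, bx, by, max_dist) {
  m <- actinpatches:::match_frame_pair(ax, ay, bx, by, max_dist)
  b <- max_dist^2
  cost <- 0
  for (i in seq_along(ax)) {
    if (is.na(m[i])) {
      cost <- cost + b
    } else {
      cost <- cost + (ax[i] - bx[m[i]])^2 + (ay[i] - by[m[i]])^2
    }
  }
  cost + b * (length(bx) - sum(!is.na(m)))
}

# Naive reference for grayscale opening with a spherical-cap element
# (replicate padding), quadratic loops -- only for small images.
naive_rolling_ball <- function(img, radius) {
  off <- actinpatches:::disc_offsets(radius)
  hgt <- sqrt(pmax(0, radius^2 - off[, 1]^2 - off[, 2]^2))
  hgt <- hgt - max(hgt)
  nr <- nrow(img); nc <- ncol(img)
  at <- function(m, r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
  ero <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ero[r, c] <- min(vapply(seq_len(nrow(off)), function(k) {
      at(img, r + off[k, 1], c + off[k, 2]) - hgt[k]
    }, numeric(1)))
  }
  dil <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dil[r, c] <- max(vapply(seq_len(nrow(off)), function(k) {
      at(ero, r - off[k, 1], c - off[k, 2]) + hgt[k]
    }, numeric(1)))
  }
  out <- img - pmin(dil, img)
  out[out < 0] <- 0
  out
}

# One isolated noiseless event on a uniform full-frame baseline (no
# bouton boundary): the clean fixture for detection/amplitude oracles.
single_event_movie <- function(amplitude_ratio = 0.68, n_frames = 40,
                               start_frame = 10, event_frames = 12,
                               frame_interval_s = 4, baseline = 100,
                               side_px = 36, pixel_size_um = 0.13) {
  data <- array(baseline, c(n_frames, side_px, side_px))
  sigma_px <- 0.255 / pixel_size_um
  ctr <- side_px / 2
  g <- amplitude_ratio * baseline *
    outer(exp(-(seq_len(side_px) - ctr)^2 / (2 * sigma_px^2)),
          exp(-(seq_len(side_px) - ctr)^2 / (2 * sigma_px^2)))
  for (t in start_frame:(start_frame + event_frames - 1L)) {
    data[t, , ] <- data[t, , ] + g
  }
  ev <- tibble::tibble(event_id = 1L,
                       x_um = (ctr - 0.5) * pixel_size_um,
                       y_um = (ctr - 0.5) * pixel_size_um,
                       start_frame = as.integer(start_frame),
                       n_frames = as.integer(event_frames),
                       duration_s = event_frames * frame_interval_s,
                       amplitude = amplitude_ratio * baseline)
  list(movie = patch_movie(data, pixel_size_um, frame_interval_s),
       mask = patch_mask(matrix(TRUE, side_px, side_px), pixel_size_um),
       events = ev)
}
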