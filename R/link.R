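# Globally optimal frame-to-frame assignment (Jonker-Volgenant style
# shortest augmenting paths with potentials, O(n^3)). Infeasible links are
# given a large finite cost and stripped afterwards.
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  if (ncol(cost) != n) abort_ap("cost matrix must be square")
  BIG <- 1e15
  a <- cost
  a[!is.finite(a)] <- BIG
  u <- numeric(n)
  v <- numeric(n)
  p <- integer(n + 1L)  # p[j] = row matched to column j; index n+1 is virtual
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- a[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      mf <- minv[free]
      k <- which.min(mf)
      delta <- mf[k]
      j1 <- free[k]
      used_j <- which(used[seq_len(n)])
      u[p[c(used_j, n + 1L)]] <- u[p[c(used_j, n + 1L)]] + delta
      v[used_j] <- v[used_j] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  assignment[p[seq_len(n)]] <- seq_len(n)
  assignment
}

# Optimal partial matching between two point sets with per-link cost d^2
# and links forbidden beyond max_dist. Returns an integer vector over
# rows of `a`: matched column in `b` or NA.
match_frame_pair <- function(ax, ay, bx, by, max_dist) {
  n1 <- length(ax)
  n2 <- length(bx)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d2 <- outer(ax, bx, function(p, q) (p - q)^2) +
    outer(ay, by, function(p, q) (p - q)^2)
  d2[d2 > max_dist^2] <- Inf
  b_alt <- max_dist^2  # cost of leaving a spot unlinked
  n <- n1 + n2
  cost <- matrix(Inf, n, n)
  cost[seq_len(n1), seq_len(n2)] <- d2
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- b_alt
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- b_alt
  lower_right <- t(d2)
  lower_right[is.finite(lower_right)] <- 0
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- lower_right
  sol <- solve_lap(cost)
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && is.finite(d2[i, j])) out[i] <- j
  }
  out
}

#' Link detected spots into patch tracks
#'
#' Spots in consecutive frames are linked by the globally optimal
#' assignment minimizing the total squared displacement, with links
#' forbidden beyond `linking_max_um`. Unlinked spots start new tracks; a
#' track with no link in the next frame terminates (no gap closing, per
#' the published parameterization `gap-closing frame gap = 0`).
#'
#' @param spots Tibble from [detect_movie_spots()] (`frame, x_um, y_um,
#'   peak_intensity, quality`).
#' @param params Tracking parameter list (see [patch_config()]
#'   `$tracking`).
#' @return The spot tibble with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(spots, params = patch_config()$tracking) {
  if (nrow(spots) == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          x_um = double(), y_um = double(),
                          peak_intensity = double(), quality = double()))
  }
  spots <- dplyr::arrange(spots, .data$frame, .data$x_um, .data$y_um)
  frames <- sort(unique(spots$frame))
  spots$track_id <- NA_integer_
  next_id <- 1L
  idx_by_frame <- split(seq_len(nrow(spots)), spots$frame)
  first <- idx_by_frame[[as.character(frames[1])]]
  spots$track_id[first] <- seq_len(length(first))
  next_id <- length(first) + 1L
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    ia <- idx_by_frame[[as.character(t)]]
    ib <- idx_by_frame[[as.character(t + 1L)]]
    if (!is.null(ib)) {
      m <- match_frame_pair(spots$x_um[ia], spots$y_um[ia],
                            spots$x_um[ib], spots$y_um[ib],
                            params$linking_max_um)
      for (k in seq_along(ia)) {
        if (!is.na(m[k])) {
          spots$track_id[ib[m[k]]] <- spots$track_id[ia[k]]
        }
      }
    }
    # spots of the next processed frame with no inherited id start tracks
    nxt <- if (fi < length(frames)) {
      idx_by_frame[[as.character(frames[fi + 1L])]]
    } else {
      NULL
    }
    if (!is.null(nxt)) {
      fresh <- nxt[is.na(spots$track_id[nxt])]
      if (length(fresh) > 0) {
        spots$track_id[fresh] <- next_id + seq_along(fresh) - 1L
        next_id <- next_id + length(fresh)
      }
    }
  }
  dplyr::arrange(
    spots[, c("track_id", "frame", "x_um", "y_um", "peak_intensity",
              "quality")],
    .data$track_id, .data$frame)
}

#' Summarize tracks
#'
#' One row per track: spot count, duration (`n_spots * frame_interval_s`,
#' the spot-count convention consistent with the printed detection floors
#' 16 s at 0.25 Hz and 4 s at 1 Hz), and censoring flags (track touches
#' the first or last movie frame, so its true duration exceeds the
#' observed one).
#'
#' @param tracks Spot-level tibble with `track_id`.
#' @param frame_interval_s Seconds per frame (NA gives NA durations).
#' @param n_movie_frames Total frames (NA gives NA `censored_end`).
#' @return Tibble `track_id, n_spots, start_frame, end_frame, duration_s,
#'   mean_quality, censored_start, censored_end`.
#' @export
track_summary <- function(tracks, frame_interval_s = NA_real_,
                          n_movie_frames = NA_integer_) {
  if (nrow(tracks) == 0) {
    return(tibble::tibble(track_id = integer(), n_spots = integer(),
                          start_frame = integer(), end_frame = integer(),
                          duration_s = double(), mean_quality = double(),
                          censored_start = logical(),
                          censored_end = logical()))
  }
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      start_frame = min(.data$frame),
      end_frame = max(.data$frame),
      mean_quality = mean(.data$quality),
      .groups = "drop") |>
    dplyr::mutate(
      duration_s = .data$n_spots * frame_interval_s,
      censored_start = .data$start_frame == 1L,
      censored_end = if (is.na(n_movie_frames)) NA else
        .data$end_frame == n_movie_frames) |>
    dplyr::select("track_id", "n_spots", "start_frame", "end_frame",
                  "duration_s", "mean_quality", "censored_start",
                  "censored_end")
}

#' Filter linked tracks
#'
#' Rejects tracks with fewer than `min_spots` detections (`too_short`, the
#' detection floor: 4 spots = 16 s at 0.25 Hz), erratic tracks whose
#' median per-frame displacement exceeds `max_median_step_um`
#' (`erratic`: patches are stationary structures, so a wandering track is
#' a tracking defect, typically noise walking along an intensity ridge),
#' and resolves tracking-path overlap: if two concurrent tracks ever come
#' within `linking_max_um` of each other, the shorter (fewer spots; tie
#' broken by lower mean quality) is rejected (`overlap`);
#' `overlap_policy = "both"` rejects both. The rejection counts feed the
#' upper-bound frequency correction.
#'
#' @param tracks Spot-level tibble from [link_tracks()].
#' @param params Tracking parameter list.
#' @param frame_interval_s,n_movie_frames Passed to [track_summary()].
#' @return List with `accepted` and `rejected` spot tibbles, the
#'   `summary` of all tracks (with a `status` column: accepted /
#'   too_short / erratic / overlap), and `report`, a tibble of rejection
#'   counts by reason.
#' @export
filter_tracks <- function(tracks, params = patch_config()$tracking,
                          frame_interval_s = NA_real_,
                          n_movie_frames = NA_integer_) {
  smry <- track_summary(tracks, frame_interval_s, n_movie_frames)
  status <- stats::setNames(rep("accepted", nrow(smry)),
                            as.character(smry$track_id))
  # erratic tracks: median per-frame step beyond the stationarity limit
  max_step <- params$max_median_step_um %||% NULL
  if (!is.null(max_step) && nrow(tracks) > 0) {
    steps <- tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(
        med_step = if (dplyr::n() < 2) 0 else
          stats::median(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
        .groups = "drop")
    err_ids <- steps$track_id[steps$med_step > max_step]
    status[as.character(err_ids)] <- "erratic"
  }
  # path overlap among concurrent tracks
  if (nrow(tracks) > 0) {
    conflict <- list()
    for (fr in split(tracks, tracks$frame)) {
      if (nrow(fr) < 2) next
      d <- as.matrix(stats::dist(cbind(fr$x_um, fr$y_um)))
      hits <- which(upper.tri(d) & d <= params$linking_max_um, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        conflict[[length(conflict) + 1L]] <- cbind(
          fr$track_id[hits[, 1]], fr$track_id[hits[, 2]])
      }
    }
    if (length(conflict) > 0) {
      pairs <- unique(do.call(rbind, conflict))
      pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        if (identical(params$overlap_policy, "both")) {
          status[as.character(c(a, b))] <- "overlap"
          next
        }
        sa <- smry[smry$track_id == a, ]
        sb <- smry[smry$track_id == b, ]
        loser <- if (sa$n_spots != sb$n_spots) {
          if (sa$n_spots < sb$n_spots) a else b
        } else if (sa$mean_quality != sb$mean_quality) {
          if (sa$mean_quality < sb$mean_quality) a else b
        } else {
          max(a, b)
        }
        status[as.character(loser)] <- "overlap"
      }
    }
  }
  short <- smry$track_id[smry$n_spots < params$min_spots]
  status[as.character(short)] <- "too_short"  # floor takes precedence
  smry$status <- unname(status[as.character(smry$track_id)])
  accepted_ids <- smry$track_id[smry$status == "accepted"]
  list(
    accepted = tracks[tracks$track_id %in% accepted_ids, , drop = FALSE],
    rejected = tracks[!tracks$track_id %in% accepted_ids, , drop = FALSE],
    summary = smry,
    report = tibble::tibble(
      reason = c("accepted", "too_short", "erratic", "overlap"),
      n = c(sum(smry$status == "accepted"),
            sum(smry$status == "too_short"),
            sum(smry$status == "erratic"),
            sum(smry$status == "overlap")))
  )
}
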