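## regular grid step of a profile, with interior NAs interpolated and NA
## edges trimmed; returns list(offset, value, step)
profile_series <- function(profile) {
  off <- profile$offset
  v <- profile$value
  step <- unique(diff(off))
  if (length(step) != 1) {
    step <- median(diff(off))
    if (any(diff(off) != step)) abort("profile offsets must be on a regular grid.")
  }
  fin <- which(is.finite(v))
  if (length(fin) < 3) abort("profile has fewer than 3 finite values.")
  keep <- fin[1]:fin[length(fin)]
  off <- off[keep]
  v <- zoo::na.approx(v[keep], na.rm = FALSE)
  list(offset = off, value = v, step = step)
}

running_mean <- function(v, w_points, partial = FALSE) {
  w <- max(3L, as.integer(w_points))
  if (w %% 2 == 0) w <- w + 1L
  if (partial) {
    zoo::rollapply(v, w, mean, partial = TRUE)
  } else {
    as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  }
}

## running-median detrend: follows step edges (track boundaries, gene ends)
## without smearing them into the residual, unlike a running mean
detrend_series <- function(v, w_points) {
  w <- max(3L, as.integer(w_points))
  if (w %% 2 == 0) w <- w + 1L
  w <- min(w, if (length(v) %% 2 == 1) length(v) else length(v) - 1L)
  v - stats::runmed(v, w, endrule = "median")
}

parabolic_refine <- function(y_m1, y_0, y_p1) {
  denom <- y_m1 - 2 * y_0 + y_p1
  if (!is.finite(denom) || denom == 0) return(0)
  max(-0.5, min(0.5, 0.5 * (y_m1 - y_p1) / denom))
}

#' Estimate the dominant spatial period of a profile
#'
#' Detrends the profile by subtracting a running median (window
#' `detrend_window` bp; the 5'->3' intensity drift and the sharp signal
#' edges at the transcribed-unit boundaries would otherwise dominate
#' short-lag correlation — the median follows those edges without smearing
#' them into the residual) and locates the highest local maximum of the
#' autocorrelation function within `lag_range`, refined to sub-grid
#' resolution by parabolic interpolation. Used to quantify the
#' nucleosome-linked periodicity (~165 bp repeat) of nascent-signal
#' metagenes.
#'
#' @param profile A `metagene_profile` (or any tibble with regular
#'   `offset` and `value` columns).
#' @param lag_range Search range for the period, in bp.
#' @param detrend_window Running-mean window in bp.
#' @return A `phasing_result` list: `period` (bp, `NA` if no local maximum
#'   is found in range), `peak_r`, `periodic` flag, the `acf` curve
#'   (tibble of `lag`, `r`) and the search range.
#' @export
#' @examples
#' p <- tibble::tibble(offset = seq(0, 800, 8),
#'                     value = cos(2 * pi * seq(0, 800, 8) / 165))
#' glance(estimate_period(p))$period
estimate_period <- function(profile, lag_range = c(100, 250),
                            detrend_window = 250) {
  s <- profile_series(profile)
  n <- length(s$value)
  if (n < 2 * lag_range[2] / s$step) {
    abort("profile too short for the requested lag range.")
  }
  x <- detrend_series(s$value, detrend_window / s$step)
  n <- length(x)
  k_max <- min(floor(lag_range[2] / s$step) + 1L, n - 3L)
  r <- vapply(0:k_max, function(k) {
    if (sd(x[1:(n - k)]) == 0 || sd(x[(k + 1):n]) == 0) return(NA_real_)
    cor(x[1:(n - k)], x[(k + 1):n])
  }, numeric(1))
  lag_bp <- (0:k_max) * s$step
  in_range <- which(lag_bp >= lag_range[1] & lag_bp <= lag_range[2])
  peaks <- in_range[vapply(in_range, function(i) {
    i > 1 && i < length(r) && is.finite(r[i]) &&
      is.finite(r[i - 1]) && is.finite(r[i + 1]) &&
      r[i] > r[i - 1] && r[i] >= r[i + 1]
  }, logical(1))]
  res <- list(
    period = NA_real_, peak_r = NA_real_, periodic = FALSE,
    lag_range = lag_range, detrend_window = detrend_window,
    acf = tibble(lag = lag_bp, r = r)
  )
  if (length(peaks) > 0) {
    best <- peaks[which.max(r[peaks])]
    delta <- parabolic_refine(r[best - 1], r[best], r[best + 1])
    res$period <- (best - 1 + delta) * s$step
    res$peak_r <- r[best]
    res$periodic <- TRUE
  }
  structure(res, class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  if (x$periodic) {
    cat(sprintf("<phasing_result> period %.1f bp (acf peak r = %.3f, range %d-%d bp)\n",
                x$period, x$peak_r, x$lag_range[1], x$lag_range[2]))
  } else {
    cat("<phasing_result> no periodicity detected in range\n")
  }
  invisible(x)
}

#' Call peaks on a smoothed profile
#'
#' Local maxima of the running-mean-smoothed profile with prominence at or
#' above a threshold. Prominence is the drop from the peak to the higher of
#' the two bounding saddles (walking out to the nearest higher point or the
#' profile end on each side). Plateau ties are broken towards the anchor
#' (the offset of smallest absolute value).
#'
#' @param profile A `metagene_profile`.
#' @param smooth_bw Running-mean bandwidth in bp (at least one grid step).
#' @param min_prominence Minimum prominence; default 5% of the smoothed
#'   profile's range.
#' @return A `peak_set` tibble: `offset`, `height`, `prominence`, sorted by
#'   offset.
#' @export
call_peaks <- function(profile, smooth_bw = 24, min_prominence = NULL) {
  s <- profile_series(profile)
  if (smooth_bw < s$step) abort("`smooth_bw` must be at least one grid step.")
  v <- running_mean(s$value, smooth_bw / s$step, partial = TRUE)
  n <- length(v)
  min_prominence <- min_prominence %||% (0.05 * diff(range(v)))

  ## candidate maxima, collapsing plateaus toward the anchor
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (v[i] > v[i - 1L] && (j == n || v[j + 1L] < v[i])) {
      run <- i:j
      cand <- c(cand, run[which.min(abs(s$offset[run]))])
    }
    i <- j + 1L
  }
  if (length(cand) == 0) {
    return(structure(
      tibble(offset = numeric(), height = numeric(), prominence = numeric()),
      smooth_bw = smooth_bw, class = c("peak_set", class(tibble()))
    ))
  }
  prom <- vapply(cand, function(p) {
    left <- if (p == 1L) numeric(0) else v[(p - 1L):1L]
    higher <- which(left > v[p])
    base_l <- if (length(left) == 0) v[p] else
      min(left[seq_len(if (length(higher)) higher[1] - 1 else length(left))])
    right <- if (p == n) numeric(0) else v[(p + 1L):n]
    higher <- which(right > v[p])
    base_r <- if (length(right) == 0) v[p] else
      min(right[seq_len(if (length(higher)) higher[1] - 1 else length(right))])
    v[p] - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  structure(
    tibble(offset = s$offset[cand[keep]], height = v[cand[keep]],
           prominence = prom[keep]) |> arrange(.data$offset),
    smooth_bw = smooth_bw,
    class = c("peak_set", class(tibble()))
  )
}

#' Estimate the displacement between two profiles
#'
#' Lag (bp) maximizing the Pearson correlation between `profile_a` and the
#' lag-shifted `profile_b` after running-median detrending, refined by
#' parabolic interpolation between grid lags. Positive values mean
#' `profile_b` is displaced downstream of `profile_a`. Used to quantify
#' the coordinated shift of run-on peaks and nucleosomes between wild type
#' and a remodeler mutant.
#'
#' @param profile_a,profile_b `metagene_profile`s sharing offsets.
#' @param max_lag Maximum |lag| examined, in bp.
#' @param detrend_window Running-mean window in bp.
#' @return The displacement in bp (a length-1 numeric with attributes `r`,
#'   the correlation at the optimum, and `curve`, the lag-correlation
#'   tibble).
#' @export
estimate_displacement <- function(profile_a, profile_b, max_lag = 50,
                                  detrend_window = 250) {
  common <- intersect(profile_a$offset, profile_b$offset)
  if (length(common) < 3) abort("profiles share too few offsets.")
  pa <- profile_a[profile_a$offset %in% common, c("offset", "value")]
  pb <- profile_b[profile_b$offset %in% common, c("offset", "value")]
  sa <- profile_series(pa)
  sb <- profile_series(pb)
  if (sa$step != sb$step) abort("profiles are on different grids.")
  step <- sa$step
  ## align the trimmed series on shared offsets
  off <- intersect(sa$offset, sb$offset)
  a <- sa$value[match(off, sa$offset)]
  b <- sb$value[match(off, sb$offset)]
  a <- detrend_series(a, detrend_window / step)
  b <- detrend_series(b, detrend_window / step)
  n <- length(a)
  k_max <- floor(max_lag / step)
  lags <- (-k_max):k_max
  r <- vapply(lags, function(L) {
    ia <- seq(max(1, 1 - L), min(n, n - L))
    if (length(ia) < 10) return(NA_real_)
    cor(a[ia], b[ia + L])
  }, numeric(1))
  if (all(is.na(r))) abort("fewer than 10 overlapping points after shifting.")
  best <- which.max(r)
  delta <- if (best > 1 && best < length(r) &&
               is.finite(r[best - 1]) && is.finite(r[best + 1])) {
    parabolic_refine(r[best - 1], r[best], r[best + 1])
  } else 0
  structure((lags[best] + delta) * step,
            r = r[best], curve = tibble(lag = lags * step, r = r))
}

#' Boundary extension of the nascent signal beyond the mature mRNA
#'
#' For each profile the transcribed-unit boundary is the outermost offset
#' (walking outward from the anchor) at which the profile crosses the
#' half-plateau level — the midpoint between a plateau estimate (mean over
#' gene-body offsets) and a floor estimate (mean over far-flank offsets) —
#' located by linear interpolation between grid points. The extension is
#' the absolute distance between the nascent and mature boundaries, e.g.
#' ~70 bp upstream of the TSS and ~150 bp downstream of the pA site for
#' nascent run-on signal versus mRNA.
#'
#' @param nascent,mature `metagene_profile`s anchored at the relevant
#'   anchor (TSS for the upstream side, pA for the downstream side).
#' @param side `"upstream_of_tss"` or `"downstream_of_pa"`.
#' @param plateau_range,floor_range Length-2 offset ranges (bp) used for
#'   the plateau and floor estimates; sensible defaults are chosen per
#'   side (gene-body offsets for the plateau, the outermost 100 bp of the
#'   window for the floor).
#' @return One-row tibble: `side`, `nascent_boundary`, `mature_boundary`,
#'   `extension` (bp).
#' @export
extension_length <- function(nascent, mature,
                             side = c("upstream_of_tss", "downstream_of_pa"),
                             plateau_range = NULL, floor_range = NULL) {
  side <- match.arg(side)
  dir <- if (side == "upstream_of_tss") -1 else 1
  rng <- range(nascent$offset)
  if (is.null(plateau_range)) {
    plateau_range <- if (dir < 0) c(100, min(400, rng[2])) else c(max(-400, rng[1]), -100)
  }
  if (is.null(floor_range)) {
    floor_range <- if (dir < 0) c(rng[1], rng[1] + 100) else c(rng[2] - 100, rng[2])
  }
  b_n <- half_crossing(nascent, dir, plateau_range, floor_range)
  b_m <- half_crossing(mature, dir, plateau_range, floor_range)
  tibble(side = side, nascent_boundary = b_n, mature_boundary = b_m,
         extension = abs(b_n - b_m))
}

half_crossing <- function(profile, dir, plateau_range, floor_range) {
  off <- profile$offset
  v <- profile$value
  pl <- v[off >= plateau_range[1] & off <= plateau_range[2]]
  fl <- v[off >= floor_range[1] & off <= floor_range[2]]
  if (sum(is.finite(pl)) < 3 || sum(is.finite(fl)) < 3) {
    abort("too few finite values in the plateau/floor ranges.")
  }
  half <- (mean(pl, na.rm = TRUE) + mean(fl, na.rm = TRUE)) / 2
  ## walk outward, starting from the gene-body (plateau) side of the anchor
  sel <- if (dir < 0) order(-off) else order(off)
  sel <- sel[if (dir < 0) off[sel] <= plateau_range[1] else off[sel] >= plateau_range[2]]
  o <- off[sel]
  x <- v[sel]
  fin <- is.finite(x)
  o <- o[fin]; x <- x[fin]
  cross <- which(x[-length(x)] >= half & x[-1] < half)
  if (length(cross) == 0) {
    abort("profile never crosses the half-plateau level; boundary undefined.")
  }
  i <- cross[length(cross)]
  frac <- (x[i] - half) / (x[i] - x[i + 1])
  o[i] + frac * (o[i + 1] - o[i])
}
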