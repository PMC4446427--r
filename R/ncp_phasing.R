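# Nucleosome core particle (NCP) phasing analyses.
#
# d is the base-pair distance from the dyad axis, restricted to the 147-bp
# particle: d in [-73, 73].  A tract pairs with every midpoint within reach
# (each midpoint contributes independently); `nearest_only` restricts each
# tract to its closest midpoint.

NCP_HALF <- 73L

# 0-based coordinate of the tract center base; even lengths use the
# left-of-center base (deterministic).
tract_center <- function(tracts) {
  tracts$start + (tracts$n - 1L) %/% 2L
}

pair_tract_midpoints <- function(tracts, midpoints, nearest_only = FALSE) {
  stopifnot_cols(midpoints, c("chrom", "pos"), "midpoints")
  if (!nrow(tracts) || !nrow(midpoints))
    return(data.frame(tract = integer(0), mid = integer(0)))
  tgr <- tracts_granges(tracts)
  mgr <- GenomicRanges::GRanges(midpoints$chrom,
                                IRanges::IRanges(midpoints$pos + 1L - NCP_HALF,
                                                 midpoints$pos + 1L + NCP_HALF))
  hits <- GenomicRanges::findOverlaps(tgr, mgr)
  pairs <- data.frame(tract = S4Vectors::queryHits(hits),
                      mid = S4Vectors::subjectHits(hits))
  if (nearest_only && nrow(pairs)) {
    dist <- abs(tract_center(tracts)[pairs$tract] - midpoints$pos[pairs$mid])
    pairs <- pairs[order(pairs$tract, dist), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$tract), , drop = FALSE]
  }
  pairs
}

#' Dyad-distance profile of tracts around nucleosome midpoints
#'
#' Counts tract base pairs (`unit = "bp"`) or tract centers
#' (`unit = "center"`) at each distance d in \[-73, 73\] from nucleosome dyad
#' positions.  For G-class tracts, strand-orientation counts are carried
#' along: `c_fwd` counts tracts whose forward-strand representation is a
#' C-run (purine strand "-"), `g_fwd` those reading as a G-run ("+").
#'
#' @param tracts tract data.frame (pre-filter by class/length as needed).
#' @param midpoints data.frame with `chrom` and `pos` (0-based dyad base
#'   coordinate); see [read_midpoints_bed()].
#' @param unit "bp" or "center".
#' @param nearest_only restrict each tract to its nearest midpoint.
#' @return data.frame (`d`, `count`, `c_fwd`, `g_fwd`) covering d = -73..73.
#' @export
dyad_profile <- function(tracts, midpoints, unit = c("bp", "center"),
                         nearest_only = FALSE) {
  unit <- match.arg(unit)
  pairs <- pair_tract_midpoints(tracts, midpoints, nearest_only)
  ds <- -NCP_HALF:NCP_HALF
  out <- data.frame(d = ds, count = 0, c_fwd = 0, g_fwd = 0)
  if (!nrow(pairs)) return(out)
  mp <- midpoints$pos[pairs$mid]
  if (unit == "center") {
    d <- tract_center(tracts)[pairs$tract] - mp
    keep <- abs(d) <= NCP_HALF
    d <- d[keep]
    strand <- tracts$purine_strand[pairs$tract][keep]
  } else {
    s <- tracts$start[pairs$tract]
    e <- tracts$end[pairs$tract]
    lo <- pmax(s, mp - NCP_HALF)
    hi <- pmin(e - 1L, mp + NCP_HALF)
    keep <- lo <= hi
    lens <- hi[keep] - lo[keep] + 1L
    d <- sequence(lens, from = lo[keep] - mp[keep])
    strand <- rep(tracts$purine_strand[pairs$tract][keep], lens)
  }
  add <- function(vals) {
    t0 <- tabulate(vals + NCP_HALF + 1L, nbins = 2L * NCP_HALF + 1L)
    as.numeric(t0)
  }
  out$count <- add(d)
  out$c_fwd <- add(d[strand == "-"])
  out$g_fwd <- add(d[strand == "+"])
  out
}

#' Locate extrema of a dyad profile
#'
#' Smooths the count series with a centered running mean and returns the
#' positions d of its local maxima and minima.  Plateau ties are resolved
#' toward the position of smallest |d|; boundary points are never extrema.
#'
#' @param profile data.frame with `d` and `count` ([dyad_profile()]).
#' @param window odd smoothing window in bp (default 3; 1 = no smoothing).
#' @return list with integer vectors `maxima` and `minima` (values of d).
#' @export
classify_extrema <- function(profile, window = 3L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  y <- profile$count
  d <- profile$d
  if (window > 1L) {
    k <- rep(1 / window, window)
    ys <- stats::filter(y, k, sides = 2)
    h <- (window - 1L) %/% 2L
    ys[seq_len(h)] <- ys[h + 1L]
    ys[(length(y) - h + 1L):length(y)] <- ys[length(y) - h]
    y <- as.numeric(ys)
  }
  n <- length(y)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  dy <- diff(y)
  sgn <- sign(dy)
  # propagate through flat segments so plateaus register once
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1L) sgn[i] <- sgn[i - 1L]
  idx_max <- integer(0); idx_min <- integer(0)
  run_start <- 1L
  for (i in 2L:(n - 1L)) {
    if (y[i] != y[i - 1L]) run_start <- i
    left <- sgn[i - 1L]; right <- sgn[i]
    if (left > 0 && right < 0) {
      cand <- run_start:i   # plateau members share the extremum value
      idx_max <- c(idx_max, cand[which.min(abs(d[cand]))])
    } else if (left < 0 && right > 0) {
      cand <- run_start:i
      idx_min <- c(idx_min, cand[which.min(abs(d[cand]))])
    }
  }
  list(maxima = d[sort(unique(idx_max))], minima = d[sort(unique(idx_min))])
}

#' Label tracts by the profile extremum their center sits on
#'
#' @param tracts tract data.frame.
#' @param midpoints midpoint data.frame (`chrom`, `pos`).
#' @param maxima,minima integer vectors of extremum positions d
#'   ([classify_extrema()]).
#' @param tol tolerance in bp for center/extremum coincidence (default 1).
#' @param nearest_only see [dyad_profile()].
#' @return data.frame of the matching tracts with added columns `extremum`
#'   ("max"/"min"), `extremum_d` and `site` (rank of the extremum ordered by
#'   d, within its kind) - the pairing key for the paired t-tests.
#' @export
assign_tracts_to_extrema <- function(tracts, midpoints, maxima, minima,
                                     tol = 1L, nearest_only = FALSE) {
  pairs <- pair_tract_midpoints(tracts, midpoints, nearest_only)
  if (!nrow(pairs)) return(cbind(empty_tracts(), extremum = character(0),
                                 extremum_d = integer(0), site = integer(0)))
  d <- tract_center(tracts)[pairs$tract] - midpoints$pos[pairs$mid]
  lab <- function(ext, kind) {
    if (!length(ext)) return(NULL)
    ext <- sort(ext)
    hit <- lapply(seq_along(ext), function(k) {
      sel <- abs(d - ext[k]) <= tol
      if (!any(sel)) return(NULL)
      cbind(tracts[pairs$tract[sel], , drop = FALSE],
            extremum = kind, extremum_d = ext[k], site = k,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, hit)
  }
  out <- rbind(lab(maxima, "max"), lab(minima, "min"))
  if (is.null(out)) out <- cbind(empty_tracts(), extremum = character(0),
                                 extremum_d = integer(0), site = integer(0))
  rownames(out) <- NULL
  out
}

#' Compare per-position SNV rates between tracts at maxima and minima
#'
#' For every tract position p, computes %SNV (tract SNVs per 100 tracts) in
#' each extremum group, the percent increase at minima relative to maxima,
#' and a paired t-test pairing the k-th maximum with the k-th minimum
#' (ordered along the NCP by d).  Both raw and Benjamini-Hochberg-adjusted
#' p-values are reported.
#'
#' @param assignments assignment data.frame from [map_variants()].
#' @param grouped_tracts output of [assign_tracts_to_extrema()].
#' @return data.frame (`position`, `pct_max`, `pct_min`, `pct_increase`,
#'   `t`, `p_value`, `p_adj`).
#' @export
max_min_comparison <- function(assignments, grouped_tracts) {
  g <- grouped_tracts
  if (!nrow(g)) stop("no tracts assigned to extrema")
  n <- unique(g$n)
  if (length(n) != 1L)
    stop("grouped tracts must share one tract length; got ",
         paste(n, collapse = ", "))
  key <- function(chrom, start, end) paste(chrom, start, end)
  snv <- assignments[assignments$category == "tract_SNV", , drop = FALSE]
  snv_key <- key(snv$chrom, snv$tract_start, snv$tract_end)
  # per-site, per-position %SNV
  sites <- unique(g[c("extremum", "site")])
  per_site <- function(kind, k, p) {
    sel <- g$extremum == kind & g$site == k
    tk <- key(g$chrom, g$start, g$end)[sel]
    ntr <- sum(sel)
    if (!ntr) return(NA_real_)
    cnt <- sum(snv_key %in% tk & snv$position == p)
    cnt / ntr * 100
  }
  kmax <- sort(unique(g$site[g$extremum == "max"]))
  kmin <- sort(unique(g$site[g$extremum == "min"]))
  K <- min(length(kmax), length(kmin))
  if (K < 2L) stop("need at least two max/min site pairs for a paired test")
  res <- lapply(seq_len(n), function(p) {
    mx <- vapply(kmax[seq_len(K)], function(k) per_site("max", k, p),
                 numeric(1))
    mn <- vapply(kmin[seq_len(K)], function(k) per_site("min", k, p),
                 numeric(1))
    pm <- mean(mx); pn <- mean(mn)
    if (all(mn == mx)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(mn, mx, paired = TRUE)
    }
    data.frame(position = p, pct_max = pm, pct_min = pn,
               pct_increase = if (pm > 0) (pn - pm) / pm * 100 else NA_real_,
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Strand-orientation ratio profile for G-tracts
#'
#' At each dyad distance d, the ratio of G-class tracts whose forward-strand
#' representation is a C-run (purine strand "-") to those reading as a G-run
#' ("+"), using tract centers.  With `snv_assignments`, also the ratio of
#' %SNV at position 1 between the two orientations for the CG\[n\] subset
#' (5' flank C), the CpG-mutable position.
#'
#' @param tracts tract data.frame; non-G tracts are dropped.
#' @param midpoints midpoint data.frame.
#' @param snv_assignments optional assignment data.frame.
#' @param nearest_only see [dyad_profile()].
#' @return data.frame (`d`, `c_fwd`, `g_fwd`, `ratio`, and with assignments
#'   `snv_ratio`); ratios are NA where the denominator count is 0.
#' @export
orientation_ratio_profile <- function(tracts, midpoints,
                                      snv_assignments = NULL,
                                      nearest_only = FALSE) {
  g <- tracts[tracts$tract_class == "G", , drop = FALSE]
  prof <- dyad_profile(g, midpoints, unit = "center",
                       nearest_only = nearest_only)
  prof$ratio <- ifelse(prof$g_fwd > 0, prof$c_fwd / prof$g_fwd, NA_real_)
  if (is.null(snv_assignments)) return(prof[c("d", "c_fwd", "g_fwd", "ratio")])

  cg <- g[g$flank5 == "C", , drop = FALSE]
  pairs <- pair_tract_midpoints(cg, midpoints, nearest_only)
  d <- tract_center(cg)[pairs$tract] - midpoints$pos[pairs$mid]
  keep <- abs(d) <= NCP_HALF
  pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
  snv <- snv_assignments[snv_assignments$category == "tract_SNV" &
                           snv_assignments$position == 1L, , drop = FALSE]
  snv_key <- paste(snv$chrom, snv$tract_start, snv$tract_end)
  tk <- paste(cg$chrom, cg$start, cg$end)[pairs$tract]
  hit <- tk %in% snv_key
  strand <- cg$purine_strand[pairs$tract]
  tab <- function(sel) tabulate(d[sel] + NCP_HALF + 1L,
                                nbins = 2L * NCP_HALF + 1L)
  c_n <- tab(strand == "-"); g_n <- tab(strand == "+")
  c_s <- tab(strand == "-" & hit); g_s <- tab(strand == "+" & hit)
  pc <- ifelse(c_n > 0, c_s / c_n * 100, NA_real_)
  pg <- ifelse(g_n > 0, g_s / g_n * 100, NA_real_)
  prof$snv_ratio <- ifelse(!is.na(pg) & pg > 0, pc / pg, NA_real_)
  prof[c("d", "c_fwd", "g_fwd", "ratio", "snv_ratio")]
}

#' Local-regression smoothing of a profile series
#'
#' Locally weighted polynomial regression with tricube weights (the classic
#' loess scheme), fitted at every point.  Written in-package because the
#' analysis calls for polynomial degree 3, while `stats::loess()` supports
#' at most degree 2; at degrees 0-2 this function agrees with
#' `stats::loess(..., family = "gaussian", surface = "direct")`.
#'
#' @param x,y numeric vectors (x need not be equispaced).
#' @param span sampling proportion: fraction of points in each local window
#'   (default 0.100).
#' @param degree local polynomial degree (default 3).
#' @return numeric vector of fitted values at each x.
#' @export
smooth_profile <- function(x, y, span = 0.100, degree = 3L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  q <- max(degree + 2L, ceiling(span * n))
  if (q > n) stop("need at least degree + 2 points within the window")
  xo <- x[ok]; yo <- y[ok]
  fit_at <- function(x0) {
    dist <- abs(xo - x0)
    idx <- order(dist)[seq_len(q)]
    h <- max(dist[idx])
    w <- if (h == 0) rep(1, q) else (1 - pmin(dist[idx] / h, 1)^3)^3
    w[w <= 0] <- 1e-12
    X <- outer(xo[idx] - x0, 0:degree, `^`)
    b <- tryCatch(lm.wfit(X, yo[idx], w)$coefficients,
                  error = function(e) rep(NA_real_, degree + 1L))
    b[1L]
  }
  out <- rep(NA_real_, length(x))
  out[ok] <- vapply(xo, fit_at, numeric(1))
  out
}

#' Estimate the dominant period of a positional series
#'
#' Least-squares harmonic power (equivalent to the periodogram, valid off the
#' Fourier grid) is evaluated on a dense period grid within `range`, the
#' maximum refined by quadratic interpolation, and significance assessed by a
#' permutation null: the series values are shuffled and the maximum power
#' re-measured.
#'
#' @param y numeric series sampled at unit (1 bp) spacing; NA values dropped
#'   pairwise with their positions.
#' @param x positions (default `seq_along(y)`).
#' @param range candidate period range in bp (default `c(8, 13)`).
#' @param grid_step period grid step (default 0.01 bp).
#' @param n_perm number of permutations for the null (default 1000; 0 skips
#'   the test).
#' @param seed optional RNG seed for the permutations.
#' @return list with `period` (bp), `power`, and `p_value` (NA when
#'   `n_perm = 0`).
#' @export
estimate_period <- function(y, x = seq_along(y), range = c(8, 13),
                            grid_step = 0.01, n_perm = 1000L, seed = NULL) {
  ok <- is.finite(y)
  y <- y[ok] - mean(y[ok])
  x <- x[ok]
  if (length(y) < 8L) stop("series too short for period estimation")
  periods <- seq(range[1], range[2], by = grid_step)
  # orthonormal cos/sin basis per candidate period, stacked column-wise, so
  # the explained power at every period is two inner products per series
  M <- do.call(cbind, lapply(periods, function(Tp) {
    w <- 2 * pi / Tp
    qr.Q(qr(cbind(cos(w * x), sin(w * x))))
  }))
  pow <- function(yy) {
    z <- crossprod(M, yy)
    z1 <- z[seq(1L, length(z), by = 2L)]
    z2 <- z[seq(2L, length(z), by = 2L)]
    z1^2 + z2^2
  }
  p_obs <- pow(y)
  i <- which.max(p_obs)
  period <- periods[i]
  if (i > 1L && i < length(periods)) {    # quadratic refinement
    y1 <- p_obs[i - 1L]; y2 <- p_obs[i]; y3 <- p_obs[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) period <- period + grid_step * 0.5 * (y1 - y3) / denom
  }
  p_value <- NA_real_
  if (n_perm > 0L) {
    obs <- max(p_obs)
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) {
        max(pow(sample(y))) >= obs
      }, logical(1)))
    })
    p_value <- (1 + exceed) / (n_perm + 1)
  }
  list(period = period, power = max(p_obs), p_value = p_value)
}
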