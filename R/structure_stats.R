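# Flexibility and geometry statistics from tabulated trajectory data.

STEP_PARAMS <- c("shift", "slide", "rise", "tilt", "roll", "twist")

#' Base-pair-step flexibility volume (V_step)
#'
#' V_step summarizes the conformational fluctuation of a base-pair step as
#' the product of the square roots of the six eigenvalues of the sample
#' covariance of its step parameters (shift, slide, rise in Angstrom; tilt,
#' roll, twist in degrees):
#' \deqn{V_{step} = \prod_{i=1}^{6} \sqrt{\lambda_i} = \sqrt{\det \Sigma}}
#' in units of Angstrom^3 deg^3.  The unbiased (n-1) covariance is used.
#'
#' @param series numeric matrix or data.frame of frames x 6 parameters
#'   (columns shift, slide, rise, tilt, roll, twist in that order, named or
#'   not).
#' @return the V_step value; a singular covariance gives 0 with a warning,
#'   and fewer than 7 frames (covariance not of full rank with certainty)
#'   also warns.
#' @export
v_step <- function(series) {
  m <- as.matrix(series[, seq_len(6L), drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("step parameters must be finite")
  if (nrow(m) < 2L) stop("need at least 2 frames")
  if (nrow(m) < 7L)
    warning("fewer than 7 frames: covariance is rank-deficient")
  ev <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0 & ev > -1e-12] <- 0
  if (any(ev <= 0)) {
    warning("singular covariance; V_step reported as 0")
    return(0)
  }
  prod(sqrt(ev))
}

#' V_step for every step label in a long table
#'
#' @param step_table data.frame with columns `frame`, `step_label` and the
#'   six step parameters (see [read_step_params()]).
#' @return data.frame (`step_label`, `n_frames`, `v_step`).
#' @export
v_step_by_step <- function(step_table) {
  stopifnot_cols(step_table, c("step_label", STEP_PARAMS), "step table")
  sp <- split(step_table, step_table$step_label)
  out <- do.call(rbind, lapply(names(sp), function(lbl) {
    data.frame(step_label = lbl, n_frames = nrow(sp[[lbl]]),
               v_step = v_step(sp[[lbl]][STEP_PARAMS]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Minor groove width from phosphate coordinates
#'
#' Per frame and per position, the Euclidean distance between a
#' convention-selected pair of phosphates, optionally minus a constant
#' (e.g. 5.8 Angstrom for two phosphate radii), averaged over frames.
#' Conventions: `"cross_strand"` pairs (strand 1, residue i) with
#' (strand 2, residue i + offset); `"within_strand"` pairs (strand 1, i)
#' with (strand 1, i + offset).
#'
#' @param trace data.frame with columns `frame`, `strand` (1 or 2), `resid`,
#'   `x`, `y`, `z` (Angstrom).
#' @param convention "cross_strand" (default) or "within_strand".
#' @param offset residue offset of the pairing (default 3).
#' @param subtract constant subtracted from every distance (default 0).
#' @return data.frame (`resid`, `n_frames`, `mean`, `sd`); frames missing a
#'   phosphate of a pair are skipped for that position.  The convention and
#'   offset are recorded as attributes.
#' @export
groove_width <- function(trace, convention = c("cross_strand",
                                               "within_strand"),
                         offset = 3L, subtract = 0) {
  convention <- match.arg(convention)
  stopifnot_cols(trace, c("frame", "strand", "resid", "x", "y", "z"), "trace")
  s1 <- trace[trace$strand == 1L, , drop = FALSE]
  s2 <- if (convention == "cross_strand")
    trace[trace$strand == 2L, , drop = FALSE] else s1
  if (convention == "cross_strand" && !nrow(s2))
    stop("cross-strand convention needs both strands")
  partner <- s2
  partner$resid <- partner$resid - offset
  m <- merge(s1, partner, by = c("frame", "resid"),
             suffixes = c("_a", "_b"))
  if (convention == "within_strand")
    m <- m[m$strand_a == 1L & m$strand_b == 1L, , drop = FALSE]
  if (!nrow(m)) stop("no phosphate pairs found for this convention/offset")
  dist <- sqrt((m$x_a - m$x_b)^2 + (m$y_a - m$y_b)^2 +
                 (m$z_a - m$z_b)^2) - subtract
  agg <- aggregate(list(mean = dist), list(resid = m$resid), mean)
  agg$sd <- aggregate(list(sd = dist), list(resid = m$resid),
                      function(v) if (length(v) > 1L) sd(v) else 0)$sd
  agg$n_frames <- aggregate(list(n = dist), list(resid = m$resid),
                            length)$n
  out <- agg[order(agg$resid), c("resid", "n_frames", "mean", "sd")]
  rownames(out) <- NULL
  attr(out, "convention") <- convention
  attr(out, "offset") <- offset
  attr(out, "subtract") <- subtract
  out
}

#' Minor-groove water-bridge occupancy
#'
#' Per position, the fraction of frames with exactly one and exactly two
#' bridging waters.
#'
#' @param counts data.frame with columns `frame`, `position`, `count`
#'   (non-negative integers).
#' @return data.frame (`position`, `n_frames`, `f_one`, `f_two`), with
#'   `f_one + f_two <= 1` at every position.
#' @export
bridge_occupancy <- function(counts) {
  stopifnot_cols(counts, c("frame", "position", "count"), "bridge counts")
  if (!nrow(counts)) stop("need at least one frame")
  if (any(counts$count < 0)) stop("bridge counts must be non-negative")
  agg <- aggregate(list(n_frames = counts$count,
                        one = counts$count == 1L,
                        two = counts$count == 2L),
                   list(position = counts$position),
                   FUN = length)
  one <- aggregate(list(v = counts$count == 1L),
                   list(position = counts$position), sum)$v
  two <- aggregate(list(v = counts$count == 2L),
                   list(position = counts$position), sum)$v
  out <- data.frame(position = agg$position, n_frames = agg$n_frames,
                    f_one = one / agg$n_frames, f_two = two / agg$n_frames)
  out[order(out$position), , drop = FALSE]
}
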