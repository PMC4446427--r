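# Synthetic genomes, variant sets, nucleosome placements and step-parameter
# ensembles, each with a truth table, so the analysis stages can be validated
# by parameter recovery.  All generators are deterministic per seed.

#' Default mutation model for the synthetic generator
#'
#' The defaults emulate the qualitative structure of homopolymer mutagenesis
#' in human population data: A-tract SNV hotspots at the first and last
#' position with overall rates peaking at length 9, G-tract hotspots at
#' positions 2-3 peaking at length 8, flank-directed substitution at A-tracts
#' (probability `theta`), a bell-shaped slippage rate over length with a +1
#' excess, and an indel rate that plateaus for long tracts.  Every element
#' can be overridden.
#'
#' @param theta probability that an A-tract SNV is directed toward a flanking
#'   base (default 0.9).
#' @param snv_scale per-class SNV rate scale: the per-tract rate is
#'   `snv_scale * (n / snv_peak) * exp(-(n - snv_peak)^2 / 8)`, so the
#'   normalized fraction F SNV peaks at `snv_peak` with height
#'   `snv_scale / snv_peak` — the defaults put the maxima near 0.017 for
#'   A-tracts (length 9) and 0.067 for G-tracts (length 8), the magnitudes
#'   seen in population call sets.
#' @param snv_peak named vector: length at which F SNV peaks, per class.
#' @param slip_mu,slip_sigma,slip_height bell-shaped per-base slippage rate
#'   s(n) = height * exp(-(n - mu)^2 / (2 sigma^2)); the per-tract event
#'   probability is n * s(n).  The default height puts the peak F slip near
#'   0.02.
#' @param slip_ratio +1 : -1 slippage odds (default 2).
#' @param indel_n0,indel_high,indel_low per-class, per-base indel rate:
#'   `indel_high` for n >= n0, `indel_low` below (plateau model, an order of
#'   magnitude higher for G-tracts); per-tract probability is n * rate,
#'   split evenly between insertions and deletions.
#' @param indel_geom_p geometric size parameter for indel sizes on 1..200.
#' @param g_spectrum substitution weights for G-tract SNVs (G>T, G>C, G>A).
#' @param w_profile function(class, n) returning positional weights of
#'   length n; the default puts weight 6 on the hotspot positions, 1
#'   elsewhere.
#' @return a list with class `mutation_model`.
#' @export
default_mutation_model <- function(theta = 0.9,
                                   snv_scale = c(A = 0.15, G = 0.54),
                                   snv_peak = c(A = 9, G = 8),
                                   slip_mu = c(A = 8, G = 9),
                                   slip_sigma = 1.5, slip_height = 0.02,
                                   slip_ratio = 2,
                                   indel_n0 = 7,
                                   indel_high = c(A = 0.003, G = 0.03),
                                   indel_low = c(A = 3e-4, G = 3e-3),
                                   indel_geom_p = 0.5,
                                   g_spectrum = c(`G>T` = 0.45, `G>C` = 0.35,
                                                  `G>A` = 0.20),
                                   w_profile = NULL) {
  if (is.null(w_profile)) {
    w_profile <- function(tract_class, n) {
      w <- rep(1, n)
      if (tract_class == "A") w[c(1L, n)] <- 6 else w[c(2L, min(3L, n))] <- 6
      w
    }
  }
  stopifnot(theta >= 0, theta <= 1, all(g_spectrum >= 0))
  model <- list(theta = theta, snv_scale = snv_scale, snv_peak = snv_peak,
                slip_mu = slip_mu, slip_sigma = slip_sigma,
                slip_height = slip_height, slip_ratio = slip_ratio,
                indel_n0 = indel_n0, indel_high = indel_high,
                indel_low = indel_low, indel_geom_p = indel_geom_p,
                g_spectrum = g_spectrum / sum(g_spectrum),
                w_profile = w_profile)
  class(model) <- "mutation_model"
  model
}

# background base sampler: iid with given GC, then iteratively resample any
# position extending a run to length >= 4 (vectorized; converges quickly)
background_chars <- function(len, gc) {
  if (len <= 0L) return(character(0))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ch <- sample(names(p), len, replace = TRUE, prob = p)
  repeat {
    r <- rle(ch)
    if (all(r$lengths < 4L)) break
    bad_run <- which(r$lengths >= 4L)
    ends <- cumsum(r$lengths)
    # resample every 4th-and-later member of an over-long run
    idx <- unlist(lapply(bad_run, function(k) {
      (ends[k] - r$lengths[k] + 4L):ends[k]
    }))
    ch[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  ch
}

# pick one base per row, uniform over ACGT minus the row's forbidden bases
sample_excluding <- function(forbid1, forbid2 = NULL) {
  n <- length(forbid1)
  out <- sample(.BASES, n, replace = TRUE)
  repeat {
    bad <- out == forbid1
    if (!is.null(forbid2)) bad <- bad | out == forbid2
    if (!any(bad)) break
    out[bad] <- sample(.BASES, sum(bad), replace = TRUE)
  }
  out
}

#' Simulate a genome with planted maximal tracts
#'
#' Builds one synthetic chromosome containing the requested tracts, each
#' written as 5'-flank + run + 3'-flank on the forward strand (reverse
#' tracts are embedded as their reverse complement), separated by background
#' spacers.  The background is generated run-free (no run of 4 or more
#' identical bases) and spacer boundary bases are constrained so planted
#' flanks stay maximal, which makes the truth table and [scan_sequence()]
#' output reconcile exactly.
#'
#' @param placements data.frame with columns `tract_class` ("A"/"G"), `n`,
#'   `count`, and optionally `flank5`, `flank3` (purine-strand bases; drawn
#'   at random from the legal set when absent) and `purine_strand` (drawn
#'   at random when absent).
#' @param spacer_len background spacer length between tracts (default 15).
#' @param gc background GC fraction (default 0.41, roughly genomic).
#' @param seed RNG seed (required for reproducibility).
#' @param chrom chromosome name (default "sim1").
#' @return list with `sequences` (named character vector of length 1) and
#'   `tracts` (truth tract table in the [scan_sequence()] layout, coordinate
#'   sorted).
#' @export
simulate_genome <- function(placements, spacer_len = 15L, gc = 0.41,
                            seed = NULL, chrom = "sim1") {
  stopifnot_cols(placements, c("tract_class", "n", "count"), "placements")
  stopifnot(all(placements$n >= 4L), all(placements$n <= 13L),
            all(placements$count >= 0L), spacer_len >= 2L)
  with_seed(seed, {
    idx <- rep(seq_len(nrow(placements)), placements$count)
    nt <- length(idx)
    if (!nt) {
      seqs <- setNames(paste(background_chars(1000L, gc), collapse = ""),
                       chrom)
      return(list(sequences = seqs, tracts = empty_tracts()))
    }
    idx <- sample(idx)                      # interleave strata
    cls <- placements$tract_class[idx]
    n <- placements$n[idx]
    strand <- if ("purine_strand" %in% names(placements))
      placements$purine_strand[idx] else sample(c("+", "-"), nt, TRUE)
    legal5 <- lapply(cls, function(cl) setdiff(.BASES, cl))
    f5 <- if ("flank5" %in% names(placements) &&
              !all(is.na(placements$flank5)))
      placements$flank5[idx] else
        vapply(legal5, function(s) sample(s, 1L), character(1))
    f3 <- if ("flank3" %in% names(placements) &&
              !all(is.na(placements$flank3)))
      placements$flank3[idx] else
        vapply(legal5, function(s) sample(s, 1L), character(1))
    if (any(f5 == cls | f3 == cls))
      stop("flank base equal to the tract base would break maximality")

    # forward-strand rendering of each unit
    fb <- ifelse(strand == "+", cls, comp_base(cls))       # run base
    lf <- ifelse(strand == "+", f5, comp_base(f3))         # left flank
    rf <- ifelse(strand == "+", f3, comp_base(f5))         # right flank
    unit <- paste0(lf, strrep(fb, n), rf)

    # spacers: interior run-free; boundary bases avoid extending flanks and
    # avoid forming a new run of 4 at the junction
    spacers <- replicate(nt + 1L, background_chars(spacer_len, gc),
                         simplify = FALSE)
    for (i in seq_len(nt + 1L)) {
      sp <- spacers[[i]]
      # last base of spacer i sits before unit i's left flank
      if (i <= nt)
        sp[length(sp)] <- sample_excluding(lf[i], sp[length(sp) - 1L])
      # first base of spacer i sits after unit (i-1)'s right flank
      if (i > 1L)
        sp[1L] <- sample_excluding(rf[i - 1L], sp[2L])
      spacers[[i]] <- sp
    }
    sp_str <- vapply(spacers, paste, character(1), collapse = "")
    pieces <- character(2L * nt + 1L)
    pieces[seq(1L, 2L * nt + 1L, by = 2L)] <- sp_str
    pieces[seq(2L, 2L * nt, by = 2L)] <- unit
    genome <- paste(pieces, collapse = "")

    unit_len <- n + 2L
    offsets <- cumsum(c(0L, unit_len + spacer_len))[seq_len(nt)] + spacer_len
    start <- offsets + 1L                    # 0-based run start (skip flank)
    tracts <- data.frame(chrom = chrom, start = start, end = start + n,
                         n = as.integer(n), tract_class = cls,
                         purine_strand = strand, flank5 = f5, flank3 = f3,
                         stringsAsFactors = FALSE)
    tracts <- tracts[order(tracts$start), , drop = FALSE]
    rownames(tracts) <- NULL
    list(sequences = setNames(genome, chrom), tracts = tracts)
  })
}

bell <- function(n, mu, sigma, height) height * exp(-(n - mu)^2 / (2 * sigma^2))

# broadcast a scalar or per-class named parameter over a class vector
per_class <- function(x, cls) {
  if (length(x) == 1L && is.null(names(x))) rep(as.numeric(x), length(cls))
  else unname(x[cls])
}

#' Simulate variants over a synthetic genome
#'
#' Draws SNVs, slippage events and general indels per tract under a
#' [default_mutation_model()]-style model and returns both left-aligned
#' VCF-like records and a truth assignment table in the [map_variants()]
#' layout.  SNV positions are drawn proportional to the model's positional
#' weight profile; A-tract alternates are flank-directed with probability
#' `theta` (and otherwise uniform over the non-tract, non-flank bases, so the
#' flank-direction fraction recovers theta exactly); G-tract alternates
#' follow `g_spectrum`.  At most one slippage record per (tract, sign) is
#' emitted because left-aligned slippage records at one tract are identical
#' (sites, not alleles, are the unit of counting).  General insertions use
#' non-tract bases only, which keeps their junction placement unambiguous
#' under left-alignment.
#'
#' @param genome list from [simulate_genome()] (or a named character vector
#'   plus a `tracts` argument).
#' @param model mutation model list ([default_mutation_model()]).
#' @param seed RNG seed.
#' @param tracts truth tract table; defaults to `genome$tracts`.
#' @return list with `variants` (chrom, pos, ref, alt, vtype, size;
#'   coordinate sorted, deduplicated) and `truth` (assignment-table layout
#'   plus a `tract_id` column).
#' @export
simulate_variants <- function(genome, model = default_mutation_model(),
                              seed = NULL, tracts = NULL) {
  seqs <- if (is.list(genome)) genome$sequences else genome
  if (is.null(tracts)) tracts <- genome$tracts
  stopifnot(!is.null(tracts), nrow(tracts) > 0)
  s <- as_reference(seqs)
  with_seed(seed, {
    nt <- nrow(tracts)
    chrom <- tracts$chrom
    sseq <- s[chrom]                       # per-tract sequence string
    cls <- tracts$tract_class
    n <- tracts$n
    start <- tracts$start; end <- tracts$end
    strand <- tracts$purine_strand
    fb <- ifelse(strand == "+", cls, comp_base(cls))
    lf_chr <- substr(sseq, start, start)   # forward left flank char
    truth <- list(); vcf <- list()

    ## --- SNVs -----------------------------------------------------------
    # per-tract rate scales with n so F SNV (= rate / n in expectation)
    # peaks at snv_peak with height snv_scale / snv_peak
    peak <- per_class(model$snv_peak, cls)
    rate <- per_class(model$snv_scale, cls) * (n / peak) *
      exp(-(n - peak)^2 / (2 * 2^2))
    n_snv <- rpois(nt, rate)
    if (any(n_snv > 0)) {
      ti <- rep(seq_len(nt), n_snv)
      # position ~ w(class, n), drawn per stratum
      p <- integer(length(ti))
      key <- paste(cls[ti], n[ti])
      for (k in unique(key)) {
        rows <- which(key == k)
        cl1 <- cls[ti[rows[1]]]; n1 <- n[ti[rows[1]]]
        w <- model$w_profile(cl1, n1)
        p[rows] <- sample.int(n1, length(rows), replace = TRUE, prob = w)
      }
      from <- cls[ti]
      to <- character(length(ti))
      isA <- from == "A"
      if (any(isA)) {
        rowsA <- which(isA)
        flankset <- cbind(tracts$flank5[ti[rowsA]], tracts$flank3[ti[rowsA]])
        directed <- runif(length(rowsA)) < model$theta
        pick <- ifelse(runif(length(rowsA)) < 0.5, flankset[, 1L],
                       flankset[, 2L])
        pick[pick == "N"] <- apply(flankset[pick == "N", , drop = FALSE], 1L,
                                   function(r) r[r != "N"][1L])
        other <- vapply(seq_along(rowsA), function(i) {
          cand <- setdiff(setdiff(.BASES, "A"),
                          flankset[i, ][flankset[i, ] != "N"])
          if (!length(cand)) cand <- setdiff(.BASES, "A")
          sample(cand, 1L)
        }, character(1))
        to[rowsA] <- ifelse(directed, pick, other)
      }
      if (any(!isA)) {
        rowsG <- which(!isA)
        subs <- sample(names(model$g_spectrum), length(rowsG), replace = TRUE,
                       prob = model$g_spectrum)
        to[rowsG] <- substr(subs, 3L, 3L)
      }
      ok <- !is.na(to) & to != from
      ti <- ti[ok]; p <- p[ok]; from <- from[ok]; to <- to[ok]
      x <- ifelse(strand[ti] == "+", start[ti] + p - 1L, end[ti] - p)
      ref_f <- ifelse(strand[ti] == "+", from, comp_base(from))
      alt_f <- ifelse(strand[ti] == "+", to, comp_base(to))
      vcf$snv <- data.frame(chrom = chrom[ti], pos = x + 1L, ref = ref_f,
                            alt = alt_f, stringsAsFactors = FALSE)
      truth$snv <- data.frame(tract_id = ti, category = "tract_SNV",
                              position = as.integer(p),
                              location = NA_character_,
                              sub_from = from, sub_to = to,
                              indel_size = 0L, stringsAsFactors = FALSE)
    }

    ## --- slippage (at most one per tract and sign) ----------------------
    s_rate <- pmin(0.9, n * bell(n, per_class(model$slip_mu, cls),
                                 model$slip_sigma, model$slip_height))
    has_slip <- runif(nt) < s_rate
    plus <- runif(nt) < model$slip_ratio / (1 + model$slip_ratio)
    si <- which(has_slip)
    if (length(si)) {
      isp <- plus[si]
      ref <- ifelse(isp, lf_chr[si], paste0(lf_chr[si], fb[si]))
      alt <- ifelse(isp, paste0(lf_chr[si], fb[si]), lf_chr[si])
      vcf$slip <- data.frame(chrom = chrom[si], pos = start[si], ref = ref,
                             alt = alt, stringsAsFactors = FALSE)
      truth$slip <- data.frame(
        tract_id = si,
        category = ifelse(isp, "slippage_plus", "slippage_minus"),
        position = NA_integer_, location = NA_character_,
        sub_from = NA_character_, sub_to = NA_character_,
        indel_size = 1L, stringsAsFactors = FALSE)
    }

    ## --- general indels -------------------------------------------------
    i_rate <- pmin(0.9, n * ifelse(n >= model$indel_n0,
                                   per_class(model$indel_high, cls),
                                   per_class(model$indel_low, cls)))
    has_ind <- runif(nt) < i_rate
    ii <- which(has_ind)
    if (length(ii)) {
      size <- pmin(200L, 1L + rgeom(length(ii), model$indel_geom_p))
      is_ins <- runif(length(ii)) < 0.5
      rec <- vector("list", length(ii))
      tru <- vector("list", length(ii))
      for (k in seq_along(ii)) {
        i <- ii[k]
        if (is_ins[k]) {
          # insertion of non-tract bases at an interior junction (between
          # purine positions j and j+1, 1 <= j <= n-1): unambiguous placement
          j <- if (n[i] > 2L) sample(seq_len(n[i] - 1L), 1L) else 1L
          x <- if (strand[i] == "+") start[i] + j - 1L else end[i] - j - 1L
          anchor <- substr(sseq[i], x + 1L, x + 1L)
          ins_p <- fb[i]
          ins <- paste(sample_excluding(rep(ins_p, size[k])), collapse = "")
          rec[[k]] <- data.frame(chrom = chrom[i], pos = x + 1L,
                                 ref = anchor, alt = paste0(anchor, ins),
                                 stringsAsFactors = FALSE)
          tru[[k]] <- data.frame(tract_id = i, category = "indel_ins",
                                 position = as.integer(j),
                                 location = ins_location(j, n[i]),
                                 sub_from = NA_character_,
                                 sub_to = NA_character_,
                                 indel_size = as.integer(size[k]),
                                 stringsAsFactors = FALSE)
        } else {
          # deletion: multi-base within-run (left-aligned to the run start)
          # or single-base flank deletion
          loc <- sample(c("in", "flank5", "flank3"), 1L,
                        prob = c(0.6, 0.2, 0.2))
          if (loc == "in") {
            k2 <- max(2L, min(size[k], n[i] - 1L))
            x0 <- start[i] - 1L              # anchor at left flank
            ref <- substr(sseq[i], x0 + 1L, x0 + 1L + k2)
            alt <- substr(ref, 1L, 1L)
            dsz <- k2
            d0 <- start[i]; d1 <- start[i] + k2 - 1L
          } else {
            xdel <- if (loc == "flank5") start[i] - 1L else end[i]
            x0 <- xdel - 1L
            if (x0 < 0L) next
            ref <- substr(sseq[i], x0 + 1L, x0 + 2L)
            alt <- substr(ref, 1L, 1L)
            dsz <- 1L
            d0 <- xdel; d1 <- xdel
          }
          pp <- purine_pos(c(d0, d1), start[i], end[i], strand[i])
          locc <- if (min(pp) <= 0L) "before_tract"
                  else if (max(pp) >= n[i] + 1L) "after_tract"
                  else "in_tract"
          rec[[k]] <- data.frame(chrom = chrom[i], pos = x0 + 1L, ref = ref,
                                 alt = alt, stringsAsFactors = FALSE)
          tru[[k]] <- data.frame(tract_id = i, category = "indel_del",
                                 position = NA_integer_, location = locc,
                                 sub_from = NA_character_,
                                 sub_to = NA_character_,
                                 indel_size = as.integer(dsz),
                                 stringsAsFactors = FALSE)
        }
      }
      keep <- !vapply(rec, is.null, logical(1))
      if (any(keep)) {
        vcf$indel <- do.call(rbind, rec[keep])
        truth$indel <- do.call(rbind, tru[keep])
      }
    }

    variants <- if (length(vcf)) do.call(rbind, vcf) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), stringsAsFactors = FALSE)
    truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
    if (!is.null(truth_df)) {
      tmeta <- tracts[truth_df$tract_id,
                      c("chrom", "start", "end", "n", "tract_class",
                        "purine_strand", "flank5", "flank3")]
      names(tmeta)[names(tmeta) == "start"] <- "tract_start"
      names(tmeta)[names(tmeta) == "end"] <- "tract_end"
      # variant rows and truth rows are built part-by-part in the same order
      truth_df <- cbind(tmeta, variants[c("pos", "ref", "alt")], truth_df)
      rownames(truth_df) <- NULL
    }
    # drop exact duplicate records (and their truth rows) - site-level counting
    vkey <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    dup <- duplicated(vkey)
    if (any(dup) && !is.null(truth_df)) truth_df <- truth_df[!dup, , drop = FALSE]
    variants <- variants[!dup, , drop = FALSE]
    o <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[o, , drop = FALSE]
    if (!is.null(truth_df)) truth_df <- truth_df[o, , drop = FALSE]
    rl <- nchar(variants$ref); al <- nchar(variants$alt)
    variants$vtype <- ifelse(rl == 1L & al == 1L, "SNV",
                             ifelse(al > rl, "INS", "DEL"))
    variants$size <- abs(al - rl)
    rownames(variants) <- NULL
    list(variants = variants, truth = truth_df)
  })
}

#' Simulate nucleosome midpoints phased to tracts
#'
#' Places `n_midpoints` dyad positions relative to randomly chosen tract
#' centers, with the tract-center-to-dyad distance d drawn from a density
#' proportional to `1 + amplitude * cos(2 pi d / period)` on \[-73, 73\].
#' With `orientation_bias > 0` and G-class tracts available, the tract
#' receiving a midpoint at distance d is drawn from the "-" (C-forward) pool
#' with probability `r/(1+r)`, `r = 1 + orientation_bias * cos(2 pi d /
#' period)`, so the C/G orientation ratio oscillates in phase with d.
#'
#' @param tracts tract data.frame to phase against.
#' @param n_midpoints number of midpoints to place.
#' @param period phasing period in bp (default 10.5).
#' @param amplitude cosine modulation amplitude in \[0, 1) (default 0.5).
#' @param orientation_bias amplitude of the C-forward preference (default 0).
#' @param seed RNG seed.
#' @return list with `midpoints` (chrom, pos) and `truth` (tract_id, d).
#' @export
simulate_ncp <- function(tracts, n_midpoints, period = 10.5,
                         amplitude = 0.5, orientation_bias = 0, seed = NULL) {
  stopifnot(period >= 8, period <= 13, amplitude >= 0, amplitude < 1,
            orientation_bias >= 0, nrow(tracts) > 0)
  with_seed(seed, {
    ds <- -NCP_HALF:NCP_HALF
    dens <- 1 + amplitude * cos(2 * pi * ds / period)
    d <- sample(ds, n_midpoints, replace = TRUE, prob = dens)
    if (orientation_bias > 0) {
      pool_c <- which(tracts$purine_strand == "-")
      pool_g <- which(tracts$purine_strand == "+")
      if (!length(pool_c) || !length(pool_g))
        stop("orientation bias needs tracts on both strands")
      r <- 1 + orientation_bias * cos(2 * pi * d / period)
      use_c <- runif(n_midpoints) < r / (1 + r)
      ti <- integer(n_midpoints)
      ti[use_c] <- sample(pool_c, sum(use_c), replace = TRUE)
      ti[!use_c] <- sample(pool_g, sum(!use_c), replace = TRUE)
    } else {
      ti <- sample.int(nrow(tracts), n_midpoints, replace = TRUE)
    }
    centers <- tract_center(tracts)[ti]
    pos <- centers - d
    keep <- pos >= NCP_HALF                  # keep the particle on-sequence
    list(midpoints = data.frame(chrom = tracts$chrom[ti[keep]],
                                pos = pos[keep],
                                stringsAsFactors = FALSE),
         truth = data.frame(tract_id = ti[keep], d = d[keep]))
  })
}

#' Simulate a base-pair-step parameter ensemble
#'
#' Frames drawn from a multivariate normal with the given mean and
#' covariance, for validating [v_step()] against the closed form
#' sqrt(det(cov)).
#'
#' @param mean length-6 mean vector.
#' @param cov 6x6 positive-semidefinite covariance.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param step_label label recorded on the result (default "sim").
#' @return data.frame with `frame`, `step_label` and the six step parameters.
#' @export
simulate_step_params <- function(mean = rep(0, 6), cov = diag(6),
                                 n_frames = 1000L, seed = NULL,
                                 step_label = "sim") {
  stopifnot(length(mean) == 6L, all(dim(cov) == c(6L, 6L)))
  with_seed(seed, {
    m <- MASS::mvrnorm(n_frames, mu = mean, Sigma = cov)
    out <- data.frame(frame = seq_len(n_frames), step_label = step_label,
                      m, stringsAsFactors = FALSE)
    names(out)[3:8] <- STEP_PARAMS
    out
  })
}

#' Compare estimates with generator truth
#'
#' @param estimates data.frame with columns `parameter`, `truth`, `estimate`
#'   and optionally `se` (standard error; 0 or NA means an exact check).
#' @param z_max flag threshold on |z| (default 3).
#' @return the input with added `z`, `ci_lo`, `ci_hi` and logical `pass`.
#' @export
recovery_report <- function(estimates, z_max = 3) {
  stopifnot_cols(estimates, c("parameter", "truth", "estimate"), "estimates")
  se <- if ("se" %in% names(estimates)) estimates$se else
    rep(NA_real_, nrow(estimates))
  z <- ifelse(!is.na(se) & se > 0,
              (estimates$estimate - estimates$truth) / se, NA_real_)
  pass <- ifelse(!is.na(z), abs(z) <= z_max,
                 estimates$estimate == estimates$truth)
  out <- estimates
  out$z <- z
  out$ci_lo <- ifelse(!is.na(se) & se > 0, out$estimate - z_max * se,
                      out$estimate)
  out$ci_hi <- ifelse(!is.na(se) & se > 0, out$estimate + z_max * se,
                      out$estimate)
  out$pass <- pass
  out
}
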