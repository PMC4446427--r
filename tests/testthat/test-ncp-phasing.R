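one_tract <- function(start, n = 5L, class = "A", strand = "+",
                      chrom = "c1") {
  data.frame(chrom = chrom, start = start, end = start + n, n = n,
             tract_class = class, purine_strand = strand, flank5 = "T",
             flank3 = "T", stringsAsFactors = FALSE)
}

test_that("dyad profile counts centers and base pairs at the right distances", {
  mid <- data.frame(chrom = "c1", pos = 100L)
  tr <- one_tract(98L)   # length-5 tract centered on the dyad
  pc <- dyad_profile(tr, mid, unit = "center")
  expect_equal(pc$count[pc$d == 0], 1)
  expect_equal(sum(pc$count), 1)
  pb <- dyad_profile(tr, mid, unit = "bp")
  expect_equal(pb$count[abs(pb$d) <= 2], rep(1, 5))
  expect_equal(sum(pb$count), 5)
  # even length: left-of-center base defines d
  tr6 <- one_tract(98L, n = 6L)
  pc6 <- dyad_profile(tr6, mid, unit = "center")
  expect_equal(pc6$count[pc6$d == 0], 1)  # center base = start + 2
  # outside the 147-bp particle nothing is counted
  farm <- data.frame(chrom = "c1", pos = 600L)
  expect_equal(sum(dyad_profile(tr, farm, unit = "bp")$count), 0)
})

test_that("dyad profile is invariant under joint translation", {
  set.seed(401)
  starts <- sample.int(5000, 80) + 200L
  tr <- do.call(rbind, lapply(starts, one_tract))
  mid <- data.frame(chrom = "c1", pos = sample.int(5000, 40) + 200L)
  p1 <- dyad_profile(tr, mid, unit = "bp")
  tr2 <- tr
  tr2$start <- tr$start + 1000L
  tr2$end <- tr$end + 1000L
  mid2 <- mid
  mid2$pos <- mid$pos + 1000L
  expect_equal(dyad_profile(tr2, mid2, unit = "bp"), p1)
})

test_that("extrema of a discrete 10.5-bp cosine match the analytic count", {
  d <- -73:73
  prof <- data.frame(d = d, count = cos(2 * pi * d / 10.5))
  ex <- classify_extrema(prof, window = 1L)
  # analytic maxima at 10.5k for k = -6..6 -> 13 interior maxima; minima at
  # 10.5(k + 1/2) -> 14 interior minima
  expect_length(ex$maxima, 13L)
  expect_length(ex$minima, 14L)
  expect_true(0 %in% ex$maxima)
  # maxima and minima alternate along d
  merged <- rbind(data.frame(d = ex$maxima, kind = "max"),
                  data.frame(d = ex$minima, kind = "min"))
  merged <- merged[order(merged$d), ]
  expect_true(all(merged$kind[-1] != merged$kind[-nrow(merged)]))
  # monotone and constant profiles have no interior extrema
  mono <- data.frame(d = d, count = seq_along(d))
  expect_length(classify_extrema(mono, 1L)$maxima, 0L)
  flat <- data.frame(d = d, count = rep(2, length(d)))
  expect_length(classify_extrema(flat, 1L)$maxima, 0L)
  expect_length(classify_extrema(flat, 1L)$minima, 0L)
})

test_that("max/min comparison is zero for identical rates and antisymmetric", {
  set.seed(402)
  # 6 maxima and 6 minima sites, 30 tracts each, deterministic SNV layout
  mk_group <- function(kind, sites, base) {
    do.call(rbind, lapply(seq_along(sites), function(k) {
      tr <- do.call(rbind, lapply(1:30, function(i)
        one_tract(base + k * 1000L + i * 20L)))
      cbind(tr, extremum = kind, extremum_d = sites[k], site = k)
    }))
  }
  gmax <- mk_group("max", seq(-60, -10, by = 10), 0L)
  gmin <- mk_group("min", seq(10, 60, by = 10), 100000L)
  grouped <- rbind(gmax, gmin)
  # identical per-site SNV pattern: one SNV at position 2 of the first five
  # tracts of every site
  snv_rows <- grouped[ave(seq_len(nrow(grouped)),
                          grouped$extremum, grouped$site,
                          FUN = seq_along) <= 5, ]
  asn <- do.call(rbind, lapply(seq_len(nrow(snv_rows)), function(i) {
    a <- make_assignment("tract_SNV", n = 5L, position = 2L,
                         sub_from = "A", sub_to = "T",
                         tract_start = snv_rows$start[i])
    a$chrom <- snv_rows$chrom[i]
    a$tract_end <- snv_rows$end[i]
    a
  }))
  cmp <- max_min_comparison(asn, grouped)
  expect_equal(cmp$pct_increase[cmp$position == 2], 0)
  expect_equal(cmp$t[cmp$position == 2], 0)
  expect_equal(cmp$p_value[cmp$position == 2], 1)

  # label swap flips the sign of the increase but not the p-value
  asn2 <- asn
  extra <- asn[asn$tract_start %in% gmin$start, ][1:10, ]
  asn2 <- rbind(asn2, extra)   # minima now carry more SNVs
  cmp2 <- max_min_comparison(asn2, grouped)
  swapped <- grouped
  swapped$extremum <- ifelse(grouped$extremum == "max", "min", "max")
  cmp3 <- max_min_comparison(asn2, swapped)
  expect_equal(cmp3$pct_max, cmp2$pct_min)
  expect_equal(cmp3$p_value, cmp2$p_value, tolerance = 1e-12)
  i2 <- cmp2$pct_increase[cmp2$position == 2]
  i3 <- cmp3$pct_increase[cmp3$position == 2]
  expect_true(i2 > 0 && i3 < 0)
})

test_that("orientation ratio reflects strand composition and inverts on flip", {
  set.seed(403)
  n_tr <- 400L
  # spacing > 2 x 73 bp: each tract pairs only with its own midpoint
  starts <- seq(200L, by = 200L, length.out = n_tr)
  strands <- rep(c("+", "-"), length.out = n_tr)
  tr <- do.call(rbind, lapply(seq_len(n_tr), function(i)
    one_tract(starts[i], class = "G", strand = strands[i])))
  offs <- sample(-20:20, n_tr, replace = TRUE)
  mid <- data.frame(chrom = "c1", pos = starts + 2L + offs)
  # equal strand counts at every covered distance -> ratio 1 where defined
  prof <- orientation_ratio_profile(tr, mid)
  covered <- prof[prof$c_fwd > 0 & prof$g_fwd > 0, ]
  # flipping every strand inverts the ratio
  tr_flip <- tr
  tr_flip$purine_strand <- ifelse(tr$purine_strand == "+", "-", "+")
  prof_f <- orientation_ratio_profile(tr_flip, mid)
  cov_f <- prof_f[prof_f$c_fwd > 0 & prof_f$g_fwd > 0, ]
  expect_equal(cov_f$ratio, 1 / covered$ratio)
  # all G-forward: ratio 0 at covered distances
  tr_g <- tr
  tr_g$purine_strand <- "+"
  prof_g <- orientation_ratio_profile(tr_g, mid)
  expect_equal(prof_g$ratio[prof_g$g_fwd > 0],
               rep(0, sum(prof_g$g_fwd > 0)))
  # balanced strands at identical offsets: ratio exactly 1
  mid0 <- data.frame(chrom = "c1", pos = starts + 2L)
  prof0 <- orientation_ratio_profile(tr, mid0)
  expect_equal(prof0$ratio[prof0$d == 0], 1)
})

test_that("local-regression smoother reproduces polynomials and loess", {
  x <- seq(0, 10, length.out = 80)
  y3 <- 2 - x + 0.5 * x^2 - 0.03 * x^3
  # span 1, degree 3: exact interpolation of a cubic
  expect_equal(smooth_profile(x, y3, span = 1, degree = 3L), y3,
               tolerance = 1e-8)
  # constant series stays constant at any span
  yc <- rep(4, 80)
  expect_equal(smooth_profile(x, yc, span = 0.2, degree = 2L), yc)
  # agreement with stats::loess at degree 2 (the degrees loess supports)
  set.seed(404)
  y <- sin(x) + rnorm(80, 0, 0.1)
  mine <- smooth_profile(x, y, span = 0.4, degree = 2L)
  ref <- predict(stats::loess(y ~ x, span = 0.4, degree = 2L,
                              family = "gaussian", surface = "direct"))
  expect_equal(mine, unname(ref), tolerance = 0.02)
  # smoothing a noisy cosine reduces the residual variance
  yn <- cos(2 * pi * x / 3) + rnorm(80, 0, 0.3)
  sm <- smooth_profile(x, yn, span = 0.15, degree = 3L)
  expect_lt(var(yn - sm), var(rnorm(80, 0, 0.3)) + var(yn - cos(2 * pi * x / 3)))
})

test_that("period estimation recovers injected periods and rejects noise", {
  d <- 0:146
  y105 <- cos(2 * pi * d / 10.5)
  est <- estimate_period(y105, d, n_perm = 0L)
  expect_lt(abs(est$period - 10.5), 0.1)
  y12 <- cos(2 * pi * d / 12)
  expect_lt(abs(estimate_period(y12, d, n_perm = 0L)$period - 12), 0.1)
  # significance: strong cosine is significant, white noise mostly is not
  set.seed(405)
  sig <- estimate_period(y105 + rnorm(147, 0, 0.3), d, n_perm = 200L,
                         seed = 1L)
  expect_lt(sig$p_value, 0.05)
  nonsig <- vapply(1:10, function(k) {
    set.seed(500 + k)
    estimate_period(rnorm(147), d, n_perm = 200L, seed = k)$p_value
  }, numeric(1))
  expect_gte(sum(nonsig > 0.05), 8L)
})
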