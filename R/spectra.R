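# Normalized mutation statistics and spectra.
#
# Every statistic here is an exact count / denominator formula, with the
# denominator drawn from the tract census of the same (class, n[, flank])
# stratum.  Ratios with zero denominators are emitted as NA, never Inf.

census_lookup <- function(census, flank5 = NULL, flank3 = NULL) {
  m <- census_marginal(census, flank5 = flank5, flank3 = flank3)
  setNames(m$count, paste(m$tract_class, m$n))
}

count_by <- function(df, keys) {
  if (!nrow(df)) return(NULL)
  aggregate(list(count = rep(1L, nrow(df))), df[keys], sum)
}

#' Normalized fraction of polymorphic tracts (F SNV)
#'
#' F SNV for a (class, n) stratum is the number of tract SNVs divided by both
#' the number of tracts in the census and the tract length:
#' `F = count / (N * n)`.
#'
#' @param assignments assignment data.frame from [map_variants()]; only
#'   `tract_SNV` rows are used.
#' @param census tract census from [build_census()].
#' @return data.frame (`tract_class`, `n`, `count`, `denominator`, `f_snv`);
#'   strata with N = 0 are omitted.
#' @export
f_snv_table <- function(assignments, census) {
  a <- assignments[assignments$category == "tract_SNV", , drop = FALSE]
  N <- census_marginal(census)
  N <- N[N$count > 0, , drop = FALSE]
  cnt <- count_by(a, c("tract_class", "n"))
  out <- merge(N, cnt, by = c("tract_class", "n"), all.x = TRUE,
               suffixes = c("_census", ""))
  out$count[is.na(out$count)] <- 0L
  out$denominator <- out$count_census * out$n
  out$f_snv <- out$count / out$denominator
  out <- out[order(out$tract_class, out$n),
             c("tract_class", "n", "count", "denominator", "f_snv")]
  rownames(out) <- NULL
  out
}

#' Per-position SNV spectrum
#'
#' Percent of SNVs at each purine-strand position, by substitution type:
#' `percent = C(class, n, p, from->to) / N(class, n) * 100`, with p in
#' 0..n+1 (flank rows use flank_SNV counts).  Optional flank filters restrict
#' both the numerator assignments and the denominator census strata
#' consistently (e.g. `flank5 = "T", flank3 = "T"` gives the TA[n]T spectrum
#' divided by the number of TA[n]T tracts).
#'
#' @param assignments assignment data.frame ([map_variants()]).
#' @param census tract census.
#' @param flank5,flank3 optional single-base flank filters.
#' @param per_tract count tracts with at least one SNV at the cell instead of
#'   SNV events (default FALSE: events are counted).
#' @return data.frame (`tract_class`, `n`, `position`, `substitution`,
#'   `count`, `denominator`, `percent`); strata with N = 0 omitted.
#' @export
positional_spectrum <- function(assignments, census, flank5 = NULL,
                                flank3 = NULL, per_tract = FALSE) {
  a <- assignments[assignments$category %in% c("tract_SNV", "flank_SNV"), ,
                   drop = FALSE]
  if (!is.null(flank5)) a <- a[a$flank5 == flank5, , drop = FALSE]
  if (!is.null(flank3)) a <- a[a$flank3 == flank3, , drop = FALSE]
  if (per_tract && nrow(a)) {
    key <- paste(a$chrom, a$tract_start, a$tract_end, a$position,
                 a$sub_from, a$sub_to)
    a <- a[!duplicated(key), , drop = FALSE]
  }
  N <- census_marginal(census, flank5 = flank5, flank3 = flank3)
  N <- N[N$count > 0, , drop = FALSE]
  if (!nrow(N) || !nrow(a)) {
    return(data.frame(tract_class = character(0), n = integer(0),
                      position = integer(0), substitution = character(0),
                      count = integer(0), denominator = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  a$substitution <- paste0(a$sub_from, ">", a$sub_to)
  cnt <- count_by(a, c("tract_class", "n", "position", "substitution"))
  out <- merge(cnt, N, by = c("tract_class", "n"),
               suffixes = c("", "_census"))
  names(out)[names(out) == "count_census"] <- "denominator"
  out$percent <- out$count / out$denominator * 100
  out <- out[order(out$tract_class, out$n, out$position, out$substitution),
             c("tract_class", "n", "position", "substitution", "count",
               "denominator", "percent")]
  rownames(out) <- NULL
  out
}

#' Flank-direction bias of tract SNVs
#'
#' Fraction of tract SNVs whose alternate base (purine strand) equals the 5'
#' flank, the 3' flank, or either.  Tracts with an N flank are excluded.
#'
#' @param assignments assignment data.frame; `tract_SNV` rows are used.
#' @param by_position also stratify by position p (default FALSE).
#' @return data.frame (`tract_class`, `n`[, `position`], `n_snv`,
#'   `frac_to_flank5`, `frac_to_flank3`, `frac_to_either`).
#' @export
direction_bias <- function(assignments, by_position = FALSE) {
  a <- assignments[assignments$category == "tract_SNV" &
                     assignments$flank5 != "N" & assignments$flank3 != "N", ,
                   drop = FALSE]
  keys <- c("tract_class", "n", if (by_position) "position")
  if (!nrow(a)) {
    out <- data.frame(tract_class = character(0), n = integer(0))
    if (by_position) out$position <- integer(0)
    out$n_snv <- integer(0)
    out$frac_to_flank5 <- out$frac_to_flank3 <- out$frac_to_either <- numeric(0)
    return(out)
  }
  hit5 <- a$sub_to == a$flank5
  hit3 <- a$sub_to == a$flank3
  agg <- aggregate(list(n_snv = rep(1L, nrow(a)), to5 = hit5, to3 = hit3,
                        either = hit5 | hit3), a[keys], sum)
  agg$frac_to_flank5 <- agg$to5 / agg$n_snv
  agg$frac_to_flank3 <- agg$to3 / agg$n_snv
  agg$frac_to_either <- agg$either / agg$n_snv
  out <- agg[do.call(order, agg[keys]),
             c(keys, "n_snv", "frac_to_flank5", "frac_to_flank3",
               "frac_to_either")]
  rownames(out) <- NULL
  out
}

#' Slippage fractions and +1/-1 ratio
#'
#' `F slip = (slippage_plus + slippage_minus) / (N * n)` per (class, n), and
#' the ratio of +1 to -1 event counts (NA when there are no -1 events).
#'
#' @param assignments assignment data.frame.
#' @param census tract census.
#' @return data.frame (`tract_class`, `n`, `plus`, `minus`, `denominator`,
#'   `f_slip`, `ratio_plus_minus`); strata with N = 0 omitted.
#' @export
slippage_stats <- function(assignments, census) {
  a <- assignments[assignments$category %in%
                     c("slippage_plus", "slippage_minus"), , drop = FALSE]
  N <- census_marginal(census)
  N <- N[N$count > 0, , drop = FALSE]
  plus <- count_by(a[a$category == "slippage_plus", , drop = FALSE],
                   c("tract_class", "n"))
  minus <- count_by(a[a$category == "slippage_minus", , drop = FALSE],
                    c("tract_class", "n"))
  out <- N
  names(out)[names(out) == "count"] <- "n_tracts"
  out <- merge(out, if (is.null(plus)) data.frame(tract_class = character(0),
                                                  n = integer(0),
                                                  count = integer(0)) else plus,
               by = c("tract_class", "n"), all.x = TRUE)
  names(out)[names(out) == "count"] <- "plus"
  out <- merge(out, if (is.null(minus)) data.frame(tract_class = character(0),
                                                   n = integer(0),
                                                   count = integer(0)) else minus,
               by = c("tract_class", "n"), all.x = TRUE)
  names(out)[names(out) == "count"] <- "minus"
  out$plus[is.na(out$plus)] <- 0L
  out$minus[is.na(out$minus)] <- 0L
  out$denominator <- out$n_tracts * out$n
  out$f_slip <- (out$plus + out$minus) / out$denominator
  out$ratio_plus_minus <- ifelse(out$minus > 0, out$plus / out$minus,
                                 NA_real_)
  out <- out[order(out$tract_class, out$n),
             c("tract_class", "n", "plus", "minus", "denominator", "f_slip",
               "ratio_plus_minus")]
  rownames(out) <- NULL
  out
}

#' Indel fractions by location (F Indel)
#'
#' For events along the tract (`in_tract`), `F Indel = count / (N * n)`; for
#' events at the immediately flanking positions (`before_tract`,
#' `after_tract`), `F Indel = count / N`.  Only general indels
#' (`indel_ins` / `indel_del`) are counted; slippage is a disjoint category.
#'
#' @param assignments assignment data.frame.
#' @param census tract census.
#' @return data.frame (`tract_class`, `n`, `location`, `count`,
#'   `denominator`, `f_indel`); strata with N = 0 omitted.
#' @export
indel_fractions <- function(assignments, census) {
  a <- assignments[assignments$category %in% c("indel_ins", "indel_del"), ,
                   drop = FALSE]
  N <- census_marginal(census)
  N <- N[N$count > 0, , drop = FALSE]
  grid <- merge(N, data.frame(location = c("before_tract", "in_tract",
                                           "after_tract")))
  cnt <- count_by(a, c("tract_class", "n", "location"))
  out <- merge(grid, cnt, by = c("tract_class", "n", "location"), all.x = TRUE,
               suffixes = c("_census", ""))
  out$count[is.na(out$count)] <- 0L
  out$denominator <- ifelse(out$location == "in_tract",
                            out$count_census * out$n, out$count_census)
  out$f_indel <- out$count / out$denominator
  out$location <- factor(out$location,
                         levels = c("before_tract", "in_tract", "after_tract"))
  out <- out[order(out$tract_class, out$n, out$location),
             c("tract_class", "n", "location", "count", "denominator",
               "f_indel")]
  out$location <- as.character(out$location)
  rownames(out) <- NULL
  out
}

#' Insertion percent by junction position
#'
#' Percent of insertions at each junction j in 0..n+1 (insertion between
#' purine positions j and j+1): `count / N * 100`.  By default both slippage
#' insertions and general insertions are included; restrict with `include`.
#'
#' @param assignments assignment data.frame.
#' @param census tract census.
#' @param include categories to count (default `c("indel_ins",
#'   "slippage_plus")`).  Slippage insertions carry no observable junction
#'   (their placement in a run is degenerate); they are assigned j = 0, the
#'   leftmost equivalent placement.
#' @param wide return a list of per-(class, n) matrices instead of the tidy
#'   table.
#' @return tidy data.frame (`tract_class`, `n`, `junction`, `count`,
#'   `denominator`, `percent`) covering every j in 0..n+1, or a named list of
#'   vectors when `wide = TRUE`.
#' @export
insertion_position_matrix <- function(assignments, census,
                                      include = c("indel_ins",
                                                  "slippage_plus"),
                                      wide = FALSE) {
  a <- assignments[assignments$category %in% include, , drop = FALSE]
  a$position[is.na(a$position)] <- 0L
  N <- census_marginal(census)
  N <- N[N$count > 0, , drop = FALSE]
  grid <- do.call(rbind, lapply(seq_len(nrow(N)), function(i) {
    data.frame(tract_class = N$tract_class[i], n = N$n[i],
               junction = 0:(N$n[i] + 1L), denominator = N$count[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(grid)) grid <- data.frame(tract_class = character(0),
                                        n = integer(0), junction = integer(0),
                                        denominator = integer(0))
  names(a)[names(a) == "position"] <- "junction"
  cnt <- count_by(a, c("tract_class", "n", "junction"))
  out <- merge(grid, cnt, by = c("tract_class", "n", "junction"), all.x = TRUE)
  out$count[is.na(out$count)] <- 0L
  out$percent <- out$count / out$denominator * 100
  out <- out[order(out$tract_class, out$n, out$junction),
             c("tract_class", "n", "junction", "count", "denominator",
               "percent")]
  rownames(out) <- NULL
  if (!wide) return(out)
  sp <- split(out, paste0(out$tract_class, out$n))
  lapply(sp, function(d) setNames(d$percent, d$junction))
}

#' Equalize two spectrum tables at an anchor stratum
#'
#' Computes the factor that equalizes the total percent of the anchor
#' (class, anchor_n) stratum between dataset A and dataset B, and rescales
#' B's percents by it.  This is the rescaling used to compare call sets of
#' very different sizes (e.g. cancer vs. population) on one axis.
#'
#' @param tableA,tableB tidy tables with columns `tract_class`, `n` and
#'   `percent` (e.g. from [positional_spectrum()]).
#' @param tract_class class to anchor on ("A" or "G").
#' @param anchor_n anchor length (default 4).
#' @return list with `factor` and `rescaled` (tableB with percent multiplied
#'   by the factor).
#' @export
equalize_datasets <- function(tableA, tableB, tract_class, anchor_n = 4L) {
  ta <- sum(tableA$percent[tableA$tract_class == tract_class &
                             tableA$n == anchor_n])
  tb <- sum(tableB$percent[tableB$tract_class == tract_class &
                             tableB$n == anchor_n])
  if (tb == 0 || ta == 0)
    stop("anchor stratum (", tract_class, ", ", anchor_n,
         ") is empty in one of the tables")
  f <- ta / tb
  out <- tableB
  out$percent <- out$percent * f
  list(factor = f, rescaled = out)
}
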