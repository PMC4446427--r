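ref1 <- c(c1 = "ATTTTG")

test_that("normalization trims, splits and left-aligns against the reference", {
  # homopolymer deletion shifts to the leftmost placement
  v <- normalize_variants(data.frame(chrom = "c1", pos = 4L, ref = "TT",
                                     alt = "T"), ref1)
  expect_equal(v$pos, 1L)
  expect_equal(v$ref, "AT")
  expect_equal(v$alt, "A")
  expect_equal(v$vtype, "DEL")
  expect_equal(v$size, 1L)
  # non-variant dropped
  expect_equal(nrow(normalize_variants(
    data.frame(chrom = "c1", pos = 5L, ref = "T", alt = "T"), ref1)), 0L)
  # multi-allelic split
  v2 <- normalize_variants(data.frame(chrom = "c1", pos = 6L, ref = "G",
                                      alt = "A,T"), ref1)
  expect_equal(nrow(v2), 2L)
  expect_equal(sort(v2$alt), c("A", "T"))
  expect_true(all(v2$vtype == "SNV"))
  # failed reference check drops with a warning
  expect_warning(
    out <- normalize_variants(data.frame(chrom = "c1", pos = 2L, ref = "A",
                                         alt = "C"), ref1),
    "reference allele")
  expect_equal(nrow(out), 0L)
  # unknown contig errors, naming it
  expect_error(normalize_variants(data.frame(chrom = "c9", pos = 1L,
                                             ref = "A", alt = "C"), ref1),
               "c9")
  # padded representation trims to the parsimonious one
  v3 <- normalize_variants(data.frame(chrom = "c1", pos = 1L, ref = "ATT",
                                      alt = "ACT"), ref1)
  expect_equal(v3$pos, 2L)
  expect_equal(v3$ref, "T")
  expect_equal(v3$alt, "C")
})

test_that("normalization agrees with bcftools norm on messy records", {
  skip_if(Sys.which("bcftools") == "" || Sys.which("samtools") == "")
  set.seed(201)
  seq <- paste0("GC", random_dna(60), "CAAAAAAT", random_dna(60),
                "TGGGGGGA", random_dna(60), "GC")
  refv <- c(z = seq)
  # messy records: right-anchored homopolymer indels, padded SNVs
  raw <- data.frame(
    chrom = "z",
    pos = c(66L, 68L, 69L, 134L, 136L, 20L),
    ref = c(substr(seq, 66, 67), substr(seq, 68, 69), substr(seq, 69, 69),
            substr(seq, 134, 135), substr(seq, 136, 137), substr(seq, 20, 21)),
    alt = c(substr(seq, 66, 66), paste0(substr(seq, 68, 69), "A"),
            "C", substr(seq, 134, 134), paste0(substr(seq, 136, 137), "G"),
            paste0(substr(seq, 20, 20), "T")),
    stringsAsFactors = FALSE)
  raw <- raw[raw$ref != raw$alt, ]
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "r.fa"); vcfp <- file.path(dir, "v.vcf")
  write_fasta(refv, fa)
  system2("samtools", c("faidx", fa), stdout = NULL, stderr = NULL)
  write_vcf(raw[order(raw$pos), ], vcfp, contigs = setNames(nchar(seq), "z"))
  outp <- file.path(dir, "n.vcf")
  system2("bcftools", c("norm", "-f", fa, "-m-", "-Ov", "-o", outp, vcfp),
          stdout = NULL, stderr = NULL)
  bt <- read_vcf_file(outp)
  bt <- bt[order(bt$pos, bt$ref, bt$alt), c("chrom", "pos", "ref", "alt")]
  mine <- dedupe_variants(normalize_variants(raw, refv))
  expect_equal(mine[c("chrom", "pos", "ref", "alt")], bt,
               ignore_attr = TRUE)
})

test_that("dedupe keeps unique alleles in coordinate order", {
  v <- data.frame(chrom = "c1", pos = c(5L, 2L, 5L, 5L),
                  ref = c("T", "T", "T", "T"), alt = c("A", "G", "A", "C"),
                  vtype = "SNV", size = 0L, stringsAsFactors = FALSE)
  d <- dedupe_variants(v)
  expect_equal(nrow(d), 3L)
  expect_equal(d$pos, c(2L, 5L, 5L))
  expect_equal(d$alt, c("G", "A", "C"))
  # order of input does not matter
  d2 <- dedupe_variants(v[c(3, 1, 4, 2), ])
  expect_equal(d, d2)
})

test_that("assign_snv places SNVs in purine coordinates with complementation", {
  tr_plus <- data.frame(chrom = "c1", start = 10L, end = 14L, n = 4L,
                        tract_class = "A", purine_strand = "+", flank5 = "C",
                        flank3 = "T", stringsAsFactors = FALSE)
  v <- data.frame(chrom = "c1", pos = 11L, ref = "A", alt = "T",
                  vtype = "SNV", size = 0L, stringsAsFactors = FALSE)
  a <- assign_snv(tr_plus, v)
  expect_equal(a$category, "tract_SNV")
  expect_equal(a$position, 1L)
  expect_equal(paste0(a$sub_from, ">", a$sub_to), "A>T")

  # "-" tract: p = end - x and the substitution complements
  tr_minus <- data.frame(chrom = "c1", start = 20L, end = 25L, n = 5L,
                         tract_class = "G", purine_strand = "-", flank5 = "T",
                         flank3 = "A", stringsAsFactors = FALSE)
  vm <- data.frame(chrom = "c1", pos = 23L, ref = "C", alt = "A",
                   vtype = "SNV", size = 0L, stringsAsFactors = FALSE)
  am <- assign_snv(tr_minus, vm)
  expect_equal(am$category, "tract_SNV")
  expect_equal(am$position, 3L)
  expect_equal(paste0(am$sub_from, ">", am$sub_to), "G>T")

  # flank SNV toward the tract base flags extension
  vf <- data.frame(chrom = "c1", pos = 10L, ref = "C", alt = "A",
                   vtype = "SNV", size = 0L, stringsAsFactors = FALSE)
  af <- assign_snv(tr_plus, vf)
  expect_equal(af$category, "flank_SNV")
  expect_equal(af$position, 0L)
  expect_true(af$extends_tract)
  # outside the flanks: no assignment
  v0 <- data.frame(chrom = "c1", pos = 8L, ref = "C", alt = "A",
                   vtype = "SNV", size = 0L, stringsAsFactors = FALSE)
  expect_null(assign_snv(tr_plus, v0))
})

test_that("assign_indel separates slippage from general indels by rescan", {
  seq <- c(c1 = paste0("GGTC", "AAAAA", "TCGTACGT"))
  tr <- scan_sequence("c1", seq[[1]])
  expect_equal(tr$n, 5L)
  # deletion of one tract A (left-aligned) -> slippage_minus
  del <- normalize_variants(data.frame(chrom = "c1", pos = 4L, ref = "CA",
                                       alt = "C"), seq)
  a <- assign_indel(tr, del, seq)
  expect_equal(a$category, "slippage_minus")
  # insertion of an A -> slippage_plus
  ins <- normalize_variants(data.frame(chrom = "c1", pos = 4L, ref = "C",
                                       alt = "CA"), seq)
  expect_equal(assign_indel(tr, ins, seq)$category, "slippage_plus")
  # insertion of a G between p2 and p3 splits the run -> indel_ins, j = 2
  insg <- normalize_variants(data.frame(chrom = "c1", pos = 6L, ref = "A",
                                        alt = "AG"), seq)
  ag <- assign_indel(tr, insg, seq)
  expect_equal(ag$category, "indel_ins")
  expect_equal(ag$position, 2L)
  # two-base deletion within the run is an indel, in_tract
  del2 <- normalize_variants(data.frame(chrom = "c1", pos = 4L, ref = "CAA",
                                        alt = "C"), seq)
  a2 <- assign_indel(tr, del2, seq)
  expect_equal(a2$category, "indel_del")
  expect_equal(a2$location, "in_tract")
  # deleting the 5' flank changes flank composition -> indel, before_tract
  delf <- normalize_variants(data.frame(chrom = "c1", pos = 3L, ref = "TC",
                                        alt = "T"), seq)
  af <- assign_indel(tr, delf, seq)
  expect_equal(af$category, "indel_del")
  expect_equal(af$location, "before_tract")
  # an event far away does not assign
  far <- normalize_variants(data.frame(chrom = "c1", pos = 14L, ref = "AC",
                                       alt = "A"), seq)
  expect_null(assign_indel(tr, far, seq))
})

test_that("mapping a variant onto a '-' tract equals mapping its complement", {
  set.seed(202)
  for (i in 1:20) {
    core <- random_dna(30)
    s_fwd <- paste0("GC", core, "C", strrep("A", 6), "T", core, "CG")
    s_rev <- rc(s_fwd)
    tr_f <- scan_sequence("c", s_fwd)
    tr_r <- scan_sequence("c", s_rev)
    tr_f <- tr_f[tr_f$tract_class == "A" & tr_f$n == 6 &
                   tr_f$purine_strand == "+", ][1, ]
    tr_r <- tr_r[tr_r$tract_class == "A" & tr_r$n == 6 &
                   tr_r$purine_strand == "-", ][1, ]
    p <- sample.int(6, 1)
    to <- sample(setdiff(c("C", "G", "T"), NA), 1)
    # forward representation: SNV at purine position p
    x_f <- tr_f$start + p - 1L
    v_f <- data.frame(chrom = "c", pos = x_f + 1L, ref = "A", alt = to,
                      vtype = "SNV", size = 0L, stringsAsFactors = FALSE)
    # same biological event seen on the reverse-complemented sequence
    x_r <- tr_r$end - p
    v_r <- data.frame(chrom = "c", pos = x_r + 1L, ref = "T",
                      alt = COMP_TBL[to], vtype = "SNV", size = 0L,
                      stringsAsFactors = FALSE)
    a_f <- assign_snv(tr_f, v_f)
    a_r <- assign_snv(tr_r, v_r)
    expect_equal(a_r$position, a_f$position)
    expect_equal(a_r$sub_from, a_f$sub_from)
    expect_equal(a_r$sub_to, a_f$sub_to)
    expect_equal(a_r$category, a_f$category)
  }
})

test_that("map_variants joins streams, demands sorted input, partitions events", {
  set.seed(203)
  g <- simulate_genome(data.frame(tract_class = c("A", "G"), n = c(6L, 8L),
                                  count = 40L), seed = 204)
  sv <- simulate_variants(g, seed = 205)
  vn <- dedupe_variants(normalize_variants(sv$variants[1:4], g$sequences))
  asn <- map_variants(g$tracts, vn, g$sequences)
  # each (tract, variant) pair gets exactly one category
  expect_false(any(duplicated(
    asn[c("chrom", "tract_start", "pos", "ref", "alt")])))
  expect_true(all(asn$category %in%
                    c("tract_SNV", "flank_SNV", "slippage_plus",
                      "slippage_minus", "indel_ins", "indel_del")))
  # all of the generator's truth events are recovered
  expect_equal(nrow(asn), nrow(sv$truth))
  # unsorted input must error
  if (nrow(vn) > 1L)
    expect_error(map_variants(g$tracts, vn[rev(seq_len(nrow(vn))), ],
                              g$sequences), "sorted")
  expect_error(map_variants(g$tracts[rev(seq_len(nrow(g$tracts))), ], vn,
                            g$sequences), "sorted")
})

test_that("slippage assignments round-trip: applying the edit rescans to n±1", {
  g <- simulate_genome(data.frame(tract_class = rep(c("A", "G"), each = 5),
                                  n = rep(c(4L, 6L, 8L, 10L, 12L), 2),
                                  count = 60L), seed = 206)
  model <- default_mutation_model(slip_height = 0.08, slip_sigma = 50,
                                  snv_scale = 0, indel_high = 0,
                                  indel_low = 0)
  sv <- simulate_variants(g, model = model, seed = 207)
  vn <- dedupe_variants(normalize_variants(sv$variants[1:4], g$sequences))
  asn <- map_variants(g$tracts, vn, g$sequences)
  slip <- asn[asn$category %in% c("slippage_plus", "slippage_minus"), ]
  expect_gt(nrow(slip), 100L)
  s <- g$sequences[[1]]
  run_at <- function(chars, i) {   # maximal run through 1-based index i
    b <- chars[i]
    lo <- i; while (lo > 1L && chars[lo - 1L] == b) lo <- lo - 1L
    hi <- i; while (hi < length(chars) && chars[hi + 1L] == b) hi <- hi + 1L
    list(base = b, lo = lo, hi = hi)
  }
  ok_len <- ok_base <- ok_flanks <- logical(nrow(slip))
  for (k in seq_len(nrow(slip))) {
    r <- slip[k, ]
    edited <- paste0(substr(s, 1, r$pos - 1), r$alt,
                     substr(s, r$pos + nchar(r$ref), nchar(s)))
    ech <- strsplit(edited, "")[[1]]
    fb <- if (r$purine_strand == "+") r$tract_class else
      COMP_TBL[[r$tract_class]]
    run <- run_at(ech, r$tract_start + 1L)  # first run base: left-anchored
    want <- r$n + (if (r$category == "slippage_plus") 1L else -1L)
    ok_base[k] <- run$base == fb
    ok_len[k] <- (run$hi - run$lo + 1L) == want
    ok_flanks[k] <- ech[run$lo - 1L] == substr(s, r$tract_start,
                                               r$tract_start) &&
      ech[run$hi + 1L] == substr(s, r$tract_end + 1L, r$tract_end + 1L)
  }
  expect_true(all(ok_base))
  expect_true(all(ok_len))
  expect_true(all(ok_flanks))
})
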