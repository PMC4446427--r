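# End-to-end pipeline driver: scan -> census -> map -> spectra
# (-> nucleosome phasing, -> structure stats when inputs are given).

#' Run the full analysis pipeline from a configuration
#'
#' Validates the configuration, then executes the stages and writes tidy TSV
#' outputs plus a JSON run manifest into the output directory.  Rerunning
#' with an identical configuration reproduces identical outputs.  Every
#' output table carries the manifest hash as a leading `# run:` comment
#' line; nothing is written when validation fails.
#'
#' Configuration fields (a YAML file path or an R list):
#' \describe{
#'   \item{fasta}{reference FASTA path (required).}
#'   \item{vcf}{variant call set path; required unless `spectra: false`.}
#'   \item{mask_bed}{optional BED mask restricting the census (e.g. exons).}
#'   \item{midpoints_bed}{optional nucleosome midpoint BED/bedGraph; enables
#'     the phasing stage.}
#'   \item{step_params_tsv}{optional step-parameter TSV; enables V_step.}
#'   \item{outdir}{output directory (required).}
#'   \item{spectra}{logical toggle, default TRUE.}
#'   \item{seed}{RNG seed; required when any stochastic option is enabled
#'     (periodicity permutation test).}
#' }
#'
#' @param config list or path to a YAML file.
#' @return invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  cfg <- utils::modifyList(list(spectra = TRUE, mask_bed = NULL,
                                midpoints_bed = NULL, step_params_tsv = NULL,
                                vcf = NULL, seed = NULL), config)

  # ---- validation before any computation or output ----
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config validation failed: missing required field '", field, "'")
  }
  need("fasta"); need("outdir")
  if (isTRUE(cfg$spectra)) need("vcf")
  for (f in c("fasta", "vcf", "mask_bed", "midpoints_bed",
              "step_params_tsv")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config validation failed: '", f, "' does not exist: ", cfg[[f]])
  }
  if (!is.null(cfg$midpoints_bed) && is.null(cfg$seed))
    stop("config validation failed: 'seed' is required when the phasing ",
         "stage (periodicity permutation test) is enabled")

  # manifest and its hash (inputs by checksum, parameters verbatim)
  inputs <- Filter(Negate(is.null),
                   cfg[c("fasta", "vcf", "mask_bed", "midpoints_bed",
                         "step_params_tsv")])
  manifest <- list(
    package = "homotract",
    version = as.character(utils::packageVersion("homotract")),
    parameters = cfg[setdiff(names(cfg), "outdir")],
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1))))
  mjson <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(mjson, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest$manifest_md5 <- hash

  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  emit <- function(df, name) {
    p <- file.path(cfg$outdir, paste0(name, ".tsv"))
    write_stat_tsv(df, p, hash)
    out[[name]] <<- p
  }

  # ---- scan + census ----
  reference <- read_fasta(cfg$fasta)
  tracts <- scan_fasta(reference)
  tracts <- tracts[order(tracts$chrom, tracts$start), , drop = FALSE]
  mask <- if (!is.null(cfg$mask_bed)) read_intervals_bed(cfg$mask_bed)
  census <- build_census(tracts, mask = mask)
  bed_path <- file.path(cfg$outdir, "tracts.bed")
  write_tracts_bed(tracts, bed_path)
  out$tracts <- bed_path
  emit(census, "census")

  # ---- map + spectra ----
  if (isTRUE(cfg$spectra)) {
    raw <- read_vcf_file(cfg$vcf)
    variants <- dedupe_variants(normalize_variants(raw, reference))
    assignments <- map_variants(tracts, variants, reference)
    emit(assignments, "assignments")
    emit(f_snv_table(assignments, census), "f_snv")
    emit(positional_spectrum(assignments, census), "positional_spectrum")
    emit(direction_bias(assignments), "direction_bias")
    emit(slippage_stats(assignments, census), "slippage")
    emit(indel_fractions(assignments, census), "indel_fractions")
    emit(insertion_position_matrix(assignments, census), "insertion_matrix")
  }

  # ---- nucleosome phasing ----
  if (!is.null(cfg$midpoints_bed)) {
    midpoints <- read_midpoints_bed(cfg$midpoints_bed)
    prof <- dyad_profile(tracts, midpoints, unit = "center")
    prof$smoothed <- smooth_profile(prof$d, prof$count)
    pe <- estimate_period(prof$count, prof$d, seed = cfg$seed)
    prof$ratio <- ifelse(prof$g_fwd > 0, prof$c_fwd / prof$g_fwd, NA)
    attrd <- data.frame(key = c("period_bp", "period_p_value"),
                        value = c(pe$period, pe$p_value))
    emit(prof, "dyad_profile")
    emit(attrd, "periodicity")
  }

  # ---- structure stats ----
  if (!is.null(cfg$step_params_tsv)) {
    emit(v_step_by_step(read_step_params(cfg$step_params_tsv)), "v_step")
  }

  mpath <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$manifest <- mpath
  invisible(out)
}
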