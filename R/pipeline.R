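# One-command pipeline: annotate -> candidates -> P-sites -> QC -> call ->
# [variants], with a machine-readable run manifest. Identical configurations
# produce byte-identical outputs (the manifest carries no timestamps).

#' Build a pipeline run configuration
#'
#' Defaults follow the shipped analysis parameters: minimum uORF coding
#' length 18 nt, RPF length filter 27-32 nt, uORF score threshold 0.5,
#' periodicity alpha 0.05, minimum 10 P-sites per call. Values from a flat
#' `key = value` config file are applied over the defaults, and direct
#' arguments (flags) win over the file.
#'
#' @param gtf,genome_fasta annotation and genome paths.
#' @param alignments P-site TSV or BAM path.
#' @param space alignment coordinate space (`"transcript"` or `"genome"`).
#' @param collapsed_fasta optional collapsed FASTA (enables the file-size
#'   QC gate).
#' @param vcf optional VCF of variants to annotate.
#' @param offsets_tsv optional user offset table (skips calibration).
#' @param output_dir artifact directory.
#' @param start_codons,min_len_nt,length_filter,score_threshold,periodicity_alpha,min_reads
#'   analysis parameters (see the stage functions).
#' @param force proceed to uORF calling even when QC fails.
#' @param seed integer seed recorded in the manifest.
#' @param config_file optional flat key=value file.
#' @return a `run_config` list.
#' @export
run_config <- function(gtf = NULL, genome_fasta = NULL, alignments = NULL,
                       space = "transcript", collapsed_fasta = NULL,
                       vcf = NULL, offsets_tsv = NULL, output_dir = "uorfkit_out",
                       start_codons = START_CODONS, min_len_nt = 18L,
                       length_filter = 27:32, score_threshold = 0.5,
                       periodicity_alpha = 0.05, min_reads = 10L,
                       force = FALSE, seed = 1L, config_file = NULL) {
  cfg <- list(gtf = gtf, genome_fasta = genome_fasta, alignments = alignments,
              space = space, collapsed_fasta = collapsed_fasta, vcf = vcf,
              offsets_tsv = offsets_tsv, output_dir = output_dir,
              start_codons = start_codons, min_len_nt = min_len_nt,
              length_filter = length_filter,
              score_threshold = score_threshold,
              periodicity_alpha = periodicity_alpha, min_reads = min_reads,
              force = force, seed = seed)
  if (!is.null(config_file)) {
    filed <- read_config_file(config_file)
    supplied <- names(as.list(match.call()))[-1]
    supplied <- setdiff(supplied, "config_file")
    for (k in names(filed))
      if (!k %in% supplied) cfg[[k]] <- filed[[k]]
  }
  class(cfg) <- "run_config"
  cfg
}

# flat "key = value" config file; comma-separated lists become vectors
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (grepl(",", val, fixed = TRUE))
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (identical(val, "TRUE") || identical(val, "FALSE"))
      val <- as.logical(val)
    if (key == "length_filter" && length(val) == 2L)
      val <- seq.int(val[1L], val[2L])
    out[[key]] <- val
  }
  out
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full uORF analysis pipeline
#'
#' Stages (in order): annotation parsing, candidate enumeration, alignment
#' ingestion + P-site offsetting, quality control, active-uORF calling with
#' representative selection, and (when a VCF is supplied) variant-effect
#' annotation. A QC failure halts active calling unless `force = TRUE`.
#' Artifacts are written under `output_dir` together with a machine-readable
#' manifest (inputs with checksums, parameters, package version, seed).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the key in-memory results (`annotation`,
#'   `candidates`, `qc`, `calls`, `effects`, `manifest_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  stage_msg("annotate", "parsing ", config$gtf)
  ann <- tryCatch(parse_annotation(config$gtf, config$genome_fasta),
                  error = function(e)
                    stop("stage 'annotate' failed: ", conditionMessage(e)))
  stage_msg("annotate", length(ann$models), " transcript model(s)")

  stage_msg("candidates", "enumerating candidate uORFs")
  candidates <- enumerate_all_candidates(
    ann$models, ann$sequences, start_codons = config$start_codons,
    min_len_nt = config$min_len_nt)
  collapsed <- collapse_isoforms(candidates)
  write_candidates_tsv(candidates, out("candidates.tsv"))
  write_candidates_tsv(collapsed, out("candidates_collapsed.tsv"))
  stage_msg("candidates", nrow(candidates), " candidate(s), ",
            nrow(collapsed), " after isoform collapsing")

  calls <- NULL; qc <- NULL; effects <- NULL
  if (!is.null(config$alignments)) {
    stage_msg("psites", "loading alignments from ", config$alignments)
    hits <- tryCatch(
      load_alignments(config$alignments, space = config$space,
                      models = ann$models),
      error = function(e)
        stop("stage 'psites' failed: ", conditionMessage(e)))
    offsets <- if (!is.null(config$offsets_tsv)) {
      read_offset_table(config$offsets_tsv)
    } else {
      estimate_offsets(hits, ann$models, lengths = config$length_filter)
    }
    write_offset_table(offsets, out("offsets.tsv"))
    profiles <- build_psite_profiles(hits, offsets, ann$models,
                                     length_filter = config$length_filter)

    stage_msg("qc", "computing library QC")
    qc <- qc_report(hits, profiles, ann$models,
                    fasta_path = config$collapsed_fasta)
    write_qc_report(qc, out("qc.json"), hist_tsv = out("length_hist.tsv"),
                    metagene_tsv = out("metagene.tsv"))
    if (!qc$pass && !config$force)
      stop("QC gate failed (",
           paste(names(Filter(isFALSE, qc$gates)), collapse = ", "),
           "); use force = TRUE to call anyway")

    stage_msg("call", "scoring candidates for active translation")
    calls <- call_uorfs(candidates, profiles,
                        sample_id = basename(config$alignments),
                        min_reads = config$min_reads,
                        score_threshold = config$score_threshold,
                        alpha = config$periodicity_alpha)
    write_calls_tsv(calls, out("calls.tsv"))
    stage_msg("call", sum(calls$active), " active uORF call(s)")
  }

  if (!is.null(config$vcf)) {
    stage_msg("variants", "annotating 5'UTR variants from ", config$vcf)
    vars <- tryCatch(
      extract_utr5_variants(config$vcf, ann$models),
      error = function(e)
        stop("stage 'variants' failed: ", conditionMessage(e)))
    effects <- annotate_effects(vars, ann$models, ann$sequences, candidates,
                                start_codons = config$start_codons,
                                min_len_nt = config$min_len_nt)
    write_effects_tsv(effects, out("variant_effects.tsv"))
    summ <- summarize_effects(effects)
    jsonlite::write_json(
      list(class_counts = as.list(summ$class_counts),
           n_affecting = summ$n_affecting, n_total = summ$n_total),
      out("variant_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    stage_msg("variants", summ$n_affecting, " of ", summ$n_total,
              " (variant, transcript) records affect a uORF")
  }

  manifest <- list(
    tool = "uorfkit",
    version = as.character(utils::packageVersion("uorfkit")),
    seed = config$seed,
    inputs = lapply(
      Filter(Negate(is.null),
             list(gtf = config$gtf, genome_fasta = config$genome_fasta,
                  alignments = config$alignments, vcf = config$vcf,
                  collapsed_fasta = config$collapsed_fasta)),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = list(
      start_codons = config$start_codons,
      min_len_nt = config$min_len_nt,
      length_filter = range(config$length_filter),
      score_threshold = config$score_threshold,
      periodicity_alpha = config$periodicity_alpha,
      min_reads = config$min_reads,
      space = config$space,
      force = config$force))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_msg("done", "artifacts in ", config$output_dir)
  invisible(list(annotation = ann, candidates = candidates,
                 collapsed = collapsed, qc = qc, calls = calls,
                 effects = effects, manifest_path = out("manifest.json")))
}
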