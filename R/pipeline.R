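# End-to-end analysis pipeline: symmetry scan -> identity statistics ->
# Z-score significance -> topology profiling, with a machine-readable report.
#
# The pipeline is configuration-driven and fully deterministic: all seeds are
# explicit, the configuration (and its hash) is echoed into the report, and
# re-running an identical configuration byte-reproduces the JSON report.

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the stages present in `config` in the analysis order: internal
#' symmetry scan (with common-core statistics), cross-group identity with a
#' shuffled null and excess identity, Z-score-to-p-value conversion with
#' database-scale interpretation, and topology profiling. Writes a JSON
#' report plus TSV tables to `config$out_dir`. All inputs are validated
#' before any stage runs.
#'
#' @param config A list with `out_dir` and any of the stage blocks:
#' \describe{
#'   \item{symmetry}{`structure` (path) or `trace` (a `"trace"`), optional
#'     `chain`, `scan_from`/`scan_to` (split window), `core_cutoff` (default
#'     4), `threshold` (default 0.30), optional `frame = c(width, shift)`.}
#'   \item{identity}{`msa` (path or `"msa"`), `group_a`, `group_b`, `mode`
#'     (default `"from_msa"`), `shuffle_reps` (default 10), `seed` (default
#'     1), `per_length` (default 200).}
#'   \item{zscores}{`z` (vector), optional `db_size`, optional `combine_with`
#'     (additional p-values to combine with each z's p by Fisher's method).}
#'   \item{topo}{`fasta` (path) or `sequences` (named character), `window`
#'     (default 9), `threshold` (default 1.6), `min_len` (default 15),
#'     `bin_width` (default 25).}
#' }
#' @return The report list, invisibly; side effect: `report.json` and TSV
#'   tables under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  # validate all inputs before any stage runs
  for (p in c(config$symmetry$structure, config$identity$msa_path,
              config$topo$fasta)) {
    if (is.character(p) && !file.exists(p))
      stop("config error: input file not found: ", p)
  }
  if (!is.null(config$identity$msa) && is.character(config$identity$msa) &&
      !file.exists(config$identity$msa))
    stop("config error: input file not found: ", config$identity$msa)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    pipeline = "pseudosym",
    version = as.character(utils::packageVersion("pseudosym")),
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]))

  if (!is.null(config$symmetry)) {
    s <- config$symmetry
    tr <- if (!is.null(s$trace)) s$trace
          else get_trace(read_structure(s$structure), s$chain %||% NULL, "all")
    frame <- if (!is.null(s$frame))
      membrane_frame(s$frame[1], s$frame[2] %||% 0) else NULL
    rep_s <- scan_splits(tr, c(s$scan_from, s$scan_to),
                         core_cutoff = s$core_cutoff %||% 4,
                         threshold = s$threshold %||% 0.30,
                         frame = frame)
    write.table(rep_s$scan, file.path(config$out_dir, "symmetry_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_alignment_tsv(rep_s$alignment,
                        file.path(config$out_dir, "half_alignment.tsv"))
    report$symmetry <- list(
      verdict = rep_s$verdict, threshold = rep_s$threshold,
      split_index = rep_s$split_index,
      core_size = rep_s$core$core_size, core_rmsd = rep_s$core$core_rmsd,
      core_tm = rep_s$core$tm_core,
      rotation_angle_deg = if (!is.null(rep_s$axis)) rep_s$axis$angle_deg,
      c2_deviation_deg = if (!is.null(rep_s$axis)) rep_s$axis$c2_deviation_deg,
      axis_tilt_out_of_membrane_deg =
        if (!is.null(rep_s$axis)) rep_s$axis$membrane_parallel_tilt_deg)
  }

  if (!is.null(config$identity)) {
    idc <- config$identity
    m <- if (inherits(idc$msa, "msa")) idc$msa else read_msa(idc$msa)
    if (!is.null(idc$groups)) m$group <- idc$groups
    mode <- idc$mode %||% "from_msa"
    obs <- pairwise_identity(m, idc$group_a, idc$group_b, mode)
    null <- shuffled_identity_null(m, idc$group_a, idc$group_b,
                                   n_reps = idc$shuffle_reps %||% 10L,
                                   seed = idc$seed %||% 1L, mode = mode)
    per_len <- idc$per_length %||% 200L
    exc <- excess_identity(obs, null, per_len)
    write.table(as.data.frame(obs$matrix),
                file.path(config$out_dir, "identity_matrix.tsv"),
                sep = "\t", quote = FALSE)
    report$identity <- list(
      mode = mode, n_pairs = obs$n_pairs,
      observed_mean_pct = obs$mean_pct, observed_sd_pct = obs$sd_pct,
      null_mean_pct = null$mean_pct, null_sd_pct = null$sd_pct,
      shuffle_reps = null$n_reps, seed = null$seed,
      excess_identity_aa = as.integer(exc), per_length = per_len)
  }

  if (!is.null(config$zscores)) {
    zc <- config$zscores
    ps <- z_to_p(zc$z)
    entry <- list(z = zc$z, p = ps,
                  candidate_threshold = candidate_threshold(ps),
                  candidate_threshold_presented =
                    candidate_threshold(ps, present = TRUE))
    if (!is.null(zc$db_size))
      entry$expected_false_hits <- expected_false_hits(ps, zc$db_size)
    if (!is.null(zc$combine_with))
      entry$combined_p <- vapply(ps, function(p)
        combine_pvalues(c(p, zc$combine_with)), numeric(1))
    report$zscores <- entry
  }

  if (!is.null(config$topo)) {
    tc <- config$topo
    seqs <- if (!is.null(tc$sequences)) tc$sequences
            else {
              ss <- Biostrings::readAAStringSet(tc$fasta)
              stats::setNames(as.character(ss), names(ss))
            }
    w <- tc$window %||% 9L
    recs <- data.frame(id = names(seqs), length = nchar(seqs),
                       n_tmh = vapply(seqs, count_tmh, integer(1), window = w,
                                      threshold = tc$threshold %||% 1.6,
                                      min_len = tc$min_len %||% 15L))
    h <- length_tmh_histogram(recs, tc$bin_width %||% 25L)
    write.table(recs, file.path(config$out_dir, "tmh_records.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(h$counts, file.path(config$out_dir, "length_tmh_histogram.tsv"),
                sep = "\t", quote = FALSE)
    first <- hydropathy_profile(seqs[[1]], w)
    write_profile_tsv(first, file.path(config$out_dir, "hydropathy_first.tsv"))
    report$topo <- list(n_sequences = length(seqs), window = w,
                        total_records = h$n,
                        histogram_total = sum(h$counts))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
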