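#' Search run configuration
#'
#' Collects every tunable of [run_search()] with the pipeline defaults:
#' filter P target 0.02 (the conventional pass rate of the ungapped filter
#' stage), no threshold adjustment, hardware segment width 12,288, forward
#' strand only, Gumbel parameters from the model file's STATS line.
#'
#' @param p_value Filter P target in (0, 1).
#' @param adjust_bits Additive threshold adjustment in bits.
#' @param segment_width Segment width `n` for the segmented engine.
#' @param seed Integer seed driving ambiguity replacement, padding and
#'   (optionally) calibration.
#' @param strand `"forward"` or `"both"` (adds a reverse-complement pass;
#'   minus-strand hit positions are reported in forward coordinates of the
#'   crossing cell).
#' @param calibration `"stats"` (use the file's Gumbel line; error if
#'   absent) or `"simulate"` (always calibrate by simulation).
#' @param calib_n_seqs,calib_seq_len Simulation-calibration settings.
#' @param ambig_mode Ambiguity replacement mode, see [encode_2bit()].
#' @param report_rejected Keep boundary-rejected rows in the hit table.
#' @param verbose Log per-phase progress to standard error.
#' @return A `RunConfig` list.
#' @export
run_config <- function(p_value = 0.02, adjust_bits = 0,
                       segment_width = DEFAULT_SEGMENT_WIDTH, seed = 1L,
                       strand = c("forward", "both"),
                       calibration = c("stats", "simulate"),
                       calib_n_seqs = 1000L, calib_seq_len = 1000L,
                       ambig_mode = c("iupac", "uniform"),
                       report_rejected = FALSE, verbose = FALSE) {
  if (!is.finite(p_value) || p_value <= 0 || p_value >= 1)
    stop("p_value must be in (0, 1)")
  if (segment_width < 1L) stop("segment_width must be >= 1")
  structure(list(
    p_value = p_value, adjust_bits = adjust_bits,
    segment_width = as.integer(segment_width), seed = as.integer(seed),
    strand = match.arg(strand), calibration = match.arg(calibration),
    calib_n_seqs = as.integer(calib_n_seqs),
    calib_seq_len = as.integer(calib_seq_len),
    ambig_mode = match.arg(ambig_mode),
    report_rejected = isTRUE(report_rejected), verbose = isTRUE(verbose)
  ), class = "RunConfig")
}

.log_phase <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

# soft capacity warnings mirroring the reference accelerator's memory banks
.capacity_warnings <- function(total_residues, total_model_length, n_hits) {
  if (total_residues > 16e9)
    warning("aggregate target length exceeds 16 Gbp (reference hardware limit)")
  if (total_model_length > 1048576L)
    warning("total model positions exceed 1,048,576 (reference hardware limit)")
  if (n_hits > 469762048)
    warning("hit count exceeds 469,762,048 (reference hardware limit)")
}

# search one strand: encoded sequences -> validated hit frame
.search_strand <- function(encoded, mdb, projected, cfg, strand_label) {
  sdb <- build_sequence_db(encoded, n = cfg$segment_width, seed = cfg$seed)
  scores8_all <- do.call(rbind, lapply(projected, `[[`, "scores8"))
  global <- ssv_hits_segmented(sdb, scores8_all)
  cand <- resolve_hits(global, sdb, mdb)
  val <- validate_hits(cand, sdb, mdb, projected,
                       report_rejected = cfg$report_rejected)
  val$strand <- if (nrow(val)) strand_label else character(0)
  list(sdb = sdb, n_global = nrow(global), n_candidates = nrow(cand),
       hits = val)
}

#' Run the full SSV filter pipeline
#'
#' End-to-end all-to-all search of every FASTA target against every model in
#' a HMMER3 file, mirroring the four driver phases: (i) input parsing, (ii)
#' preprocessing (2-bit encoding, per-model threshold/tau projection at the
#' shared P target, concatenation and padding), (iii) the segmented 8-bit
#' kernel over the concatenated coordinate spaces, and (iv) hit resolution
#' and boundary validation. Fully deterministic under a fixed seed.
#'
#' @param fasta_path Nucleotide FASTA of target sequences.
#' @param hmm_path HMMER3 model file (one or more nucleotide models).
#' @param config A [run_config()].
#' @param out Optional path for the TSV hit table.
#' @param bed_out Optional path for a BED6 rendering.
#' @param summary_out Optional path for a JSON run summary.
#' @return Invisibly, `list(hits = <data frame>, summary = <list>)`.
#' @export
run_search <- function(fasta_path, hmm_path, config = run_config(),
                       out = NULL, bed_out = NULL, summary_out = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t_all <- proc.time()[["elapsed"]]
  phase <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    list(res = res, secs = proc.time()[["elapsed"]] - t0)
  }

  p1 <- phase({
    list(targets = read_fasta(fasta_path), models = read_hmm_file(hmm_path))
  })
  targets <- p1$res$targets; models <- p1$res$models
  .log_phase(config$verbose, "[setup] %d sequences, %d models (%.2fs)",
             length(targets), length(models), p1$secs)

  p2 <- phase({
    encoded <- lapply(seq_along(targets), function(i)
      encode_2bit(targets[[i]]$residues, seed = config$seed + i - 1L,
                  name = targets[[i]]$name, ambig_mode = config$ambig_mode))
    mdb <- build_model_db(models)
    projected <- lapply(seq_along(models), function(m) {
      hmm <- models[[m]]
      if (config$calibration == "simulate" ||
          (is.na(hmm$gumbel_mu) || is.na(hmm$gumbel_lambda))) {
        if (config$calibration == "stats" && is.na(hmm$gumbel_mu))
          stop("model '", hmm$name, "' has no STATS line; ",
               "use calibration = 'simulate'")
        gl <- calibrate_gumbel_by_simulation(
          hmm, n_seqs = config$calib_n_seqs, seq_len = config$calib_seq_len,
          seed = config$seed + m)
        hmm <- profile_hmm(hmm$name, hmm$match_scores, hmm$accession,
                           gumbel_mu = gl[["mu"]],
                           gumbel_lambda = gl[["lambda"]])
      }
      project_model(hmm, p_value = config$p_value,
                    adjust_bits = config$adjust_bits)
    })
    list(encoded = encoded, mdb = mdb, projected = projected)
  })
  encoded <- p2$res$encoded; mdb <- p2$res$mdb; projected <- p2$res$projected
  .log_phase(config$verbose, "[preprocess] %d model positions projected (%.2fs)",
             mdb$total_length, p2$secs)

  p3 <- phase({
    fwd <- .search_strand(encoded, mdb, projected, config, "+")
    rev <- NULL
    if (config$strand == "both") {
      enc_rc <- lapply(encoded, function(e) {
        e$codes <- revcomp_codes(e$codes)
        e
      })
      rev <- .search_strand(enc_rc, mdb, projected, config, "-")
      # map minus-strand crossing cells back to forward coordinates
      if (nrow(rev$hits)) {
        lens <- vapply(encoded, function(e) e$length, integer(1))
        rev$hits$seq_pos <- lens[rev$hits$seq_idx] - rev$hits$seq_pos + 1L
      }
    }
    list(fwd = fwd, rev = rev)
  })
  fwd <- p3$res$fwd; rev <- p3$res$rev
  hits <- rbind(fwd$hits, if (!is.null(rev)) rev$hits)
  hits <- hits[order(hits$seq_name, hits$seq_pos, hits$model_name,
                     hits$model_pos), , drop = FALSE]
  rownames(hits) <- NULL
  .log_phase(config$verbose, "[kernel+resolve] %d raw, %d candidate, %d kept (%.2fs)",
             fwd$n_global + if (is.null(rev)) 0L else rev$n_global,
             fwd$n_candidates + if (is.null(rev)) 0L else rev$n_candidates,
             nrow(hits), p3$secs)

  total_residues <- fwd$sdb$padding_start
  .capacity_warnings(total_residues, mdb$total_length, nrow(hits))

  summary <- list(
    n_sequences = length(encoded),
    n_models = length(models),
    total_residues = total_residues,
    padded_length = fwd$sdb$padded_length,
    total_model_length = mdb$total_length,
    cell_count = as.numeric(fwd$sdb$padded_length) * mdb$total_length *
      (if (config$strand == "both") 2 else 1),
    p_value = config$p_value,
    seed = config$seed,
    segment_width = config$segment_width,
    strand = config$strand,
    models = lapply(projected, function(pm)
      list(name = pm$source$name, threshold_bits = pm$threshold_bits,
           tau = pm$tau, clamped_count = pm$clamped_count)),
    hits_raw = fwd$n_global + if (is.null(rev)) 0L else rev$n_global,
    hits_candidates = fwd$n_candidates +
      if (is.null(rev)) 0L else rev$n_candidates,
    hits_validated = sum(hits$status == "validated"),
    hits_rejected = sum(hits$status == "boundary_rejected"),
    phase_seconds = list(setup = p1$secs, preprocess = p2$secs,
                         kernel_resolve = p3$secs,
                         total = proc.time()[["elapsed"]] - t_all)
  )

  p4 <- phase({
    if (!is.null(out)) write_hits_tsv(hits, out)
    if (!is.null(bed_out)) write_hits_bed(hits, bed_out)
    if (!is.null(summary_out))
      jsonlite::write_json(summary, summary_out, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  })
  summary$phase_seconds$output <- p4$secs
  .log_phase(config$verbose, "[done] %d validated hits (%.2fs total)",
             summary$hits_validated, summary$phase_seconds$total)
  invisible(list(hits = hits, summary = summary))
}
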