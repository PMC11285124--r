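#' Generate a random profile HMM
#'
#' Per-position emission probabilities are drawn from a symmetric
#' Dirichlet(`concentration`) over A, C, G, T and stored as negative natural
#' logs. Small concentrations (e.g. 0.5) give sharp, informative positions;
#' very large concentrations approach the uniform background (all scores
#' near `ln 4`). No Gumbel statistics are attached unless requested, which
#' exercises the simulation-calibration path.
#'
#' @param K Model length (>= 1).
#' @param concentration Dirichlet concentration (> 0), default 0.5.
#' @param seed Integer seed.
#' @param name Model name.
#' @param with_stats If `TRUE`, attach Gumbel parameters calibrated by
#'   simulation (`calib_*` arguments are passed through).
#' @param calib_n_seqs,calib_seq_len,calib_seed Calibration settings used
#'   when `with_stats = TRUE`.
#' @return A [profile_hmm()].
#' @export
generate_model <- function(K, concentration = 0.5, seed = 1L,
                           name = sprintf("synthetic_K%d_seed%d", K, seed),
                           with_stats = FALSE, calib_n_seqs = 1000L,
                           calib_seq_len = 1000L, calib_seed = seed + 1L) {
  stopifnot(K >= 1L, concentration > 0)
  probs <- with_seed(seed, {
    g <- matrix(rgamma(K * 4L, shape = concentration), nrow = K)
    g / rowSums(g)
  })
  probs <- pmax(probs, 1e-300)  # guard against gamma underflow at tiny shape
  hmm <- profile_hmm(name = name, match_scores = -log(probs))
  if (with_stats) {
    gl <- calibrate_gumbel_by_simulation(hmm, n_seqs = calib_n_seqs,
                                         seq_len = calib_seq_len,
                                         seed = calib_seed)
    hmm <- profile_hmm(name = name, match_scores = hmm$match_scores,
                       gumbel_mu = gl[["mu"]], gumbel_lambda = gl[["lambda"]])
  }
  hmm
}

#' Generate i.i.d. uniform random target sequences
#'
#' @param count Number of sequences (>= 1).
#' @param length Residues per sequence (>= 1).
#' @param seed Integer seed.
#' @param prefix Name prefix; records are named `<prefix>1`, `<prefix>2`, ...
#' @return A list of `list(name =, residues =)` records, the same shape
#'   [read_fasta()] returns.
#' @export
generate_targets <- function(count, length, seed = 1L, prefix = "target") {
  stopifnot(count >= 1L, length >= 1L)
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      list(name = paste0(prefix, i),
           residues = paste(sample(c("A", "C", "G", "T"), length,
                                   replace = TRUE), collapse = ""))
    })
  })
}

#' Plant an ungapped homologous segment into a target
#'
#' Overwrites `length` residues of one target so that the diagonal starting
#' at (`seq_start`, `model_start`) scores highly against the model: at each
#' position the model's most probable letter is written with probability
#' `strength`, otherwise a uniform random letter. The returned truth record
#' stores both the expected and the realized full-precision bit score of the
#' planted diagonal, so quantization-envelope tests can reason about
#' rounding exactly.
#'
#' @param targets List of records as from [generate_targets()].
#' @param model A [profile_hmm()].
#' @param seq_index 1-based index of the target to modify.
#' @param seq_start,model_start 0-based start positions of the planted
#'   diagonal in the target and the model.
#' @param length Segment length; must fit inside both records.
#' @param strength Probability in (0, 1] of writing the model's argmax
#'   letter at each position.
#' @param seed Integer seed.
#' @return `list(targets = <modified list>, truth = <list>)`; the truth
#'   entry has fields `seq_index`, `seq_start`, `model_start`, `length`,
#'   `expected_score_bits` (expectation over the planting distribution) and
#'   `realized_score_bits` (exact bit score of the letters actually
#'   written), plus `seed`.
#' @export
plant_segment <- function(targets, model, seq_index, seq_start, model_start,
                          length, strength = 1.0, seed = 1L) {
  stopifnot(inherits(model, "ProfileHMM"),
            seq_index >= 1L, seq_index <= base::length(targets),
            strength > 0, strength <= 1)
  rec <- targets[[seq_index]]
  L <- nchar(rec$residues)
  if (seq_start < 0L || seq_start + length > L)
    stop("planted segment does not fit inside the target sequence")
  if (model_start < 0L || model_start + length > model$K)
    stop("planted segment does not fit inside the model")
  B <- bit_scores(model)
  letters4 <- c("A", "C", "G", "T")
  jj <- model_start + seq_len(length)          # 1-based model rows
  argmax <- max.col(-model$match_scores[jj, , drop = FALSE],
                    ties.method = "first")
  planted_codes <- with_seed(seed, {
    use_max <- runif(length) <= strength
    ifelse(use_max, argmax, sample(1:4, length, replace = TRUE))
  })
  expected <- sum(strength * B[cbind(jj, argmax)] +
                    (1 - strength) * rowMeans(B[jj, , drop = FALSE]))
  realized <- sum(B[cbind(jj, planted_codes)])
  chars <- strsplit(rec$residues, "")[[1]]
  chars[seq_start + seq_len(length)] <- letters4[planted_codes]
  targets[[seq_index]]$residues <- paste(chars, collapse = "")
  truth <- list(seq_index = seq_index, seq_start = seq_start,
                model_start = model_start, length = length,
                strength = strength,
                expected_score_bits = expected,
                realized_score_bits = realized,
                seed = seed)
  list(targets = targets, truth = truth)
}

#' Write planted-segment ground truth as TSV
#'
#' @param truths List of truth records from [plant_segment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truths, path) {
  if (!is.null(truths$seq_index)) truths <- list(truths)
  df <- do.call(rbind, lapply(truths, function(t)
    data.frame(seq_index = t$seq_index, seq_start = t$seq_start,
               model_start = t$model_start, length = t$length,
               strength = t$strength,
               expected_score_bits = t$expected_score_bits,
               realized_score_bits = t$realized_score_bits,
               seed = t$seed)))
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
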