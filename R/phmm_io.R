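#' Construct a nucleotide profile HMM
#'
#' A `ProfileHMM` holds the only model parameters the SSV filter consumes:
#' per-position match-state emission scores, stored as negative natural-log
#' likelihoods over the fixed alphabet A, C, G, T, plus the Gumbel
#' location/scale parameters used to turn a P-value into a bit-score
#' threshold.
#'
#' @param name Model name (single string).
#' @param match_scores Numeric `K x 4` matrix of negative-log-likelihood
#'   emission scores, columns in A, C, G, T order. All entries must be
#'   non-negative (a probability is at most 1); the value `999` is the
#'   "impossible emission" sentinel corresponding to HMMER's `*`.
#' @param accession Optional accession string (`NA` if absent).
#' @param gumbel_mu,gumbel_lambda Gumbel location and scale for the ungapped
#'   score distribution (`NA` when the model carries no statistics; see
#'   [calibrate_gumbel_by_simulation()]).
#' @param stats Optional named list of `c(mu, lambda)` pairs keyed by the
#'   HMMER STATS line type (`"MSV"`, `"VITERBI"`, `"FORWARD"`), preserved for
#'   file round-trips.
#' @return An object of class `ProfileHMM`.
#' @export
profile_hmm <- function(name, match_scores, accession = NA_character_,
                        gumbel_mu = NA_real_, gumbel_lambda = NA_real_,
                        stats = NULL) {
  match_scores <- as.matrix(match_scores)
  storage.mode(match_scores) <- "double"
  if (nrow(match_scores) < 1L || ncol(match_scores) != 4L)
    stop("match_scores must be a K x 4 matrix with K >= 1")
  if (any(!is.finite(match_scores)) || any(match_scores < 0))
    stop("match_scores entries must be finite and >= 0 (negative log of a probability)")
  if (!is.na(gumbel_lambda) && gumbel_lambda <= 0)
    stop("gumbel_lambda must be > 0")
  if (is.null(stats) && !is.na(gumbel_mu) && !is.na(gumbel_lambda))
    stats <- list(MSV = c(mu = gumbel_mu, lambda = gumbel_lambda))
  colnames(match_scores) <- c("A", "C", "G", "T")
  structure(
    list(
      name = as.character(name),
      accession = accession,
      K = nrow(match_scores),
      match_scores = match_scores,
      gumbel_mu = gumbel_mu,
      gumbel_lambda = gumbel_lambda,
      stats = stats,
      alphabet = c("A", "C", "G", "T")
    ),
    class = "ProfileHMM"
  )
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat(sprintf("ProfileHMM '%s' (K = %d)\n", x$name, x$K))
  if (!is.na(x$gumbel_mu))
    cat(sprintf("  Gumbel: mu = %.4f, lambda = %.5f\n",
                x$gumbel_mu, x$gumbel_lambda))
  else
    cat("  Gumbel: not set (calibrate by simulation)\n")
  invisible(x)
}

.parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

#' Read a HMMER3-format nucleotide profile HMM file
#'
#' Parses the HMMER3 ASCII profile dialect (`HMMER3/f` header, `NAME`,
#' `LENG`, `ALPH DNA`/`RNA`, optional `STATS LOCAL ...` lines, per-node match
#' emission rows, `//` record terminator). Only the fields the SSV filter
#' needs are retained: match-state emissions, model length, name/accession
#' and Gumbel statistics. Insert emissions and state transitions are read and
#' discarded (the single-segment model has neither inserts nor deletes). The
#' `*` impossible-emission sentinel maps to the finite negative-log value 999
#' so that its projected score saturates at the int8 minimum.
#'
#' @param path Path to a `.hmm` file (one or more model records).
#' @param stats_line Which `STATS LOCAL` line supplies the Gumbel parameters
#'   exposed as `gumbel_mu`/`gumbel_lambda`; the ungapped filter threshold is
#'   conventionally derived from the `MSV` line. All parsed STATS lines are
#'   kept in the `stats` field regardless.
#' @return A list of [profile_hmm()] objects, in file order.
#' @export
read_hmm_file <- function(path, stats_line = c("MSV", "VITERBI")) {
  stats_line <- match.arg(stats_line)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  i <- 1L
  n <- length(lines)
  skip_blank <- function(i) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    i
  }
  i <- skip_blank(i)
  if (i > n) .parse_error(path, 1L, "empty file")
  while (i <= n) {
    if (!startsWith(lines[i], "HMMER3"))
      .parse_error(path, i, "expected HMMER3 format header")
    i <- i + 1L
    name <- NULL; acc <- NA_character_; leng <- NULL; alph <- NULL
    stats <- list()
    # header block
    repeat {
      if (i > n) .parse_error(path, i, "truncated record: no HMM line")
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) == 0L) { i <- i + 1L; next }
      key <- tok[1]
      if (key == "HMM") break
      if (key == "NAME") name <- tok[2]
      else if (key == "ACC") acc <- tok[2]
      else if (key == "LENG") leng <- suppressWarnings(as.integer(tok[2]))
      else if (key == "ALPH") alph <- toupper(tok[2])
      else if (key == "STATS") {
        if (length(tok) < 5L) .parse_error(path, i, "malformed STATS line")
        stats[[tok[3]]] <- c(mu = as.numeric(tok[4]),
                             lambda = as.numeric(tok[5]))
      }
      i <- i + 1L
    }
    if (is.null(name)) .parse_error(path, i, "record has no NAME line")
    if (is.null(leng) || is.na(leng) || leng < 1L)
      .parse_error(path, i, "record has no valid LENG line")
    if (is.null(alph) || !alph %in% c("DNA", "RNA"))
      .parse_error(path, i,
                   sprintf("alphabet '%s' is not nucleotide (DNA/RNA)",
                           if (is.null(alph)) "?" else alph))
    i <- i + 1L  # past "HMM  A C G T"
    if (i > n) .parse_error(path, i, "truncated record after HMM line")
    i <- i + 1L  # past the transition-name header line
    # optional COMPO line, then node-0 insert emission + transition lines
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) > 0L && tok[1] == "COMPO") i <- i + 1L
    i <- i + 2L
    scores <- matrix(NA_real_, nrow = leng, ncol = 4L)
    for (k in seq_len(leng)) {
      if (i > n) .parse_error(path, i, "truncated record inside match states")
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < 5L || is.na(suppressWarnings(as.integer(tok[1]))) ||
          as.integer(tok[1]) != k)
        .parse_error(path, i, sprintf(
          "expected match state %d of %d (K mismatch with LENG?)", k, leng))
      v <- tok[2:5]
      num <- ifelse(v == "*", INF_NLL, suppressWarnings(as.numeric(v)))
      if (any(is.na(num)))
        .parse_error(path, i, "non-numeric match emission score")
      scores[k, ] <- num
      i <- i + 3L  # skip insert emission + transition lines
    }
    if (i > n || trimws(lines[i]) != "//")
      .parse_error(path, min(i, n), "record not terminated by //")
    i <- i + 1L
    gm <- if (!is.null(stats[[stats_line]])) stats[[stats_line]][["mu"]] else NA_real_
    gl <- if (!is.null(stats[[stats_line]])) stats[[stats_line]][["lambda"]] else NA_real_
    models[[length(models) + 1L]] <- profile_hmm(
      name = name, match_scores = scores, accession = acc,
      gumbel_mu = gm, gumbel_lambda = gl,
      stats = if (length(stats)) stats else NULL)
    i <- skip_blank(i)
  }
  models
}

.fmt_score <- function(x) {
  ifelse(x >= INF_NLL - 1, "      *", sprintf("%.5f", x))
}

#' Write profile HMMs in a minimal HMMER3 dialect
#'
#' Emits a text file readable by [read_hmm_file()] (and by HMMER itself for
#' the fields this package uses). Insert emissions are written as the uniform
#' background and transitions as a fixed ungapped-friendly stanza; only
#' match emissions, LENG, NAME/ACC and STATS round-trip with meaning.
#'
#' @param models Non-empty list of [profile_hmm()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_hmm_file <- function(models, path) {
  if (inherits(models, "ProfileHMM")) models <- list(models)
  if (length(models) == 0L) stop("models must be a non-empty list")
  bg <- sprintf("%.5f", log(4))
  ins_line <- paste0("        ", paste(rep(bg, 4), collapse = "  "))
  # ungapped-friendly transitions: m->m certain, inserts/deletes unreachable
  # but normalized (i->m and d->m probability 1) so HMMER accepts the file
  trans_mid <- "        0.00000        *        *  0.00000        *  0.00000        *"
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in models) {
    stopifnot(inherits(m, "ProfileHMM"))
    writeLines(sprintf("HMMER3/f [ssvfilter %s]",
                       as.character(utils::packageVersion("ssvfilter"))), con)
    writeLines(sprintf("NAME  %s", m$name), con)
    if (!is.na(m$accession)) writeLines(sprintf("ACC   %s", m$accession), con)
    writeLines(sprintf("LENG  %d", m$K), con)
    writeLines("ALPH  DNA", con)
    writeLines("MAP   yes", con)
    writeLines("CONS  yes", con)
    for (st in c("MSV", "VITERBI", "FORWARD")) {
      if (!is.null(m$stats[[st]]))
        writeLines(sprintf("STATS LOCAL %-8s %.5f  %.5f", st,
                           m$stats[[st]][["mu"]], m$stats[[st]][["lambda"]]),
                   con)
    }
    writeLines("HMM          A        C        G        T", con)
    writeLines("            m->m     m->i     m->d     i->m     i->i     d->m     d->d", con)
    writeLines(paste0("  COMPO ", paste(rep(bg, 4), collapse = "  ")), con)
    writeLines(ins_line, con)
    writeLines(trans_mid, con)
    letters4 <- c("A", "C", "G", "T")
    for (k in seq_len(m$K)) {
      cons <- letters4[which.min(m$match_scores[k, ])]
      writeLines(sprintf("%7d  %s %6d %s - - -", k,
                         paste(.fmt_score(m$match_scores[k, ]), collapse = "  "),
                         k, tolower(cons)),
                 con)
      writeLines(ins_line, con)
      writeLines(trans_mid, con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Assemble the concatenated model database
#'
#' All models searched in one invocation live in a single global model
#' coordinate space: model `m` occupies positions `offsets[m] ..
#' offsets[m] + K_m - 1` (0-based). Hits come back in these global
#' coordinates and are resolved with [resolve_hits()].
#'
#' @param models Non-empty list of [profile_hmm()] objects.
#' @return An object of class `ModelDB` with fields `models`, `offsets`
#'   (0-based global start of each model) and `total_length`.
#' @export
build_model_db <- function(models) {
  if (inherits(models, "ProfileHMM")) models <- list(models)
  if (length(models) == 0L) stop("at least one model is required")
  ok <- vapply(models, inherits, logical(1), what = "ProfileHMM")
  if (!all(ok)) stop("all elements must be ProfileHMM objects")
  K <- vapply(models, function(m) m$K, integer(1))
  offsets <- cumsum(c(0L, K[-length(K)]))
  structure(
    list(models = models, offsets = as.integer(offsets),
         total_length = as.integer(sum(K)),
         names = vapply(models, function(m) m$name, character(1))),
    class = "ModelDB"
  )
}

#' @export
print.ModelDB <- function(x, ...) {
  cat(sprintf("ModelDB: %d model(s), %d total match positions\n",
              length(x$models), x$total_length))
  invisible(x)
}
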