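# IUPAC nucleotide expansions used for seeded ambiguity replacement;
# U is folded to T before lookup.
IUPAC_EXPANSION <- list(
  A = 0L, C = 1L, G = 2L, T = 3L,
  R = c(0L, 2L), Y = c(1L, 3L), S = c(1L, 2L), W = c(0L, 3L),
  K = c(2L, 3L), M = c(0L, 1L),
  B = c(1L, 2L, 3L), D = c(0L, 2L, 3L), H = c(0L, 1L, 3L), V = c(0L, 1L, 2L),
  N = c(0L, 1L, 2L, 3L)
)

#' Read nucleotide FASTA records
#'
#' Records are returned in file order; the name is the description line up to
#' the first whitespace. Residues may be upper or lower case and may use any
#' IUPAC nucleotide code (including U); anything else is an error naming the
#' offending record.
#'
#' @param path FASTA file path.
#' @return A list with one element per record: `list(name =, residues =)`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  names_short <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(set))
  for (r in seq_along(set)) {
    residues <- toupper(as.character(set[[r]]))
    if (!nzchar(residues))
      stop("FASTA record '", names_short[r], "' has no residues")
    bad <- regmatches(residues, regexpr("[^ACGTURYSWKMBDHVN]", residues))
    if (length(bad) && nzchar(bad))
      stop("record '", names_short[r],
           "' contains non-IUPAC nucleotide character '", bad, "'")
    out[[r]] <- list(name = names_short[r], residues = residues)
  }
  out
}

#' Write FASTA records
#'
#' Counterpart of [read_fasta()] used by the synthetic fixture generator.
#'
#' @param records List of `list(name =, residues =)` entries.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (length(records) == 0L) stop("no records to write")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$name), con)
    s <- rec$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' 2-bit encode a nucleotide sequence with seeded ambiguity replacement
#'
#' Maps A, C, G, T (and U) to the codes 0..3. Every IUPAC ambiguity letter is
#' replaced by a concrete code drawn with the seeded generator, by default
#' uniformly from the letter's IUPAC expansion (e.g. R from \{A, G\});
#' `ambig_mode = "uniform"` instead draws from all four letters, matching the
#' looser "replace by random letters" convention. Identical
#' `(residues, seed)` always yields identical output.
#'
#' @param residues Non-empty IUPAC nucleotide string.
#' @param seed Integer seed for the replacement draws.
#' @param name Optional record name carried along.
#' @param ambig_mode `"iupac"` (default) or `"uniform"`.
#' @return An `EncodedSequence`: `name`, `length`, `codes` (integer vector in
#'   0..3) and `ambiguity_positions` (0-based indices that were replaced).
#' @export
encode_2bit <- function(residues, seed, name = NA_character_,
                        ambig_mode = c("iupac", "uniform")) {
  ambig_mode <- match.arg(ambig_mode)
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  chars <- strsplit(toupper(residues), "")[[1]]
  chars[chars == "U"] <- "T"
  bad <- which(!chars %in% names(IUPAC_EXPANSION))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  base <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  codes <- unname(base[chars])
  ambig <- which(is.na(codes))
  if (length(ambig)) {
    codes[ambig] <- with_seed(seed, {
      vapply(chars[ambig], function(ch) {
        pool <- if (ambig_mode == "uniform") 0:3 else IUPAC_EXPANSION[[ch]]
        if (length(pool) == 1L) pool else sample(pool, 1L)
      }, integer(1), USE.NAMES = FALSE)
    })
  }
  structure(
    list(name = name, length = length(codes), codes = codes,
         ambiguity_positions = as.integer(ambig - 1L)),
    class = "EncodedSequence"
  )
}

#' Concatenate encoded sequences into the padded global target space
#'
#' All target sequences searched in one invocation are laid end to end in a
#' single global coordinate space, then padded with random residues so the
#' total length is a multiple of the segment width `n` (the systolic-array
#' convention; padding matches are discarded during hit resolution).
#'
#' @param seqs Non-empty list of [encode_2bit()] results.
#' @param n Segment width (>= 1).
#' @param seed Integer seed for the padding residues.
#' @return A `SequenceDB` with fields `sequences`, `offsets` (0-based global
#'   starts), `padding_start`, `padded_length`, `concatenated` (code vector)
#'   and `rng_seed`.
#' @export
build_sequence_db <- function(seqs, n, seed) {
  if (inherits(seqs, "EncodedSequence")) seqs <- list(seqs)
  if (length(seqs) == 0L) stop("at least one sequence is required")
  if (n < 1L) stop("segment width n must be >= 1")
  lens <- vapply(seqs, function(s) s$length, integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  total <- sum(lens)
  padded <- as.integer(ceiling(total / n) * n)
  pad <- if (padded > total)
    with_seed(seed, sample(0:3, padded - total, replace = TRUE))
  else integer(0)
  concatenated <- c(unlist(lapply(seqs, `[[`, "codes"), use.names = FALSE), pad)
  structure(
    list(sequences = seqs, offsets = as.integer(offsets),
         padding_start = as.integer(total), padded_length = padded,
         concatenated = as.integer(concatenated), n = as.integer(n),
         rng_seed = as.integer(seed),
         names = vapply(seqs, function(s) as.character(s$name), character(1))),
    class = "SequenceDB"
  )
}

#' @export
print.SequenceDB <- function(x, ...) {
  cat(sprintf(
    "SequenceDB: %d sequence(s), %d residues (+%d padding to %d, n = %d)\n",
    length(x$sequences), x$padding_start,
    x$padded_length - x$padding_start, x$padded_length, x$n))
  invisible(x)
}

# reverse-complement on 2-bit codes: A<->T (0<->3), C<->G (1<->2)
revcomp_codes <- function(codes) {
  rev(3L - codes)
}
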