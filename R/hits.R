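#' Resolve global hit coordinates to per-record positions
#'
#' The search engine reports hits as global `(i, j)` cell coordinates over
#' the concatenated sequence and model spaces. Resolution maps each hit by
#' binary search over the offset tables to its (sequence record, local
#' position) and (model record, local position); hits falling in the random
#' padding tail (`seq_pos >= padding_start`) are padding artifacts and are
#' dropped immediately. Reported positions are 1-based inclusive and refer
#' to the threshold-crossing cell (the hit's end), following the usual
#' coordinate convention of homology search tools.
#'
#' @param hits Integer matrix with columns `seq_pos`, `model_pos` (0-based
#'   global), as returned by [ssv_hits_segmented()].
#' @param sdb A `SequenceDB` from [build_sequence_db()].
#' @param mdb A `ModelDB` from [build_model_db()].
#' @return A data frame of candidates sorted by
#'   `(seq_name, seq_pos, model_name, model_pos)` and deduplicated, with
#'   columns `seq_name`, `seq_pos`, `model_name`, `model_pos`, `status`
#'   (`"candidate"`), plus internal 1-based record indices `seq_idx`,
#'   `model_idx` used by [validate_hits()].
#' @export
resolve_hits <- function(hits, sdb, mdb) {
  stopifnot(inherits(sdb, "SequenceDB"), inherits(mdb, "ModelDB"))
  hits <- as.matrix(hits)
  empty <- data.frame(seq_name = character(0), seq_pos = integer(0),
                      model_name = character(0), model_pos = integer(0),
                      status = character(0), seq_idx = integer(0),
                      model_idx = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  i <- as.integer(hits[, 1]); j <- as.integer(hits[, 2])
  if (any(i < 0L | i >= sdb$padded_length))
    stop("hit sequence coordinate outside the padded space")
  if (any(j < 0L | j >= mdb$total_length))
    stop("hit model coordinate outside the concatenated model space")
  keep <- i < sdb$padding_start
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)
  seq_idx <- findInterval(i, sdb$offsets)       # 1-based record index
  model_idx <- findInterval(j, mdb$offsets)
  out <- data.frame(
    seq_name = sdb$names[seq_idx],
    seq_pos = i - sdb$offsets[seq_idx] + 1L,
    model_name = mdb$names[model_idx],
    model_pos = j - mdb$offsets[model_idx] + 1L,
    status = "candidate",
    seq_idx = seq_idx,
    model_idx = model_idx,
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out[order(out$seq_name, out$seq_pos, out$model_name, out$model_pos), ,
      drop = FALSE]
}

#' Validate candidate hits against concatenation artifacts
#'
#' Concatenated all-to-all search can produce false hits whose accumulation
#' started in a neighboring sequence or model, and carry-over across a
#' boundary can also shift a genuine crossing a few cells early. The
#' validity check reruns the 8-bit recurrence restricted to the candidate's
#' own (sequence, model) pair along the single diagonal through the hit
#' cell, starting at the records' local starts — sufficient, since the
#' recurrence along one diagonal is self-contained. Every cell at which the
#' restricted diagonal crosses 256 is reported as a validated hit (so a
#' crossing shifted by boundary carry is remapped to its true in-pair
#' coordinates); a candidate whose restricted diagonal never crosses is a
#' boundary artifact and is rejected.
#'
#' @param candidates Data frame from [resolve_hits()].
#' @param sdb,mdb The databases the candidates refer to.
#' @param projected List of `ProjectedModel` objects in `mdb` model order
#'   (or a single one for a one-model database).
#' @param report_rejected If `TRUE`, rejected candidate rows are returned
#'   too, with `status = "boundary_rejected"`; otherwise only validated
#'   rows.
#' @return A hit frame with the same columns as `candidates`; validated
#'   rows carry the in-pair crossing coordinates, sorted and deduplicated.
#' @export
validate_hits <- function(candidates, sdb, mdb, projected,
                          report_rejected = FALSE) {
  stopifnot(inherits(sdb, "SequenceDB"), inherits(mdb, "ModelDB"))
  if (inherits(projected, "ProjectedModel")) projected <- list(projected)
  if (length(projected) != length(mdb$models))
    stop("need one ProjectedModel per model in the ModelDB")
  if (nrow(candidates) == 0L) return(candidates)
  kept <- vector("list", nrow(candidates))
  rejected <- logical(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    codes <- sdb$sequences[[candidates$seq_idx[r]]]$codes
    scores8 <- projected[[candidates$model_idx[r]]]$scores8
    cells <- ssv_diag_hits_cpp(codes, scores8,
                               candidates$seq_pos[r] - 1L,
                               candidates$model_pos[r] - 1L)
    if (nrow(cells) == 0L) {
      rejected[r] <- TRUE
    } else {
      row <- candidates[r, , drop = FALSE]
      kept[[r]] <- data.frame(
        seq_name = row$seq_name, seq_pos = cells[, 1] + 1L,
        model_name = row$model_name, model_pos = cells[, 2] + 1L,
        status = "validated", seq_idx = row$seq_idx,
        model_idx = row$model_idx, stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, kept[!vapply(kept, is.null, logical(1))]))
  if (is.null(out)) out <- candidates[0, , drop = FALSE]
  if (report_rejected && any(rejected)) {
    rej <- candidates[rejected, , drop = FALSE]
    rej$status <- "boundary_rejected"
    out <- rbind(out, rej)
  }
  out <- out[order(out$seq_name, out$seq_pos, out$model_name,
                   out$model_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hit table as TSV
#'
#' Columns: `seq_name`, `seq_pos`, `model_name`, `model_pos`, `status`.
#' @param hits Data frame from [validate_hits()] (or [resolve_hits()]).
#' @param path Output path (or `""` for standard output).
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("seq_name", "seq_pos", "model_name", "model_pos", "status")
  write.table(hits[, cols, drop = FALSE], file = path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write hits as BED6 intervals
#'
#' One 0-based half-open single-base interval per hit at the
#' threshold-crossing cell; `name` is the model name, `score` 0, strand `+`.
#' @param hits Data frame from [validate_hits()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$seq_name,
                    start = hits$seq_pos - 1L,
                    end = hits$seq_pos,
                    name = hits$model_name,
                    score = 0L,
                    strand = if ("strand" %in% names(hits)) hits$strand else "+",
                    stringsAsFactors = FALSE)
  write.table(bed, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
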