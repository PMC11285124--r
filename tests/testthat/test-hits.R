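make_layout <- function(seq_lens, model_ks, n = 16L, seed = 2L) {
  seqs <- lapply(seq_along(seq_lens), function(i)
    encode_2bit(paste(sample(c("A", "C", "G", "T"), seq_lens[i],
                             replace = TRUE), collapse = ""),
                seed = i, name = paste0("s", i)))
  models <- lapply(seq_along(model_ks), function(m)
    generate_model(K = model_ks[m], seed = 50L + m,
                   name = paste0("m", m)))
  list(sdb = build_sequence_db(seqs, n = n, seed = seed),
       mdb = build_model_db(models))
}

test_that("resolve_hits maps the origin and drops padding artifacts", {
  set.seed(1)
  lay <- make_layout(5L, 3L, n = 4L)       # padded 5 -> 8
  origin <- resolve_hits(matrix(c(0L, 0L), nrow = 1), lay$sdb, lay$mdb)
  expect_equal(origin$seq_pos, 1L)
  expect_equal(origin$model_pos, 1L)
  expect_equal(origin$seq_name, "s1")
  # global i in the padding region is a padding artifact
  pad_hit <- resolve_hits(matrix(c(6L, 0L), nrow = 1), lay$sdb, lay$mdb)
  expect_equal(nrow(pad_hit), 0L)
  expect_error(resolve_hits(matrix(c(8L, 0L), nrow = 1), lay$sdb, lay$mdb),
               "outside the padded space")
  expect_error(resolve_hits(matrix(c(0L, 3L), nrow = 1), lay$sdb, lay$mdb),
               "model coordinate")
})

test_that("resolution agrees with an independent linear-scan lookup", {
  set.seed(33)
  lay <- make_layout(sample(20:60, 10, replace = TRUE),
                     sample(5:25, 5, replace = TRUE), n = 32L)
  sdb <- lay$sdb; mdb <- lay$mdb
  hits <- cbind(sample(0:(sdb$padding_start - 1L), 100, replace = TRUE),
                sample(0:(mdb$total_length - 1L), 100, replace = TRUE))
  got <- resolve_hits(hits, sdb, mdb)
  # linear scan over records instead of binary search
  scan <- function(pos, offsets, lens) {
    for (r in seq_along(offsets))
      if (pos >= offsets[r] && pos < offsets[r] + lens[r]) return(r)
    stop("unmapped")
  }
  seq_lens <- vapply(sdb$sequences, `[[`, integer(1), "length")
  model_ks <- vapply(mdb$models, function(m) m$K, integer(1))
  want <- data.frame(
    seq_name = character(0), seq_pos = integer(0),
    model_name = character(0), model_pos = integer(0))
  for (r in seq_len(nrow(hits))) {
    si <- scan(hits[r, 1], sdb$offsets, seq_lens)
    mi <- scan(hits[r, 2], mdb$offsets, model_ks)
    want <- rbind(want, data.frame(
      seq_name = sdb$names[si], seq_pos = hits[r, 1] - sdb$offsets[si] + 1L,
      model_name = mdb$names[mi], model_pos = hits[r, 2] - mdb$offsets[mi] + 1L))
  }
  want <- unique(want)
  want <- want[order(want$seq_name, want$seq_pos, want$model_name,
                     want$model_pos), ]
  rownames(want) <- NULL
  got_cmp <- got[, c("seq_name", "seq_pos", "model_name", "model_pos")]
  rownames(got_cmp) <- NULL
  expect_equal(got_cmp, want)
})

test_that("a hit contained in one pair survives validation", {
  hmm <- generate_model(K = 20, concentration = 0.2, seed = 71, name = "m1")
  B <- ssvfilter:::bit_scores(hmm)
  argmax <- max.col(B, ties.method = "first")
  bits <- sum(B[cbind(1:20, argmax)])
  pm <- reproject_scores(hmm, 280 / bits)
  letters4 <- c("A", "C", "G", "T")
  seq1 <- paste(letters4[argmax], collapse = "")
  enc <- encode_2bit(seq1, seed = 1, name = "s1")
  sdb <- build_sequence_db(list(enc), n = 4L, seed = 3L)
  mdb <- build_model_db(list(hmm))
  cand <- resolve_hits(ssv_hits_segmented(sdb, pm$scores8), sdb, mdb)
  expect_gt(nrow(cand), 0L)
  kept <- validate_hits(cand, sdb, mdb, list(pm))
  expect_equal(nrow(kept), nrow(cand))
  expect_true(all(kept$status == "validated"))
})

test_that("boundary-straddling runs with sub-threshold halves are rejected", {
  fx <- straddle_fixture(first_half = rep(7L, 20), second_half = rep(7L, 20))
  cand <- resolve_hits(ssv_hits_segmented(fx$sdb, fx$scores8), fx$sdb, fx$mdb)
  expect_gt(nrow(cand), 0L)             # concatenation does produce hits
  out <- validate_hits(cand, fx$sdb, fx$mdb, fx$projected,
                       report_rejected = TRUE)
  expect_true(all(out$status == "boundary_rejected"))
  expect_equal(nrow(validate_hits(cand, fx$sdb, fx$mdb, fx$projected)), 0L)
})

test_that("a straddling run whose second half alone crosses is retained", {
  # first half feeds 60 into the junction; the +127 spike crosses at the
  # same cell with or without that carry, so the in-pair hit survives
  fx <- straddle_fixture(first_half = rep(3L, 20),
                         second_half = c(rep(20L, 8), 127L))
  cand <- resolve_hits(ssv_hits_segmented(fx$sdb, fx$scores8), fx$sdb, fx$mdb)
  kept <- validate_hits(cand, fx$sdb, fx$mdb, fx$projected)
  expect_true(any(kept$seq_name == "s2" & kept$seq_pos == 9L &
                    kept$model_pos == 29L))
})

test_that("no true in-pair hit is lost to concatenation (property)", {
  # Hit-sparse fixtures in the regime the filter is built for: strong
  # planted segments in random background at realistic thresholds. (With
  # dense hits the boundary carry-in can legitimately shift crossing cells;
  # the validity check is designed for rare-hit filtering.)
  n_checked <- 0L
  for (trial in 1:10) {
    set.seed(900 + trial)
    tg <- generate_targets(5, 120, seed = 910 + trial)
    models <- lapply(1:2, function(m)
      generate_model(sample(15:30, 1), concentration = 0.3,
                     seed = trial * 100L + m, name = paste0("m", m)))
    projected <- vector("list", 2)
    for (m in 1:2) {
      K <- models[[m]]$K
      len <- K - 5L
      ps <- plant_segment(tg, models[[m]], seq_index = sample(1:5, 1),
                          seq_start = sample(10:(120 - len - 10), 1),
                          model_start = 2, length = len, strength = 1,
                          seed = trial * 1000L + m)
      tg <- ps$targets
      projected[[m]] <- reproject_scores(
        models[[m]], (300 + 10 * m) / ps$truth$realized_score_bits)
    }
    seqs <- lapply(tg, function(r)
      encode_2bit(r$residues, seed = 1, name = r$name))
    sdb <- build_sequence_db(seqs, n = 16L, seed = trial)
    mdb <- build_model_db(models)
    validated <- validate_hits(
      resolve_hits(ssv_hits_segmented(
        sdb, do.call(rbind, lapply(projected, `[[`, "scores8"))), sdb, mdb),
      sdb, mdb, projected)
    val_key <- paste(validated$seq_name, validated$seq_pos,
                     validated$model_name, validated$model_pos)
    for (si in seq_along(seqs)) {
      for (mi in seq_along(models)) {
        iso <- ssv_hits_rowmajor(seqs[[si]]$codes, projected[[mi]]$scores8)
        if (nrow(iso) == 0L) next
        n_checked <- n_checked + nrow(iso)
        iso_key <- paste(seqs[[si]]$name, iso[, 1] + 1L,
                         models[[mi]]$name, iso[, 2] + 1L)
        expect_true(all(iso_key %in% val_key))
      }
    }
  }
  expect_gt(n_checked, 10L)   # the property was exercised on real hits
})
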