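# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's DP engines: brute-force enumeration
# and bit-level adder emulation, kept simple enough to audit by eye.

# Maximum over ALL ungapped diagonal segments of the plain segment sum.
# Equivalent to the floor-at-zero recurrence: the recurrence value at (i, j)
# is the best suffix-sum of the diagonal ending there, so the global maximum
# is the best segment sum over every (start, length).
brute_ssv_max <- function(codes, scores) {
  L <- length(codes)
  K <- nrow(scores)
  best <- -Inf
  for (i in seq_len(L)) {
    for (j in seq_len(K)) {
      s <- 0
      d <- 0
      while (i - d >= 1 && j - d >= 1) {
        s <- s + scores[j - d, codes[i - d] + 1L]
        if (s > best) best <- s
        d <- d + 1
      }
    }
  }
  best
}

# 8-bit full-adder emulation of one cell update: the addend is taken as its
# unsigned byte (two's complement), summed with the accumulator, and the
# carry bit out of the 8-bit adder is combined with the addend's sign bit:
# negative addend + no carry -> underflow reset; non-negative addend +
# carry -> hit and reset; otherwise keep the low 8 bits.
adder_cell_update <- function(m, p) {
  pu <- p %% 256L                 # unsigned byte of the signed addend
  sum9 <- m + pu
  carry <- sum9 >= 256L
  low8 <- sum9 %% 256L
  hit <- (p >= 0L) & carry
  reset <- ((p < 0L) & !carry) | hit
  list(score = ifelse(reset, 0L, low8), hit = hit)
}

# random engine instance: codes plus an int8 score matrix
rand_instance <- function(seed, Lmax = 60L, Kmax = 60L,
                          score_lo = -60L, score_hi = 60L) {
  set.seed(seed)
  L <- sample(1:Lmax, 1)
  K <- sample(1:Kmax, 1)
  list(
    codes = sample(0:3, L, replace = TRUE),
    scores8 = matrix(sample(score_lo:score_hi, K * 4L, replace = TRUE),
                     nrow = K)
  )
}

# canonical sorted representation of a hit matrix for set comparison
hit_key <- function(h) {
  if (nrow(h) == 0L) return(character(0))
  sort(paste(h[, 1], h[, 2], sep = ":"))
}

# Deterministic boundary-straddling fixture: a high-scoring ungapped run
# split across the junction of two concatenated sequences. Symbol A carries
# the planted per-cell scores given in `first_half` / `second_half` (model
# rows), every other symbol scores `mismatch`. seq1 ends with length(first..)
# A's, seq2 starts with length(second..) A's, so the concatenated diagonal
# accumulates across the boundary.
straddle_fixture <- function(first_half, second_half, mismatch = -50L,
                             flank1 = 40L, flank2 = 40L) {
  K <- length(first_half) + length(second_half)
  scores8 <- matrix(mismatch, nrow = K, ncol = 4L)
  scores8[, 1] <- c(first_half, second_half)
  seq1 <- paste0(strrep("C", flank1), strrep("A", length(first_half)))
  seq2 <- paste0(strrep("A", length(second_half)), strrep("C", flank2))
  enc <- list(encode_2bit(seq1, seed = 1, name = "s1"),
              encode_2bit(seq2, seed = 1, name = "s2"))
  total <- nchar(seq1) + nchar(seq2)
  n <- if (total %% 8L == 0L) 8L else 1L
  sdb <- build_sequence_db(enc, n = n, seed = 9L)
  fake_model <- profile_hmm("straddle", matrix(log(4), nrow = K, ncol = 4L))
  mdb <- build_model_db(list(fake_model))
  pm <- reproject_scores(fake_model, tau = 1)
  pm$scores8 <- scores8            # planted int8 scores drive the engine
  list(sdb = sdb, mdb = mdb, projected = list(pm), scores8 = scores8)
}
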