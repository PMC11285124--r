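test_that("a minimal single-model file parses to a uniform background model", {
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c(
    "HMMER3/f [handwritten]",
    "NAME  uniform1",
    "LENG  1",
    "ALPH  DNA",
    "STATS LOCAL MSV      -5.0000  0.70000",
    "HMM          A        C        G        T",
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    "  COMPO   1.38629  1.38629  1.38629  1.38629",
    "          1.38629  1.38629  1.38629  1.38629",
    "          0.00000        *        *        *        *        *        *",
    "      1   1.38629  1.38629  1.38629  1.38629",
    "          1.38629  1.38629  1.38629  1.38629",
    "          0.00000        *        *        *        *        *        *",
    "//"), f)
  m <- read_hmm_file(f)
  expect_length(m, 1)
  expect_equal(m[[1]]$K, 1L)
  expect_equal(unname(m[[1]]$match_scores[1, ]), rep(log(4), 4),
               tolerance = 1e-4)
  expect_equal(m[[1]]$gumbel_mu, -5)
  expect_equal(m[[1]]$gumbel_lambda, 0.7)
})

test_that("an hmmbuild-produced DNA model file parses faithfully", {
  f <- system.file("extdata", "hmmbuild_dna_example.hmm",
                   package = "ssvfilter")
  m <- read_hmm_file(f)
  expect_length(m, 1)
  expect_equal(m[[1]]$name, "aln")
  expect_equal(m[[1]]$K, 48L)
  # STATS LOCAL MSV       -7.4523  0.72517
  expect_equal(m[[1]]$gumbel_mu, -7.4523)
  expect_equal(m[[1]]$gumbel_lambda, 0.72517)
  # first match row as printed in the file
  expect_equal(unname(m[[1]]$match_scores[1, ]),
               c(3.40455, 4.21669, 0.06803, 4.02890))
  # emissions are negative logs of probabilities: rows are distributions
  expect_true(all(abs(rowSums(exp(-m[[1]]$match_scores)) - 1) < 1e-3))
  # the VITERBI stats line is retained alongside
  expect_equal(unname(m[[1]]$stats$VITERBI[["mu"]]), -8.0847)
})

test_that("malformed files fail with errors naming the line", {
  bad_header <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c("HMMER2.0", "NAME x"), bad_header)
  expect_error(read_hmm_file(bad_header), "HMMER3")

  amino <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c("HMMER3/f", "NAME  x", "LENG  1", "ALPH  amino",
               "HMM ..."), amino)
  expect_error(read_hmm_file(amino), "not nucleotide")

  # LENG promises 2 nodes but only 1 is present
  trunc <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c(
    "HMMER3/f", "NAME  x", "LENG  2", "ALPH  DNA",
    "HMM          A        C        G        T",
    "            m->m",
    "  COMPO   1.4  1.4  1.4  1.4",
    "          1.4  1.4  1.4  1.4",
    "          0.0  *  *  *  *  *  *",
    "      1   1.4  1.4  1.4  1.4",
    "          1.4  1.4  1.4  1.4",
    "          0.0  *  *  *  *  *  *",
    "//"), trunc)
  expect_error(read_hmm_file(trunc), "match state 2|truncated")

  expect_error(read_hmm_file(withr::local_tempfile(fileext = ".hmm")),
               "no such file")
})

test_that("write -> read round-trips generated models, byte-stable on rewrite", {
  models <- lapply(c(11L, 12L, 13L), function(s)
    generate_model(K = sample(5:40, 1), concentration = 0.5, seed = s))
  # attach stats to one model to round-trip the STATS line too
  models[[2]] <- profile_hmm(models[[2]]$name, models[[2]]$match_scores,
                             accession = "SYN002",
                             gumbel_mu = 3.25, gumbel_lambda = 0.693)
  f1 <- withr::local_tempfile(fileext = ".hmm")
  f2 <- withr::local_tempfile(fileext = ".hmm")
  expect_error(write_hmm_file(list(), f1), "non-empty")
  write_hmm_file(models, f1)
  back <- read_hmm_file(f1)
  expect_length(back, 3)
  for (k in seq_along(models)) {
    expect_equal(back[[k]]$name, models[[k]]$name)
    expect_equal(back[[k]]$K, models[[k]]$K)
    expect_equal(back[[k]]$match_scores, models[[k]]$match_scores,
                 tolerance = 1e-4)
  }
  expect_equal(back[[2]]$accession, "SYN002")
  expect_equal(back[[2]]$gumbel_mu, 3.25)
  # second write is byte-identical to the first rewrite
  write_hmm_file(back, f2)
  f3 <- withr::local_tempfile(fileext = ".hmm")
  write_hmm_file(read_hmm_file(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("the impossible-emission sentinel survives a round trip", {
  m <- generate_model(K = 4, seed = 21L)
  m$match_scores[2, 3] <- 999
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm_file(list(m), f)
  expect_match(paste(readLines(f), collapse = "\n"), "\\*")
  back <- read_hmm_file(f)[[1]]
  expect_equal(unname(back$match_scores[2, 3]), 999)
})

test_that("a generated multi-model fixture re-reads to the generator's records", {
  ks <- c(7L, 19L, 12L)
  models <- lapply(seq_along(ks), function(i)
    generate_model(K = ks[i], concentration = 0.5, seed = 7L + i))
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm_file(models, f)
  back <- read_hmm_file(f)
  expect_equal(vapply(back, `[[`, integer(1), "K"), ks)
  for (i in seq_along(ks))
    expect_equal(back[[i]]$match_scores, models[[i]]$match_scores,
                 tolerance = 1e-4)
})

test_that("build_model_db computes running-sum offsets", {
  one <- generate_model(K = 5, seed = 1)
  db1 <- build_model_db(list(one))
  expect_equal(db1$offsets, 0L)
  expect_equal(db1$total_length, 5L)

  two <- build_model_db(list(generate_model(K = 3, seed = 2),
                             generate_model(K = 4, seed = 3)))
  expect_equal(two$offsets, c(0L, 3L))
  expect_equal(two$total_length, 7L)

  expect_error(build_model_db(list()), "at least one")

  # property: offsets are prefix sums of K for arbitrary model lists
  set.seed(42)
  ks <- sample(1:30, 50, replace = TRUE)
  models <- lapply(seq_along(ks), function(i)
    generate_model(K = ks[i], seed = 100L + i))
  db <- build_model_db(models)
  expect_equal(db$offsets, as.integer(cumsum(c(0L, ks[-50]))))
  expect_equal(db$total_length, as.integer(sum(ks)))
})
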