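test_that("BPE training reproduces the classic trace via the oracle", {
  corpus <- "aaabdaaabac"
  oracle <- oracle_bpe_merges(corpus, 3L)
  # frozen expectation computed with the brute-force oracle
  expect_identical(oracle, list(c("a", "a"), c("a", "b"), c("aa", "ab")))
  model <- train_bpe(corpus, target_vocab_size = 4L + 2L + 3L)
  expect_identical(model$merges, oracle)
})

test_that("BPE matches the brute-force oracle on random corpora", {
  for (s in 1:8) {
    set.seed(s)
    corpus <- vapply(seq_len(3L), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
            collapse = ""), "")
    n_merges <- 6L
    model <- train_bpe(corpus, target_vocab_size = 2L +
                         length(unique(unlist(strsplit(corpus, "")))) +
                         n_merges)
    expect_identical(model$merges,
                     oracle_bpe_merges(corpus, n_merges),
                     info = paste("seed", s))
  }
})

test_that("BPE training is deterministic and corpus-order invariant", {
  set.seed(33)
  corpus <- vapply(1:4, function(i) random_dna(80), "")
  m1 <- train_bpe(corpus, 30L)
  m2 <- train_bpe(corpus, 30L)
  m3 <- train_bpe(rev(corpus), 30L)
  expect_identical(m1$merges, m2$merges)
  expect_identical(m1$merges, m3$merges)
})

test_that("encode/decode round-trips; unknowns and truncation behave", {
  set.seed(34)
  corpus <- vapply(1:4, function(i) random_dna(120), "")
  model <- train_bpe(corpus, 20L)
  s <- corpus[1]
  enc <- encode_bpe(s, model, capacity = 200L)
  expect_s3_class(enc, "token_sentence")
  expect_length(enc, 200L)
  expect_identical(decode_bpe(enc, model), s)
  # padding is suffix-only
  n <- attr(enc, "n_tokens")
  expect_true(all(enc[seq_len(n)] != 0L))
  expect_true(all(enc[-seq_len(n)] == 0L))
  # empty string -> all-pad sentence
  expect_true(all(encode_bpe("", model, capacity = 10L) == 0L))
  # unknown characters map to id 1
  encu <- encode_bpe("XXAC", model, capacity = 10L)
  expect_equal(as.integer(encu)[1:2], c(1L, 1L))
  # truncation keeps the prefix
  long <- random_dna(3000, seed = 35)
  full <- plasmeld:::bpe_tokenize(long, model)
  trunc <- encode_bpe(long, model, capacity = 50L)
  expect_equal(attr(trunc, "n_tokens"), 50L)
  expect_identical(unname(model$vocab[full[1:50]]), as.integer(trunc)[1:50])
})

test_that("BPE vocabulary accounting matches the target", {
  set.seed(36)
  corpus <- vapply(1:3, function(i) random_dna(200), "")
  target <- 2L + 4L + 10L
  model <- train_bpe(corpus, target)
  expect_equal(model$vocab_size, target)
  expect_length(model$merges, 10L)
  # ids contiguous from 2
  expect_equal(sort(unname(model$vocab)), seq(2L, target - 1L))
})

test_that("BPE merge frequencies are non-increasing over the trace", {
  set.seed(37)
  corpus <- vapply(1:3, function(i) random_dna(150), "")
  model <- train_bpe(corpus, 25L)
  # recompute the frequency of each merge at its merge time via the oracle
  toks <- lapply(corpus, function(s) strsplit(s, "")[[1]])
  freqs <- numeric(0)
  for (pair in model$merges) {
    counts <- plasmeld:::bpe_pairs(toks)
    key <- paste(pair[1], pair[2], sep = "\x1f")
    freqs <- c(freqs, as.numeric(counts[key]))
    toks <- lapply(toks, plasmeld:::bpe_apply_merge, pair[1], pair[2])
  }
  expect_false(is.unsorted(rev(freqs)))
})

test_that("BPE JSON serialization round-trips", {
  set.seed(38)
  model <- train_bpe(vapply(1:2, function(i) random_dna(100), ""), 15L)
  path <- tempfile(fileext = ".json")
  write_bpe(model, path)
  back <- read_bpe(path)
  expect_identical(lapply(back$merges, as.character), model$merges)
  expect_equal(unlist(back$vocab[names(model$vocab)]),
               model$vocab, ignore_attr = TRUE)
  s <- random_dna(60, seed = 39)
  expect_identical(as.integer(encode_bpe(s, back, capacity = 80L)),
                   as.integer(encode_bpe(s, model, capacity = 80L)))
})

test_that("amino-acid tokenizer maps the 22-symbol alphabet", {
  enc <- encode_aa("ACD")
  expect_length(enc, 1000L)
  map <- aa_alphabet()
  expect_equal(as.integer(enc)[1:3],
               unname(map[c("A", "C", "D")]))
  expect_true(all(enc[4:1000] == 0L))
  # X -> undefined id; B (non-standard) -> other id
  expect_equal(as.integer(encode_aa("X"))[1], unname(map[["X"]]))
  expect_equal(as.integer(encode_aa("B"))[1], unname(map[["OTHER"]]))
  # long proteins keep the first 1000 residues
  long <- paste(rep("A", 1200), collapse = "")
  el <- encode_aa(long)
  expect_equal(attr(el, "n_tokens"), 1000L)
  expect_true(all(el == map[["A"]]))
})

test_that("PC sentences encode token ids in genomic order with suffix padding", {
  s <- encode_pc(c(5L, 7L, 1L))
  expect_length(s, 400L)
  expect_equal(as.integer(s)[1:4], c(5L, 7L, 1L, 0L))
  expect_false(attr(s, "untokenizable"))
  # no proteins -> all-mask sentence flagged untokenizable
  s0 <- encode_pc(plasmeld:::empty_protein_records(), vocab = NULL)
  expect_true(attr(s0, "untokenizable"))
  expect_true(all(s0 == 0L))
  # more proteins than capacity -> first 400 kept
  many <- encode_pc(rep(2L, 450L))
  expect_equal(attr(many, "n_tokens"), 400L)
  expect_true(all(many == 2L))
})

test_that("padding never precedes a token id (property over random sentences)", {
  set.seed(40)
  for (i in 1:25) {
    n <- sample(0:30, 1)
    s <- encode_pc(sample(1:9, n, TRUE), capacity = 30L)
    v <- as.integer(s)
    first_pad <- match(0L, v)
    if (!is.na(first_pad)) expect_true(all(v[first_pad:30] == 0L))
  }
})
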