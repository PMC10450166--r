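# Four token schemes, each producing fixed-length integer sentences:
#   nt-BPE  byte-pair encoding on nucleotides, capacity 350
#   AA      one token per amino acid (22-symbol alphabet), capacity 1000
#   aa-BPE  byte-pair encoding on amino acids, capacity 400
#   PC      one token per protein, id = protein cluster, capacity 400
# Ids 0 (pad/mask) and 1 (unknown) are reserved in every scheme.

SCHEME_CAPACITY <- c("nt-bpe" = 350L, "aa" = 1000L, "aa-bpe" = 400L,
                     "pc" = 400L)

#' Fixed-length token sentence
#'
#' @param ids Integer vector of token ids (pre-truncation).
#' @param scheme One of \code{"nt-bpe"}, \code{"aa"}, \code{"aa-bpe"},
#'   \code{"pc"}.
#' @param capacity Sentence capacity; defaults to the scheme's standard
#'   capacity (350/1000/400/400).
#' @return Integer vector of length \code{capacity}, zero-padded as a
#'   suffix, with attributes \code{scheme}, \code{capacity} and
#'   \code{n_tokens}; class \code{"token_sentence"}.
#' @export
token_sentence <- function(ids, scheme, capacity = SCHEME_CAPACITY[[scheme]]) {
  ids <- as.integer(ids)
  n <- min(length(ids), capacity)
  out <- integer(capacity)
  if (n > 0L) out[seq_len(n)] <- ids[seq_len(n)]
  structure(out, scheme = scheme, capacity = capacity, n_tokens = n,
            class = "token_sentence")
}

# ---------------------------------------------------------------------------
# Byte-pair encoding
# ---------------------------------------------------------------------------

bpe_pairs <- function(tokens_list) {
  # count all adjacent pairs across the corpus
  pairs <- unlist(lapply(tokens_list, function(t) {
    if (length(t) < 2L) return(character())
    paste(t[-length(t)], t[-1L], sep = "\x1f")
  }), use.names = FALSE)
  if (!length(pairs)) return(integer())
  table(pairs)
}

bpe_apply_merge <- function(tokens, left, right) {
  # left-to-right, non-overlapping replacement of (left, right) pairs
  repeat {
    idx <- which(tokens[-length(tokens)] == left & tokens[-1L] == right)
    if (!length(idx)) return(tokens)
    if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
    keep <- rep(TRUE, length(tokens))
    keep[idx + 1L] <- FALSE
    tokens[idx] <- paste0(left, right)
    tokens <- tokens[keep]
  }
}

#' Train a byte-pair-encoding model
#'
#' Greedy BPE: starting from single characters, repeatedly merge the most
#' frequent adjacent token pair into a new token until the vocabulary (two
#' reserved ids + alphabet + merges) reaches \code{target_vocab_size} or no
#' pair occurs at least twice. Ties on frequency are broken by the
#' lexicographically smallest pair (byte order), which makes training
#' deterministic and independent of corpus order.
#'
#' @param corpus Character vector of training strings.
#' @param target_vocab_size Total vocabulary size including the two reserved
#'   ids (pad 0, unknown 1). The published nucleotide model uses 5002.
#' @return A \code{bpe_model}: list with \code{alphabet}, \code{merges}
#'   (list of character pairs, in training order), \code{vocab} (named
#'   integer map token -> id) and \code{vocab_size}.
#' @export
train_bpe <- function(corpus, target_vocab_size) {
  stopifnot(length(corpus) > 0L, all(nchar(corpus) > 0L))
  alphabet <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))),
                   method = "radix")
  if (target_vocab_size < length(alphabet) + 2L) {
    stop("target_vocab_size must be at least |alphabet| + 2 reserved ids")
  }
  tokens_list <- strsplit(corpus, "", fixed = TRUE)
  merges <- list()
  while (length(alphabet) + 2L + length(merges) < target_vocab_size) {
    counts <- bpe_pairs(tokens_list)
    if (!length(counts) || max(counts) < 2L) break
    top <- names(counts)[counts == max(counts)]
    best <- sort(top, method = "radix")[1L]
    pair <- strsplit(best, "\x1f", fixed = TRUE)[[1L]]
    merges[[length(merges) + 1L]] <- pair
    tokens_list <- lapply(tokens_list, bpe_apply_merge, pair[1L], pair[2L])
  }
  toks <- c(alphabet, vapply(merges, function(p) paste0(p[1L], p[2L]), ""))
  vocab <- stats::setNames(seq_along(toks) + 1L, toks)  # ids from 2
  structure(list(alphabet = alphabet, merges = merges, vocab = vocab,
                 vocab_size = length(vocab) + 2L), class = "bpe_model")
}

#' @export
print.bpe_model <- function(x, ...) {
  cat("BPE model: |alphabet| =", length(x$alphabet), ", merges =",
      length(x$merges), ", vocab size =", x$vocab_size, "\n")
  invisible(x)
}

bpe_tokenize <- function(seq, model) {
  tokens <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (pair in model$merges) {
    tokens <- bpe_apply_merge(tokens, pair[1L], pair[2L])
  }
  tokens
}

#' Encode a sequence with a trained BPE model
#'
#' Applies the merges in training order, maps tokens to ids (characters
#' outside the training alphabet become the unknown id 1), truncates to
#' \code{capacity} keeping the 5'-most content, and pads with 0.
#'
#' @param seq A single string.
#' @param model A \code{bpe_model}.
#' @param scheme Sentence scheme label (\code{"nt-bpe"} or \code{"aa-bpe"}).
#' @param capacity Sentence capacity; defaults per scheme.
#' @return A \code{\link{token_sentence}}.
#' @export
encode_bpe <- function(seq, model, scheme = "nt-bpe",
                       capacity = SCHEME_CAPACITY[[scheme]]) {
  if (nchar(seq) == 0L) return(token_sentence(integer(), scheme, capacity))
  tokens <- bpe_tokenize(seq, model)
  ids <- unname(model$vocab[tokens])
  ids[is.na(ids)] <- 1L
  token_sentence(ids, scheme, capacity)
}

#' Decode a BPE sentence back to a string
#'
#' Inverse of \code{\link{encode_bpe}} whenever no truncation occurred and
#' no unknown ids are present (unknowns decode to \code{"?"}).
#'
#' @param sentence A \code{token_sentence}.
#' @param model The \code{bpe_model} used to encode.
#' @return A single string.
#' @export
decode_bpe <- function(sentence, model) {
  ids <- sentence[seq_len(attr(sentence, "n_tokens"))]
  rev_map <- stats::setNames(names(model$vocab), model$vocab)
  out <- rev_map[as.character(ids)]
  out[ids == 1L] <- "?"
  paste(out, collapse = "")
}

#' Serialize a BPE model to JSON
#' @param model A \code{bpe_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bpe <- function(model, path) {
  jsonlite::write_json(list(alphabet = model$alphabet,
                            merges = lapply(model$merges, identity),
                            vocab = as.list(model$vocab)),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Load a BPE model written by \code{\link{write_bpe}}
#' @param path JSON path.
#' @return A \code{bpe_model}.
#' @export
read_bpe <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  merges <- if (is.matrix(x$merges)) {
    lapply(seq_len(nrow(x$merges)), function(i) x$merges[i, ])
  } else as.list(x$merges)
  vocab <- unlist(x$vocab)
  structure(list(alphabet = x$alphabet, merges = merges,
                 vocab = vocab, vocab_size = length(vocab) + 2L),
            class = "bpe_model")
}

# ---------------------------------------------------------------------------
# Amino-acid tokenizer
# ---------------------------------------------------------------------------

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid token alphabet
#'
#' 22 symbols: the 20 standard amino acids (ids 2-21), \code{X} for an
#' undefined amino acid (id 22) and a catch-all "other" symbol for anything
#' else (id 23).
#' @return Named integer vector mapping symbol to id.
#' @export
aa_alphabet <- function() {
  stats::setNames(2:23, c(AA_STANDARD, "X", "OTHER"))
}

#' Encode a protein as an amino-acid sentence
#'
#' One token per residue over the 22-symbol alphabet, capacity 1000 (the
#' reference plasmid databases have 98.6\% of proteins under 1000 aa);
#' longer proteins keep their first 1000 residues.
#'
#' @param aa_seq A single amino-acid string.
#' @param capacity Sentence capacity.
#' @return A \code{\link{token_sentence}} with scheme \code{"aa"}.
#' @export
encode_aa <- function(aa_seq, capacity = SCHEME_CAPACITY[["aa"]]) {
  if (nchar(aa_seq) == 0L) return(token_sentence(integer(), "aa", capacity))
  chars <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1L]]
  map <- aa_alphabet()
  ids <- unname(map[chars])
  ids[is.na(ids) & chars == "X"] <- map[["X"]]
  ids[is.na(ids)] <- map[["OTHER"]]
  token_sentence(ids, "aa", capacity)
}

# ---------------------------------------------------------------------------
# Protein-cluster tokenizer
# ---------------------------------------------------------------------------

#' Encode a contig's proteins as a PC sentence
#'
#' Position i carries the PC token of the i-th protein in genomic order
#' (ascending start coordinate on the forward strand, regardless of gene
#' strand). Proteins beyond the capacity are dropped from the end; unused
#' positions carry the mask token 0.
#'
#' @param proteins Protein-record data.frame sorted by start (as returned by
#'   \code{\link{predict_genes}}), or a precomputed integer vector of PC
#'   token ids in genomic order.
#' @param vocab A \code{pc_vocab}; ignored when \code{proteins} is already an
#'   id vector.
#' @param engine Protein aligner engine for PC assignment.
#' @param thresholds PC-assignment thresholds.
#' @param capacity Sentence capacity.
#' @return A \code{\link{token_sentence}} with scheme \code{"pc"} and
#'   attribute \code{untokenizable = TRUE} when the contig has no proteins.
#' @export
encode_pc <- function(proteins, vocab = NULL,
                      engine = default_engines()$protein,
                      thresholds = pc_assign_thresholds(),
                      capacity = SCHEME_CAPACITY[["pc"]]) {
  if (is.data.frame(proteins)) {
    if (nrow(proteins) == 0L) {
      out <- token_sentence(integer(), "pc", capacity)
      attr(out, "untokenizable") <- TRUE
      return(out)
    }
    stopifnot(!is.unsorted(proteins$start))
    seqs <- stats::setNames(proteins$aa_seq,
                            paste0(proteins$contig_id, "_",
                                   proteins$index_on_contig))
    ids <- unname(assign_pc(seqs, vocab, engine, thresholds))
  } else {
    ids <- as.integer(proteins)
    if (!length(ids)) {
      out <- token_sentence(integer(), "pc", capacity)
      attr(out, "untokenizable") <- TRUE
      return(out)
    }
  }
  out <- token_sentence(ids, "pc", capacity)
  attr(out, "untokenizable") <- FALSE
  out
}

#' Export sentences as a TSV for inspection
#' @param sentences List of \code{token_sentence}s (or an integer matrix).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  m <- if (is.matrix(sentences)) sentences else
    do.call(rbind, lapply(sentences, as.integer))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
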