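# Shared fixture builders. Everything is generated in code at test time.

# Erdos-Renyi style random weighted graph as a protein_graph
random_graph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (stats::runif(1) < p) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
        w <- c(w, stats::runif(1, 0.5, 5))
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE)),
            class = "protein_graph")
}

# graph from an explicit edge list (unit weights by default)
graph_of <- function(nodes, pairs, weight = 1) {
  edges <- if (length(pairs)) {
    data.frame(from = vapply(pairs, `[`, "", 1L),
               to = vapply(pairs, `[`, "", 2L),
               weight = weight, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "protein_graph")
}

clique_pairs <- function(members) {
  out <- list()
  for (i in seq_len(length(members) - 1)) {
    for (j in seq((i + 1), length(members))) {
      out[[length(out) + 1L]] <- c(members[i], members[j])
    }
  }
  out
}

random_aa <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste0("M", paste(sample(aa, len - 1L, replace = TRUE), collapse = ""))
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(records, wrap = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (nm in names(records)) {
    s <- records[[nm]]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    lines <- c(lines, paste0(">", nm), body)
  }
  writeLines(lines, path)
  path
}

# small hit-table builder for pipeline unit tests
hit_row <- function(qseqid, sseqid, pident, length, evalue, bitscore,
                    qstart, qend, sstart = 1L, send = length,
                    qcovhsp = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, evalue = evalue, bitscore = bitscore,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             qcovhsp = qcovhsp, stringsAsFactors = FALSE)
}

tiny_transformer <- function(L = 6L, vocab = 10L, d_model = 8L, heads = 2L,
                             fc_hidden = 5L, seed = 3L, ...) {
  cfg <- transformer_config(sentence_len = L, vocab_size = vocab,
                            d_model = d_model, heads = heads,
                            fc_hidden = fc_hidden, dropout = 0,
                            seed = seed, ...)
  init_transformer(cfg)
}
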