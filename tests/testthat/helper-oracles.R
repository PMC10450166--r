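# Independent reference implementations (oracles). These deliberately share
# no code with the package: brute-force loops, global dense matrices, and a
# different cluster-extraction reading, so agreement is informative.

# Global dense-matrix MCL run to convergence; clusters read off via
# attractor rows (positive diagonal) and the nodes they attract, merging
# attractor rows that share nodes.
oracle_mcl <- function(nodes, edges, inflation = 2, max_iter = 100,
                       tol = 1e-6) {
  n <- length(nodes)
  M <- matrix(0, n, n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- which(nodes == edges$from[r]); j <- which(nodes == edges$to[r])
      M[i, j] <- edges$weight[r]; M[j, i] <- edges$weight[r]
    }
  }
  for (i in seq_len(n)) M[i, i] <- M[i, i] + 1
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    if (max(abs(E - M)) < tol) { M <- E; break }
    M <- E
  }
  eps <- min(1e-4, 0.5 / n)
  owner <- vector("list", n)          # attractor rows supporting column j
  for (j in seq_len(n)) owner[[j]] <- which(M[, j] >= eps)
  # merge columns sharing any attractor row
  cluster_id <- rep(NA_integer_, n); cid <- 0
  repeat {
    todo <- which(is.na(cluster_id))
    if (!length(todo)) break
    cid <- cid + 1
    members <- todo[1]
    repeat {
      rows <- unique(unlist(owner[members]))
      grown <- which(vapply(seq_len(n), function(j)
        any(owner[[j]] %in% rows), TRUE) & is.na(cluster_id))
      grown <- union(grown, members)
      if (length(grown) == length(members)) break
      members <- grown
    }
    cluster_id[members] <- cid
  }
  parts <- lapply(split(seq_len(n), cluster_id), function(ix) sort(nodes[ix]))
  names(parts) <- NULL
  parts
}

# canonical form of a partition for set comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, function(p) sort(as.character(p)))
  parts[order(vapply(parts, `[`, "", 1L))]
}

# Brute-force BPE merge trace: count every adjacent pair with explicit
# loops, pick the most frequent (lexicographically smallest pair on ties),
# rewrite token lists left to right, repeat n_merges times or until no pair
# occurs twice.
oracle_bpe_merges <- function(corpus, n_merges) {
  toks <- lapply(corpus, function(s) strsplit(s, "")[[1]])
  merges <- list()
  for (m in seq_len(n_merges)) {
    counts <- list()
    for (t in toks) {
      if (length(t) < 2) next
      for (i in seq_len(length(t) - 1)) {
        key <- paste0(t[i], "\x1f", t[i + 1])
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
    if (!length(counts)) break
    freq <- unlist(counts)
    if (max(freq) < 2) break
    cand <- sort(names(freq)[freq == max(freq)], method = "radix")[1]
    pair <- strsplit(cand, "\x1f")[[1]]
    merges[[m]] <- pair
    toks <- lapply(toks, function(t) {
      out <- character(0); i <- 1
      while (i <= length(t)) {
        if (i < length(t) && t[i] == pair[1] && t[i + 1] == pair[2]) {
          out <- c(out, paste0(pair[1], pair[2])); i <- i + 2
        } else {
          out <- c(out, t[i]); i <- i + 1
        }
      }
      out
    })
  }
  merges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Relative-error numerical gradient check over every parameter tensor of a
# transformer on a fixed mini-batch, via central differences.
max_grad_error <- function(model, sentences, y, w, n_probe = 12L,
                           eps = 1e-5) {
  analytic <- plasmeld:::transformer_batch_grads(model, sentences, y, w)
  worst <- 0
  for (nm in names(model$params)) {
    sz <- length(model$params[[nm]])
    idxs <- if (sz <= n_probe) seq_len(sz) else
      round(seq(1, sz, length.out = n_probe))
    for (idx in idxs) {
      up <- model; up$params[[nm]][idx] <- up$params[[nm]][idx] + eps
      dn <- model; dn$params[[nm]][idx] <- dn$params[[nm]][idx] - eps
      ng <- (plasmeld:::transformer_batch_grads(up, sentences, y, w)$loss -
             plasmeld:::transformer_batch_grads(dn, sentences, y, w)$loss) /
        (2 * eps)
      ag <- analytic$grads[[nm]][idx]
      denom <- max(abs(ng) + abs(ag), 1e-6)
      worst <- max(worst, abs(ng - ag) / denom)
    }
  }
  worst
}
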