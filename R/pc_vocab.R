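# Protein-cluster (PC) vocabulary: all-vs-all protein alignment -> similarity
# graph at e-value <= 1e-5 -> Markov clustering -> clusters of >= 2 members
# become tokens. Reserved token ids: 0 = mask/padding, 1 = unknown protein.

#' All-against-all protein alignment
#'
#' @param proteins Named character vector or \code{AAStringSet} (>= 2
#'   sequences).
#' @param engine Aligner engine (see \code{\link{sw_protein_engine}},
#'   \code{\link{blast_protein_engine}}).
#' @return Hit data.frame; self-hits are retained here and dropped during
#'   graph construction.
#' @export
all_vs_all_hits <- function(proteins, engine = default_engines()$protein) {
  proteins <- as_seq_set(proteins)
  if (length(proteins) < 2L) stop("need at least 2 proteins")
  engine(proteins, proteins)
}

#' Build the protein similarity graph
#'
#' Nodes are proteins; one undirected edge joins each unordered pair whose
#' best (minimum) pairwise e-value is at or below \code{edge_evalue_max}.
#' Edge weight is \code{-log10(evalue)}, capped at 200 so an e-value of zero
#' stays finite. Self-hits never become edges.
#'
#' @param hits Hit data.frame from \code{\link{all_vs_all_hits}}.
#' @param nodes Node ids; defaults to all ids appearing in \code{hits}.
#' @param edge_evalue_max Inclusion threshold (default \code{1e-5}).
#' @return A list with \code{nodes} (character) and \code{edges}
#'   (data.frame \code{from}, \code{to}, \code{weight}), class
#'   \code{"protein_graph"}.
#' @export
build_protein_graph <- function(hits, nodes = NULL, edge_evalue_max = 1e-5) {
  if (is.null(nodes)) nodes <- sort(unique(c(hits$qseqid, hits$sseqid)))
  if (nrow(hits)) {
    hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  }
  if (nrow(hits)) {
    a <- pmin(hits$qseqid, hits$sseqid)
    b <- pmax(hits$qseqid, hits$sseqid)
    ev <- tapply(hits$evalue, paste(a, b, sep = "\r"), min)
    keep <- ev <= edge_evalue_max
    pairs <- strsplit(names(ev)[keep], "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(pairs, `[`, "", 1L),
      to = vapply(pairs, `[`, "", 2L),
      weight = pmin(-log10(pmax(ev[keep], 1e-200)), 200),
      stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "protein_graph")
}

# Connected components of a protein_graph; returns a list of node-id
# character vectors, each sorted.
graph_components <- function(graph) {
  nodes <- graph$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  if (nrow(graph$edges)) {
    fi <- idx[graph$edges$from]; ti <- idx[graph$edges$to]
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
  }
  comp <- rep(NA_integer_, length(nodes)); nc <- 0L
  for (v in seq_along(nodes)) {
    if (!is.na(comp[v])) next
    nc <- nc + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (!is.na(comp[u])) next
      comp[u] <- nc
      nb <- adj[[u]]
      stack <- c(stack, nb[is.na(comp[nb])])
    }
  }
  unname(lapply(split(nodes, comp), sort))
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Native dense-matrix MCL: the weighted adjacency matrix gets unit
#' self-loops and is column-normalized to a stochastic matrix; each iteration
#' applies expansion (matrix squaring) followed by inflation (elementwise
#' power \code{inflation}, then column renormalization) until the maximum
#' absolute change is below \code{tol} or \code{max_iter} is reached.
#' Clusters are read off the converged matrix as connected components of its
#' support, which always yields a partition; nodes in different graph
#' components can never be merged.
#'
#' @param graph A \code{protein_graph} (or any list with \code{nodes} and
#'   \code{edges}).
#' @param inflation Inflation exponent (> 1; default 2, the canonical MCL
#'   setting).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max elementwise change.
#' @return List of character vectors (the clusters), with attribute
#'   \code{converged}. A warning is raised when \code{max_iter} is hit.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 100L, tol = 1e-6) {
  stopifnot(inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(structure(list(), converged = TRUE))
  # The MCL matrix is block-diagonal over connected components, so nodes in
  # different components can never merge; iterate each component separately
  # (identical fixed points, much cheaper than one dense n x n matrix).
  comp0 <- graph_components(graph)
  if (length(comp0) > 1L) {
    out <- list(); conv <- TRUE
    for (cp in comp0) {
      sub <- list(nodes = cp,
                  edges = graph$edges[graph$edges$from %in% cp &
                                        graph$edges$to %in% cp, , drop = FALSE])
      res <- mcl_cluster(sub, inflation, max_iter, tol)
      conv <- conv && attr(res, "converged")
      out <- c(out, res)
    }
    return(structure(out, converged = conv))
  }
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    M[cbind(i, j)] <- e$weight
    M[cbind(j, i)] <- e$weight
  }
  diag(M) <- diag(M) + 1           # self-loops
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                  # expansion
    M2 <- M2^inflation             # inflation
    M2[M2 < 1e-300] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")
  # clusters = connected components of the support of the converged matrix
  eps <- min(1e-4, 0.5 / n)
  supp <- (M >= eps) | (t(M) >= eps)
  diag(supp) <- TRUE
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    nc <- nc + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- nc
      queue <- c(queue, which(supp[u, ] & is.na(comp)))
    }
  }
  out <- lapply(split(nodes, comp), sort)
  names(out) <- NULL
  structure(out, converged = converged)
}

#' Size-filter clusters into a PC vocabulary
#'
#' Clusters with fewer than \code{min_size} members (default 2) are dropped.
#' Surviving clusters receive token ids 2, 3, ... in order of decreasing
#' size, ties broken by the lexicographically smallest member id. The
#' representative of each cluster is its longest member (ties by smallest
#' id). Ids 0 (mask/padding) and 1 (unknown) are reserved.
#'
#' @param partition List of character vectors from \code{\link{mcl_cluster}}.
#' @param proteins Named character vector or \code{AAStringSet} providing the
#'   member sequences (used for representative choice and query alignment).
#' @param min_size Minimum cluster size.
#' @return A \code{pc_vocab} object: list with \code{clusters} (named list,
#'   token id -> member ids), \code{representatives} (named character, token
#'   id -> protein id), \code{rep_seqs} (named character) and
#'   \code{reserved}.
#' @export
filter_clusters <- function(partition, proteins, min_size = 2L) {
  proteins <- as_seq_set(proteins)
  keep <- partition[vapply(partition, length, 1L) >= min_size]
  if (length(keep)) {
    sizes <- vapply(keep, length, 1L)
    first_member <- vapply(keep, function(m) sort(m)[1L], "")
    ord <- order(-sizes, first_member, method = "radix")
    keep <- keep[ord]
    reps <- vapply(keep, function(m) {
      len <- nchar(proteins[m])
      m[order(-len, m, method = "radix")][1L]
    }, "")
    ids <- as.character(seq_along(keep) + 1L)
    clusters <- stats::setNames(lapply(keep, sort), ids)
    representatives <- stats::setNames(reps, ids)
    rep_seqs <- stats::setNames(unname(proteins[reps]), ids)
  } else {
    clusters <- stats::setNames(list(), character())
    representatives <- stats::setNames(character(), character())
    rep_seqs <- stats::setNames(character(), character())
  }
  structure(list(clusters = clusters, representatives = representatives,
                 rep_seqs = rep_seqs,
                 reserved = c(mask = 0L, unknown = 1L)),
            class = "pc_vocab")
}

#' @export
print.pc_vocab <- function(x, ...) {
  cat("PC vocabulary:", length(x$clusters), "clusters (token ids 2..",
      length(x$clusters) + 1L, "), reserved 0=mask 1=unknown\n", sep = "")
  invisible(x)
}

#' PC-assignment thresholds
#'
#' Stringent cutoffs a query-vs-representative alignment must meet before
#' the query inherits the cluster's token id: e-value at most
#' \code{evalue_max}, percent identity at least \code{min_pident}, query
#' coverage at least \code{min_qcov}.
#'
#' @param evalue_max,min_pident,min_qcov Cutoffs.
#' @return Named list.
#' @export
pc_assign_thresholds <- function(evalue_max = 1e-5, min_pident = 30,
                                 min_qcov = 50) {
  list(evalue_max = evalue_max, min_pident = min_pident, min_qcov = min_qcov)
}

#' Assign PC token ids to query proteins
#'
#' Aligns each query against all cluster representatives; the best hit by
#' bitscore (ties: lower e-value, then smaller token id) wins. If the best
#' hit fails the thresholds, the unknown token (id 1) is assigned.
#'
#' @param proteins Named character vector or \code{AAStringSet} of query
#'   proteins (a single unnamed string is also accepted).
#' @param vocab A \code{pc_vocab}.
#' @param engine Protein aligner engine.
#' @param thresholds See \code{\link{pc_assign_thresholds}}.
#' @return Integer vector of token ids, one per query, named by query id.
#' @export
assign_pc <- function(proteins, vocab, engine = default_engines()$protein,
                      thresholds = pc_assign_thresholds()) {
  if (is.character(proteins) && is.null(names(proteins)) &&
      length(proteins) == 1L) {
    proteins <- c(query = proteins)
  }
  proteins <- as_seq_set(proteins)
  if (!length(vocab$clusters)) {
    return(stats::setNames(rep(1L, length(proteins)), names(proteins)))
  }
  reps <- stats::setNames(vocab$rep_seqs,
                          paste0("PC", names(vocab$rep_seqs)))
  hits <- engine(proteins, reps)
  ids <- stats::setNames(rep(1L, length(proteins)), names(proteins))
  if (nrow(hits)) {
    hits$token <- as.integer(sub("^PC", "", hits$sseqid))
    hits <- hits[order(hits$qseqid, -hits$bitscore, hits$evalue, hits$token,
                       method = "radix"), , drop = FALSE]
    best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
    ok <- best$evalue <= thresholds$evalue_max &
      best$pident >= thresholds$min_pident &
      best$qcovhsp >= thresholds$min_qcov
    ids[best$qseqid[ok]] <- best$token[ok]
  }
  ids
}

#' Write a PC vocabulary bundle
#'
#' Two plain-text files: \code{<prefix>_reps.faa} (representative sequences,
#' FASTA) and \code{<prefix>_clusters.tsv} (token_id, comma-joined
#' member_ids, representative_id).
#'
#' @param vocab A \code{pc_vocab}.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_vocab <- function(vocab, prefix) {
  faa <- paste0(prefix, "_reps.faa")
  tsv <- paste0(prefix, "_clusters.tsv")
  write_fasta(stats::setNames(vocab$rep_seqs,
                              paste0("PC", names(vocab$rep_seqs))), faa)
  df <- data.frame(
    token_id = names(vocab$clusters),
    member_ids = vapply(vocab$clusters, paste, "", collapse = ","),
    representative_id = unname(vocab$representatives),
    stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(faa, tsv))
}

#' Read a PC vocabulary bundle written by \code{\link{write_vocab}}
#'
#' @param prefix Path prefix used when writing.
#' @return A \code{pc_vocab}.
#' @export
read_vocab <- function(prefix) {
  faa <- paste0(prefix, "_reps.faa")
  tsv <- paste0(prefix, "_clusters.tsv")
  df <- utils::read.table(tsv, sep = "\t", header = TRUE,
                          colClasses = "character")
  reps <- Biostrings::readAAStringSet(faa)
  ids <- df$token_id
  structure(list(
    clusters = stats::setNames(strsplit(df$member_ids, ",", fixed = TRUE), ids),
    representatives = stats::setNames(df$representative_id, ids),
    rep_seqs = stats::setNames(as.character(reps)[paste0("PC", ids)], ids),
    reserved = c(mask = 0L, unknown = 1L)), class = "pc_vocab")
}

#' Number of token ids in a vocabulary (reserved ids included)
#' @param vocab A \code{pc_vocab}.
#' @return Integer: \code{2 + number of clusters}.
#' @export
vocab_size <- function(vocab) 2L + length(vocab$clusters)
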