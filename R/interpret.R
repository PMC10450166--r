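# Attention-based token importance: how much total attention a token
# receives, averaged over heads and over its occurrences across sentences.
# This operationalizes "importance" as attention received (column sums of
# the row-stochastic attention matrices); a token that many contexts attend
# to accumulates incoming weight.

#' Score token importance from attention distributions
#'
#' For every sentence the per-head attention matrices are computed; the
#' importance of position j is the mean over heads of the column sum of the
#' attention matrix (total attention received by j). Scores are aggregated
#' per token id as the mean over all occurrences at non-pad positions, so
#' frequency does not dominate importance; occurrence counts are reported
#' separately. The pad token (id 0) never appears in the ranking.
#'
#' @param model A trained \code{plasmeld_transformer}.
#' @param sentences Integer matrix \code{n x L} of 0-based token ids (or a
#'   list of \code{\link{token_sentence}}s).
#' @return data.frame \code{token_id}, \code{mean_attention},
#'   \code{occurrences}, \code{rank} (1 = most important; ties broken by
#'   smaller token id), sorted by rank.
#' @export
token_importance <- function(model, sentences) {
  if (is.list(sentences) && !is.data.frame(sentences)) {
    sentences <- do.call(rbind, lapply(sentences, as.integer))
  }
  if (is.null(dim(sentences))) sentences <- matrix(as.integer(sentences), 1L)
  stopifnot(nrow(sentences) > 0L)
  score_sum <- numeric(); occ <- integer()
  for (b in seq_len(nrow(sentences))) {
    ids <- as.integer(sentences[b, ])
    maps <- attention_maps(model, ids)
    recv <- Reduce(`+`, lapply(maps, colSums)) / length(maps)
    keep <- ids != 0L
    for (tok in unique(ids[keep])) {
      key <- as.character(tok)
      s <- sum(recv[keep & ids == tok])
      n <- sum(keep & ids == tok)
      score_sum[key] <- if (is.na(score_sum[key])) s else score_sum[key] + s
      occ[key] <- if (is.na(occ[key])) n else occ[key] + n
    }
  }
  if (!length(occ)) {
    return(data.frame(token_id = integer(), mean_attention = numeric(),
                      occurrences = integer(), rank = integer()))
  }
  df <- data.frame(token_id = as.integer(names(occ)),
                   mean_attention = unname(score_sum[names(occ)] / occ),
                   occurrences = unname(occ), stringsAsFactors = FALSE)
  df <- df[order(-df$mean_attention, df$token_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Top-k token importance report
#'
#' Joins the importance ranking with the vocabulary's representative
#' proteins for downstream annotation. When fewer than \code{k} tokens are
#' available, all are returned.
#'
#' @param importances Output of \code{\link{token_importance}}.
#' @param vocab Optional \code{pc_vocab} supplying representatives.
#' @param k Number of tokens to report (default 50).
#' @return data.frame \code{token_id}, \code{score}, \code{occurrences},
#'   \code{representative_protein_id}.
#' @export
top_k_report <- function(importances, vocab = NULL, k = 50L) {
  top <- utils::head(importances[order(importances$rank), , drop = FALSE], k)
  rep_id <- rep(NA_character_, nrow(top))
  if (!is.null(vocab)) {
    m <- match(as.character(top$token_id), names(vocab$representatives))
    rep_id <- unname(vocab$representatives[m])
  }
  data.frame(token_id = top$token_id, score = top$mean_attention,
             occurrences = top$occurrences,
             representative_protein_id = rep_id, stringsAsFactors = FALSE)
}

#' Dump per-sentence attention heatmaps
#'
#' Writes one position-by-position matrix (mean over heads) per sentence as
#' TSV, for inspection or plotting.
#'
#' @param model A \code{plasmeld_transformer}.
#' @param sentences Integer matrix of sentences.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
dump_attention <- function(model, sentences, dir, prefix = "attention") {
  if (is.null(dim(sentences))) sentences <- matrix(as.integer(sentences), 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(sentences))
  for (b in seq_len(nrow(sentences))) {
    maps <- attention_maps(model, as.integer(sentences[b, ]))
    avg <- Reduce(`+`, maps) / length(maps)
    paths[b] <- file.path(dir, sprintf("%s_%03d.tsv", prefix, b))
    utils::write.table(avg, paths[b], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
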