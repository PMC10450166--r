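# Two-stage decision procedure:
#   length filter -> alignment shortcut (coverage & identity >= 90%) ->
#   order routing by best-hit e-value (< 10) -> order-specific attention
#   model -> thresholded (PC) or majority-voted (segment/protein schemes)
#   prediction, plus optional marking of chromosome-like regions.

#' Pipeline thresholds
#'
#' @param tau_cov,tau_ident Alignment-shortcut thresholds on overall query
#'   coverage and identity (fractions; both 0.90 by default, boundary
#'   values accepted, i.e. \code{>=}).
#' @param tau Per-unit probability threshold (default 0.5, strict
#'   \code{>}).
#' @param vote_nt_bpe,vote_aa,vote_aa_bpe Majority-vote proportion
#'   thresholds for the segment/protein schemes (0.55, 0.41, 0.17).
#' @param order_evalue_max Hits with e-value below this bound can assign an
#'   order (BLAST default 10).
#' @return Named list of class \code{"pipeline_thresholds"}.
#' @export
pipeline_thresholds <- function(tau_cov = 0.90, tau_ident = 0.90, tau = 0.5,
                                vote_nt_bpe = 0.55, vote_aa = 0.41,
                                vote_aa_bpe = 0.17, order_evalue_max = 10) {
  structure(list(tau_cov = tau_cov, tau_ident = tau_ident, tau = tau,
                 vote_nt_bpe = vote_nt_bpe, vote_aa = vote_aa,
                 vote_aa_bpe = vote_aa_bpe,
                 order_evalue_max = order_evalue_max),
            class = "pipeline_thresholds")
}

#' Overall query coverage and identity of one query/subject pair
#'
#' Coverage is the merged-interval query coverage: the union of the query
#' HSP intervals divided by the query length. Identity is the
#' alignment-length-weighted mean of the HSP identities over the merged
#' set: HSPs are admitted greedily by decreasing bitscore and an HSP whose
#' query interval is already mostly (> 50\%) covered by better HSPs is
#' skipped, so paralogous repeats re-aligning the same query region do not
#' dilute the estimate.
#'
#' @param hits Hit data.frame restricted to one query/subject pair
#'   (non-empty).
#' @param query_len Query length in bp.
#' @return Named numeric \code{c(coverage=, identity=)}, both fractions.
#' @export
overall_cov_identity <- function(hits, query_len) {
  stopifnot(nrow(hits) > 0L)
  hits <- hits[order(-hits$bitscore, hits$evalue), , drop = FALSE]
  qs <- pmin(hits$qstart, hits$qend); qe <- pmax(hits$qstart, hits$qend)
  covered <- IRanges::IRanges()
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    iv <- IRanges::IRanges(qs[r], qe[r])
    novel <- IRanges::width(iv) -
      sum(IRanges::width(IRanges::intersect(iv, covered)))
    if (novel > 0.5 * IRanges::width(iv)) {
      keep[r] <- TRUE
      covered <- IRanges::reduce(c(covered, iv))
    }
  }
  cov <- sum(IRanges::width(covered)) / unname(query_len)
  ident <- sum(hits$pident[keep] * hits$length[keep]) /
    sum(hits$length[keep]) / 100
  c(coverage = unname(cov), identity = unname(ident))
}

#' Alignment-shortcut stage
#'
#' A contig is called plasmid outright when some reference plasmid achieves
#' overall query coverage >= tau_cov and identity >= tau_ident; otherwise it
#' passes through to order assignment.
#'
#' @param hits Hit data.frame for one contig against the plasmid DB (may be
#'   empty).
#' @param query_len Contig length.
#' @param thresholds A \code{\link{pipeline_thresholds}}.
#' @return List \code{(hit = TRUE/FALSE, subject = best reference or NA)}.
#' @export
alignment_stage <- function(hits, query_len,
                            thresholds = pipeline_thresholds()) {
  if (nrow(hits) == 0L) return(list(hit = FALSE, subject = NA_character_))
  per_subj <- lapply(split(hits, hits$sseqid), overall_cov_identity,
                     query_len = query_len)
  cov <- vapply(per_subj, `[[`, 0, "coverage")
  idn <- vapply(per_subj, `[[`, 0, "identity")
  ok <- cov >= thresholds$tau_cov & idn >= thresholds$tau_ident
  if (!any(ok)) return(list(hit = FALSE, subject = NA_character_))
  best <- names(per_subj)[ok][order(-cov[ok], -idn[ok],
                                    names(per_subj)[ok])][1L]
  list(hit = TRUE, subject = best)
}

#' Assign a contig to a host order
#'
#' Among hits with e-value below \code{order_evalue_max}, the order of the
#' best hit wins (lowest e-value; ties by highest bitscore, then
#' lexicographically smallest order name). A contig with no qualifying hit
#' gets no order and is classified non-plasmid downstream.
#'
#' @param hits Hit data.frame for one contig against the plasmid DB.
#' @param order_labels Named character vector: reference id -> order.
#' @param thresholds A \code{\link{pipeline_thresholds}}.
#' @return Order name, or \code{NA_character_}.
#' @export
assign_order <- function(hits, order_labels,
                         thresholds = pipeline_thresholds()) {
  if (nrow(hits) == 0L) return(NA_character_)
  unknown <- setdiff(unique(hits$sseqid), names(order_labels))
  if (length(unknown)) stop("no order label for reference: ", unknown[1L])
  hits <- hits[hits$evalue < thresholds$order_evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA_character_)
  hits$order <- unname(order_labels[hits$sseqid])
  hits <- hits[order(hits$evalue, -hits$bitscore, hits$order,
                     method = "radix"), , drop = FALSE]
  hits$order[1L]
}

#' Majority vote over per-unit probabilities
#'
#' The proportion of units (segments or proteins) whose probability exceeds
#' \code{tau} is compared with the scheme's voting threshold; the contig is
#' plasmid when the proportion is strictly greater.
#'
#' @param unit_probs Non-empty numeric vector of per-unit probabilities.
#' @param tau Per-unit probability threshold (strict \code{>}).
#' @param vote_threshold Scheme voting threshold (0.55 nt-BPE, 0.41 AA,
#'   0.17 aa-BPE; strict \code{>}).
#' @return \code{"plasmid"} or \code{"non-plasmid"}.
#' @export
majority_vote <- function(unit_probs, tau = 0.5, vote_threshold) {
  if (length(unit_probs) == 0L) stop("majority_vote needs at least one unit")
  prop <- mean(unit_probs > tau)
  if (prop > vote_threshold) "plasmid" else "non-plasmid"
}

#' Mark chromosome-like regions on a contig
#'
#' Merged query intervals of chromosome-database hits with identity >= 90\%
#' and HSP length >= 500 bp, reported 1-based inclusive. Useful for flagging
#' shared (chromosome-derived) regions inside predicted plasmids.
#'
#' @param hits Hit data.frame for one contig against the chromosome DB.
#' @param min_pident,min_len Inclusion thresholds.
#' @return data.frame \code{start}, \code{end}, \code{tag}.
#' @export
mark_shared_regions <- function(hits, min_pident = 90, min_len = 500L) {
  empty <- data.frame(start = integer(), end = integer(),
                      tag = character(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$pident >= min_pident & hits$length >= min_len, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  qs <- pmin(hits$qstart, hits$qend); qe <- pmax(hits$qstart, hits$qend)
  merged <- IRanges::reduce(IRanges::IRanges(qs, qe))
  data.frame(start = IRanges::start(merged), end = IRanges::end(merged),
             tag = "chromosome-like", stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Reference bundle: vocabulary + models + databases
# ---------------------------------------------------------------------------

#' Build a classifier reference from labeled training contigs
#'
#' End-to-end training: call genes on the reference plasmids, build the PC
#' vocabulary (all-vs-all alignment, e-value <= 1e-5 graph, MCL, clusters of
#' >= 2), tokenize the training contigs (optionally window-augmented), and
#' train the attention classifier. Per-order models are trained when an
#' order has plasmids; a pooled all-orders model is always trained and used
#' as the fallback for orders without their own model.
#'
#' @param contigs Named character vector / \code{DNAStringSet} of training
#'   sequences (plasmids and chromosomes).
#' @param labels \code{"plasmid"}/\code{"chromosome"} per contig.
#' @param orders Host order per contig (used for per-order models and for
#'   routing queries); chromosomes may carry \code{NA}.
#' @param d_model,epochs,seed Model hyperparameters (d_model 512 published;
#'   64 is the CPU-scale default here).
#' @param windows Augmentation window sizes; \code{NULL} disables
#'   augmentation. The published training uses \{200..4000\}; the default
#'   here is the desk-scale subset \{1000, 2000, 4000\}.
#' @param batch_size,lr Desk-scale optimizer settings: with roughly a
#'   thousand training sentences, the published batch 256 / lr 0.001 yields
#'   too few Adam steps inside the fixed two epochs; 16 / 0.003 is the
#'   calibrated equivalent (see the methods vignette). Pass 256 / 0.001 to
#'   reproduce the published configuration on full-scale data.
#' @param per_order Also train one model per order.
#' @param gene_engine,protein_engine Engine overrides.
#' @param db_gene_engine Gene caller for the reference plasmids; complete
#'   references do not need edge-partial ORF calls, so partials are off
#'   here by default.
#' @param pc_thresholds PC-assignment thresholds.
#' @param verbose Progress messages.
#' @return A \code{plasmeld_ref} bundle: vocab, models (named list with at
#'   least \code{"pooled"}), plasmid_db, order_labels, config pieces.
#' @export
fit_plasmeld <- function(contigs, labels, orders = NULL, d_model = 64L,
                       epochs = 2L, seed = 1L,
                       windows = c(1000L, 2000L, 4000L),
                       batch_size = 16L, lr = 0.003,
                       per_order = FALSE,
                       gene_engine = orf_engine(),
                       db_gene_engine = orf_engine(allow_partial = FALSE),
                       protein_engine = default_engines()$protein,
                       pc_thresholds = pc_assign_thresholds(),
                       verbose = FALSE) {
  contigs <- as_seq_set(contigs)
  stopifnot(length(labels) == length(contigs))
  if (is.null(orders)) orders <- rep(NA_character_, length(contigs))
  is_p <- labels == "plasmid"
  say <- function(...) if (verbose) message(...)

  say("calling genes on ", sum(is_p), " reference plasmids")
  db_prot <- list()
  for (i in which(is_p)) {
    df <- predict_genes(contigs[i], engine = db_gene_engine,
                        contig_id = names(contigs)[i])
    if (nrow(df)) db_prot[[length(db_prot) + 1L]] <- df
  }
  db_prot <- do.call(rbind, db_prot)
  prot_set <- stats::setNames(db_prot$aa_seq,
                              paste0(db_prot$contig_id, "_",
                                     db_prot$index_on_contig))
  say("building PC vocabulary from ", length(prot_set), " proteins")
  hits <- all_vs_all_hits(prot_set, engine = protein_engine)
  graph <- build_protein_graph(hits, nodes = names(prot_set))
  part <- mcl_cluster(graph)
  vocab <- filter_clusters(part, prot_set)
  say("vocabulary: ", length(vocab$clusters), " clusters")

  train_seqs <- contigs
  train_labels <- labels
  if (!is.null(windows)) {
    aug <- augment_training_set(contigs, labels, windows = windows)
    train_seqs <- stats::setNames(aug$seq, make.unique(aug$source_id))
    train_labels <- aug$label
    aug_orders <- orders[match(aug$source_id, names(contigs))]
  } else {
    aug_orders <- orders
  }
  say("tokenizing ", length(train_seqs), " training sequences")
  sent <- tokenize_pc_batch(train_seqs, vocab, gene_engine, protein_engine,
                            pc_thresholds)
  keep <- !sent$untokenizable
  smat <- sent$matrix[keep, , drop = FALSE]
  slab <- train_labels[keep]
  sord <- aug_orders[keep]

  cfg <- transformer_config(sentence_len = SCHEME_CAPACITY[["pc"]],
                            vocab_size = vocab_size(vocab),
                            d_model = d_model, epochs = epochs, seed = seed,
                            batch_size = batch_size, lr = lr)
  say("training pooled model on ", nrow(smat), " sentences")
  models <- list(pooled = train_transformer(init_transformer(cfg),
                                            smat, slab))
  if (per_order) {
    for (o in stats::na.omit(unique(orders[is_p]))) {
      sel <- (sord == o & slab == "plasmid") | slab == "chromosome"
      sel[is.na(sel)] <- FALSE
      if (sum(slab[sel] == "plasmid") < 2L) next
      say("training order model: ", o)
      models[[o]] <- train_transformer(init_transformer(cfg),
                                       smat[sel, , drop = FALSE], slab[sel])
    }
  }
  structure(list(
    vocab = vocab,
    models = models,
    plasmid_db = stats::setNames(unname(contigs[is_p]), names(contigs)[is_p]),
    order_labels = stats::setNames(orders[is_p], names(contigs)[is_p]),
    pc_thresholds = pc_thresholds,
    config = cfg), class = "plasmeld_ref")
}

# Tokenize many contigs under the PC scheme with one batched PC assignment.
tokenize_pc_batch <- function(seqs, vocab, gene_engine, protein_engine,
                              pc_thresholds, capacity = SCHEME_CAPACITY[["pc"]]) {
  seqs <- as_seq_set(seqs)
  prot <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    prot[[i]] <- predict_genes(seqs[i], engine = gene_engine,
                               contig_id = paste0("s", i))
  }
  all_prot <- do.call(rbind, prot)
  mat <- matrix(0L, length(seqs), capacity)
  untok <- vapply(prot, nrow, 1L) == 0L
  if (!is.null(all_prot) && nrow(all_prot)) {
    # identical peptides (window samples repeat their source's ORFs) are
    # assigned once and the token fanned back out
    uniq <- unique(all_prot$aa_seq)
    pset <- stats::setNames(uniq, paste0("u", seq_along(uniq)))
    ids_u <- assign_pc(pset, vocab, protein_engine, pc_thresholds)
    ids <- unname(ids_u[match(all_prot$aa_seq, uniq)])
    offsets <- c(0L, cumsum(vapply(prot, nrow, 1L)))
    for (i in seq_along(seqs)) {
      if (untok[i]) next
      tok <- ids[(offsets[i] + 1L):offsets[i + 1L]]
      n <- min(length(tok), capacity)
      mat[i, seq_len(n)] <- tok[seq_len(n)]
    }
  }
  list(matrix = mat, untokenizable = untok)
}

route_levels <- c("alignment", "transformer", "rejected-no-order",
                  "rejected-length")

#' Predict plasmid/non-plasmid for a set of contigs
#'
#' Runs the full two-stage pipeline under the PC scheme: length filter,
#' alignment shortcut against the reference plasmids, order assignment by
#' best-hit e-value, PC tokenization and the order's attention model (pooled
#' fallback). Every contig receives exactly one route among
#' \code{alignment}, \code{transformer}, \code{rejected-no-order},
#' \code{rejected-length}. Contigs with no predicted proteins under the PC
#' scheme are non-plasmid with probability 0.
#'
#' @param contigs Named character vector / \code{DNAStringSet}.
#' @param ref A \code{plasmeld_ref} from \code{\link{fit_plasmeld}}.
#' @param thresholds A \code{\link{pipeline_thresholds}}.
#' @param min_bp,max_bp Length-filter bounds.
#' @param chromosome_db Optional chromosome reference sequences for
#'   chromosome-like region marking.
#' @param gene_engine,nt_engine,protein_engine Engine overrides.
#' @return data.frame: \code{contig_id}, \code{label},
#'   \code{probability} (NA off the transformer route), \code{route},
#'   \code{order}, \code{regions} (semicolon-joined \code{start-end}).
#' @export
predict_contigs <- function(contigs, ref,
                            thresholds = pipeline_thresholds(),
                            min_bp = 1000L, max_bp = 350000L,
                            chromosome_db = NULL,
                            gene_engine = orf_engine(),
                            nt_engine = default_engines()$nucleotide,
                            protein_engine = default_engines()$protein) {
  contigs <- as_seq_set(contigs)
  n <- length(contigs)
  out <- data.frame(contig_id = names(contigs),
                    label = "non-plasmid", probability = NA_real_,
                    route = NA_character_, order = NA_character_,
                    regions = "", stringsAsFactors = FALSE)
  len <- nchar(contigs)
  inlen <- len >= min_bp & len <= max_bp
  out$route[!inlen] <- "rejected-length"
  surv <- which(inlen)
  hits_all <- if (length(surv)) {
    nt_engine(contigs[surv], ref$plasmid_db)
  } else empty_hits()
  by_query <- split(hits_all, factor(hits_all$qseqid,
                                     levels = names(contigs)[surv]))
  need_tf <- integer()
  for (i in surv) {
    h <- by_query[[names(contigs)[i]]]
    if (is.null(h)) h <- empty_hits()
    st <- alignment_stage(h, len[i], thresholds)
    if (st$hit) {
      out$label[i] <- "plasmid"; out$route[i] <- "alignment"
      out$order[i] <- unname(ref$order_labels[st$subject])
      next
    }
    o <- assign_order(h, ref$order_labels, thresholds)
    if (is.na(o)) {
      out$route[i] <- "rejected-no-order"
    } else {
      out$route[i] <- "transformer"; out$order[i] <- o
      need_tf <- c(need_tf, i)
    }
  }
  if (length(need_tf)) {
    tok <- tokenize_pc_batch(contigs[need_tf], ref$vocab, gene_engine,
                             protein_engine, ref$pc_thresholds)
    for (j in seq_along(need_tf)) {
      i <- need_tf[j]
      if (tok$untokenizable[j]) {
        out$probability[i] <- 0
        next
      }
      model <- ref$models[[out$order[i]]]
      if (is.null(model)) model <- ref$models$pooled
      p <- predict_proba(model, tok$matrix[j, , drop = FALSE])
      out$probability[i] <- p
      if (p > thresholds$tau) out$label[i] <- "plasmid"
    }
  }
  if (!is.null(chromosome_db) && length(chromosome_db)) {
    ch <- nt_engine(contigs[surv], as_seq_set(chromosome_db))
    for (i in surv) {
      hi <- ch[ch$qseqid == names(contigs)[i], , drop = FALSE]
      reg <- mark_shared_regions(hi)
      if (nrow(reg)) {
        out$regions[i] <- paste(paste0(reg$start, "-", reg$end),
                                collapse = ";")
      }
    }
  }
  stopifnot(!anyNA(out$route))
  out
}

#' Predict a single contig
#'
#' Convenience wrapper around \code{\link{predict_contigs}}.
#' @param contig One sequence (named character or length-1
#'   \code{DNAStringSet}).
#' @param ... Passed to \code{\link{predict_contigs}}.
#' @inheritParams predict_contigs
#' @return One-row prediction data.frame.
#' @export
predict_contig <- function(contig, ref, ...) {
  predict_contigs(contig, ref, ...)
}

#' Write predictions as TSV
#' @param predictions data.frame from \code{\link{predict_contigs}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
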