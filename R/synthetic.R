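# Synthetic order-structured plasmid/chromosome fixture generator. Genomes
# are concatenations of codon-realized genes drawn from protein families
# (plasmid-only, chromosome-only or shared), separated by random intergenic
# spacers, with full ground truth recorded. Every plasmid carries a gene
# from a designated "replicon" family (a marker present only in plasmids,
# like a replication-initiation gene), which the interpretation tests try
# to recover. Codon realization samples synonymous codons uniformly so that
# the class signal lives in protein-family content, not codon bias.

#' Synthetic benchmark specification
#'
#' @param n_orders Number of host orders.
#' @param plasmids_per_order,chromosomes_per_order Genomes per order.
#' @param n_plasmid_pcs,n_chromosome_pcs Class-specific protein-family
#'   counts.
#' @param shared_fraction Fraction (of all class-specific families) of
#'   additional families present in both classes; 0 makes the class PC sets
#'   disjoint.
#' @param mutation_rate Per-site amino-acid substitution rate between a
#'   family member and its ancestor (0.05 gives ~90\% pairwise member
#'   identity).
#' @param plasmid_genes,chromosome_genes Gene-count ranges per genome.
#' @param protein_len Ancestral protein length range (aa).
#' @param spacer_len Intergenic spacer length range (bp).
#' @param members_per_family Pre-generated members per family.
#' @param fragment_lengths Test-contig fragment lengths (bp).
#' @param frags_per_length Fragments sampled per test genome per length.
#' @param train_frac Train fraction of genomes per order (roughly 4:1).
#' @param include_marker Plant the replicon marker family in every plasmid.
#' @param seed RNG seed; a fixed seed reproduces the benchmark
#'   byte-for-byte.
#' @return Named list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_orders = 4L, plasmids_per_order = 10L,
                           chromosomes_per_order = 10L,
                           n_plasmid_pcs = 30L, n_chromosome_pcs = 30L,
                           shared_fraction = 0, mutation_rate = 0.05,
                           plasmid_genes = c(6L, 12L),
                           chromosome_genes = c(10L, 20L),
                           protein_len = c(80L, 400L),
                           spacer_len = c(50L, 200L),
                           members_per_family = 6L,
                           fragment_lengths = c(1000L, 2000L, 3000L),
                           frags_per_length = 2L,
                           train_frac = 0.8, include_marker = TRUE,
                           seed = 1L) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1, mutation_rate >= 0,
            mutation_rate <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# codon table: amino acid -> synonymous codons (stop codons excluded)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

mutate_protein <- function(aa, rate) {
  if (rate == 0) return(aa)
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  # keep the leading M so the realized gene always starts with ATG
  hit <- which(stats::runif(length(chars)) < rate & seq_along(chars) > 1L)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate the protein-family universe
#'
#' Families are an ancestral protein plus \code{members_per_family}
#' independently mutated copies. Families are labelled plasmid-only,
#' chromosome-only or shared; class-specific families are partitioned
#' round-robin across orders to give each order a biased gene composition.
#' Uses the ambient RNG state (seed it, or call via
#' \code{\link{generate_benchmark}}).
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return List of family records (\code{id}, \code{label}, \code{order},
#'   \code{is_marker}, \code{ancestor}, \code{members}), class
#'   \code{"pc_universe"}.
#' @export
generate_pc_universe <- function(spec) {
  orders <- paste0("order", seq_len(spec$n_orders))
  n_shared <- round(spec$shared_fraction *
                      (spec$n_plasmid_pcs + spec$n_chromosome_pcs))
  mk <- function(label, k, with_orders = TRUE) {
    lapply(seq_len(k), function(i) {
      len <- sample(spec$protein_len[1L]:spec$protein_len[2L], 1L)
      anc <- random_protein(len)
      list(id = paste0(substr(label, 1L, 1L), i), label = label,
           order = if (with_orders) orders[(i - 1L) %% spec$n_orders + 1L]
                   else NA_character_,
           is_marker = FALSE, ancestor = anc,
           members = vapply(seq_len(spec$members_per_family), function(j)
             mutate_protein(anc, spec$mutation_rate), ""))
    })
  }
  fam <- c(mk("plasmid", spec$n_plasmid_pcs),
           mk("chromosome", spec$n_chromosome_pcs),
           mk("shared", n_shared, with_orders = FALSE))
  if (spec$include_marker) fam[[1L]]$is_marker <- TRUE
  names(fam) <- vapply(fam, `[[`, "", "id")
  structure(fam, class = "pc_universe")
}

realize_gene <- function(aa, codons) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  body <- vapply(chars, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste(c(body, stop_codon), collapse = "")
}

random_spacer <- function(range) {
  n <- sample(range[1L]:range[2L], 1L)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate one synthetic genome
#'
#' Concatenates codon-realized genes (class- and order-appropriate
#' families; every plasmid starts its gene list with the replicon marker
#' when enabled) separated by random spacers, and records the ground-truth
#' coordinates, family and protein of every gene. All genes sit on the
#' forward strand.
#'
#' @param kind \code{"plasmid"} or \code{"chromosome"}.
#' @param order Host order label.
#' @param universe From \code{\link{generate_pc_universe}}.
#' @param spec A \code{\link{synthetic_spec}}.
#' @return List \code{seq} (string) and \code{map} (data.frame
#'   \code{gene_idx}, \code{family}, \code{start}, \code{end},
#'   \code{strand}, \code{aa_seq}).
#' @export
generate_genome <- function(kind, order, universe, spec) {
  codons <- codon_table()
  labels <- vapply(universe, `[[`, "", "label")
  fam_orders <- vapply(universe, `[[`, "", "order")
  markers <- vapply(universe, `[[`, TRUE, "is_marker")
  own <- names(universe)[labels == kind &
                           (is.na(fam_orders) | fam_orders == order)]
  pool <- c(own, names(universe)[labels == "shared"])
  rng <- if (kind == "plasmid") spec$plasmid_genes else spec$chromosome_genes
  n_genes <- sample(rng[1L]:rng[2L], 1L)
  fams <- sample(pool, n_genes, replace = TRUE)
  if (kind == "plasmid" && spec$include_marker) {
    fams[1L] <- names(universe)[markers][1L]
  }
  pieces <- character(0)
  map <- list()
  pos <- 0L
  for (g in seq_along(fams)) {
    sp <- random_spacer(spec$spacer_len)
    pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    fam <- universe[[fams[g]]]
    aa <- fam$members[sample.int(length(fam$members), 1L)]
    gene <- realize_gene(aa, codons)
    map[[g]] <- data.frame(gene_idx = g, family = fam$id,
                           start = pos + 1L, end = pos + nchar(gene),
                           strand = "+", aa_seq = aa,
                           stringsAsFactors = FALSE)
    pieces <- c(pieces, gene); pos <- pos + nchar(gene)
  }
  pieces <- c(pieces, random_spacer(spec$spacer_len))
  list(seq = paste(pieces, collapse = ""), map = do.call(rbind, map))
}

#' Generate a full train/test benchmark
#'
#' Seeds the RNG from \code{spec$seed} (byte-identical output for the same
#' seed), builds the family universe, generates genomes per order and
#' splits them ~4:1 into train and test per order and class. Test genomes
#' are additionally fragmented at 1000/2000/3000 bp (random windows). The
#' training plasmids double as the reference plasmid database with host
#' order labels.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return List with \code{universe}, \code{train}, \code{test} (each:
#'   \code{contigs} named character, \code{labels}, \code{orders},
#'   \code{maps}), \code{plasmid_db}, \code{order_labels}, \code{spec}.
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  universe <- generate_pc_universe(spec)
  orders <- paste0("order", seq_len(spec$n_orders))
  gen <- list(contigs = character(), labels = character(),
              orders = character(), maps = list())
  for (o in orders) {
    for (kind in c("plasmid", "chromosome")) {
      nk <- if (kind == "plasmid") spec$plasmids_per_order else
        spec$chromosomes_per_order
      for (i in seq_len(nk)) {
        g <- generate_genome(kind, o, universe, spec)
        id <- paste(o, kind, i, sep = "_")
        gen$contigs[id] <- g$seq
        gen$labels[id] <- kind
        gen$orders[id] <- o
        gen$maps[[id]] <- g$map
      }
    }
  }
  # per-order, per-class ~4:1 split
  train_idx <- logical(length(gen$contigs))
  ids <- names(gen$contigs)
  for (o in orders) {
    for (kind in c("plasmid", "chromosome")) {
      sel <- which(gen$orders == o & gen$labels == kind)
      n_tr <- max(1L, min(length(sel) - 1L,
                          round(spec$train_frac * length(sel))))
      train_idx[sel[seq_len(n_tr)]] <- TRUE
    }
  }
  subset_split <- function(keep) {
    list(contigs = gen$contigs[keep], labels = unname(gen$labels[keep]),
         orders = unname(gen$orders[keep]), maps = gen$maps[ids[keep]])
  }
  train <- subset_split(train_idx)
  test <- subset_split(!train_idx)
  # fragment the test genomes
  frags <- character(); flab <- character(); ford <- character()
  for (i in seq_along(test$contigs)) {
    s <- test$contigs[[i]]
    for (L in spec$fragment_lengths) {
      if (nchar(s) < L) next
      for (k in seq_len(spec$frags_per_length)) {
        st <- sample.int(nchar(s) - L + 1L, 1L)
        id <- paste0(names(test$contigs)[i], "_frag", L, "_", k)
        frags[id] <- substr(s, st, st + L - 1L)
        flab[id] <- test$labels[i]
        ford[id] <- test$orders[i]
      }
    }
  }
  test$contigs <- c(test$contigs, frags)
  test$labels <- c(test$labels, unname(flab))
  test$orders <- c(test$orders, unname(ford))
  is_p <- train$labels == "plasmid"
  list(universe = universe, train = train, test = test,
       plasmid_db = train$contigs[is_p],
       order_labels = stats::setNames(train$orders[is_p],
                                      names(train$contigs)[is_p]),
       spec = spec)
}

#' Write a benchmark to disk
#'
#' Emits plain-text artifacts: contig and reference FASTA files, a
#' ground-truth TSV (contig_id, split, label, order) and a JSON echo of the
#' generating spec.
#'
#' @param bench From \code{\link{generate_benchmark}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(bench$train$contigs, file.path(dir, "train_contigs.fasta"))
  write_fasta(bench$test$contigs, file.path(dir, "test_contigs.fasta"))
  write_fasta(bench$plasmid_db, file.path(dir, "plasmid_db.fasta"))
  truth <- rbind(
    data.frame(contig_id = names(bench$train$contigs), split = "train",
               label = bench$train$labels, order = bench$train$orders),
    data.frame(contig_id = names(bench$test$contigs), split = "test",
               label = bench$test$labels, order = bench$test$orders))
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spec_out <- bench$spec[!vapply(bench$spec, is.function, TRUE)]
  jsonlite::write_json(spec_out, file.path(dir, "spec.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
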