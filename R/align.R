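# Alignment engines. Every engine is a function
#   engine(queries, subjects) -> hit data.frame
# over named character vectors / XStringSets, returning BLAST-style tabular
# hits so that command-line aligners (BLASTP/BLASTN, or DIAMOND-compatible
# tabular output) and the internal Smith-Waterman are interchangeable.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore",
                 "qstart", "qend", "sstart", "send", "qcovhsp")

empty_hits <- function() {
  df <- data.frame(qseqid = character(), sseqid = character(),
                   pident = numeric(), length = integer(), evalue = numeric(),
                   bitscore = numeric(), qstart = integer(), qend = integer(),
                   sstart = integer(), send = integer(), qcovhsp = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Read BLAST/DIAMOND tabular alignment output
#'
#' Parses tabular hits in the
#' \code{qseqid sseqid pident length evalue bitscore qstart qend sstart send
#' qcovhsp} dialect (the format every engine in this package emits and
#' consumes).
#'
#' @param path Path to a tab-separated hits file without header.
#' @return Hit data.frame.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) return(empty_hits())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = HIT_COLUMNS, stringsAsFactors = FALSE)
  df
}

as_seq_set <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (methods::is(x, "XStringSet")) x <- stats::setNames(as.character(x), names(x))
  stopifnot(is.character(x), !is.null(names(x)), !anyDuplicated(names(x)))
  x
}

# Karlin-Altschul conversion: bitscore from raw score, e-value from the
# product of query length and total database length.
ka_stats <- function(score, qlen, dblen, lambda, K) {
  bits <- (lambda * score - log(K)) / log(2)
  list(bitscore = bits, evalue = qlen * dblen * 2^(-bits))
}

#' Internal Smith-Waterman protein aligner
#'
#' Local alignment with BLOSUM62 (gap open 11 / extend 1) and a
#' Karlin-Altschul e-value surrogate using the standard gapped BLOSUM62
#' parameters (lambda 0.267, K 0.041). Intended for tests and small inputs;
#' production runs use \code{\link{blast_protein_engine}}.
#'
#' @param evalue_max Hits with larger e-value are dropped.
#' @param lambda,K Karlin-Altschul parameters.
#' @return An aligner engine function.
#' @export
sw_protein_engine <- function(evalue_max = 10, lambda = 0.267, K = 0.041) {
  function(queries, subjects) {
    queries <- as_seq_set(queries); subjects <- as_seq_set(subjects)
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    mat <- data_env$BLOSUM62
    dblen <- sum(nchar(subjects))
    qset <- Biostrings::AAStringSet(queries)
    out <- vector("list", length(subjects))
    for (j in seq_along(subjects)) {
      pa <- Biostrings::pairwiseAlignment(
        qset, Biostrings::AAString(subjects[[j]]), type = "local",
        substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
      ka <- ka_stats(Biostrings::score(pa), nchar(queries), dblen, lambda, K)
      alen <- Biostrings::nchar(pa)
      df <- data.frame(
        qseqid = names(queries), sseqid = names(subjects)[j],
        pident = Biostrings::pid(pa, type = "PID1"),
        length = alen, evalue = ka$evalue, bitscore = ka$bitscore,
        qstart = Biostrings::start(Biostrings::pattern(pa)),
        qend = Biostrings::end(Biostrings::pattern(pa)),
        sstart = Biostrings::start(Biostrings::subject(pa)),
        send = Biostrings::end(Biostrings::subject(pa)),
        stringsAsFactors = FALSE)
      df$qcovhsp <- 100 * (df$qend - df$qstart + 1L) / nchar(queries)
      out[[j]] <- df[df$evalue <= evalue_max, , drop = FALSE]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$qseqid, res$evalue), , drop = FALSE]
  }
}

#' Internal Smith-Waterman nucleotide aligner
#'
#' Local alignment with match +2 / mismatch -3, gap open 5 / extend 2 and the
#' corresponding BLASTN Karlin-Altschul parameters (lambda 0.625, K 0.41).
#' One best local alignment per query/subject pair; for production-scale
#' multi-HSP search use \code{\link{blast_nucleotide_engine}}.
#'
#' @inheritParams sw_protein_engine
#' @return An aligner engine function.
#' @export
sw_nucleotide_engine <- function(evalue_max = 10, lambda = 0.625, K = 0.41) {
  function(queries, subjects) {
    queries <- as_seq_set(queries); subjects <- as_seq_set(subjects)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    dblen <- sum(nchar(subjects))
    out <- list()
    for (j in seq_along(subjects)) {
      subj <- Biostrings::DNAString(subjects[[j]])
      for (i in seq_along(queries)) {
        best <- NULL
        for (strand in c("+", "-")) {
          q <- Biostrings::DNAString(queries[[i]])
          if (strand == "-") q <- Biostrings::reverseComplement(q)
          pa <- Biostrings::pairwiseAlignment(
            q, subj, type = "local", substitutionMatrix = mat,
            gapOpening = 5, gapExtension = 2)
          if (is.null(best) || Biostrings::score(pa) > best$score) {
            best <- list(pa = pa, score = Biostrings::score(pa), strand = strand)
          }
        }
        pa <- best$pa
        qlen <- nchar(queries[[i]])
        ka <- ka_stats(best$score, qlen, dblen, lambda, K)
        qs <- Biostrings::start(Biostrings::pattern(pa))
        qe <- Biostrings::end(Biostrings::pattern(pa))
        if (best$strand == "-") { tmp <- qs; qs <- qlen - qe + 1L; qe <- qlen - tmp + 1L }
        df <- data.frame(
          qseqid = names(queries)[i], sseqid = names(subjects)[j],
          pident = Biostrings::pid(pa, type = "PID1"),
          length = Biostrings::nchar(pa), evalue = ka$evalue,
          bitscore = ka$bitscore, qstart = qs, qend = qe,
          sstart = Biostrings::start(Biostrings::subject(pa)),
          send = Biostrings::end(Biostrings::subject(pa)),
          stringsAsFactors = FALSE)
        df$qcovhsp <- 100 * (qe - qs + 1L) / qlen
        if (df$evalue <= evalue_max) out[[length(out) + 1L]] <- df
      }
    }
    if (!length(out)) return(empty_hits())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
}

blast_engine <- function(program, dbtype, evalue_max, extra_args = character()) {
  if (Sys.which(program) == "" || Sys.which("makeblastdb") == "") {
    stop(program, "/makeblastdb not found on PATH")
  }
  function(queries, subjects) {
    queries <- as_seq_set(queries); subjects <- as_seq_set(subjects)
    td <- tempfile("blast"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    qf <- file.path(td, "q.fa"); sf <- file.path(td, "s.fa")
    hf <- file.path(td, "hits.tsv")
    write_fasta(queries, qf); write_fasta(subjects, sf)
    st <- system2("makeblastdb", c("-in", sf, "-dbtype", dbtype,
                                   "-out", file.path(td, "db")),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0L) stop("makeblastdb failed")
    st <- system2(program,
                  c("-query", qf, "-db", file.path(td, "db"),
                    "-evalue", format(evalue_max), "-outfmt",
                    shQuote(paste("6", paste(HIT_COLUMNS, collapse = " "))),
                    "-out", hf, extra_args),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0L) stop(program, " failed")
    read_tabular_hits(hf)
  }
}

#' BLASTP production aligner engine
#'
#' Shells out to \code{makeblastdb}/\code{blastp} and parses the tabular
#' output. Interchangeable with \code{\link{sw_protein_engine}}.
#'
#' @param evalue_max E-value cutoff passed to blastp.
#' @param threads Number of worker threads.
#' @return An aligner engine function.
#' @export
blast_protein_engine <- function(evalue_max = 10, threads = 1L) {
  blast_engine("blastp", "prot", evalue_max,
               c("-num_threads", threads))
}

#' BLASTN production aligner engine
#'
#' @inheritParams blast_protein_engine
#' @param task blastn task (\code{"blastn"} keeps sensitivity for diverged
#'   references; \code{"megablast"} is faster for near-identical ones).
#' @return An aligner engine function.
#' @export
blast_nucleotide_engine <- function(evalue_max = 10, threads = 1L,
                                    task = "blastn") {
  blast_engine("blastn", "nucl", evalue_max,
               c("-task", task, "-num_threads", threads, "-dust", "no"))
}

#' Pick the default engines
#'
#' Uses BLAST command-line engines when available, otherwise the internal
#' Smith-Waterman engines.
#' @return List with elements \code{protein} and \code{nucleotide}.
#' @export
default_engines <- function() {
  has_blast <- Sys.which("blastp") != "" && Sys.which("makeblastdb") != ""
  list(
    protein = if (has_blast) blast_protein_engine() else sw_protein_engine(),
    nucleotide = if (has_blast) blast_nucleotide_engine() else sw_nucleotide_engine()
  )
}
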