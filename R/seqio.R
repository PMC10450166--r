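#' Read assembled contigs from a FASTA file
#'
#' Reads a (possibly gzip-compressed, multi-line) nucleotide FASTA file into a
#' \code{DNAStringSet}. Sequences are uppercased and \code{U} is mapped to
#' \code{T}; IUPAC ambiguity codes other than \code{N} are converted to
#' \code{N} so that downstream code only ever sees the \code{{A,C,G,T,N}}
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(raw) == 0L) return(Biostrings::DNAStringSet())
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate record id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1L]], "' contains non-nucleotide characters")
  }
  # collapse residual ambiguity codes to N
  seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("record '", ids[which(nchar(seqs) == 0L)[1L]], "' has an empty sequence")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named \code{XStringSet} or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Filter contigs by length
#'
#' Keeps contigs whose length lies inside the closed interval
#' \code{[min_bp, max_bp]} (defaults 1 kb and 350 kb; boundary values are
#' kept). Input order is preserved and the operation is idempotent.
#'
#' @param contigs A \code{DNAStringSet} (or named character vector).
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return The surviving subset, same container type as the input.
#' @export
filter_by_length <- function(contigs, min_bp = 1000L, max_bp = 350000L) {
  stopifnot(min_bp <= max_bp)
  len <- if (is.character(contigs)) nchar(contigs) else Biostrings::width(contigs)
  contigs[len >= min_bp & len <= max_bp]
}

#' Cut a sequence into windows
#'
#' Substrings of length \code{window} starting at offsets
#' \code{0, step, 2*step, ...}. A trailing segment shorter than the window is
#' kept as its own segment when it is longer than \code{window/2}; otherwise
#' it is merged into the previous segment, so no segment is degenerately
#' short. When \code{window >= nchar(seq)} the whole sequence is returned as
#' a single segment. With \code{step == window} (the default) concatenating
#' the segments reconstructs the input exactly.
#'
#' @param seq A single nucleotide (or any) string.
#' @param window Window size in bp.
#' @param step Step between window starts; defaults to \code{window}
#'   (non-overlapping).
#' @return Character vector of segments.
#' @export
segment_sequence <- function(seq, window, step = window) {
  stopifnot(length(seq) == 1L, window >= 1L, step >= 1L)
  n <- nchar(seq)
  if (window >= n) return(seq)
  starts <- seq.int(1L, n, by = step)
  # drop starts that begin past the final full window when overlapping
  segs <- substring(seq, starts, pmin(starts + window - 1L, n))
  tail_len <- nchar(segs[length(segs)])
  if (tail_len < window && length(segs) > 1L && tail_len <= window / 2) {
    # merge the short tail into the previous segment
    segs[length(segs) - 1L] <- substring(seq, starts[length(segs) - 1L], n)
    segs <- segs[-length(segs)]
  }
  segs
}

# ---------------------------------------------------------------------------
# Gene calling
# ---------------------------------------------------------------------------

#' Internal ORF-scanner gene caller
#'
#' Returns a gene-calling engine that scans all six frames for open reading
#' frames using the standard genetic code. Within each stop-to-stop region the
#' ORF runs from the first ATG to the stop (the longest ORF in that region).
#' When \code{allow_partial} is \code{TRUE}, genes truncated by the sequence
#' boundary are also called (no ATG required at the 5' edge, no stop required
#' at the 3' edge), mimicking how production gene callers handle contig
#' fragments. ORFs containing \code{N} are discarded.
#'
#' @param min_orf_nt Minimum ORF length in nucleotides (including the stop
#'   codon when present).
#' @param allow_partial Call edge-truncated genes.
#' @return An engine function \code{function(seq, contig_id)} returning a
#'   protein-record data.frame (see \code{\link{predict_genes}}).
#' @export
orf_engine <- function(min_orf_nt = 60L, allow_partial = TRUE) {
  force(min_orf_nt); force(allow_partial)
  function(seq, contig_id) {
    scan_orfs(seq, contig_id, min_orf_nt = min_orf_nt,
              allow_partial = allow_partial)
  }
}

#' Prodigal gene-calling engine
#'
#' Wraps the \code{prodigal} command-line gene finder (metagenomic mode by
#' default). Requires \code{prodigal} on the PATH; used in production runs,
#' while tests rely on \code{\link{orf_engine}}.
#'
#' @param mode \code{"meta"} or \code{"single"}.
#' @return An engine function compatible with \code{\link{predict_genes}}.
#' @export
prodigal_engine <- function(mode = c("meta", "single")) {
  mode <- match.arg(mode)
  if (Sys.which("prodigal") == "") stop("prodigal not found on PATH")
  function(seq, contig_id) {
    td <- tempfile("prodigal")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    fin <- file.path(td, "in.fna"); faa <- file.path(td, "out.faa")
    write_fasta(stats::setNames(as.character(seq), contig_id), fin)
    status <- system2("prodigal",
                      c("-i", fin, "-a", faa, "-p", mode, "-q",
                        "-o", file.path(td, "out.gbk")),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("prodigal failed on contig ", contig_id)
    aa <- Biostrings::readAAStringSet(faa)
    if (length(aa) == 0L) return(empty_protein_records())
    hdr <- strsplit(names(aa), " # ", fixed = TRUE)
    df <- data.frame(
      contig_id = contig_id,
      index_on_contig = seq_along(aa) - 1L,
      start = as.integer(vapply(hdr, `[`, "", 2L)),
      end = as.integer(vapply(hdr, `[`, "", 3L)),
      strand = ifelse(vapply(hdr, `[`, "", 4L) == "1", "+", "-"),
      aa_seq = sub("\\*$", "", as.character(aa)),
      stringsAsFactors = FALSE
    )
    df[order(df$start), , drop = FALSE]
  }
}

empty_protein_records <- function() {
  data.frame(contig_id = character(), index_on_contig = integer(),
             start = integer(), end = integer(), strand = character(),
             aa_seq = character(), stringsAsFactors = FALSE)
}

revcomp_chr <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

# Scan one contig for ORFs on both strands. Coordinates are 1-based inclusive
# on the forward strand regardless of gene strand.
scan_orfs <- function(seq, contig_id, min_orf_nt = 60L, allow_partial = TRUE) {
  s <- as.character(seq)
  n <- nchar(s)
  if (n < min_orf_nt) return(empty_protein_records())
  starts <- integer(); ends <- integer(); strands <- character()
  peps <- character()
  gc_map <- Biostrings::GENETIC_CODE
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else revcomp_chr(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 2L) next
      cod_start <- frame + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(str_seq, cod_start, cod_start + 2L)
      aa <- unname(gc_map[codons])             # NA for codons with N
      is_stop <- !is.na(aa) & aa == "*"
      # stop-to-stop regions (codon index space)
      bounds <- c(0L, which(is_stop), if (!is_stop[ncod]) ncod + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b] + 1L; hi <- bounds[b + 1L] # hi = stop (or past-end)
        if (hi <= lo) next
        open_left <- bounds[b] == 0L   # region touches 5' edge of this strand
        open_right <- hi == ncod + 1L  # runs off the 3' edge (no stop)
        if (open_right && !allow_partial) next
        cds_last <- if (open_right) ncod else hi - 1L
        atg <- which(codons[lo:cds_last] == "ATG")
        first <- if (length(atg)) lo + atg[1L] - 1L else
          if (open_left && allow_partial) lo else NA_integer_
        if (is.na(first) || first > cds_last) next
        orf_cod <- (if (open_right) cds_last else hi) - first + 1L
        if (orf_cod * 3L < min_orf_nt) next
        pep <- aa[first:cds_last]
        if (anyNA(pep)) next                   # ORF spans N
        p1 <- frame + 3L * (first - 1L) + 1L   # strand coordinates
        # footprint includes the stop codon when present
        p2 <- frame + 3L * (if (open_right) cds_last else hi)
        k <- length(starts) + 1L
        if (strand == "+") {
          starts[k] <- p1; ends[k] <- p2
        } else {
          starts[k] <- n - p2 + 1L; ends[k] <- n - p1 + 1L
        }
        strands[k] <- strand
        peps[k] <- paste(pep, collapse = "")
      }
    }
  }
  if (!length(starts)) return(empty_protein_records())
  df <- data.frame(contig_id = contig_id, index_on_contig = NA_integer_,
                   start = starts, end = ends, strand = strands,
                   aa_seq = peps, stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$index_on_contig <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  df
}

#' Predict protein-coding genes on a contig
#'
#' Gene calling is a pluggable contract: the engine is any function taking a
#' sequence and a contig id and returning protein records. The production
#' engine wraps Prodigal (\code{\link{prodigal_engine}}); the internal
#' three-frame/both-strand ORF scanner (\code{\link{orf_engine}}) keeps tests
#' free of external processes.
#'
#' @param contig A single-element \code{DNAStringSet}, \code{DNAString}, or
#'   character string. A name, if present, becomes the contig id.
#' @param engine A gene-calling engine; default \code{orf_engine()}.
#' @param contig_id Contig id override.
#' @return A data.frame with columns \code{contig_id},
#'   \code{index_on_contig} (0-based, ascending by start), \code{start},
#'   \code{end} (1-based inclusive), \code{strand}, \code{aa_seq}, sorted by
#'   \code{start}.
#' @export
predict_genes <- function(contig, engine = orf_engine(), contig_id = NULL) {
  if (methods::is(contig, "XStringSet")) {
    stopifnot(length(contig) == 1L)
    if (is.null(contig_id)) contig_id <- names(contig)
    contig <- as.character(contig[[1L]])
  }
  contig <- as.character(contig)
  if (is.null(contig_id)) contig_id <- "contig"
  out <- tryCatch(engine(contig, contig_id),
                  error = function(e) stop("gene calling failed on contig '",
                                           contig_id, "': ", conditionMessage(e)))
  stopifnot(!is.unsorted(out$start))
  out
}

#' Export protein records as FASTA
#'
#' Record ids are \code{<contig_id>_<index_on_contig>}.
#'
#' @param proteins Protein-record data.frame from \code{\link{predict_genes}}.
#' @return A named \code{AAStringSet}.
#' @export
proteins_as_fasta <- function(proteins) {
  if (nrow(proteins) == 0L) return(Biostrings::AAStringSet())
  out <- Biostrings::AAStringSet(proteins$aa_seq)
  names(out) <- paste0(proteins$contig_id, "_", proteins$index_on_contig)
  out
}
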