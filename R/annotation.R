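#' Transcript annotation access
#'
#' Transcript models are read from a GTF file plus a genome FASTA, so that
#' protein effect prediction needs no network or annotation service. Only
#' `exon` and `CDS` features are used; a transcript is treated as protein
#' coding iff it has CDS features. The CDS genomic interval is taken as the
#' span of the CDS records (the stop codon is expected to be included in the
#' CDS features, as the toy fixtures and many GTF exports do; a separate
#' `stop_codon` feature, if present, is merged in).
#'
#' @param gtf_path GTF file with gene/transcript/exon/CDS features.
#' @param genome_fasta_path genome FASTA.
#' @return object of class `splice_annotation`: list with `genome`
#'   (DNAStringSet), `transcripts` (named list of transcript models) and
#'   `genes` (gene_id -> transcript ids).
#' @export
read_annotation <- function(gtf_path, genome_fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  txs <- split(seq_along(gr), md$transcript_id)
  transcripts <- lapply(names(txs), function(tid) {
    idx <- txs[[tid]]
    sub <- gr[idx]
    types <- S4Vectors::mcols(sub)$type
    ex <- sub[types == "exon"]
    cds <- sub[types %in% c("CDS", "stop_codon")]
    exons <- cbind(start = GenomicRanges::start(ex),
                   end = GenomicRanges::end(ex))
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    transcript_model(
      transcript_id = tid,
      gene_id = S4Vectors::mcols(sub)$gene_id[1L],
      contig = as.character(GenomicRanges::seqnames(sub))[1L],
      strand = as.character(GenomicRanges::strand(sub))[1L],
      exons = exons,
      cds_interval = if (length(cds))
        c(min(GenomicRanges::start(cds)), max(GenomicRanges::end(cds))))
  })
  names(transcripts) <- names(txs)
  genes <- split(names(transcripts),
                 vapply(transcripts, `[[`, "", "gene_id"))
  structure(list(genome = genome, transcripts = transcripts, genes = genes),
            class = "splice_annotation")
}

#' @export
print.splice_annotation <- function(x, ...) {
  cat(sprintf("<splice_annotation: %d transcripts in %d genes, %d contigs>\n",
              length(x$transcripts), length(x$genes), length(x$genome)))
  invisible(x)
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig,strand location.
#' @param exons integer matrix with columns `start`, `end` (1-based
#'   inclusive, genomic order, non-overlapping).
#' @param cds_interval genomic `c(start, end)` of the coding span including
#'   start and stop codons, or NULL for non-coding transcripts.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds_interval = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L]))
    stop("transcript_model: exon end < start", call. = FALSE)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("transcript_model: overlapping exons", call. = FALSE)
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 contig = as.character(contig),
                 strand = as.character(strand),
                 exons = exons,
                 cds_interval = if (!is.null(cds_interval))
                   as.integer(cds_interval)),
            class = "transcript_model")
}

is_coding <- function(tx) !is.null(tx$cds_interval)

# introns as a donor/acceptor matrix (genomic order)
transcript_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("donor", "acceptor"))))
  cbind(donor = tx$exons[-n, 2L], acceptor = tx$exons[-1L, 1L])
}

# genomic position -> coordinate along the mature (spliced) transcript,
# counted 5' -> 3'; NA if the position is intronic or outside the span
genomic_to_tx <- function(tx, pos) {
  w <- tx$exons[, 2L] - tx$exons[, 1L] + 1L
  off <- cumsum(c(0L, w[-length(w)]))
  hit <- which(pos >= tx$exons[, 1L] & pos <= tx$exons[, 2L])
  if (!length(hit)) return(NA_integer_)
  plus_coord <- off[hit] + (pos - tx$exons[hit, 1L]) + 1L
  if (tx$strand == "+") plus_coord else sum(w) - plus_coord + 1L
}

# mature transcript sequence, 5' -> 3'
spliced_sequence <- function(tx, genome) {
  if (!tx$contig %in% names(genome))
    stop(sprintf("contig '%s' missing from genome", tx$contig),
         call. = FALSE)
  chr <- genome[[tx$contig]]
  parts <- apply(tx$exons, 1L, function(e)
    Biostrings::subseq(chr, e[1L], e[2L]))
  s <- do.call(Biostrings::xscat, parts)
  if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Translate a transcript model
#'
#' Extracts the spliced sequence 5' to 3' (reverse complemented on the minus
#' strand), locates the annotated start codon, and translates with the
#' standard genetic code until the first stop codon. If no stop is reached
#' before the transcript end, the protein is flagged as a stop-loss
#' candidate. Frame is taken from the start codon, so an edited transcript
#' whose CDS is no longer a multiple of three simply reads through in the
#' shifted frame, which is exactly what frameshift classification needs.
#'
#' @param tx a [transcript_model()] with a CDS.
#' @param genome DNAStringSet.
#' @return list with `protein` (character, `*` marks the stop when present)
#'   and `has_stop`; NULL if the start codon is not exonic.
#' @export
translate_transcript <- function(tx, genome) {
  if (!is_coding(tx)) return(NULL)
  start_pos <- if (tx$strand == "+") tx$cds_interval[1L] else
    tx$cds_interval[2L]
  tx_start <- genomic_to_tx(tx, start_pos)
  if (is.na(tx_start)) return(NULL)
  mrna <- spliced_sequence(tx, genome)
  if (tx_start > length(mrna) - 2L) return(NULL)
  cds <- Biostrings::subseq(mrna, tx_start, length(mrna))
  ncod <- length(cds) %/% 3L
  if (ncod < 1L) return(NULL)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::subseq(cds, 1L, ncod * 3L), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(protein = substr(aa, 1L, stop_at), has_stop = TRUE)
  } else {
    list(protein = aa, has_stop = FALSE)
  }
}
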