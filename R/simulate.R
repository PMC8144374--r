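#' Simulate beta-binomial splice-event count tables
#'
#' Generates per-event, per-sample isoform counts under the same generative
#' model the statistical tests assume: for each sample, a latent PSI is
#' drawn from Beta(omega * psi, omega * (1 - psi)), the total depth from the
#' depth model, and the isoform-1 count from Binomial(depth, PSI).
#' Zero-depth draws are kept, exercising the missing-data paths.
#'
#' @param n_events number of events.
#' @param groups list of group specifications, each a list with `label`,
#'   `n_samples`, `psi`; sample names are `{label}_{i}`.
#' @param omega beta concentration (> 2).
#' @param depth mean of the Poisson depth model.
#' @param outlier optional list with `n_samples` and `psi`: extra samples
#'   (named `outlier_{i}`) drawn at a different PSI, for outlier-detection
#'   scenarios.
#' @param seed integer seed; identical seeds give identical tables.
#' @return an [event_count_table()] whose events are distinct synthetic A3
#'   events on contig "1".
#' @export
simulate_counts <- function(n_events, groups, omega, depth, outlier = NULL,
                            seed = 1L) {
  stopifnot(n_events >= 1, omega > 2, depth >= 0)
  for (g in groups)
    if (g$psi <= 0 || g$psi >= 1)
      stop("simulate_counts: psi must be in (0, 1)", call. = FALSE)
  specs <- groups
  if (!is.null(outlier))
    specs <- c(specs, list(list(label = "outlier",
                                n_samples = outlier$n_samples,
                                psi = outlier$psi)))
  samples <- unlist(lapply(specs, function(g)
    paste0(g$label, "_", seq_len(g$n_samples))))
  psi_by_sample <- unlist(lapply(specs, function(g)
    rep(g$psi, g$n_samples)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ns <- length(samples)
  iso1 <- matrix(0L, n_events, ns, dimnames = list(NULL, samples))
  iso2 <- iso1
  for (j in seq_len(ns)) {
    p <- stats::rbeta(n_events, omega * psi_by_sample[j],
                      omega * (1 - psi_by_sample[j]))
    t <- stats::rpois(n_events, depth)
    i <- stats::rbinom(n_events, t, p)
    iso1[, j] <- i
    iso2[, j] <- t - i
  }
  events <- lapply(seq_len(n_events), function(k) {
    base <- 1000L + 500L * k
    splice_event(sprintf("sim_%05d", k), sprintf("SIMG%05d", k), "1", "+",
                 "A3",
                 matrix(c(base, base + 200L), ncol = 2),
                 matrix(c(base, base + 230L), ncol = 2))
  })
  event_count_table(events, iso1, iso2)
}

# ---- toy genome / annotation fixtures -------------------------------------

# codon filler without stop codons; cycles a fixed pool deterministically
safe_codons <- function(n, phase = 0L) {
  pool <- c("GCT", "GAA", "CTG", "AAA", "GAT", "TTC", "GGT", "CAT", "ATT",
            "CTT", "CCA", "AGA", "ACC", "GTG", "AGC", "CAG", "ATG", "GAC")
  paste(pool[((seq_len(n) - 1L + phase) %% length(pool)) + 1L],
        collapse = "")
}

# stop codons in all three frames, used as 3' UTR so frameshifted reading
# always terminates within the transcript
UTR3_ALLFRAME <- strrep("TAAC", 8L)

# a 3' UTR with no stop codon in frame 0, for stop-loss designs
UTR3_NOSTOP <- strrep("GGC", 20L)

toy_effect_designs <- function() {
  list(
    list(event_type = "ES", effect_cat = "Deletion", cassette = 102L),
    list(event_type = "ES", effect_cat = "FrameDisruption", cassette = 103L),
    list(event_type = "ES", effect_cat = "Truncation"),
    list(event_type = "ES", effect_cat = "StopLoss"),
    list(event_type = "ES", effect_cat = "NonCoding"),
    list(event_type = "IR", effect_cat = "Insertion", intron_len = 30L),
    list(event_type = "IR", effect_cat = "FrameDisruption", intron_len = 31L),
    list(event_type = "IR", effect_cat = "Truncation", intron_len = 30L),
    list(event_type = "A3", effect_cat = "Insertion", shift = 9L),
    list(event_type = "A3", effect_cat = "FrameDisruption", shift = 14L),
    list(event_type = "A5", effect_cat = "Deletion", shift = 12L),
    list(event_type = "A5", effect_cat = "FrameDisruption", shift = 8L),
    list(event_type = "MX", effect_cat = "Deletion", alt_exon = 24L),
    list(event_type = "MX", effect_cat = "Insertion", alt_exon = 36L),
    list(event_type = "MX", effect_cat = "FrameDisruption", alt_exon = 25L))
}

#' Supported toy-fixture effect catalog
#'
#' The (event type, effect category) combinations that
#' [make_toy_annotation()] can realize.
#'
#' @return data.frame with `event_type` and `effect_cat`.
#' @export
toy_effect_catalog <- function() {
  d <- toy_effect_designs()
  data.frame(event_type = vapply(d, `[[`, "", "event_type"),
             effect_cat = vapply(d, `[[`, "", "effect_cat"),
             stringsAsFactors = FALSE)
}

# Build one gene in sense-space: returns list of segments (exon/intron with
# sequence), the sense-local event description, CDS sense interval, and the
# expected annotation row. All designs keep the annotated transcript equal
# to isoform 1 of the event.
toy_gene_design <- function(event_type, effect_cat, params) {
  seg <- function(kind, seq) list(kind = kind, seq = seq)
  utr5 <- "ACGTACGTACGT"                     # 12 nt, no ATG
  intron <- function(n, phase = 5L) {
    body <- safe_codons(ceiling((n - 4L) / 3) + 2L, phase)
    paste0("GT", substr(body, 1L, n - 4L), "AG")
  }
  # atg_exon: which exon (sense order) carries the start codon, always 12 nt
  # (the 5' UTR stub) into that exon
  out <- list(event_type = event_type, effect_cat = effect_cat,
              atg_exon = 1L)
  if (event_type == "ES") {
    if (effect_cat %in% c("Deletion", "FrameDisruption")) {
      clen <- params$cassette
      e1 <- paste0(utr5, "ATG", safe_codons(30L))          # CDS phase 0 end
      cassette <- if (clen %% 3L == 0L) safe_codons(clen %/% 3L, 3L)
        else paste0(safe_codons(clen %/% 3L, 3L),
                    substr("G", 1L, clen %% 3L))
      e3 <- paste0(safe_codons(30L, 7L), "TAA", UTR3_ALLFRAME)
      segs <- list(seg("exon", e1), seg("intron", intron(60L)),
                   seg("exon", cassette), seg("intron", intron(60L, 9L)),
                   seg("exon", e3))
      out$expected_alt_empty <- effect_cat == "Deletion"
      out$aa_change_type <- if (effect_cat == "Deletion") "Known" else "Novel"
    } else if (effect_cat == "Truncation") {
      # cassette starts mid-codon after "TA"; skipping juxtaposes "TA" with
      # the "A" opening the downstream exon -> TAA stop, frame preserved
      e1 <- paste0(utr5, "ATG", safe_codons(20L), "TA")
      cassette <- paste0("C", safe_codons(33L, 2L), "CA")   # 102 nt
      e3 <- paste0("A", safe_codons(20L, 11L), "TAA", UTR3_ALLFRAME)
      segs <- list(seg("exon", e1), seg("intron", intron(55L)),
                   seg("exon", cassette), seg("intron", intron(55L, 4L)),
                   seg("exon", e3))
      out$aa_change_type <- "Known"   # altered run is the bare stop "*"
    } else if (effect_cat == "StopLoss") {
      # annotated stop lives inside the cassette; downstream exon is a UTR
      # with no frame-0 stop, so the skip reads through to the transcript end
      e1 <- paste0(utr5, "ATG", safe_codons(24L))
      cassette <- paste0(safe_codons(11L, 6L), "TAA")       # 36 nt
      e3 <- UTR3_NOSTOP
      segs <- list(seg("exon", e1), seg("intron", intron(50L)),
                   seg("exon", cassette), seg("intron", intron(50L, 4L)),
                   seg("exon", e3))
      out$aa_change_type <- "Novel"
    } else if (effect_cat == "NonCoding") {
      e1 <- "ACGTACGTACGTACGTACGTACGT"                      # UTR exon
      cassette <- "CCATTGGATCCATTGGATCCATTGGATCGA"          # UTR exon, 30 nt
      e3 <- paste0(utr5, "ATG", safe_codons(40L), "TAA", UTR3_ALLFRAME)
      segs <- list(seg("exon", e1), seg("intron", intron(48L)),
                   seg("exon", cassette), seg("intron", intron(48L, 4L)),
                   seg("exon", e3))
      out$atg_exon <- 3L
      out$aa_change_type <- "Known"
    }
    out$segs <- segs
  } else if (event_type == "IR") {
    ilen <- params$intron_len
    # intron at a codon boundary; tryptophan codons (absent from the filler
    # pool) make retained-intron peptides recognizably novel
    iseq <- if (effect_cat == "Truncation") {
      paste0(strrep("TGG", 3L), "TAA", strrep("TGG", 6L))   # 30 nt, WWW*
    } else if (ilen %% 3L == 0L) {
      strrep("TGG", ilen %/% 3L)
    } else {
      substr(strrep("TGG", ilen %/% 3L + 1L), 1L, ilen)
    }
    e1 <- paste0(utr5, "ATG", safe_codons(25L))
    e2 <- paste0(safe_codons(25L, 9L), "TAA", UTR3_ALLFRAME)
    segs <- list(seg("exon", e1), seg("intron", iseq), seg("exon", e2))
    out$segs <- segs
    out$aa_change_type <- "Novel"
  } else if (event_type == "A3") {
    k <- params$shift
    # iso2 acceptor is k bases upstream: the last k intron bases become
    # exonic; tryptophan codons make the insertion distinctive
    tail_seq <- if (k %% 3L == 0L) strrep("TGG", k %/% 3L)
      else substr(strrep("TGG", k %/% 3L + 1L), 1L, k)
    iseq <- paste0("GT", safe_codons(15L, 5L), "AG", tail_seq)
    e1 <- paste0(utr5, "ATG", safe_codons(25L))
    e2 <- paste0(safe_codons(25L, 9L), "TAA", UTR3_ALLFRAME)
    segs <- list(seg("exon", e1), seg("intron", iseq), seg("exon", e2))
    out$segs <- segs
    out$a3_shift <- k
    out$aa_change_type <- "Novel"
  } else if (event_type == "A5") {
    k <- params$shift
    # iso2 donor is k bases upstream: the last k exon-1 bases become intronic
    e1 <- paste0(utr5, "ATG", safe_codons(25L))
    iseq <- paste0("GT", safe_codons(15L, 5L), "AG")
    e2 <- paste0(safe_codons(25L, 9L), "TAA", UTR3_ALLFRAME)
    segs <- list(seg("exon", e1), seg("intron", iseq), seg("exon", e2))
    out$segs <- segs
    out$a5_shift <- k
    out$aa_change_type <- if (k %% 3L == 0L) "Known" else "Novel"
  } else if (event_type == "MX") {
    blen <- params$alt_exon
    e1 <- paste0(utr5, "ATG", safe_codons(22L))
    ma <- strrep("GAT", 10L)                                # 30 nt, DDDD...
    mb <- if (blen %% 3L == 0L) strrep("TGG", blen %/% 3L)
      else substr(strrep("TGG", blen %/% 3L + 1L), 1L, blen)
    e3 <- paste0(safe_codons(22L, 9L), "TAA", UTR3_ALLFRAME)
    segs <- list(seg("exon", e1), seg("intron", intron(40L)),
                 seg("exon", ma), seg("intron_mx", mb),
                 seg("exon_hidden", NULL), seg("intron", intron(40L, 4L)),
                 seg("exon", e3))
    out$segs <- segs
    out$aa_change_type <- "Novel"
  }
  out
}

# lay out one designed gene at `offset` on `contig`, honoring strand;
# returns locus sequence, transcript model rows, splice event, expected row
place_toy_gene <- function(design, gene_id, tx_id, contig, strand, offset) {
  # sense-space assembly -----------------------------------------------------
  if (design$event_type == "MX") {
    # assemble explicitly: E1 - i1 - MA - gap - MB - gap - i2 - E3 with MB
    # intronic in the annotated transcript
    segs <- design$segs
    e1 <- segs[[1L]]$seq; i1 <- segs[[2L]]$seq; ma <- segs[[3L]]$seq
    mb <- segs[[4L]]$seq; i2 <- segs[[6L]]$seq; e3 <- segs[[7L]]$seq
    gap1 <- "GTCCTTCCAG"; gap2 <- "GTGGATTCAG"
    locus <- paste0(e1, i1, ma, gap1, mb, gap2, i2, e3)
    p <- cumsum(nchar(c(e1, i1, ma, gap1, mb, gap2, i2, e3)))
    exons_sense <- rbind(c(1L, p[1L]), c(p[2L] + 1L, p[3L]),
                         c(p[6L] + 1L + nchar(i2), p[8L]))
    mb_sense <- c(p[4L] + 1L, p[5L])
    iso1_sense <- rbind(c(p[1L], p[2L] + 1L),          # (donor, acceptor)
                        c(p[3L], p[7L] + 1L))
    iso2_sense <- rbind(c(p[1L], mb_sense[1L]),
                        c(mb_sense[2L], p[7L] + 1L))
  } else {
    segs <- design$segs
    seqs <- vapply(segs, `[[`, "", "seq")
    kinds <- vapply(segs, `[[`, "", "kind")
    locus <- paste(seqs, collapse = "")
    ends <- cumsum(nchar(seqs))
    starts <- c(1L, ends[-length(ends)] + 1L)
    exons_sense <- cbind(starts[kinds == "exon"], ends[kinds == "exon"])
    intr_idx <- which(kinds == "intron")
    introns_sense <- cbind(starts[intr_idx], ends[intr_idx])
    if (design$event_type == "ES") {
      iso1_sense <- rbind(c(introns_sense[1L, 1L] - 1L,
                            introns_sense[1L, 2L] + 1L),
                          c(introns_sense[2L, 1L] - 1L,
                            introns_sense[2L, 2L] + 1L))
      iso2_sense <- rbind(c(introns_sense[1L, 1L] - 1L,
                            introns_sense[2L, 2L] + 1L))
    } else if (design$event_type == "IR") {
      iso1_sense <- rbind(c(introns_sense[1L, 1L] - 1L,
                            introns_sense[1L, 2L] + 1L))
      iso2_sense <- NULL
    } else if (design$event_type == "A3") {
      d <- introns_sense[1L, 1L] - 1L
      a1 <- introns_sense[1L, 2L] + 1L
      iso1_sense <- rbind(c(d, a1))
      iso2_sense <- rbind(c(d, a1 - design$a3_shift))
    } else if (design$event_type == "A5") {
      d1 <- introns_sense[1L, 1L] - 1L
      a <- introns_sense[1L, 2L] + 1L
      iso1_sense <- rbind(c(d1, a))
      iso2_sense <- rbind(c(d1 - design$a5_shift, a))
    }
  }
  L <- nchar(locus)
  # sense CDS interval: the start codon sits 12 nt (the 5' UTR stub) into
  # its designated exon; the stop is found by translating the spliced frame
  cds_start_local <- exons_sense[design$atg_exon, 1L] + 12L
  spl <- splice_sense_seq(locus, exons_sense)
  # find stop in the spliced frame to set the sense CDS end
  cds_tx <- sense_to_tx(exons_sense, cds_start_local)
  aa <- translate_string(substr(spl, cds_tx, nchar(spl)))
  stop_i <- as.integer(regexpr("*", aa, fixed = TRUE))
  cds_end_tx <- cds_tx + stop_i * 3L - 1L
  cds_end_local <- tx_to_sense(exons_sense, cds_end_tx)
  cds_sense <- c(cds_start_local, cds_end_local)

  if (strand == "+") {
    flip <- function(x) offset + x
    gseq <- locus
    exons <- cbind(flip(exons_sense[, 1L]), flip(exons_sense[, 2L]))
    jmap <- function(j) if (is.null(j)) NULL else
      cbind(flip(j[, 1L]), flip(j[, 2L]))
    cds <- sort(flip(cds_sense))
  } else {
    flip <- function(x) offset + (L - x + 1L)
    gseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(locus)))
    exons <- cbind(flip(exons_sense[, 2L]), flip(exons_sense[, 1L]))
    # sense junction (donor, acceptor) -> genomic (flip(acceptor), flip(donor))
    jmap <- function(j) if (is.null(j)) NULL else
      cbind(flip(j[, 2L]), flip(j[, 1L]))
    cds <- sort(flip(cds_sense))
  }
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  j1 <- as_junction_matrix(jmap(iso1_sense))
  j2 <- if (is.null(iso2_sense)) matrix(integer(0), ncol = 2) else
    as_junction_matrix(jmap(iso2_sense))
  ev <- splice_event(paste0("toy_", gene_id), gene_id, contig, strand,
                     design$event_type, j1, j2)
  tx <- transcript_model(tx_id, gene_id, contig, strand, exons, cds)
  list(sequence = gseq, event = ev, transcript = tx,
       expected = data.frame(event_id = ev$event_id, gene_id = gene_id,
                             strand = strand,
                             event_type = design$event_type,
                             event_cat = EVENT_CAT[[design$event_type]],
                             effect_cat = design$effect_cat,
                             aa_change_type = design$aa_change_type,
                             stringsAsFactors = FALSE))
}

splice_sense_seq <- function(locus, exons_sense) {
  paste(vapply(seq_len(nrow(exons_sense)), function(i)
    substr(locus, exons_sense[i, 1L], exons_sense[i, 2L]), ""),
    collapse = "")
}

sense_to_tx <- function(exons_sense, pos) {
  w <- exons_sense[, 2L] - exons_sense[, 1L] + 1L
  off <- cumsum(c(0L, w[-length(w)]))
  hit <- which(pos >= exons_sense[, 1L] & pos <= exons_sense[, 2L])
  off[hit] + (pos - exons_sense[hit, 1L]) + 1L
}

tx_to_sense <- function(exons_sense, txpos) {
  w <- exons_sense[, 2L] - exons_sense[, 1L] + 1L
  off <- cumsum(c(0L, w[-length(w)]))
  hit <- max(which(off < txpos))
  exons_sense[hit, 1L] + (txpos - off[hit]) - 1L
}

translate_string <- function(s) {
  n <- (nchar(s) %/% 3L) * 3L
  if (n < 3L) return("")
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, n)), if.fuzzy.codon = "X")))
}

#' Generate a toy genome, annotation and expected effects
#'
#' Builds a small synthetic genome (one contig, well under 100 kb) carrying
#' one gene per requested (event type, effect category) combination, genes
#' alternating between the two strands, plus matching GTF transcript
#' models, a count-table skeleton with one event per gene, and the effect
#' annotation each event is constructed to produce. Running
#' [annotate_events()] on the fixture must reproduce the expected table
#' exactly; this closes the loop on the whole protein-effect pipeline.
#'
#' @param catalog data.frame with `event_type` and `effect_cat` columns
#'   (default: the full supported catalog, [toy_effect_catalog()]).
#' @param outdir optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `counts.tsv` and `expected_effects.tsv` there.
#' @return list with `genome_fasta`, `gtf`, `annotation`
#'   (a ready [read_annotation()]-shaped object), `counts`
#'   (an [event_count_table()] skeleton) and `expected` (data.frame).
#' @export
make_toy_annotation <- function(catalog = toy_effect_catalog(),
                                outdir = NULL) {
  designs <- toy_effect_designs()
  key <- function(t, e) paste(t, e, sep = ":")
  by_key <- stats::setNames(designs, vapply(designs, function(d)
    key(d$event_type, d$effect_cat), ""))
  contig <- "toy1"
  offset <- 0L
  spacer <- strrep("ACGT", 50L)
  seqs <- character(0)
  events <- list(); txs <- list(); expected <- list()
  for (i in seq_len(nrow(catalog))) {
    k <- key(catalog$event_type[i], catalog$effect_cat[i])
    d <- by_key[[k]]
    if (is.null(d))
      stop(sprintf("make_toy_annotation: unsupported combination %s", k),
           call. = FALSE)
    params <- d
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("TOYG%02d", i)
    tx_id <- sprintf("TOYT%02d", i)
    offset <- offset + nchar(spacer)
    seqs <- c(seqs, spacer)
    g <- place_toy_gene(toy_gene_design(d$event_type, d$effect_cat, params),
                        gene_id, tx_id, contig, strand, offset)
    seqs <- c(seqs, g$sequence)
    offset <- offset + nchar(g$sequence)
    events[[length(events) + 1L]] <- g$event
    txs[[tx_id]] <- g$transcript
    expected[[length(expected) + 1L]] <- g$expected
  }
  seqs <- c(seqs, spacer)
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(seqs, collapse = ""), contig))
  annotation <- structure(
    list(genome = genome, transcripts = txs,
         genes = split(names(txs),
                       vapply(txs, `[[`, "", "gene_id"))),
    class = "splice_annotation")
  samples <- c("s1", "s2", "s3")
  iso1 <- matrix(8L, length(events), length(samples),
                 dimnames = list(NULL, samples))
  iso2 <- matrix(2L, length(events), length(samples),
                 dimnames = list(NULL, samples))
  counts <- event_count_table(events, iso1, iso2)
  expected <- do.call(rbind, expected)
  rownames(expected) <- NULL
  out <- list(genome = genome, annotation = annotation, counts = counts,
              expected = expected)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa)
    gtf <- file.path(outdir, "annotation.gtf")
    write_toy_gtf(txs, gtf)
    write_count_table(counts, file.path(outdir, "counts.tsv"))
    utils::write.table(expected, file.path(outdir, "expected_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$genome_fasta <- fa
    out$gtf <- gtf
  }
  out
}

# minimal GTF emitter for the toy transcript models (exon + CDS features,
# stop codon included in the CDS)
write_toy_gtf <- function(txs, path) {
  lines <- character(0)
  for (tx in txs) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    for (i in seq_len(nrow(tx$exons)))
      lines <- c(lines, paste(tx$contig, "toy", "exon",
                              tx$exons[i, 1L], tx$exons[i, 2L], ".",
                              tx$strand, ".", attrs, sep = "\t"))
    if (is_coding(tx)) {
      cds <- IRanges::IRanges(tx$cds_interval[1L], tx$cds_interval[2L])
      ex <- IRanges::IRanges(tx$exons[, 1L], tx$exons[, 2L])
      cdsx <- IRanges::intersect(ex, cds)
      for (i in seq_along(cdsx))
        lines <- c(lines, paste(tx$contig, "toy", "CDS",
                                IRanges::start(cdsx)[i],
                                IRanges::end(cdsx)[i], ".",
                                tx$strand, "0", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
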