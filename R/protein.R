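#' @name protein_effects
#' @title Protein-level effect prediction for splice events
#'
#' @description
#' Each event isoform is matched against the annotated protein-coding
#' transcripts of its gene by comparing event junctions to transcript intron
#' boundaries. For every matching transcript, the matched isoform's
#' junctions are swapped for the other isoform's to build the alternative
#' transcript, both are translated from the annotated start codon, and the
#' altered amino-acid run is localized and classified. One sequence pair per
#' event is selected by (1) pairs of known transcripts first, (2) longest
#' altered amino-acid sequence, (3) longest starting isoform sequence, with
#' a final lexicographic tie-break on transcript id.
NULL

EVENT_CAT <- c(ES = "ExonSkip", IR = "IntronRetention", A3 = "Alt3",
               A5 = "Alt5", MX = "MutExons")

has_intron <- function(introns, donor, acceptor) {
  any(introns[, "donor"] == donor & introns[, "acceptor"] == acceptor)
}

exon_containing <- function(exons, start, end) {
  which(exons[, "start"] <= start & exons[, "end"] >= end)
}

# does the transcript realize the given isoform of the event?
matches_isoform <- function(tx, event, iso) {
  jx <- if (iso == 1L) event$iso1_junctions else event$iso2_junctions
  introns <- transcript_introns(tx)
  span <- c(tx$exons[1L, "start"], tx$exons[nrow(tx$exons), "end"])
  if (event$event_type == "IR" && iso == 2L) {
    # retained interval (and its flanking bases) inside a single exon
    d <- event$iso1_junctions[1L, "donor"]
    a <- event$iso1_junctions[1L, "acceptor"]
    return(length(exon_containing(tx$exons, d, a)) > 0L)
  }
  if (!nrow(jx)) return(FALSE)
  if (any(jx < span[1L]) || any(jx > span[2L])) return(FALSE)
  for (r in seq_len(nrow(jx)))
    if (!has_intron(introns, jx[r, "donor"], jx[r, "acceptor"]))
      return(FALSE)
  # the region between consecutive event junctions must be one exact exon
  # (the cassette / mutually exclusive exon)
  if (nrow(jx) == 2L) {
    a1 <- jx[1L, "acceptor"]; d2 <- jx[2L, "donor"]
    hit <- which(tx$exons[, "start"] == a1 & tx$exons[, "end"] == d2)
    if (!length(hit)) return(FALSE)
  }
  TRUE
}

#' Match event isoforms to annotated transcripts
#'
#' Classifies every protein-coding transcript of the event's gene as
#' matching isoform 1, isoform 2, or neither. A transcript matches an
#' isoform iff each of the isoform's junctions coincides with one of the
#' transcript's intron boundary pairs (and, for two-junction isoforms, the
#' enclosed exon is present exactly); for intron retention, isoform 2
#' matches when the retained interval lies inside a single exon.
#'
#' @param event a [splice_event()].
#' @param annotation a [read_annotation()] object.
#' @return data.frame with `transcript_id` and `matches` in
#'   `{"iso1", "iso2", "neither"}`, ordered by transcript id; zero rows if
#'   the gene is absent.
#' @export
match_transcripts <- function(event, annotation) {
  tids <- annotation$genes[[event$gene_id]]
  tids <- sort(tids[vapply(annotation$transcripts[tids], is_coding, TRUE)])
  if (!length(tids))
    return(data.frame(transcript_id = character(0), matches = character(0),
                      stringsAsFactors = FALSE))
  matches <- vapply(tids, function(tid) {
    tx <- annotation$transcripts[[tid]]
    if (tx$contig != event$contig || tx$strand != event$strand)
      return("neither")
    if (matches_isoform(tx, event, 1L)) "iso1"
    else if (matches_isoform(tx, event, 2L)) "iso2"
    else "neither"
  }, "")
  data.frame(transcript_id = tids, matches = unname(matches),
             stringsAsFactors = FALSE)
}

#' Swap event junctions within a transcript
#'
#' Removes the `from_iso` junctions from the transcript's intron chain and
#' inserts the `to_iso` junctions, then rebuilds the exon chain from the
#' transcript span and the edited intron set. All other introns are
#' untouched, so applying the inverse edit restores the original transcript
#' exactly. Returns NULL when the edit would produce an inconsistent exon
#' chain (overlapping or empty exons), which callers downgrade to an
#' Unknown effect.
#'
#' @param tx a [transcript_model()] matching `from_iso`.
#' @param event a [splice_event()].
#' @param from_iso,to_iso 1 or 2.
#' @return edited [transcript_model()] (same CDS anchor), or NULL.
#' @export
apply_splice <- function(tx, event, from_iso, to_iso) {
  stopifnot(from_iso %in% 1:2, to_iso %in% 1:2, from_iso != to_iso)
  jx_from <- if (from_iso == 1L) event$iso1_junctions else event$iso2_junctions
  jx_to <- if (to_iso == 1L) event$iso1_junctions else event$iso2_junctions
  introns <- transcript_introns(tx)
  keep <- rep(TRUE, nrow(introns))
  for (r in seq_len(nrow(jx_from))) {
    hit <- which(introns[, "donor"] == jx_from[r, "donor"] &
                 introns[, "acceptor"] == jx_from[r, "acceptor"])
    if (!length(hit)) return(NULL)
    keep[hit] <- FALSE
  }
  new_introns <- rbind(introns[keep, , drop = FALSE], jx_to)
  new_introns <- new_introns[order(new_introns[, "donor"]), , drop = FALSE]
  span <- c(tx$exons[1L, "start"], tx$exons[nrow(tx$exons), "end"])
  if (nrow(new_introns)) {
    if (any(new_introns[, "donor"] < span[1L]) ||
        any(new_introns[, "acceptor"] > span[2L])) return(NULL)
    # introns must be disjoint and ordered with non-empty exons between
    if (nrow(new_introns) > 1L) {
      d <- new_introns[-1L, "donor"]
      a <- new_introns[-nrow(new_introns), "acceptor"]
      if (any(d < a)) return(NULL)
    }
    starts <- c(span[1L], new_introns[, "acceptor"])
    ends <- c(new_introns[, "donor"], span[2L])
  } else {
    starts <- span[1L]; ends <- span[2L]
  }
  if (any(ends < starts)) return(NULL)
  transcript_model(paste0(tx$transcript_id, ".edit"),
                   tx$gene_id, tx$contig, tx$strand,
                   cbind(start = starts, end = ends), tx$cds_interval)
}

#' Localize the altered amino-acid run
#'
#' The reference and alternative proteins are identical outside one
#' contiguous edit by construction, so the altered region is found exactly
#' by trimming the longest common prefix and the longest common suffix
#' (suffix trimming is bounded so it never overlaps the prefix). A common
#' suffix consisting solely of the terminal stop `*` is not trimmed: when
#' the residues before the stop differ, the stop belongs to the altered
#' run (a frameshifted or truncated protein reports its novel tail through
#' the new stop).
#'
#' @param ref_protein,alt_protein protein strings (`*` marks the stop).
#' @return list with `refSeqPos`, `altSeqPos` (1-based inclusive
#'   `c(start, end)`; `end = start - 1` denotes an empty side) and
#'   `refPept`, `altPept`. Identical proteins yield empty peptides.
#' @export
localize_alteration <- function(ref_protein, alt_protein) {
  r <- strsplit(ref_protein, "")[[1L]]
  a <- strsplit(alt_protein, "")[[1L]]
  nr <- length(r); na <- length(a)
  if (identical(r, a))
    return(list(refSeqPos = c(1L, 0L), altSeqPos = c(1L, 0L),
                refPept = "", altPept = ""))
  nmin <- min(nr, na)
  lcp <- 0L
  while (lcp < nmin && r[lcp + 1L] == a[lcp + 1L]) lcp <- lcp + 1L
  max_lcs <- nmin - lcp
  lcs <- 0L
  while (lcs < max_lcs && r[nr - lcs] == a[na - lcs]) lcs <- lcs + 1L
  # keep a bare shared "*" inside the altered run
  if (lcs > 0L && all(r[(nr - lcs + 1L):nr] == "*")) lcs <- 0L
  list(refSeqPos = c(lcp + 1L, nr - lcs),
       altSeqPos = c(lcp + 1L, na - lcs),
       refPept = paste(r[seq_len(nr - lcs)][-seq_len(lcp)], collapse = ""),
       altPept = paste(a[seq_len(na - lcs)][-seq_len(lcp)], collapse = ""))
}

#' Classify the protein-level effect
#'
#' @param ref_protein,alt_protein translated proteins.
#' @param delta_nt spliced CDS length change (alt minus ref, bases within
#'   the annotated CDS interval).
#' @param cds_overlap does the edited genomic region intersect the CDS?
#' @param alt_has_stop did the alternative translation reach a stop codon?
#' @param altPept altered peptide from [localize_alteration()].
#' @return one of "Silent", "Insertion", "Deletion", "FrameDisruption",
#'   "Truncation", "StopLoss", "NonCoding".
#' @export
classify_effect <- function(ref_protein, alt_protein, delta_nt, cds_overlap,
                            alt_has_stop, altPept) {
  if (!cds_overlap) return("NonCoding")
  if (identical(ref_protein, alt_protein)) return("Silent")
  if (delta_nt %% 3L != 0L) return("FrameDisruption")
  if (!alt_has_stop) return("StopLoss")
  nref <- nchar(ref_protein); nalt <- nchar(alt_protein)
  if (grepl("*", altPept, fixed = TRUE)) {
    if (nalt < nref) return("Truncation")
    if (nalt > nref) return("StopLoss")
  }
  if (nalt < nref) "Deletion" else "Insertion"
}

novelty_call <- function(altPept, canonical) {
  if (!nzchar(altPept)) return("Known")
  if (any(vapply(canonical, function(p)
    grepl(altPept, p, fixed = TRUE), TRUE))) "Known" else "Novel"
}

unknown_effect_row <- function(event, reason = "no matching transcript") {
  data.frame(event_jid = make_event_jid(event),
             event_cat = EVENT_CAT[[event$event_type]],
             effect_cat = "Unknown", aa_change_type = "Unknown",
             group_increased_alt = NA_character_,
             ref_seq_header = NA_character_, alt_seq_header = NA_character_,
             refSeqPos = NA_character_, altSeqPos = NA_character_,
             refPept = NA_character_, altPept = NA_character_,
             stringsAsFactors = FALSE)
}

# which event region changes between the two isoforms, as an IRanges union
edited_region <- function(ref_tx, alt_tx) {
  r <- IRanges::IRanges(ref_tx$exons[, "start"], ref_tx$exons[, "end"])
  a <- IRanges::IRanges(alt_tx$exons[, "start"], alt_tx$exons[, "end"])
  IRanges::union(IRanges::setdiff(r, a), IRanges::setdiff(a, r))
}

cds_len <- function(tx) {
  cds <- IRanges::IRanges(tx$cds_interval[1L], tx$cds_interval[2L])
  ex <- IRanges::IRanges(tx$exons[, "start"], tx$exons[, "end"])
  sum(IRanges::width(IRanges::intersect(ex, cds)))
}

#' Predict the protein effect of one splice event
#'
#' Runs the full per-event pipeline: transcript matching, junction swap,
#' translation, alteration localization, classification, novelty call and
#' candidate prioritization. Failures (no matching transcript, inconsistent
#' edit, lost start codon) downgrade to an Unknown effect instead of
#' erroring.
#'
#' @param event a [splice_event()].
#' @param annotation a [read_annotation()] object.
#' @param stats_row optional one-row slice of a [diff_test()] result for
#'   this event, used to fill `group_increased_alt` for the isoform chosen
#'   as alternative.
#' @return list with `row` (one-row data.frame in the output schema),
#'   `ref_protein`, `alt_protein` (NULL when Unknown) and `novel` flag.
#' @export
predict_protein_effect <- function(event, annotation, stats_row = NULL) {
  mt <- match_transcripts(event, annotation)
  hit <- mt[mt$matches != "neither", , drop = FALSE]
  if (!nrow(hit))
    return(list(row = unknown_effect_row(event), ref_protein = NULL,
                alt_protein = NULL, novel = FALSE))
  canonical <- lapply(mt$transcript_id, function(tid) {
    tr <- translate_transcript(annotation$transcripts[[tid]],
                               annotation$genome)
    if (is.null(tr)) "" else tr$protein
  })
  known2 <- any(mt$matches == "iso2"); known1 <- any(mt$matches == "iso1")
  candidates <- list()
  for (r in seq_len(nrow(hit))) {
    tid <- hit$transcript_id[r]
    from_iso <- if (hit$matches[r] == "iso1") 1L else 2L
    to_iso <- 3L - from_iso
    tx <- annotation$transcripts[[tid]]
    alt_tx <- apply_splice(tx, event, from_iso, to_iso)
    if (is.null(alt_tx)) next
    ref_tr <- translate_transcript(tx, annotation$genome)
    alt_tr <- translate_transcript(alt_tx, annotation$genome)
    if (is.null(ref_tr) || is.null(alt_tr)) next
    loc <- localize_alteration(ref_tr$protein, alt_tr$protein)
    cds <- IRanges::IRanges(tx$cds_interval[1L], tx$cds_interval[2L])
    overlap <- IRanges::overlapsAny(edited_region(tx, alt_tx), cds)
    effect <- classify_effect(ref_tr$protein, alt_tr$protein,
                              cds_len(alt_tx) - cds_len(tx),
                              any(overlap), alt_tr$has_stop, loc$altPept)
    candidates[[length(candidates) + 1L]] <- list(
      transcript_id = tid, from_iso = from_iso, to_iso = to_iso,
      known_pair = if (to_iso == 2L) known2 else known1,
      ref_protein = ref_tr$protein, alt_protein = alt_tr$protein,
      loc = loc, effect = effect)
  }
  if (!length(candidates))
    return(list(row = unknown_effect_row(event), ref_protein = NULL,
                alt_protein = NULL, novel = FALSE))
  ord <- order(-vapply(candidates, function(c) as.integer(c$known_pair), 0L),
               -vapply(candidates, function(c) nchar(c$loc$altPept), 0L),
               -vapply(candidates, function(c) nchar(c$ref_protein), 0L),
               vapply(candidates, `[[`, "", "transcript_id"))
  best <- candidates[[ord[1L]]]
  aa_change <- if (best$effect %in% c("Silent", "NonCoding")) "Known" else
    novelty_call(best$loc$altPept, canonical)
  gia <- NA_character_
  if (!is.null(stats_row) && nrow(stats_row) == 1L &&
      !is.na(stats_row$psi_group1) && !is.na(stats_row$psi_group2)) {
    labs <- c(stats_row$group_label1, stats_row$group_label2)
    psi_alt <- if (best$to_iso == 1L)
      c(stats_row$psi_group1, stats_row$psi_group2)
    else c(1 - stats_row$psi_group1, 1 - stats_row$psi_group2)
    gia <- labs[which.max(psi_alt)]
  }
  from_str <- junctions_to_string(
    if (best$from_iso == 1L) event$iso1_junctions else event$iso2_junctions,
    if (best$from_iso == 2L) event$ir_interval)
  to_str <- junctions_to_string(
    if (best$to_iso == 1L) event$iso1_junctions else event$iso2_junctions,
    if (best$to_iso == 2L) event$ir_interval)
  pos_str <- function(p) if (p[2L] < p[1L]) sprintf("%d-%d", p[1L], p[2L])
    else sprintf("%d-%d", p[1L], p[2L])
  row <- data.frame(
    event_jid = make_event_jid(event),
    event_cat = EVENT_CAT[[event$event_type]],
    effect_cat = best$effect,
    aa_change_type = aa_change,
    group_increased_alt = gia,
    ref_seq_header = paste0("en|", best$transcript_id),
    alt_seq_header = paste0("en|", best$transcript_id, ":g.",
                            from_str, ">", to_str),
    refSeqPos = pos_str(best$loc$refSeqPos),
    altSeqPos = pos_str(best$loc$altSeqPos),
    refPept = best$loc$refPept,
    altPept = best$loc$altPept,
    stringsAsFactors = FALSE)
  list(row = row, ref_protein = best$ref_protein,
       alt_protein = best$alt_protein, novel = aa_change == "Novel")
}

#' Annotate all events of a table with protein effects
#'
#' Applies [predict_protein_effect()] to every event and collects the
#' effects table plus two protein FASTA databases: the known database
#' (reference isoform sequences plus alternative sequences whose altered
#' run is found in annotated isoforms) and the novel database (alternative
#' sequences with novel altered runs). Per-event failures are reported as
#' Unknown rows, never as errors.
#'
#' @param table an [event_count_table()] (or a list of [splice_event()]).
#' @param annotation a [read_annotation()] object.
#' @param stats optional [diff_test()] result; its fitted PSI values fill
#'   `group_increased_alt`.
#' @param out_prefix optional path prefix; when given, writes
#'   `{prefix}.effects.tsv`, `{prefix}.known.fasta`,
#'   `{prefix}.novel.fasta`.
#' @return list with `effects` (data.frame, one row per event in input
#'   order), `fasta_known`, `fasta_novel` (named character vectors of
#'   protein sequences).
#' @export
annotate_events <- function(table, annotation, stats = NULL,
                            out_prefix = NULL) {
  events <- if (inherits(table, "event_count_table")) table$events else table
  labs <- attr(stats, "group_labels")
  rows <- vector("list", length(events))
  known <- character(0); novel <- character(0)
  for (k in seq_along(events)) {
    ev <- events[[k]]
    srow <- NULL
    if (!is.null(stats)) {
      m <- stats[stats$event_id == ev$event_id, , drop = FALSE]
      if (nrow(m) == 1L) {
        srow <- m
        srow$group_label1 <- labs[1L]; srow$group_label2 <- labs[2L]
      }
    }
    res <- tryCatch(predict_protein_effect(ev, annotation, srow),
                    error = function(e)
                      list(row = unknown_effect_row(ev), ref_protein = NULL,
                           alt_protein = NULL, novel = FALSE))
    rows[[k]] <- res$row
    if (!is.null(res$ref_protein)) {
      known[res$row$ref_seq_header] <- res$ref_protein
      if (res$novel) novel[res$row$alt_seq_header] <- res$alt_protein
      else known[res$row$alt_seq_header] <- res$alt_protein
    }
  }
  effects <- do.call(rbind, rows)
  rownames(effects) <- NULL
  if (!is.null(out_prefix)) {
    utils::write.table(effects, paste0(out_prefix, ".effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_protein_fasta(known, paste0(out_prefix, ".known.fasta"))
    write_protein_fasta(novel, paste0(out_prefix, ".novel.fasta"))
  }
  list(effects = effects, fasta_known = known, fasta_novel = novel)
}

write_protein_fasta <- function(seqs, path) {
  if (!length(seqs)) {
    file.create(path)
    return(invisible(path))
  }
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Filter events to novel sequences increased in a group
#'
#' The selection used to shortlist candidate disease-specific isoforms:
#' events predicted to generate a novel protein sequence whose alternative
#' isoform is increased in the given group.
#'
#' @param effects effects data.frame from [annotate_events()].
#' @param group group label to require in `group_increased_alt`.
#' @return filtered data.frame.
#' @export
filter_novel_increased <- function(effects, group) {
  effects[!is.na(effects$aa_change_type) &
            effects$aa_change_type == "Novel" &
            !is.na(effects$group_increased_alt) &
            effects$group_increased_alt == group, , drop = FALSE]
}
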