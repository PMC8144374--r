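test_that("transcripts are matched to the isoform they realize", {
  fx <- make_es_fixture()
  m <- match_transcripts(fx$event, fx$annotation)
  expect_identical(m$matches[m$transcript_id == "Tinc"], "iso1")
  expect_identical(m$matches[m$transcript_id == "Tskip"], "iso2")
  # acceptor shifted by +14: the inclusion transcript matches iso1 only
  a3 <- splice_event("a3", "GENE1", "c1", "+", "A3",
                     c(40L, 81L), c(40L, 95L))
  m3 <- match_transcripts(a3, fx$annotation)
  expect_identical(m3$matches[m3$transcript_id == "Tinc"], "iso1")
  expect_identical(m3$matches[m3$transcript_id == "Tskip"], "neither")
  # junctions matching nothing -> all neither -> Unknown effect
  nowhere <- splice_event("no", "GENE1", "c1", "+", "A3",
                          c(41L, 81L), c(41L, 95L))
  expect_true(all(match_transcripts(nowhere,
                                    fx$annotation)$matches == "neither"))
  eff <- predict_protein_effect(nowhere, fx$annotation)
  expect_identical(eff$row$effect_cat, "Unknown")
  expect_identical(eff$row$aa_change_type, "Unknown")
})

test_that("junction swap edits the exon chain and is an involution", {
  fx <- make_es_fixture()
  skipped <- apply_splice(fx$tinc, fx$event, 1L, 2L)
  expect_equal(unname(skipped$exons), unname(fx$tskip$exons))
  back <- apply_splice(skipped, fx$event, 2L, 1L)
  expect_equal(unname(back$exons), unname(fx$tinc$exons))
  # intron retention merges the flanking exons into one
  ir <- splice_event("ir1", "GENE1", "c1", "+", "IR",
                     c(40L, 81L), matrix(integer(0), ncol = 2))
  two_exon <- transcript_model("T2", "GENE1", "c1", "+",
                               rbind(c(11L, 40L), c(81L, 182L)),
                               c(23L, 180L))
  merged <- apply_splice(two_exon, ir, 1L, 2L)
  expect_equal(unname(merged$exons), unname(rbind(c(11L, 182L))))
  expect_equal(unname(apply_splice(merged, ir, 2L, 1L)$exons),
               unname(two_exon$exons))
})

test_that("translation follows strand and stops at the first stop codon", {
  genome <- Biostrings::DNAStringSet(c(p = "ATGAAATAG", m = "CTATTTCAT"))
  plus <- transcript_model("tp", "g", "p", "+", rbind(c(1L, 9L)), c(1L, 9L))
  minus <- transcript_model("tm", "g", "m", "-", rbind(c(1L, 9L)), c(1L, 9L))
  expect_identical(translate_transcript(plus, genome)$protein, "MK*")
  expect_identical(translate_transcript(minus, genome)$protein, "MK*")
  # missing stop is flagged, not fatal
  genome2 <- Biostrings::DNAStringSet(c(p = "ATGAAAAAA"))
  nostop <- transcript_model("tn", "g", "p", "+", rbind(c(1L, 9L)),
                             c(1L, 9L))
  tr <- translate_transcript(nostop, genome2)
  expect_false(tr$has_stop)
  expect_identical(tr$protein, "MKK")
  expect_error(translate_transcript(
    transcript_model("tx", "g", "zz", "+", rbind(c(1L, 9L)), c(1L, 9L)),
    genome), "missing from genome|contig")
})

test_that("alteration localization trims flanks but keeps a bare new stop", {
  loc <- localize_alteration("MKLV*", "MKAV*")
  expect_equal(loc$refSeqPos, c(3L, 3L))
  expect_identical(loc$refPept, "L")
  expect_identical(loc$altPept, "A")
  silent <- localize_alteration("MKLV*", "MKLV*")
  expect_identical(silent$refPept, "")
  expect_identical(silent$altPept, "")
  # frameshift shape: shared 180-residue prefix, reference runs 210 residues
  # past the divergence, alternative stops 5 residues in
  ref <- paste0(strrep("A", 180), strrep("R", 209), "*")
  alt <- paste0(strrep("A", 180), "SSFQF*")
  loc2 <- localize_alteration(ref, alt)
  expect_equal(loc2$refSeqPos, c(181L, 390L))
  expect_equal(loc2$altSeqPos, c(181L, 186L))
  expect_identical(loc2$altPept, "SSFQF*")
  # a genuinely shared C-terminus is trimmed as usual
  loc3 <- localize_alteration("MABCDEF*", "MAXYCDEF*")
  expect_identical(loc3$refPept, "B")
  expect_identical(loc3$altPept, "XY")
})

test_that("effect classification follows frame arithmetic", {
  expect_identical(classify_effect("MAB*", "MAB*", 0L, TRUE, TRUE, ""),
                   "Silent")
  expect_identical(classify_effect("MABCDE*", "MAE*", -102L, TRUE, TRUE, ""),
                   "Deletion")
  expect_identical(classify_effect("MABCDE*", "MAXX*", -103L, TRUE, TRUE,
                                   "XX*"), "FrameDisruption")
  expect_identical(classify_effect("MABCDE*", "MAB*", -9L, TRUE, TRUE, "*"),
                   "Truncation")
  expect_identical(classify_effect("MAB*", "MABCDE", 0L, TRUE, FALSE,
                                   "CDE"), "StopLoss")
  expect_identical(classify_effect("MAB*", "MAB*", 0L, FALSE, TRUE, ""),
                   "NonCoding")
})

test_that("the known/novel call searches canonical isoform proteins", {
  fx <- make_es_fixture()
  res <- predict_protein_effect(fx$event, fx$annotation)
  # both isoforms are annotated, candidates are ranked by altered-run
  # length: the insertion direction (Tskip -> inclusion) wins
  expect_identical(res$row$event_cat, "ExonSkip")
  expect_identical(res$row$effect_cat, "Insertion")
  expect_identical(res$row$ref_seq_header, "en|Tskip")
  expect_match(res$row$alt_seq_header, "^en\\|Tskip:g\\.40j223>")
  # the inserted glutamate run exists in the annotated inclusion isoform
  expect_identical(res$row$aa_change_type, "Known")
  expect_identical(res$row$altPept, strrep("E", 34))
  # with the inclusion transcript removed the same run becomes novel
  ann2 <- fx$annotation
  ann2$transcripts <- ann2$transcripts["Tskip"]
  ann2$genes <- list(GENE1 = "Tskip")
  res2 <- predict_protein_effect(fx$event, ann2)
  expect_identical(res2$row$effect_cat, "Insertion")
  expect_identical(res2$row$aa_change_type, "Novel")
})

test_that("annotation output is self-consistent and filterable", {
  fx <- make_es_fixture()
  tab <- event_count_table(
    list(fx$event),
    matrix(5L, 1, 2, dimnames = list(NULL, c("s1", "s2"))),
    matrix(5L, 1, 2, dimnames = list(NULL, c("s1", "s2"))))
  out <- annotate_events(tab, fx$annotation)
  eff <- out$effects
  expect_identical(nrow(eff), 1L)
  seqs <- c(out$fasta_known, out$fasta_novel)
  rp <- as.integer(strsplit(eff$refSeqPos, "-")[[1]])
  ap <- as.integer(strsplit(eff$altSeqPos, "-")[[1]])
  expect_identical(substr(seqs[[eff$ref_seq_header]], rp[1], rp[2]),
                   eff$refPept)
  expect_identical(substr(seqs[[eff$alt_seq_header]], ap[1], ap[2]),
                   eff$altPept)
  fake <- data.frame(
    aa_change_type = c("Novel", "Novel", "Known"),
    group_increased_alt = c("CASE", "CTRL", "CASE"),
    stringsAsFactors = FALSE)
  expect_identical(nrow(filter_novel_increased(fake, "CASE")), 1L)
})
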