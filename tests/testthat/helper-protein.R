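# Hand-built exon-skip fixture: one plus-strand gene with an inclusion
# transcript (Tinc, carries the 102-nt cassette) and a skip transcript
# (Tskip), plus the matching ES event. Coordinates are deliberately simple:
# e1 11..40 (UTR+ATG+5 codons), cassette 81..182 (34 GAA codons),
# e3 223..282 (15 CAT codons, TAA, UTR).
make_es_fixture <- function() {
  e1 <- paste0("ACGTACGTACGT", "ATG", strrep("GCT", 5))
  i1 <- paste0("GT", strrep("T", 36), "AG")
  cassette <- strrep("GAA", 34)
  i2 <- paste0("GT", strrep("C", 36), "AG")
  e3 <- paste0(strrep("CAT", 15), "TAA", "TAACTAACTAAC")
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste0(strrep("A", 10), e1, i1, cassette, i2, e3,
                strrep("A", 10))))
  tinc <- transcript_model("Tinc", "GENE1", "c1", "+",
                           rbind(c(11L, 40L), c(81L, 182L), c(223L, 282L)),
                           c(23L, 270L))
  tskip <- transcript_model("Tskip", "GENE1", "c1", "+",
                            rbind(c(11L, 40L), c(223L, 282L)),
                            c(23L, 270L))
  annotation <- structure(
    list(genome = genome,
         transcripts = list(Tinc = tinc, Tskip = tskip),
         genes = list(GENE1 = c("Tinc", "Tskip"))),
    class = "splice_annotation")
  event <- splice_event("es1", "GENE1", "c1", "+", "ES",
                        rbind(c(40L, 81L), c(182L, 223L)), c(40L, 223L))
  list(annotation = annotation, event = event, tinc = tinc, tskip = tskip)
}
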