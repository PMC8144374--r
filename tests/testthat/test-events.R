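test_that("event identifiers render the published grammar", {
  a3_plus <- splice_event("e1", "TMEM14C", "6", "+", "A3",
                          c(10723474L, 10724789L), c(10723474L, 10724803L))
  expect_identical(make_event_jid(a3_plus),
                   "6s+:g.10723474j10724789>10723474j10724803[splA3]")
  a3_minus <- splice_event("e2", "DPH5", "1", "-", "A3",
                           c(101458310L, 101460666L),
                           c(101458296L, 101460666L))
  expect_identical(make_event_jid(a3_minus),
                   "1s-:g.101458310j101460666>101458296j101460666[splA3]")
  ir <- splice_event("e3", "G", "2", "+", "IR", c(100L, 200L),
                     matrix(integer(0), ncol = 2))
  expect_identical(make_event_jid(ir), "2s+:g.100j200>101_199[splIR]")
})

test_that("event identifiers are injective over distinct events", {
  set.seed(101)
  evs <- lapply(1:200, random_splice_event)
  jids <- vapply(evs, make_event_jid, "")
  keys <- vapply(evs, function(e)
    paste(e$contig, e$strand, paste(e$iso1_junctions, collapse = ","),
          paste(e$iso2_junctions, collapse = ","), e$event_type), "")
  expect_identical(anyDuplicated(jids[!duplicated(keys)]), 0L)
  # strand alone distinguishes
  plus <- splice_event("p", "G", "1", "+", "A3", c(10L, 100L), c(10L, 120L))
  minus <- splice_event("m", "G", "1", "-", "A3", c(10L, 100L), c(10L, 120L))
  expect_false(make_event_jid(plus) == make_event_jid(minus))
})

test_that("malformed events are rejected with the violated invariant", {
  expect_error(splice_event("x", "G", "1", "+", "ES", c(10L, 100L),
                            c(10L, 120L)),
               "requires \\(2, 1\\) junctions")
  expect_error(splice_event("x", "G", "1", "+", "A3", c(10L, 100L),
                            c(11L, 120L)),
               "share exactly one coordinate")
  expect_error(splice_event("x", "G", "1", "+", "A3", c(100L, 10L),
                            c(100L, 120L)),
               "donor_base < acceptor_base")
  expect_error(splice_event("x", "G", "1", "+", "XX", c(10L, 100L),
                            c(10L, 120L)),
               "unknown event_type")
})

test_that("PSI is the isoform-1 fraction, missing at zero depth", {
  expect_equal(compute_psi(5L, 5L), 0.5)
  expect_equal(compute_psi(7L, 0L), 1)
  expect_true(is.na(compute_psi(0L, 0L)))
  expect_error(compute_psi(-1L, 2L), "non-negative")
  # complementarity wherever defined
  set.seed(7)
  i1 <- rpois(50, 5); i2 <- rpois(50, 5)
  ok <- i1 + i2 > 0
  expect_equal(compute_psi(i1, i2)[ok] + compute_psi(i2, i1)[ok],
               rep(1, sum(ok)))
})

test_that("depth masking hides PSI below threshold but keeps counts", {
  ev <- list(splice_event("e", "G", "1", "+", "A3", c(10L, 100L),
                          c(10L, 120L)))
  tab <- event_count_table(
    ev, matrix(c(1L, 5L, 30L), 1, dimnames = list(NULL, c("a", "b", "c"))),
    matrix(c(1L, 5L, 20L), 1, dimnames = list(NULL, c("a", "b", "c"))))
  masked <- mask_low_depth(tab, 10L)
  expect_equal(as.vector(psi_matrix(masked)), c(NA, 0.5, 0.6))
  expect_identical(masked$iso1, tab$iso1)
  expect_equal(psi_matrix(mask_low_depth(tab, 0L)),
               psi_matrix(tab))
  all_masked <- mask_low_depth(tab, 100L)
  expect_true(all(is.na(psi_matrix(all_masked))))
})

test_that("count tables round-trip through the TSV dialect", {
  set.seed(33)
  evs <- lapply(1:6, random_splice_event)
  n <- length(evs); samples <- c("s1", "s2", "s3")
  iso1 <- matrix(rpois(n * 3, 20L), n, 3, dimnames = list(NULL, samples))
  iso2 <- matrix(rpois(n * 3, 10L), n, 3, dimnames = list(NULL, samples))
  tab <- event_count_table(evs, iso1, iso2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_identical(back$iso1, tab$iso1)
  expect_identical(back$iso2, tab$iso2)
  expect_identical(lapply(back$events, make_event_jid),
                   lapply(tab$events, make_event_jid))
  # write-read-write is byte stable
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("count-table parse errors name the offender and the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("event_id", "gene", "contig", "strand", "event_type",
                 "iso1_junctions", "iso2_junctions", "s1.iso1", "s1.iso2"),
               collapse = "\t")
  row <- function(...) paste(..., sep = "\t")
  # unpaired sample column
  writeLines(c(sub("s1.iso2", "s2.iso2", hdr)), path)
  expect_error(read_count_table(path), "'s1' has an .iso1 column")
  # non-integer count
  writeLines(c("# comment", hdr,
               row("e1", "G", "1", "+", "A3", "10j100", "10j120", "4", "x")),
             path)
  expect_error(read_count_table(path), "line 3: non-integer count.*'s1'")
  # duplicate id
  writeLines(c(hdr,
               row("e1", "G", "1", "+", "A3", "10j100", "10j120", "4", "1"),
               row("e1", "G", "1", "+", "A3", "10j200", "10j220", "4", "1")),
             path)
  expect_error(read_count_table(path), "line 3: duplicate event_id")
  # unknown event type
  writeLines(c(hdr,
               row("e1", "G", "1", "+", "ZZ", "10j100", "10j120", "4", "1")),
             path)
  expect_error(read_count_table(path), "unknown event_type 'ZZ'")
})
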