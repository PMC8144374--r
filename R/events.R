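#' Splice event data model
#'
#' A splice event is a local binary alternative in transcript structure with
#' two isoforms, each described by a set of splice junctions. A junction is a
#' pair of 1-based genomic positions `(donor_base, acceptor_base)`: the last
#' exonic base of the upstream exon and the first exonic base of the
#' downstream exon, in genomic order regardless of strand. The implied intron
#' is the closed interval `[donor_base + 1, acceptor_base - 1]`.
#'
#' Junction-list arity by event type:
#' \describe{
#'   \item{ES}{exon skip: isoform 1 has 2 junctions (inclusion), isoform 2
#'     has 1 (skip).}
#'   \item{IR}{intron retention: isoform 1 has 1 junction (spliced), isoform
#'     2 has none; the retained interval equals isoform 1's intron.}
#'   \item{A3, A5}{alternative acceptor/donor: 1 junction each, sharing
#'     exactly one coordinate.}
#'   \item{MX}{mutually exclusive exons: 2 junctions each, sharing the
#'     outermost donor and acceptor.}
#' }
#'
#' @param event_id opaque unique identifier string.
#' @param gene_id gene identifier (matching the annotation, when used for
#'   protein effect prediction).
#' @param contig contig/chromosome name.
#' @param strand "+" or "-".
#' @param event_type one of "ES", "IR", "A3", "A5", "MX".
#' @param iso1_junctions,iso2_junctions integer matrices with columns
#'   `donor`, `acceptor` (zero rows allowed for IR isoform 2).
#' @param ir_interval closed genomic interval `c(start, end)` of the retained
#'   intron; required for IR, derived from isoform 1's junction if omitted.
#' @return an object of class `splice_event`.
#' @export
splice_event <- function(event_id, gene_id, contig, strand, event_type,
                         iso1_junctions, iso2_junctions, ir_interval = NULL) {
  ev <- structure(
    list(event_id = as.character(event_id),
         gene_id = as.character(gene_id),
         contig = as.character(contig),
         strand = as.character(strand),
         event_type = as.character(event_type),
         iso1_junctions = as_junction_matrix(iso1_junctions),
         iso2_junctions = as_junction_matrix(iso2_junctions),
         ir_interval = if (!is.null(ir_interval)) as.integer(ir_interval)),
    class = "splice_event")
  if (ev$event_type == "IR" && is.null(ev$ir_interval) &&
      nrow(ev$iso1_junctions) == 1L)
    ev$ir_interval <- c(ev$iso1_junctions[1L, 1L] + 1L,
                        ev$iso1_junctions[1L, 2L] - 1L)
  validate_splice_event(ev)
  ev
}

as_junction_matrix <- function(x) {
  if (is.null(x)) x <- matrix(integer(0), ncol = 2)
  if (is.vector(x)) x <- matrix(as.integer(x), ncol = 2, byrow = TRUE)
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("donor", "acceptor")))
  if (nrow(x) > 1L) x <- x[order(x[, 1L]), , drop = FALSE]
  x
}

validate_splice_event <- function(ev) {
  fail <- function(what)
    stop(sprintf("invalid splice_event '%s': %s", ev$event_id, what),
         call. = FALSE)
  if (!ev$strand %in% c("+", "-")) fail("strand must be '+' or '-'")
  if (!ev$event_type %in% c("ES", "IR", "A3", "A5", "MX"))
    fail(sprintf("unknown event_type '%s'", ev$event_type))
  j1 <- ev$iso1_junctions; j2 <- ev$iso2_junctions
  for (j in list(j1, j2)) {
    if (nrow(j) && any(j[, "donor"] >= j[, "acceptor"] - 1L))
      fail("each junction needs donor_base < acceptor_base with a non-empty intron")
  }
  arity <- c(nrow(j1), nrow(j2))
  want <- switch(ev$event_type,
                 ES = c(2L, 1L), IR = c(1L, 0L),
                 A3 = c(1L, 1L), A5 = c(1L, 1L), MX = c(2L, 2L))
  if (!identical(arity, want))
    fail(sprintf("%s event requires (%d, %d) junctions, got (%d, %d)",
                 ev$event_type, want[1], want[2], arity[1], arity[2]))
  if (identical(j1, j2)) fail("isoform junction sets must differ")
  if (ev$event_type %in% c("A3", "A5") &&
      length(intersect(as.vector(j1), as.vector(j2))) != 1L)
    fail("A3/A5 junctions must share exactly one coordinate")
  if (ev$event_type == "MX" &&
      !(j1[1L, "donor"] == j2[1L, "donor"] &&
        j1[2L, "acceptor"] == j2[2L, "acceptor"]))
    fail("MX junction pairs must share the outermost donor and acceptor")
  if (ev$event_type == "IR") {
    if (is.null(ev$ir_interval) || length(ev$ir_interval) != 2L)
      fail("IR event requires ir_interval")
    if (!identical(unname(ev$ir_interval),
                   unname(c(j1[1L, 1L] + 1L, j1[1L, 2L] - 1L))))
      fail("ir_interval must equal isoform 1's intron")
  }
  invisible(ev)
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event %s: %s %s>\n", x$event_id, x$event_type,
              make_event_jid(x)))
  invisible(x)
}

junctions_to_string <- function(j, ir_interval = NULL) {
  if (nrow(j) == 0L) {
    if (is.null(ir_interval)) stop("empty junction set without interval")
    return(paste0(ir_interval[1L], "_", ir_interval[2L]))
  }
  paste(paste0(j[, "donor"], "j", j[, "acceptor"]), collapse = "_")
}

string_to_junctions <- function(s) {
  parts <- strsplit(s, "_", fixed = TRUE)[[1L]]
  if (!all(grepl("j", parts, fixed = TRUE)))
    return(NULL)  # interval form (IR isoform 2)
  m <- t(vapply(strsplit(parts, "j", fixed = TRUE),
                function(p) as.integer(p), integer(2)))
  as_junction_matrix(m)
}

#' Canonical event identifier
#'
#' Builds the canonical event identifier from contig, strand and both
#' isoforms' junction coordinates, e.g.
#' `"6s+:g.10723474j10724789>10723474j10724803[splA3]"`. The grammar is
#' \preformatted{
#'   {contig}s{strand}:g.{iso1}>{iso2}[spl{type}]
#'   iso  := junction ("_" junction)* | {start}"_"{end}   (IR isoform 2)
#'   junction := {donor_base}"j"{acceptor_base}
#' }
#' Identifiers contain no whitespace and are injective over distinct
#' (contig, strand, junction-set) triples.
#'
#' @param event a [splice_event()].
#' @return identifier string.
#' @export
make_event_jid <- function(event) {
  validate_splice_event(event)
  paste0(event$contig, "s", event$strand, ":g.",
         junctions_to_string(event$iso1_junctions),
         ">",
         junctions_to_string(event$iso2_junctions, event$ir_interval),
         "[spl", event$event_type, "]")
}

#' Percent spliced in
#'
#' PSI of isoform 1: `iso1 / (iso1 + iso2)`. Undefined (NA) where the total
#' is zero.
#'
#' @param iso1_count,iso2_count non-negative integer vectors.
#' @return numeric vector in `[0, 1]`, NA where depth is zero.
#' @export
compute_psi <- function(iso1_count, iso2_count) {
  if (any(iso1_count < 0, na.rm = TRUE) || any(iso2_count < 0, na.rm = TRUE))
    stop("compute_psi: counts must be non-negative", call. = FALSE)
  tot <- iso1_count + iso2_count
  ifelse(tot > 0, iso1_count / tot, NA_real_)
}

#' Event count table
#'
#' Container for per-event, per-sample isoform read counts. `iso1` and
#' `iso2` are events-by-samples integer matrices; rows are named by
#' event_id and align with `events`, an ordered list of [splice_event()]
#' objects.
#'
#' @param events list of [splice_event()] objects.
#' @param iso1,iso2 integer count matrices (events x samples), identical
#'   dimnames.
#' @return object of class `event_count_table`.
#' @export
event_count_table <- function(events, iso1, iso2) {
  iso1 <- as.matrix(iso1); iso2 <- as.matrix(iso2)
  storage.mode(iso1) <- "integer"; storage.mode(iso2) <- "integer"
  ids <- vapply(events, `[[`, "", "event_id")
  if (anyDuplicated(ids)) stop("duplicate event_id", call. = FALSE)
  if (nrow(iso1) != length(events) || !identical(dim(iso1), dim(iso2)))
    stop("count matrices must be events x samples and congruent",
         call. = FALSE)
  if (any(iso1 < 0) || any(iso2 < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (is.null(colnames(iso1)))
    stop("count matrices need sample column names", call. = FALSE)
  rownames(iso1) <- rownames(iso2) <- ids
  names(events) <- ids
  structure(list(events = events, iso1 = iso1, iso2 = iso2,
                 samples = colnames(iso1), min_depth = 0L),
            class = "event_count_table")
}

#' @export
print.event_count_table <- function(x, ...) {
  cat(sprintf("<event_count_table: %d events x %d samples (min_depth=%d)>\n",
              length(x$events), length(x$samples), x$min_depth))
  invisible(x)
}

#' @rdname event_count_table
#' @param table an `event_count_table`.
#' @export
total_counts <- function(table) table$iso1 + table$iso2

#' PSI matrix of a count table
#'
#' PSI of isoform 1 per event and sample. Entries with zero depth, or with
#' depth below the table's masking threshold (see [mask_low_depth()]), are
#' NA.
#'
#' @param table an [event_count_table()].
#' @return numeric matrix, events x samples.
#' @export
psi_matrix <- function(table) {
  tot <- total_counts(table)
  psi <- ifelse(tot > 0, table$iso1 / tot, NA_real_)
  if (table$min_depth > 0L) psi[tot < table$min_depth] <- NA_real_
  psi
}

#' Mask low-depth observations
#'
#' Marks PSI values as missing wherever total depth is below `min_depth`
#' (default 10, the conventional depth filter). Counts themselves are
#' unchanged; only [psi_matrix()] output is affected.
#'
#' @param table an [event_count_table()].
#' @param min_depth non-negative integer.
#' @export
mask_low_depth <- function(table, min_depth = 10L) {
  if (min_depth < 0) stop("min_depth must be >= 0", call. = FALSE)
  table$min_depth <- as.integer(min_depth)
  table
}
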