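#' Read a splice-event count table
#'
#' Reads the tab-separated count-table dialect: a header line with the fixed
#' columns `event_id`, `gene`, `contig`, `strand`, `event_type`,
#' `iso1_junctions`, `iso2_junctions`, followed by one `{sample}.iso1` /
#' `{sample}.iso2` column pair per sample. Lines starting with `#` are
#' comments and ignored. Junction columns use the identifier grammar's
#' junction encoding (`donor` `j` `acceptor`, multiple junctions joined by
#' `_`; for IR isoform 2 the retained interval `start_end`).
#'
#' Parse problems (missing paired column, non-integer count, duplicate
#' event_id, unknown event type) raise descriptive errors with the file line
#' number.
#'
#' @param path file path.
#' @return an [event_count_table()].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop(sprintf("%s: empty table", path), call. = FALSE)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- rows[[1L]]
  fixed <- c("event_id", "gene", "contig", "strand", "event_type",
             "iso1_junctions", "iso2_junctions")
  if (length(header) < length(fixed) ||
      !identical(header[seq_along(fixed)], fixed))
    stop(sprintf("%s: header must start with: %s", path,
                 paste(fixed, collapse = ", ")), call. = FALSE)
  cc <- header[-seq_along(fixed)]
  is1 <- grepl("\\.iso1$", cc); is2 <- grepl("\\.iso2$", cc)
  if (any(!is1 & !is2))
    stop(sprintf("%s: unrecognized count column '%s'", path,
                 cc[!is1 & !is2][1L]), call. = FALSE)
  s1 <- sub("\\.iso1$", "", cc[is1]); s2 <- sub("\\.iso2$", "", cc[is2])
  for (s in setdiff(s1, s2))
    stop(sprintf("%s: sample '%s' has an .iso1 column but no .iso2 column",
                 path, s), call. = FALSE)
  for (s in setdiff(s2, s1))
    stop(sprintf("%s: sample '%s' has an .iso2 column but no .iso1 column",
                 path, s), call. = FALSE)
  samples <- s1
  idx1 <- length(fixed) + which(is1)[match(samples, s1)]
  idx2 <- length(fixed) + which(is2)[match(samples, s2)]

  data <- rows[-1L]; dln <- lineno[-1L]
  nev <- length(data)
  events <- vector("list", nev)
  iso1 <- matrix(0L, nev, length(samples),
                 dimnames = list(NULL, samples))
  iso2 <- iso1
  seen <- character(0)
  for (k in seq_len(nev)) {
    f <- data[[k]]
    if (length(f) != length(header))
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   path, dln[k], length(header), length(f)), call. = FALSE)
    if (f[1L] %in% seen)
      stop(sprintf("%s line %d: duplicate event_id '%s'", path, dln[k],
                   f[1L]), call. = FALSE)
    seen <- c(seen, f[1L])
    if (!f[5L] %in% c("ES", "IR", "A3", "A5", "MX"))
      stop(sprintf("%s line %d: unknown event_type '%s'", path, dln[k],
                   f[5L]), call. = FALSE)
    j1 <- string_to_junctions(f[6L])
    j2 <- string_to_junctions(f[7L])
    ir <- NULL
    if (is.null(j2)) {  # interval form, only legal for IR isoform 2
      if (f[5L] != "IR")
        stop(sprintf("%s line %d: junction-free isoform 2 only valid for IR",
                     path, dln[k]), call. = FALSE)
      ir <- as.integer(strsplit(f[7L], "_", fixed = TRUE)[[1L]])
      j2 <- matrix(integer(0), ncol = 2)
    }
    events[[k]] <- tryCatch(
      splice_event(f[1L], f[2L], f[3L], f[4L], f[5L], j1, j2, ir),
      error = function(e)
        stop(sprintf("%s line %d: %s", path, dln[k], conditionMessage(e)),
             call. = FALSE))
    cnt1 <- suppressWarnings(as.integer(f[idx1]))
    cnt2 <- suppressWarnings(as.integer(f[idx2]))
    bad <- which(is.na(cnt1) | f[idx1] != as.character(cnt1) |
                 is.na(cnt2) | f[idx2] != as.character(cnt2))
    if (length(bad))
      stop(sprintf("%s line %d: non-integer count for sample '%s'",
                   path, dln[k], samples[bad[1L]]), call. = FALSE)
    iso1[k, ] <- cnt1; iso2[k, ] <- cnt2
  }
  event_count_table(events, iso1, iso2)
}

#' Write a splice-event count table
#'
#' Inverse of [read_count_table()]; `write_count_table()` followed by
#' [read_count_table()] is the identity on canonicalized tables.
#'
#' @param table an [event_count_table()].
#' @param path output file path.
#' @param header_comments optional character vector written as leading `#`
#'   comment lines (used by the CLI for provenance).
#' @export
write_count_table <- function(table, path, header_comments = NULL) {
  fixed <- c("event_id", "gene", "contig", "strand", "event_type",
             "iso1_junctions", "iso2_junctions")
  cols <- c(fixed, as.vector(rbind(paste0(table$samples, ".iso1"),
                                   paste0(table$samples, ".iso2"))))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  writeLines(paste(cols, collapse = "\t"), con)
  for (k in seq_along(table$events)) {
    ev <- table$events[[k]]
    counts <- as.vector(rbind(table$iso1[k, ], table$iso2[k, ]))
    writeLines(paste(c(ev$event_id, ev$gene_id, ev$contig, ev$strand,
                       ev$event_type,
                       junctions_to_string(ev$iso1_junctions),
                       junctions_to_string(ev$iso2_junctions, ev$ir_interval),
                       counts),
                     collapse = "\t"), con)
  }
  invisible(path)
}
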