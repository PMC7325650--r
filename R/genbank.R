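# Minimal GenBank flat-file reader/writer.
#
# Covers what mitogenome records need here: LOCUS/ACCESSION/ORGANISM,
# a feature table with source/CDS/intron features and join()/complement()
# locations, and the ORIGIN sequence block. Fuzzy locations (< / >),
# order() locations and trans-spliced CDS are rejected explicitly; the
# insertion-site procedure assumes contiguous genes.

#' Parse a GenBank location string
#'
#' Supports `a..b`, `a` (single base), `join(...)` and a single outer
#' `complement(...)`. Fuzzy (`<`/`>`) and `order()` locations are rejected.
#'
#' @param loc Location string.
#' @return List with `segments` (data.frame of 1-based inclusive
#'   `start`/`end` in the order written) and `strand` (`"+"` or `"-"`).
#' @keywords internal
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  if (grepl("[<>]", loc))
    stop("fuzzy GenBank location not supported: ", loc, call. = FALSE)
  if (grepl("^order\\(", loc))
    stop("order() GenBank location not supported: ", loc, call. = FALSE)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("complement", loc))
    stop("per-segment complement() (trans-splicing?) not supported: ", loc, call. = FALSE)
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  seg <- lapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      se <- c(as.integer(p), as.integer(p))
    } else {
      stop("unsupported GenBank location segment: ", p, call. = FALSE)
    }
    se
  })
  segments <- data.frame(start = vapply(seg, `[`, 0L, 1L),
                         end = vapply(seg, `[`, 0L, 2L))
  if (any(segments$end < segments$start))
    stop("location segment with end < start: ", loc, call. = FALSE)
  list(segments = segments, strand = strand)
}

#' Read a GenBank flat file
#'
#' @param path Path to a GenBank flat file (single record).
#' @return List with `locus`, `length`, `accession`, `organism`, `strain`,
#'   `sequence` (uppercase) and `features` (list of `key`, `location`,
#'   `qualifiers`).
#' @keywords internal
read_genbank <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file: ", path, call. = FALSE)

  locus_fields <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  locus <- locus_fields[2]
  declared_len <- suppressWarnings(as.integer(locus_fields[3]))

  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]][2] else locus

  org_line <- grep("^[[:space:]]{2}ORGANISM", lines, value = TRUE)
  organism <- if (length(org_line)) trimws(sub("^[[:space:]]*ORGANISM", "", org_line[1])) else NA_character_

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(origin_start) == 0L) stop("GenBank record has no ORIGIN block: ", path, call. = FALSE)

  features <- list()
  if (length(feat_start)) {
    fl <- lines[(feat_start[1] + 1L):(origin_start[1] - 1L)]
    fl <- fl[nzchar(trimws(fl))]
    # a feature header starts at column 6; continuation/qualifier lines at column 22
    is_header <- grepl("^ {5}\\S", fl)
    idx <- cumsum(is_header)
    for (i in seq_len(max(idx, 0))) {
      blk <- fl[idx == i]
      hdr <- strsplit(trimws(blk[1]), "[[:space:]]+")[[1]]
      key <- hdr[1]
      rest <- trimws(blk[-1])
      # location may continue over lines until the first qualifier
      qual_at <- grep("^/", rest)
      loc_extra <- if (length(qual_at)) rest[seq_len(min(qual_at) - 1L)] else rest
      location <- paste0(paste(hdr[-1], collapse = ""), paste(loc_extra, collapse = ""))
      quals <- list()
      if (length(qual_at)) {
        qlines <- rest[min(qual_at):length(rest)]
        qidx <- cumsum(grepl("^/", qlines))
        for (q in seq_len(max(qidx, 0))) {
          qblk <- paste(qlines[qidx == q], collapse = " ")
          qname <- sub("^/([^=]+)=?.*$", "\\1", qblk)
          qval <- if (grepl("=", qblk)) sub("^/[^=]+=", "", qblk) else TRUE
          if (is.character(qval)) qval <- gsub("^\"|\"$", "", qval)
          quals[[qname]] <- qval
        }
      }
      features[[length(features) + 1L]] <-
        list(key = key, location = location, qualifiers = quals)
    }
  }

  seq_lines <- lines[(origin_start[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(declared_len) && nchar(sequence) != declared_len)
    warning("declared LOCUS length (", declared_len, ") differs from sequence length (",
            nchar(sequence), ") in ", path)

  list(locus = locus, length = nchar(sequence), accession = accession,
       organism = organism,
       strain = .gb_source_strain(features),
       sequence = sequence, features = features)
}

.gb_source_strain <- function(features) {
  for (f in features) {
    if (f$key == "source" && !is.null(f$qualifiers$strain))
      return(as.character(f$qualifiers$strain))
  }
  ""
}

#' Write a minimal GenBank flat file
#'
#' Used by the synthetic-fixture generator; emits a single record with a
#' source feature, one CDS per gene (join() over exons) and one intron
#' feature per intron.
#'
#' @param path Output path.
#' @param locus Locus name.
#' @param accession Accession string.
#' @param organism Organism binomial.
#' @param strain Strain id (empty string to omit).
#' @param sequence Genomic sequence (character).
#' @param cds List of entries `list(gene=, segments=data.frame(start,end),
#'   strand=)`.
#' @param introns Optional list of `list(gene=, start=, end=, note=)`.
#' @return `path`, invisibly.
#' @keywords internal
write_genbank <- function(path, locus, accession, organism, strain, sequence,
                          cds, introns = list()) {
  n <- nchar(sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular     %s",
                     locus, n, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, synthetic fixture.", organism), con)
  writeLines(sprintf("ACCESSION   %s", accession), con)
  writeLines(sprintf("SOURCE      mitochondrion %s", organism), con)
  writeLines(sprintf("  ORGANISM  %s", organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  writeLines(sprintf("                     /organism=\"%s\"", organism), con)
  if (nzchar(strain))
    writeLines(sprintf("                     /strain=\"%s\"", strain), con)
  fmt_loc <- function(segments, strand) {
    segs <- sprintf("%d..%d", segments$start, segments$end)
    loc <- if (length(segs) > 1L) sprintf("join(%s)", paste(segs, collapse = ",")) else segs
    if (strand == "-") loc <- sprintf("complement(%s)", loc)
    loc
  }
  for (f in cds) {
    writeLines(sprintf("     CDS             %s", fmt_loc(f$segments, f$strand)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
  }
  for (f in introns) {
    writeLines(sprintf("     intron          %s",
                       fmt_loc(data.frame(start = f$start, end = f$end),
                               if (is.null(f$strand)) "+" else f$strand)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
    if (!is.null(f$note))
      writeLines(sprintf("                     /note=\"%s\"", f$note), con)
  }
  writeLines("ORIGIN", con)
  .write_origin_lines(con, sequence)
  writeLines("//", con)
  invisible(path)
}

.write_origin_lines <- function(con, sequence) {
  n <- nchar(sequence)
  for (p in seq(1L, n, by = 60L)) {
    starts <- seq(p, min(p + 59L, n), by = 10L)
    chunk <- substring(sequence, starts, pmin(starts + 9L, n))
    writeLines(sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))), con)
  }
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
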