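#' Construct an intron observation
#'
#' One intron of a host gene: its position on the host spliced CDS
#' (`host_offset`, 1-based "inserted after position N"), its sequence, its
#' genomic span, and any declared type evidence.
#'
#' @param host_offset Count of host spliced-CDS nucleotides 5' of the
#'   insertion point.
#' @param sequence Intron sequence (transcription orientation).
#' @param genomic_start,genomic_end 1-based inclusive genomic coordinates.
#' @param declared_type `"group_I"`, `"group_II"` or `"unknown"`.
#' @param strand `"+"` or `"-"` (host gene orientation).
#' @param old_name Optional previously published name (e.g. `"aI1"`).
#' @return An object of class `intron_obs`.
#' @export
intron_obs <- function(host_offset, sequence, genomic_start = NA_integer_,
                       genomic_end = NA_integer_, declared_type = "unknown",
                       strand = "+", old_name = NA_character_) {
  declared_type <- match.arg(declared_type, c("unknown", "group_I", "group_II"))
  sequence <- toupper(as.character(sequence))
  structure(list(
    host_offset = as.integer(host_offset),
    sequence = sequence,
    genomic_start = as.integer(genomic_start),
    genomic_end = as.integer(genomic_end),
    declared_type = declared_type,
    strand = strand,
    old_name = old_name,
    length_nt = nchar(sequence)
  ), class = "intron_obs")
}

#' Construct a gene record
#'
#' One host species' gene with its ordered exon/intron structure. Exons are
#' given in transcription orientation; `spliced_cds` must equal their
#' concatenation; intron `host_offset`s must be non-decreasing (equal only
#' for twintron members).
#'
#' @param species_name Binomial, e.g. `"Saccharomyces cerevisiae"`.
#' @param gene_name Canonical gene name.
#' @param exons data.frame with columns `genomic_start`, `genomic_end`,
#'   `sequence` (transcription order).
#' @param introns List of [intron_obs] in transcription order.
#' @param accession,strain,strand Record metadata.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(species_name, gene_name, exons, introns = list(),
                        accession = NA_character_, strain = "", strand = "+") {
  spliced <- paste(exons$sequence, collapse = "")
  offs <- vapply(introns, `[[`, 0L, "host_offset")
  if (length(offs)) {
    if (any(offs < 1L) || any(offs >= nchar(spliced)))
      stop("intron host_offset outside 1..", nchar(spliced) - 1L, call. = FALSE)
    if (is.unsorted(offs))
      stop("introns must be ordered by host_offset", call. = FALSE)
  }
  structure(list(
    species_name = species_name, strain = strain, accession = accession,
    gene_name = gene_name, strand = strand,
    exons = exons, introns = introns, spliced_cds = spliced
  ), class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s %s [%s] %s: %d exon(s), %d intron(s), spliced CDS %d nt\n",
              x$species_name, if (nzchar(x$strain)) x$strain else "", x$accession,
              x$gene_name, nrow(x$exons), length(x$introns), nchar(x$spliced_cds)))
  invisible(x)
}

# Split one annotation gap into >=1 intron observations, using intron
# features when they tile or nest within the gap (side-by-side or nested
# twintrons cannot be expressed by a CDS join() alone).
.split_gap <- function(gap_start, gap_end, intron_feats) {
  inside <- Filter(function(f) f$start >= gap_start && f$end <= gap_end, intron_feats)
  if (length(inside) >= 2L) {
    o <- order(vapply(inside, `[[`, 0L, "start"), -vapply(inside, `[[`, 0L, "end"))
    inside <- inside[o]
    starts <- vapply(inside, `[[`, 0L, "start")
    ends <- vapply(inside, `[[`, 0L, "end")
    tiles <- starts[1] == gap_start && ends[length(inside)] == gap_end &&
      all(starts[-1] == ends[-length(inside)] + 1L)
    nests <- all(starts >= starts[1] & ends <= ends[1])
    if (tiles || nests)
      return(data.frame(start = starts, end = ends))
  }
  data.frame(start = gap_start, end = gap_end)
}

#' Read host genes (exon/intron structure) from a GenBank flat file
#'
#' Extracts one [gene_record] per CDS feature whose `gene`/`product`
#' qualifier maps to a canonical mitochondrial protein-coding gene name.
#' Introns are reconstructed as the gaps between consecutive exon segments
#' of the `join()` location, with sequences taken from the genome
#' (reverse-complemented for minus-strand genes). Where `intron` features
#' tile or nest within one gap, the gap is split into multiple observations
#' (twintrons). CDS spanning the circular origin are unwrapped. Features
#' with `transl_except` or fuzzy locations are skipped with a message, as
#' are CDS whose gene cannot be mapped.
#'
#' @param path GenBank flat file.
#' @param gene_filter Optional character vector of canonical gene names to
#'   keep.
#' @return List of [gene_record] objects.
#' @export
read_genbank_genes <- function(path, gene_filter = NULL) {
  gb <- read_genbank(path)
  genome <- gb$sequence
  n <- nchar(genome)
  if (!is.null(gene_filter)) gene_filter <- normalize_gene_name(gene_filter)

  intron_feats <- list()
  for (f in gb$features) {
    if (f$key == "intron") {
      loc <- try(parse_gb_location(f$location), silent = TRUE)
      if (inherits(loc, "try-error")) next
      g <- if (!is.null(f$qualifiers$gene)) normalize_gene_name(f$qualifiers$gene) else NA
      intron_feats[[length(intron_feats) + 1L]] <-
        list(gene = g, start = loc$segments$start[1],
             end = loc$segments$end[nrow(loc$segments)])
    }
  }

  records <- list()
  for (f in gb$features) {
    if (f$key != "CDS") next
    raw_gene <- if (!is.null(f$qualifiers$gene)) f$qualifiers$gene else f$qualifiers$product
    gname <- if (is.null(raw_gene)) NA_character_ else normalize_gene_name(raw_gene)
    if (is.na(gname)) {
      message("skipping CDS (", f$location, "): gene/product '",
              if (is.null(raw_gene)) "<none>" else raw_gene,
              "' not a recognizable mitochondrial protein-coding gene")
      next
    }
    if (!is.null(gene_filter) && !gname %in% gene_filter) next
    if (!is.null(f$qualifiers$transl_except)) {
      message("skipping CDS ", gname, ": transl_except not supported")
      next
    }
    loc <- try(parse_gb_location(f$location), silent = TRUE)
    if (inherits(loc, "try-error")) {
      message("skipping CDS ", gname, ": ", conditionMessage(attr(loc, "condition")))
      next
    }
    segs <- loc$segments
    strand <- loc$strand
    if (any(segs$end > n))
      stop("CDS ", gname, " coordinates exceed sequence length", call. = FALSE)

    exon_seq_plus <- substring(genome, segs$start, segs$end)
    # gaps between consecutive segments, in genomic (file) order
    gaps <- list()
    if (nrow(segs) > 1L) {
      for (i in seq_len(nrow(segs) - 1L)) {
        gs <- segs$end[i] + 1L
        ge <- segs$start[i + 1L] - 1L
        if (segs$start[i + 1L] > segs$end[i]) {
          if (ge >= gs) gaps[[i]] <- c(gs, ge) else gaps[i] <- list(NULL)
        } else {
          # wraps the circular origin
          if (gs > n && ge == 0L) { gaps[i] <- list(NULL); next }
          gaps[[i]] <- c(gs, ge, wrap = TRUE)
        }
      }
    }

    gene_introns <- Filter(function(x) is.na(x$gene) || identical(x$gene, gname), intron_feats)

    # transcription order
    ord <- if (strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
    exon_seqs <- exon_seq_plus[ord]
    if (strand == "-") exon_seqs <- vapply(exon_seqs, .revcomp, "")
    exons <- data.frame(genomic_start = segs$start[ord], genomic_end = segs$end[ord],
                        sequence = unname(exon_seqs), stringsAsFactors = FALSE)

    introns <- list()
    exon_lens <- nchar(exons$sequence)
    gap_order <- if (strand == "+") seq_along(gaps) else rev(seq_along(gaps))
    k <- 0L
    for (gi in gap_order) {
      k <- k + 1L
      gp <- gaps[[gi]]
      if (is.null(gp)) next
      host_offset <- sum(exon_lens[seq_len(k)])
      if (length(gp) >= 3L) {  # wrapped gap
        iseq <- paste0(substring(genome, gp[1], n), substring(genome, 1L, gp[2]))
        pieces <- data.frame(start = gp[1], end = gp[2])
      } else {
        pieces <- .split_gap(gp[1], gp[2], gene_introns)
        iseq <- NULL
      }
      piece_order <- if (strand == "+") seq_len(nrow(pieces)) else rev(seq_len(nrow(pieces)))
      # nested introns keep outer-first ordering on either strand
      if (nrow(pieces) > 1L && all(pieces$start >= pieces$start[1] & pieces$end <= pieces$end[1]))
        piece_order <- seq_len(nrow(pieces))
      for (pi in piece_order) {
        s <- if (is.null(iseq)) substring(genome, pieces$start[pi], pieces$end[pi]) else iseq
        if (strand == "-") s <- .revcomp(s)
        introns[[length(introns) + 1L]] <- intron_obs(
          host_offset = host_offset, sequence = s,
          genomic_start = pieces$start[pi], genomic_end = pieces$end[pi],
          strand = strand
        )
      }
    }

    records[[length(records) + 1L]] <- gene_record(
      species_name = gb$organism, gene_name = gname, exons = exons,
      introns = introns, accession = gb$accession, strain = gb$strain,
      strand = strand
    )
  }
  records
}

#' Read a raw (unannotated) gene region from FASTA
#'
#' Entry point for the de novo path: a single-record FASTA containing one
#' gene locus including any introns, plus declared metadata.
#'
#' @param path Single-record FASTA file.
#' @param species_name Binomial of the host species.
#' @param gene_name Canonical gene name the region is believed to contain.
#' @param id Record id to select when the file has several records.
#' @param accession,strain Optional metadata.
#' @return An object of class `region`.
#' @export
read_fasta_region <- function(path, species_name, gene_name, id = NULL,
                              accession = NA_character_, strain = "") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  if (length(seqs) > 1L) {
    if (is.null(id))
      stop("multi-record FASTA; select a record with `id`: ",
           paste(sub("\\s.*$", "", names(seqs)), collapse = ", "), call. = FALSE)
    hit <- which(sub("\\s.*$", "", names(seqs)) == id)
    if (length(hit) != 1L) stop("record id not found (or not unique): ", id, call. = FALSE)
    seqs <- seqs[hit]
  }
  gname <- normalize_gene_name(gene_name)
  if (is.na(gname)) stop("not a canonical gene name: ", gene_name, call. = FALSE)
  structure(list(
    species_name = species_name, gene_name = gname,
    sequence = as.character(seqs[[1]]),
    accession = accession, strain = strain,
    id = sub("\\s.*$", "", names(seqs)[1])
  ), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s %s (%d nt, record %s)\n",
              x$species_name, x$gene_name, nchar(x$sequence), x$id))
  invisible(x)
}

#' Write a table of named introns
#'
#' @param records List of [gene_record] objects.
#' @param names List of [intron_name] objects, aligned 1:1 with the introns
#'   of `records` flattened in record order.
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (same schema).
#' @return The table, invisibly.
#' @export
write_intron_table <- function(records, names, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- intron_table(records, names)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE, na = "null")
  }
  invisible(tab)
}

#' Assemble the intron table from records and names
#'
#' @inheritParams write_intron_table
#' @return data.frame with columns `species`, `accession`, `gene`, `site`,
#'   `type_letter`, `twintron_suffix`, `variant_number`, `full_name`,
#'   `intron_length`, `host_offset`, sorted by (species, gene, site,
#'   suffix).
#' @export
intron_table <- function(records, names) {
  n_introns <- sum(vapply(records, function(r) length(r$introns), 0L))
  if (n_introns != length(names))
    stop("records carry ", n_introns, " intron(s) but ", length(names),
         " name(s) were supplied", call. = FALSE)
  rows <- list()
  i <- 0L
  for (r in records) {
    for (intr in r$introns) {
      i <- i + 1L
      nm <- names[[i]]
      rows[[i]] <- data.frame(
        species = r$species_name, accession = r$accession, gene = nm$gene_name,
        site = nm$site, type_letter = nm$type_letter,
        twintron_suffix = nm$suffix,
        variant_number = if (is.na(nm$variant)) "" else as.character(nm$variant),
        full_name = format_name(nm),
        intron_length = intr$length_nt, host_offset = intr$host_offset,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    species = character(), accession = character(), gene = character(),
    site = integer(), type_letter = character(), twintron_suffix = character(),
    variant_number = character(), full_name = character(),
    intron_length = integer(), host_offset = integer(), stringsAsFactors = FALSE
  )
  out[order(out$species, out$gene, out$site, out$twintron_suffix), , drop = FALSE]
}
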