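# Intron type -> letter. Structural typing itself (RNAweasel-style) is out
# of scope: external typing tables are consumed, with a deliberately
# conservative terminal-nucleotide heuristic as the only built-in fallback.

#' Construct type evidence
#'
#' @param declared `"group_I"`, `"group_II"` or `"unknown"`.
#' @param source `"external_table"`, `"heuristic"` or `"none"`.
#' @param confidence `"high"` or `"low"`.
#' @return An object of class `type_evidence`.
#' @export
type_evidence <- function(declared = "unknown",
                          source = c("none", "external_table", "heuristic"),
                          confidence = c("high", "low")) {
  source <- match.arg(source)
  confidence <- match.arg(confidence)
  declared <- match.arg(declared, c("unknown", "group_I", "group_II"))
  if (source == "none" && declared != "unknown")
    stop("evidence without a source must be 'unknown'", call. = FALSE)
  structure(list(source = source, declared = declared, confidence = confidence),
            class = "type_evidence")
}

#' Type letter for an intron
#'
#' Group I introns get P, group II introns get S, undetermined types get U.
#'
#' @param evidence A [type_evidence], or a declared-type string.
#' @return `"P"`, `"S"` or `"U"`.
#' @export
letter_for <- function(evidence) {
  declared <- if (inherits(evidence, "type_evidence")) evidence$declared else
    match.arg(as.character(evidence), c("unknown", "group_I", "group_II"))
  switch(declared, group_I = "P", group_II = "S", unknown = "U")
}

.normalize_type_string <- function(x) {
  key <- gsub("[ _-]", "", tolower(x))
  if (key %in% c("groupi", "i", "group1", "gi", "ia", "ib", "ic", "ic1", "ic2", "id")) return("group_I")
  if (key %in% c("groupii", "ii", "group2", "gii", "iia", "iib")) return("group_II")
  if (key %in% c("unknown", "u", "undetermined", "na")) return("unknown")
  NA_character_
}

#' Read an external intron-type table
#'
#' TSV with columns `accession`, `gene`, `intron_index` (serial number of
#' the intron within the gene, 5' to 3') or `host_offset`, and `type`.
#' Unrecognized type strings become `unknown` with a warning; structurally
#' malformed rows are an error naming the row.
#'
#' @param path TSV file.
#' @return data.frame with normalized columns `accession`, `gene`, `key`
#'   (index or offset as given), `declared`, plus the keying mode in the
#'   `by` attribute.
#' @export
read_type_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(tab) == 0L) {
    out <- data.frame(accession = character(), gene = character(),
                      key = integer(), declared = character(),
                      stringsAsFactors = FALSE)
    attr(out, "by") <- "intron_index"
    return(out)
  }
  keycol <- intersect(c("intron_index", "host_offset"), names(tab))
  need <- c("accession", "gene", "type")
  if (!all(need %in% names(tab)) || length(keycol) == 0L)
    stop("type table must have columns accession, gene, intron_index or host_offset, type",
         call. = FALSE)
  keycol <- keycol[1]
  gene <- normalize_gene_name(tab$gene)
  key <- suppressWarnings(as.integer(tab[[keycol]]))
  bad <- which(is.na(gene) | is.na(key) | !nzchar(tab$accession))
  if (length(bad))
    stop("malformed type-table row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  declared <- vapply(tab$type, .normalize_type_string, "", USE.NAMES = FALSE)
  if (anyNA(declared)) {
    warning("unrecognized intron type string(s) treated as unknown: ",
            paste(unique(tab$type[is.na(declared)]), collapse = ", "))
    declared[is.na(declared)] <- "unknown"
  }
  out <- data.frame(accession = tab$accession, gene = gene, key = key,
                    declared = declared, stringsAsFactors = FALSE)
  attr(out, "by") <- keycol
  out
}

#' Minimal splice-site heuristic for intron type
#'
#' Low-confidence guess from terminal signatures: group I introns
#' characteristically end in G (and here must also start with T or A);
#' group II introns end in AC or AT with a GTGYG-like motif in the first
#' 10 nt (at most one mismatch). Anything else, or a sequence shorter than
#' 20 nt, is `unknown`. External evidence always dominates this heuristic;
#' by default its result is still rendered as letter U unless
#' `trust_heuristic` is set in the calling pipeline.
#'
#' @param intron_seq Intron sequence.
#' @return A [type_evidence] with source `"heuristic"` and confidence
#'   `"low"` (or source `"none"` when nothing matches).
#' @export
heuristic_type <- function(intron_seq) {
  s <- .as_seq(intron_seq)
  n <- nchar(s)
  if (n < 20L) return(type_evidence("unknown", "none"))
  first1 <- substr(s, 1L, 1L)
  last1 <- substr(s, n, n)
  last2 <- substr(s, n - 1L, n)
  if (last1 == "G" && first1 %in% c("T", "A"))
    return(type_evidence("group_I", "heuristic", "low"))
  if (last2 %in% c("AC", "AT") && .has_gtgyg(substr(s, 1L, 10L)))
    return(type_evidence("group_II", "heuristic", "low"))
  type_evidence("unknown", "none")
}

#' Attach type evidence to the introns of gene records
#'
#' External table evidence (matched on accession + gene + intron serial
#' index, or host offset, per the table's key column) always wins; where it
#' is absent the splice-site heuristic is consulted, but its verdict is
#' committed to the intron only when `trust_heuristic` is TRUE -- otherwise
#' the intron stays `unknown` (letter U).
#'
#' @param records List of [gene_record].
#' @param types Optional table from [read_type_table()].
#' @param trust_heuristic Commit heuristic calls (default FALSE).
#' @return The records, with each intron's `declared_type` filled in.
#' @export
apply_type_evidence <- function(records, types = NULL, trust_heuristic = FALSE) {
  by <- if (!is.null(types)) attr(types, "by") else "intron_index"
  lapply(records, function(r) {
    for (k in seq_along(r$introns)) {
      declared <- NA_character_
      if (!is.null(types) && nrow(types)) {
        keyval <- if (by == "host_offset") r$introns[[k]]$host_offset else k
        hit <- types$accession == r$accession & types$gene == r$gene_name &
          types$key == keyval
        if (any(hit)) declared <- types$declared[which(hit)[1]]
      }
      if (is.na(declared)) {
        ev <- heuristic_type(r$introns[[k]]$sequence)
        declared <- if (trust_heuristic) ev$declared else "unknown"
      }
      r$introns[[k]]$declared_type <- declared
    }
    r
  })
}
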