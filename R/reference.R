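#' Canonical fungal mitochondrial protein-coding gene names
#'
#' The 15 protein-coding genes typically present in fungal mitogenomes.
#' These are the only genes for which reference coordinates are defined.
#'
#' @format Character vector of length 15.
#' @export
CANONICAL_GENES <- c(
  "atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "rps3"
)

# Lowercased synonym table; GenBank annotations vary widely in gene naming.
.GENE_SYNONYMS <- c(
  cytb = "cob", cytochromeb = "cob", cobb = "cob", cob1 = "cob",
  coxi = "cox1", coi = "cox1", co1 = "cox1",
  coxii = "cox2", coii = "cox2", co2 = "cox2",
  coxiii = "cox3", coiii = "cox3", co3 = "cox3",
  oli1 = "atp9", oli2 = "atp6", olI = "atp9",
  atpase6 = "atp6", atpase8 = "atp8", atpase9 = "atp9",
  nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4",
  nd4l = "nad4L", nd5 = "nad5", nd6 = "nad6",
  ndh1 = "nad1", ndh2 = "nad2", ndh3 = "nad3", ndh4 = "nad4",
  ndh4l = "nad4L", ndh5 = "nad5", ndh6 = "nad6",
  var1 = "rps3", s3 = "rps3"
)

#' Normalize a gene name to its canonical spelling
#'
#' Maps case-insensitive spellings and common synonyms (`cytb` -> `cob`,
#' `nd1` -> `nad1`, `oli1` -> `atp9`, `var1` -> `rps3`, ...) onto the
#' 15 canonical fungal mitochondrial protein-coding gene names.
#'
#' @param x Character vector of gene names as found in annotations.
#' @param synonyms Optional named character vector of extra synonyms
#'   (names = lowercase input spelling, values = canonical name).
#' @return Character vector: the canonical name, or `NA` where the input
#'   cannot be mapped.
#' @examples
#' normalize_gene_name(c("COX1", "nad4l", "cytb", "rps3", "trnM"))
#' @export
normalize_gene_name <- function(x, synonyms = NULL) {
  key <- gsub("[ _-]", "", tolower(as.character(x)))
  tab <- .GENE_SYNONYMS
  if (!is.null(synonyms)) tab <- c(tab, stats::setNames(synonyms, tolower(names(synonyms))))
  canon <- stats::setNames(CANONICAL_GENES, tolower(CANONICAL_GENES))
  out <- unname(canon[key])
  hit <- is.na(out) & key %in% names(tab)
  out[hit] <- unname(tab[key[hit]])
  out
}

#' Construct a reference gene
#'
#' A reference gene is one intron-free CDS of the reference organism; its
#' spliced sequence defines the coordinate axis on which insertion sites of
#' that gene are expressed (1-based, stop codon included).
#'
#' @param gene_name Canonical gene name (one of [CANONICAL_GENES]).
#' @param sequence DNA sequence (character, A/C/G/T/N).
#' @return An object of class `ref_gene`.
#' @export
ref_gene <- function(gene_name, sequence) {
  gene_name <- as.character(gene_name)
  if (!gene_name %in% CANONICAL_GENES)
    stop("not a canonical gene name: ", gene_name, call. = FALSE)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("empty reference sequence for ", gene_name, call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence for ", gene_name, " contains characters other than A/C/G/T/N",
         call. = FALSE)
  structure(
    list(gene_name = gene_name, sequence = sequence, length_nt = nchar(sequence)),
    class = "ref_gene"
  )
}

#' @export
print.ref_gene <- function(x, ...) {
  cat(sprintf("<ref_gene> %s (%d nt)\n", x$gene_name, x$length_nt))
  invisible(x)
}

.new_ref_set <- function(genes, source_accession = NA_character_) {
  nm <- vapply(genes, `[[`, "", "gene_name")
  if (anyDuplicated(nm)) {
    stop("duplicate gene name(s) in reference: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  genes <- genes[order(match(nm, CANONICAL_GENES))]
  names(genes) <- vapply(genes, `[[`, "", "gene_name")
  structure(list(genes = genes, source_accession = source_accession),
            class = "ref_set")
}

#' @export
print.ref_set <- function(x, ...) {
  cat(sprintf("<ref_set> %d reference gene(s), source: %s\n",
              length(x$genes), x$source_accession))
  for (g in x$genes) cat(sprintf("  %-6s %5d nt\n", g$gene_name, g$length_nt))
  invisible(x)
}

#' Load a reference gene set
#'
#' Reads the intron-free reference CDS set that defines the coordinate
#' system for intron insertion sites, either from a multi-FASTA (one record
#' per gene, record id = gene name) or from a GenBank flat file whose CDS
#' features carry the genes. Gene names are normalized to canonical
#' spelling; ids that cannot be normalized are an error for FASTA input.
#'
#' @param path Path to a FASTA or GenBank file.
#' @param format `"auto"` (default, by extension/content), `"fasta"` or
#'   `"genbank"`.
#' @param source_accession Accession recorded on the returned set; for
#'   GenBank input the record's own accession is used.
#' @return A `ref_set`: a named list of [ref_gene] objects plus the source
#'   accession.
#' @seealso [bundled_reference()] for the reference set shipped with the
#'   package.
#' @export
load_reference <- function(path, format = c("auto", "fasta", "genbank"),
                           source_accession = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read reference file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "fasta"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    canon <- normalize_gene_name(ids)
    if (anyNA(canon)) {
      stop("record id(s) not recognizable as mitochondrial protein-coding genes: ",
           paste(ids[is.na(canon)], collapse = ", "), call. = FALSE)
    }
    genes <- lapply(seq_along(seqs), function(i) ref_gene(canon[i], as.character(seqs[[i]])))
    .new_ref_set(genes, source_accession)
  } else {
    recs <- read_genbank_genes(path)
    if (length(recs) == 0L) stop("no recognizable protein-coding genes in ", path, call. = FALSE)
    genes <- lapply(recs, function(r) ref_gene(r$gene_name, r$spliced_cds))
    acc <- recs[[1]]$accession
    .new_ref_set(genes, if (is.na(source_accession)) acc else source_accession)
  }
}

#' Bundled reference gene set
#'
#' Returns the reference set shipped with the package. The shipped file is
#' a synthetic stand-in for the *Tolypocladium inflatum* ARSEF 3280
#' (NC_036382) gene set: gene count, naming and lengths match a typical
#' fungal mitogenome and every published insertion site is a valid
#' coordinate, but the nucleotide sequences are simulated. For work on real
#' data, pass the genuine NC_036382 gene set to [load_reference()].
#'
#' @return A `ref_set` with 15 genes.
#' @export
bundled_reference <- function() {
  path <- system.file("extdata", "tinflatum_ref_synthetic.fasta", package = "mitonom",
                      mustWork = TRUE)
  load_reference(path, format = "fasta", source_accession = "NC_036382-synthetic")
}

#' Sanity report for a reference set
#'
#' Lists, per gene, the sequence length, whether the length is a multiple
#' of three, and start/stop codon presence (mold mitochondrial code:
#' TGA = Trp, so TAA/TAG terminate). Biological oddities are recorded,
#' never raised.
#'
#' @param ref A `ref_set`.
#' @return A data.frame with one row per gene and a `flags` column
#'   (semicolon-separated markers such as `length_not_codon_multiple`).
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "ref_set"))
  rows <- lapply(ref$genes, function(g) {
    len <- g$length_nt
    codon_multiple <- len %% 3L == 0L
    has_start <- substr(g$sequence, 1L, 3L) == "ATG"
    last3 <- substr(g$sequence, len - 2L, len)
    has_stop <- len >= 3L && last3 %in% c("TAA", "TAG")
    flags <- c(
      if (!codon_multiple) "length_not_codon_multiple",
      if (!has_start) "no_ATG_start",
      if (!has_stop) "no_stop_codon"
    )
    data.frame(gene = g$gene_name, length_nt = len,
               codon_multiple = codon_multiple,
               has_start = has_start, has_stop = has_stop,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(gene = character(), length_nt = integer(),
                      codon_multiple = logical(), has_start = logical(),
                      has_stop = logical(), flags = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a reference set to FASTA
#'
#' @param ref A `ref_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ref_set"))
  seqs <- Biostrings::DNAStringSet(vapply(ref$genes, `[[`, "", "sequence"))
  names(seqs) <- vapply(ref$genes, `[[`, "", "gene_name")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
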