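#' Alignment parameter set
#'
#' Scoring scheme for the pairwise alignments used to lift host coordinates
#' onto the reference axis. A gap of length L costs
#' `gap_open + gap_extend * L`.
#'
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -3).
#' @param gap_open Gap opening penalty, applied once per gap (default 10).
#' @param gap_extend Gap extension penalty per gapped position (default 1).
#' @param min_identity Identity floor below which an alignment is flagged
#'   `low_confidence` (default 0.30). Never an error: a flag.
#' @param min_intron Minimum host-only run length (nt) treated as a
#'   candidate intron by [infer_introns()] (default 30).
#' @param intron_gap_extend Gap extension used only for the intron-tolerant
#'   region-vs-reference alignment in [infer_introns()], where host-only
#'   runs of intron length must stay cheaper than misaligning exons
#'   (default 0.2).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 10,
                         gap_extend = 1, min_identity = 0.30,
                         min_intron = 30L, intron_gap_extend = 0.2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_identity >= 0, min_identity <= 1, intron_gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 min_intron = as.integer(min_intron),
                 intron_gap_extend = intron_gap_extend),
            class = "align_params")
}

.subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = FALSE)
}

.as_seq <- function(x) {
  if (inherits(x, "DNAString")) return(as.character(x))
  toupper(as.character(x))
}

#' Globally align a host spliced CDS to its reference gene
#'
#' End-to-end pairwise alignment with affine gap penalties; deterministic
#' for fixed inputs and parameters. Identity is reported as matches over
#' aligned columns in which neither row has a gap. An identity below
#' `params$min_identity` sets the `low_confidence` flag (not an error).
#'
#' @param host_spliced_cds Host spliced CDS (character or `DNAString`).
#' @param ref_gene A [ref_gene].
#' @param params An [align_params] set.
#' @param host_id Identifier recorded on the result.
#' @return An object of class `alignment_map` with fields `aligned_host`,
#'   `aligned_ref`, `identity`, `score`, `low_confidence`.
#' @export
align_to_reference <- function(host_spliced_cds, ref_gene,
                               params = align_params(), host_id = "host") {
  host <- .as_seq(host_spliced_cds)
  if (!inherits(ref_gene, "ref_gene")) stop("ref_gene must be a <ref_gene>", call. = FALSE)
  if (nchar(host) == 0L) stop("empty host sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(host),
    subject = Biostrings::DNAString(ref_gene$sequence),
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  ah <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  .new_alignment_map(ah, ar, host_id, ref_gene$gene_name, params,
                     score = Biostrings::score(pa))
}

.new_alignment_map <- function(aligned_host, aligned_ref, host_id, gene_name,
                               params, score = NA_real_) {
  hc <- strsplit(aligned_host, "", fixed = TRUE)[[1]]
  rc <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  stopifnot(length(hc) == length(rc))
  both <- hc != "-" & rc != "-"
  identity <- if (any(both)) sum(hc[both] == rc[both]) / sum(both) else 0
  structure(list(
    host_id = host_id, gene_name = gene_name,
    aligned_host = aligned_host, aligned_ref = aligned_ref,
    identity = identity, score = score, params = params,
    low_confidence = identity < params$min_identity
  ), class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %s vs %s: %d columns, identity %.3f%s\n",
              x$host_id, x$gene_name, nchar(x$aligned_host), x$identity,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Lift host spliced-CDS offsets onto reference coordinates
#'
#' Locates the alignment column holding host nucleotide `host_offset` and
#' returns the count of reference nucleotides in all columns up to and
#' including it -- the insertion site "after reference position N". When
#' that column is a gap in the reference row the 5'-nearest reference
#' coordinate is returned and the observation is flagged `gap_adjacent`.
#'
#' @param aln An `alignment_map` from [align_to_reference()].
#' @param host_offset Integer vector of 1-based host offsets (each the
#'   number of spliced-CDS nucleotides 5' of an insertion point).
#' @return data.frame with columns `host_offset`, `site`, `confidence`
#'   (`"ok"`, `"gap_adjacent"`, or either prefixed with `"low_identity;"`
#'   when the alignment itself is low confidence).
#' @export
map_insertion_site <- function(aln, host_offset) {
  stopifnot(inherits(aln, "alignment_map"))
  hc <- strsplit(aln$aligned_host, "", fixed = TRUE)[[1]]
  rc <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  host_cum <- cumsum(hc != "-")
  ref_cum <- cumsum(rc != "-")
  n_host <- host_cum[length(host_cum)]
  host_offset <- as.integer(host_offset)
  if (any(host_offset < 1L) || any(host_offset >= n_host))
    stop("host_offset out of range 1..", n_host - 1L, call. = FALSE)
  col <- match(host_offset, host_cum)  # first column reaching that count
  site <- ref_cum[col]
  conf <- ifelse(rc[col] == "-", "gap_adjacent", "ok")
  if (aln$low_confidence) conf <- paste0("low_identity;", conf)
  data.frame(host_offset = host_offset, site = as.integer(site),
             confidence = conf, stringsAsFactors = FALSE)
}

#' Reference alignment score by plain dynamic programming
#'
#' Textbook quadratic Gotoh recurrences, used as an independent check on
#' the production aligner's optimal score. A gap of length L costs
#' `gap_open + gap_extend * L`.
#'
#' @param a,b Sequences (character).
#' @param params An [align_params] set.
#' @return The optimal global alignment score (numeric scalar).
#' @export
alignment_score_dp <- function(a, b, params = align_params()) {
  .dp_align_score(.as_seq(a), .as_seq(b), params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
}
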