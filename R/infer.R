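# De novo intron inference from an unannotated gene region.
#
# Procedure: (1) anchor the region on the reference CDS with exact k-mer
# seeds and check co-linearity; (2) align the region to the reference
# end-to-end in the reference (free region ends), so introns surface as
# long host-only runs; (3) refine each candidate boundary within a +/-12 nt
# window, preferring maximal exon identity with a small bonus for group
# I/II splice-site signatures (group I introns end in G; group II introns
# end in AC/AT with a GTGYG-like 5' terminus); (4) return a gene_record.

.KMER <- 12L
.KMER_STRIDE <- 3L
.REFINE_WINDOW <- 12L

.anchor_hits <- function(region, ref_seq, k = .KMER, stride = .KMER_STRIDE) {
  reg <- Biostrings::DNAString(region)
  starts <- seq(1L, nchar(ref_seq) - k + 1L, by = stride)
  hits <- list()
  for (s in starts) {
    kmer <- substr(ref_seq, s, s + k - 1L)
    m <- Biostrings::matchPattern(kmer, reg)
    if (length(m)) {
      hits[[length(hits) + 1L]] <-
        data.frame(ref_pos = s, region_pos = Biostrings::start(m))
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(ref_pos = integer(), region_pos = integer())
}

# length of the longest strictly increasing subsequence (patience sorting)
.lis_length <- function(x) {
  tails <- integer(0)
  for (v in x) {
    i <- findInterval(v - 0.5, tails) + 1L  # first tail >= v
    if (i > length(tails)) tails <- c(tails, v) else tails[i] <- v
  }
  length(tails)
}

.splice_bonus <- function(intron_seq) {
  n <- nchar(intron_seq)
  if (n < 2L) return(0)
  last1 <- substr(intron_seq, n, n)
  last2 <- substr(intron_seq, n - 1L, n)
  head10 <- substr(intron_seq, 1L, min(10L, n))
  b <- 0
  if (last1 == "G") b <- max(b, 1)
  if (last2 %in% c("AC", "AT") && .has_gtgyg(head10)) b <- max(b, 1)
  b
}

.has_gtgyg <- function(x) {
  if (nchar(x) < 5L) return(FALSE)
  for (i in seq_len(nchar(x) - 4L)) {
    w <- substr(x, i, i + 4L)
    mism <- sum(strsplit(w, "")[[1]] != c("G", "T", "G", "C", "G")) -
      (substr(w, 4L, 4L) == "T")  # Y = C or T at position 4
    if (mism <= 1) return(TRUE)
  }
  FALSE
}

#' Infer exon/intron structure of an unannotated gene region
#'
#' Aligns a raw gene region (exons plus introns) to the intron-free
#' reference CDS and calls host-only runs of at least `params$min_intron`
#' nucleotides as introns. Exon-intron boundaries are refined within a
#' +/-12 nt window by maximal flanking exon identity with a preference for
#' group I/II splice-site signatures. Region ends outside the gene are
#' tolerated (the alignment is end-to-end in the reference only); the
#' returned record spans the gene only.
#'
#' @param region A `region` from [read_fasta_region()], or a plain
#'   character sequence.
#' @param ref_gene The [ref_gene] the region is believed to contain.
#' @param params An [align_params] set.
#' @return A [gene_record] with inferred exons and introns; each intron
#'   carries a `boundary_confidence` attribute (`"ok"` or `"ambiguous"`).
#' @export
infer_introns <- function(region, ref_gene, params = align_params()) {
  if (inherits(region, "region")) {
    seqc <- toupper(region$sequence)
    meta <- region
  } else {
    seqc <- .as_seq(region)
    meta <- list(species_name = NA_character_, accession = NA_character_, strain = "")
  }
  if (!inherits(ref_gene, "ref_gene")) stop("ref_gene must be a <ref_gene>", call. = FALSE)

  anchors <- .anchor_hits(seqc, ref_gene$sequence)
  if (nrow(anchors) == 0L)
    stop("gene_not_found: no alignment anchors between region and reference ",
         ref_gene$gene_name, call. = FALSE)
  anchors <- anchors[order(anchors$region_pos, anchors$ref_pos), ]
  lis <- .lis_length(anchors$ref_pos)
  if (lis < 0.7 * length(unique(anchors$ref_pos)))
    stop("rearrangement_suspected: anchors between region and reference ",
         ref_gene$gene_name, " are not co-linear", call. = FALSE)

  # end-to-end in the reference, free ends in the region; gap extension is
  # kept low so an intron-length host-only run beats exon misalignment
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seqc),
    subject = Biostrings::DNAString(ref_gene$sequence),
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$intron_gap_extend,
    type = "local-global"
  )
  ah <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  hc <- strsplit(ah, "", fixed = TRUE)[[1]]
  rc <- strsplit(ar, "", fixed = TRUE)[[1]]
  # region coordinate of each column (position of the host char, 0 before start)
  region_offset <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  host_cum <- cumsum(hc != "-") + region_offset

  ref_cum <- cumsum(rc != "-")
  gap_runs <- rle(rc == "-")
  ends <- cumsum(gap_runs$lengths)
  starts <- ends - gap_runs$lengths + 1L
  cand <- which(gap_runs$values & gap_runs$lengths >= params$min_intron)

  gene_start <- region_offset + 1L
  gene_end <- host_cum[length(host_cum)]

  introns <- list()
  cuts <- integer(0)  # intron intervals in region coordinates
  for (ci in cand) {
    c0 <- starts[ci]; c1 <- ends[ci]
    s <- host_cum[c0]          # first intron nucleotide (host char in a ref-gap col)
    e <- host_cum[c1]
    refined <- .refine_boundary(seqc, ref_gene$sequence, s, e,
                                ref_before = ref_cum[c0])
    introns[[length(introns) + 1L]] <- list(start = refined$s, end = refined$e,
                                            confidence = refined$confidence)
    cuts <- c(cuts, refined$s, refined$e)
  }

  # assemble exons between introns
  bounds <- matrix(cuts, ncol = 2L, byrow = TRUE)
  ord <- order(bounds[, 1L][seq_len(nrow(bounds))])
  if (nrow(bounds)) bounds <- bounds[ord, , drop = FALSE]
  exon_starts <- c(gene_start, bounds[, 2L] + 1L)
  exon_ends <- c(bounds[, 1L] - 1L, gene_end)
  exons <- data.frame(
    genomic_start = exon_starts, genomic_end = exon_ends,
    sequence = substring(seqc, exon_starts, exon_ends),
    stringsAsFactors = FALSE
  )
  exon_lens <- nchar(exons$sequence)
  obs <- list()
  if (nrow(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      io <- intron_obs(
        host_offset = sum(exon_lens[seq_len(i)]),
        sequence = substring(seqc, bounds[i, 1L], bounds[i, 2L]),
        genomic_start = bounds[i, 1L], genomic_end = bounds[i, 2L]
      )
      attr(io, "boundary_confidence") <- introns[[ord[i]]]$confidence
      obs[[i]] <- io
    }
  }
  gene_record(
    species_name = meta$species_name, gene_name = ref_gene$gene_name,
    exons = exons, introns = obs, accession = meta$accession,
    strain = meta$strain, strand = "+"
  )
}

# Slide the intron interval [s, e] (region coordinates) by d in
# -window..window. Each placement is scored by how well the exon flanks it
# implies match the reference around the junction: the last W exon
# nucleotides 5' of the intron against ref[.. r0+d] and the first W exon
# nucleotides 3' of it against ref[r0+d+1 ..] (r0 = reference position of
# the junction at d = 0; shifting the boundary by d moves the junction by
# ~d reference positions). A half-point splice-signature bonus breaks ties
# between equally supported placements; remaining ties prefer d = 0, then
# the smaller |d|, and are flagged ambiguous.
.refine_boundary <- function(region, ref_seq, s, e, ref_before,
                             window = .REFINE_WINDOW) {
  n <- nchar(region)
  m <- nchar(ref_seq)
  W <- window
  score_of <- function(d) {
    s2 <- s + d; e2 <- e + d
    if (s2 < 2L || e2 >= n) return(-Inf)
    r <- ref_before + d
    if (r < 1L || r >= m) return(-Inf)
    left_host <- substring(region, max(s2 - W, 1L), s2 - 1L)
    left_ref <- substring(ref_seq, max(r - W + 1L, 1L), r)
    right_host <- substring(region, e2 + 1L, min(e2 + W, n))
    right_ref <- substring(ref_seq, r + 1L, min(r + W, m))
    .nmatch_right(left_host, left_ref) + .nmatch_left(right_host, right_ref) +
      0.5 * .splice_bonus(substring(region, s2, e2))
  }
  ds <- seq(-window, window)
  ds <- ds[order(abs(ds), ds)]  # 0 first, then +/-1, ...
  scores <- vapply(ds, score_of, 0)
  best <- which.max(scores)
  ambiguous <- sum(scores == scores[best]) > 1L
  list(s = s + ds[best], e = e + ds[best],
       confidence = if (ambiguous) "ambiguous" else "ok")
}

# matches of two strings aligned at their right (left) edge
.nmatch_right <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  k <- min(length(ac), length(bc))
  if (k == 0L) return(0L)
  sum(rev(ac)[seq_len(k)] == rev(bc)[seq_len(k)])
}

.nmatch_left <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  k <- min(length(ac), length(bc))
  if (k == 0L) return(0L)
  sum(ac[seq_len(k)] == bc[seq_len(k)])
}
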