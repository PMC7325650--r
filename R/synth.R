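# Synthetic host-gene generator: diverged copies of the reference genes
# carrying introns planted at known reference sites, with group I/II
# terminal signatures and a truth table sufficient to verify every
# downstream mapping and name exactly.

#' Describe a synthetic fixture
#'
#' @param seed Integer seed; identical spec + seed reproduce the fixture
#'   byte for byte.
#' @param plants data.frame with columns `gene`, `ref_site`,
#'   `intron_length`, `group` (`"I"`/`"II"`); optional `strand`.
#' @param divergence Per-site substitution probability (0-0.5).
#' @param indel_rate Per-site indel initiation probability (0-0.5).
#' @param indel_length_range Integer pair, inclusive.
#' @param species_label Binomial used on the emitted record.
#' @param strain Strain id.
#' @param accession Accession written to the fixture.
#' @param emit_annotation Emit an annotated GenBank (TRUE) or raw FASTA
#'   regions (FALSE).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, plants, divergence = 0.15, indel_rate = 0.01,
                         indel_length_range = c(1L, 10L),
                         species_label = "Simulata ficta",
                         strain = "", accession = "SYN000001",
                         emit_annotation = TRUE) {
  stopifnot(divergence >= 0, divergence <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5,
            all(c("gene", "ref_site", "intron_length", "group") %in% names(plants)))
  if (any(plants$intron_length < 50L))
    stop("planted introns must be at least 50 nt", call. = FALSE)
  if (!all(plants$group %in% c("I", "II")))
    stop("plant group must be 'I' or 'II'", call. = FALSE)
  plants$gene <- normalize_gene_name(plants$gene)
  if (anyNA(plants$gene)) stop("plants name non-canonical genes", call. = FALSE)
  if (is.null(plants$strand)) plants$strand <- "+"
  structure(list(seed = as.integer(seed), plants = plants,
                 divergence = divergence, indel_rate = indel_rate,
                 indel_length_range = as.integer(indel_length_range),
                 species_label = species_label, strain = strain,
                 accession = accession, emit_annotation = emit_annotation),
            class = "fixture_spec")
}

.GUARD <- 20L  # no mutation within this distance of a planted site

# Mutate one reference CDS; returns the mutated sequence and, for each
# requested reference site, the corresponding host offset after mutation.
.mutate_gene <- function(ref_seq, sites, divergence, indel_rate, indel_len) {
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  guarded <- rep(FALSE, n)
  for (s in sites) {
    lo <- max(1L, s - .GUARD); hi <- min(n, s + .GUARD)
    guarded[lo:hi] <- TRUE
  }
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n)
  sub_hit <- stats::runif(n) < divergence & !guarded
  ins_hit <- stats::runif(n) < indel_rate / 2 & !guarded
  del_hit <- stats::runif(n) < indel_rate / 2 & !guarded
  del_until <- 0L
  for (i in seq_len(n)) {
    if (i <= del_until) { out[[i]] <- character(0); next }
    if (del_hit[i]) {
      len <- sample(seq(indel_len[1], indel_len[2]), 1L)
      # never let a deletion run into a guard window
      stopat <- i + len - 1L
      g <- which(guarded[i:min(stopat, n)])
      if (length(g)) stopat <- i + g[1] - 2L
      del_until <- min(stopat, n)
      out[[i]] <- character(0)
      next
    }
    ch <- chars[i]
    if (sub_hit[i]) ch <- sample(setdiff(bases, chars[i]), 1L)
    if (ins_hit[i]) {
      len <- sample(seq(indel_len[1], indel_len[2]), 1L)
      ch <- c(ch, sample(bases, len, replace = TRUE))
    }
    out[[i]] <- ch
  }
  lens <- lengths(out)
  cum <- cumsum(lens)
  list(sequence = paste(unlist(out), collapse = ""),
       host_offset = vapply(sites, function(s) cum[s], 0))
}

.random_core <- function(len, gc) {
  pg <- gc / 2; pa <- (1 - gc) / 2
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c(pa, pa, pg, pg)), collapse = "")
}

.gc_frac <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(ch %in% c("G", "C"))
}

#' Build one intron sequence with a group I/II terminal signature
#'
#' Group I: 5' T ... 3' G. Group II: 5' GTGCG ... 3' AT. The core is random
#' with GC content matched to the host gene.
#'
#' @param length_nt Total intron length.
#' @param group `"I"` or `"II"`.
#' @param gc Target GC fraction for the core.
#' @return Intron sequence (character).
#' @keywords internal
.make_intron <- function(length_nt, group, gc = 0.3) {
  if (group == "I") {
    paste0("T", .random_core(length_nt - 2L, gc), "G")
  } else {
    paste0("GTGCG", .random_core(length_nt - 7L, gc), "AT")
  }
}

# TRUE when a shifted placement of the intron yields the identical spliced
# exon sequence and an equal splice-signature bonus -- i.e. the insertion
# point is not recoverable from sequence alone (terminal repeats between
# intron and exon). Such plants are redrawn so fixture truth stays exact.
.placement_ambiguous <- function(intron, ref_seq, site, window = 12L) {
  len <- nchar(intron)
  b0 <- .splice_bonus(intron)
  for (d in seq_len(window)) {
    # shift 3': intron prefix re-reads as exon
    if (site + d <= nchar(ref_seq) &&
        substr(intron, 1L, d) == substr(ref_seq, site + 1L, site + d)) {
      shifted <- paste0(substr(intron, d + 1L, len),
                        substr(ref_seq, site + 1L, site + d))
      if (.splice_bonus(shifted) >= b0) return(TRUE)
    }
    # shift 5': intron suffix re-reads as exon
    if (site - d >= 1L &&
        substr(intron, len - d + 1L, len) == substr(ref_seq, site - d + 1L, site)) {
      shifted <- paste0(substr(ref_seq, site - d + 1L, site),
                        substr(intron, 1L, len - d))
      if (.splice_bonus(shifted) >= b0) return(TRUE)
    }
  }
  FALSE
}

.draw_intron <- function(length_nt, group, gc, ref_seq, site, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    intron <- .make_intron(length_nt, group, gc)
    if (!.placement_ambiguous(intron, ref_seq, site)) return(intron)
  }
  stop("could not draw an unambiguous intron at site ", site, call. = FALSE)
}

#' Generate a synthetic fixture with planted introns
#'
#' For each gene named in `spec$plants` the reference CDS is mutated
#' (substitutions, then indels; never within 20 nt of a planted site), the
#' introns are inserted at the planted sites with group I/II terminal
#' signatures and random cores, and the result is written either as an
#' annotated GenBank record (CDS `join()` plus intron features) or as raw
#' FASTA regions. The truth table records each intron's host offset as
#' recomputed after mutation.
#'
#' @param spec A [fixture_spec].
#' @param ref A `ref_set`.
#' @param dir Output directory (created if needed).
#' @return List with `path` (the GenBank or FASTA file) and `truth`
#'   (data.frame: `gene`, `ref_site`, `host_offset`, `group`, `strand`,
#'   `intron_seq`, `suffix`).
#' @export
generate_fixture <- function(spec, ref, dir = tempdir()) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(ref, "ref_set"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plants <- spec$plants
  genes <- unique(plants$gene)

  for (g in genes) {
    rg <- ref$genes[[g]]
    if (is.null(rg)) stop("no reference gene: ", g, call. = FALSE)
    p <- plants[plants$gene == g, ]
    if (any(p$ref_site < 1L | p$ref_site >= rg$length_nt))
      stop("planted site outside reference gene ", g, call. = FALSE)
    s <- sort(unique(p$ref_site))
    if (length(s) > 1L && any(diff(s) <= .GUARD) && !all(diff(s) == 0))
      stop("planted sites within one guard window in gene ", g, call. = FALSE)
  }

  gene_out <- list()   # per gene: sequence with introns + intron coords
  truth_rows <- list()
  for (g in genes) {
    rg <- ref$genes[[g]]
    p <- plants[plants$gene == g, , drop = FALSE]
    p <- p[order(p$ref_site), , drop = FALSE]
    mut <- .mutate_gene(rg$sequence, p$ref_site, spec$divergence,
                        spec$indel_rate, spec$indel_length_range)
    gc <- .gc_frac(rg$sequence)
    gc <- min(max(gc + stats::runif(1, -0.05, 0.05), 0.05), 0.95)
    p$host_offset <- mut$host_offset
    # annotated fixtures carry exact boundaries in the join(); only raw
    # regions need the insertion point to be recoverable from sequence
    # alone, so only they reject plants with terminal-repeat ambiguity
    p$intron_seq <- vapply(seq_len(nrow(p)), function(i) {
      if (spec$emit_annotation)
        .make_intron(p$intron_length[i], p$group[i], gc)
      else
        .draw_intron(p$intron_length[i], p$group[i], gc, rg$sequence, p$ref_site[i])
    }, "")
    # suffixes expected downstream: letters within a same-site group
    p$suffix <- ""
    for (s in unique(p$ref_site)) {
      at <- which(p$ref_site == s)
      if (length(at) > 1L) p$suffix[at] <- letters[seq_along(at)]
    }
    # insert 3' to 5' (same-site members in reverse listed order) so that
    # earlier offsets stay valid and listed order reads 5' to 3'
    seq_with <- mut$sequence
    for (i in rev(order(p$host_offset))) {
      at <- p$host_offset[i]
      seq_with <- paste0(substr(seq_with, 1L, at),
                         p$intron_seq[i],
                         substr(seq_with, at + 1L, nchar(seq_with)))
    }
    # intron positions within the gene region, 5' to 3'
    region_pos <- integer(nrow(p))
    shift <- 0L
    for (i in order(p$host_offset)) {
      region_pos[i] <- p$host_offset[i] + shift + 1L
      shift <- shift + nchar(p$intron_seq[i])
    }
    p$region_start <- region_pos
    p$region_end <- region_pos + nchar(p$intron_seq) - 1L
    gene_out[[g]] <- list(sequence = seq_with, plants = p,
                          exonic_length = nchar(mut$sequence))
    truth_rows[[g]] <- p[, c("gene", "ref_site", "host_offset", "group",
                             "strand", "intron_seq", "suffix")]
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  if (spec$emit_annotation) {
    path <- file.path(dir, paste0(spec$accession, ".gb"))
    flank <- 100L
    genome <- character(0)
    cds <- list(); intr <- list()
    offset <- 0L
    spacer <- .random_core(flank, 0.3)
    genome <- spacer; offset <- flank
    for (g in genes) {
      gp <- gene_out[[g]]
      seq_g <- gp$sequence
      strand <- gp$plants$strand[1]
      n_g <- nchar(seq_g)
      # exon segments in region coordinates
      iv <- gp$plants[order(gp$plants$region_start), , drop = FALSE]
      ex_start <- c(1L, iv$region_end + 1L)
      ex_end <- c(iv$region_start - 1L, n_g)
      keep <- ex_end >= ex_start
      ex_start <- ex_start[keep]; ex_end <- ex_end[keep]
      if (strand == "-") {
        gseq <- .revcomp(seq_g)
        seg_start <- offset + (n_g - ex_end + 1L)
        seg_end <- offset + (n_g - ex_start + 1L)
        o <- order(seg_start)
        segs <- data.frame(start = seg_start[o], end = seg_end[o])
        istart <- offset + (n_g - iv$region_end + 1L)
        iend <- offset + (n_g - iv$region_start + 1L)
      } else {
        gseq <- seq_g
        segs <- data.frame(start = offset + ex_start, end = offset + ex_end)
        istart <- offset + iv$region_start
        iend <- offset + iv$region_end
      }
      genome <- paste0(genome, gseq)
      offset <- offset + n_g
      cds[[length(cds) + 1L]] <- list(gene = g, segments = segs, strand = strand)
      for (ii in seq_along(istart)) {
        intr[[length(intr) + 1L]] <- list(gene = g, start = istart[ii],
                                          end = iend[ii], strand = strand,
                                          note = "synthetic planted intron")
      }
      spacer <- .random_core(flank, 0.3)
      genome <- paste0(genome, spacer)
      offset <- offset + flank
    }
    write_genbank(path, locus = spec$accession, accession = spec$accession,
                  organism = spec$species_label, strain = spec$strain,
                  sequence = genome, cds = cds, introns = intr)
  } else {
    path <- file.path(dir, paste0(spec$accession, ".fasta"))
    con <- file(path, "w")
    for (g in genes) {
      cat(sprintf(">%s_%s %s\n", spec$accession, g, spec$species_label), file = con)
      s <- gene_out[[g]]$sequence
      starts <- seq(1, nchar(s), by = 70)
      writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
    }
    close(con)
  }
  list(path = path, truth = truth)
}

#' Generate strain variants of one planted intron site
#'
#' Emits `n_strains` fixtures of one species that all carry an intron at
#' the same reference site, with intron cores drawn from `variant_groups`
#' unrelated sequences (strains within a group differ by light
#' substitution, ~2%). The truth lists the expected variant numbering:
#' contiguous blocks in registration order, or none when a single group is
#' used.
#'
#' @param spec A [fixture_spec] with a single plant row.
#' @param n_strains Number of strains (>= 2).
#' @param variant_groups Number of unrelated intron cores (<= n_strains).
#' @param ref A `ref_set`.
#' @param dir Output directory.
#' @return List with `paths`, `strains`, `truth` (adds `expected_variant`,
#'   `NA` when variant_groups == 1).
#' @export
generate_strain_variants <- function(spec, n_strains, variant_groups, ref,
                                     dir = tempdir()) {
  stopifnot(n_strains >= 2L, variant_groups <= n_strains, variant_groups >= 1L,
            nrow(spec$plants) == 1L)
  set.seed(spec$seed)
  g <- spec$plants$gene[1]
  len <- spec$plants$intron_length[1]
  group <- spec$plants$group[1]
  gc <- .gc_frac(ref$genes[[g]]$sequence)
  cores <- vapply(seq_len(variant_groups), function(i) .make_intron(len, group, gc), "")
  assign_group <- as.integer(ceiling(seq_len(n_strains) * variant_groups / n_strains))
  paths <- character(n_strains)
  truths <- list()
  for (i in seq_len(n_strains)) {
    core <- cores[assign_group[i]]
    # light within-group divergence
    ch <- strsplit(core, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < 0.02)
    hit <- hit[hit > 5L & hit < length(ch) - 2L]  # keep terminal signatures
    if (length(hit))
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    intron_i <- paste(ch, collapse = "")
    spec_i <- spec
    spec_i$seed <- spec$seed + i
    spec_i$strain <- sprintf("STR%02d", i)
    spec_i$accession <- sprintf("%s_%02d", spec$accession, i)
    fx <- generate_fixture(spec_i, ref, dir = dir)
    # replace the planted intron with the variant core, re-emitting the file
    fx <- .replant_intron(fx, spec_i, ref, intron_i, dir)
    truth <- fx$truth
    truth$strain <- spec_i$strain
    truth$expected_variant <- if (variant_groups == 1L) NA_integer_ else assign_group[i]
    truths[[i]] <- truth
    paths[i] <- fx$path
  }
  list(paths = paths, strains = sprintf("STR%02d", seq_len(n_strains)),
       truth = do.call(rbind, truths))
}

# swap the planted intron sequence inside an emitted fixture for a given
# core, keeping coordinates consistent (same length by construction)
.replant_intron <- function(fx, spec, ref, intron_seq, dir) {
  stopifnot(nchar(intron_seq) == nchar(fx$truth$intron_seq[1]))
  recs <- read_genbank_genes(fx$path)
  rec <- recs[[which(vapply(recs, `[[`, "", "gene_name") == fx$truth$gene[1])]]
  gb <- read_genbank(fx$path)
  io <- rec$introns[[1]]
  plus_seq <- if (io$strand == "-") .revcomp(intron_seq) else intron_seq
  genome <- paste0(substr(gb$sequence, 1L, io$genomic_start - 1L), plus_seq,
                   substr(gb$sequence, io$genomic_end + 1L, nchar(gb$sequence)))
  lines <- readLines(fx$path)
  ostart <- grep("^ORIGIN", lines)
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(lines[seq_len(ostart)], tmp)
  con <- file(tmp, "a")
  .write_origin_lines(con, genome)
  writeLines("//", con)
  close(con)
  file.copy(tmp, fx$path, overwrite = TRUE)
  fx$truth$intron_seq[1] <- intron_seq
  fx
}
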