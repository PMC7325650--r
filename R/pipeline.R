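#' Name every intron in a set of annotated or raw inputs
#'
#' The full workflow: read exon/intron structure (GenBank) or infer it de
#' novo (raw regions), lift each intron's insertion point onto the
#' reference coordinate axis by pairwise alignment, assign the P/S/U letter
#' from external evidence or (optionally) the splice-site heuristic,
#' abbreviate species names, and resolve twintron letters and strain
#' variant numbers.
#'
#' @param inputs Character vector of GenBank flat-file paths, and/or a list
#'   of [gene_record] / `region` objects (regions go through
#'   [infer_introns()]).
#' @param reference A `ref_set`; defaults to the bundled (synthetic
#'   stand-in) reference.
#' @param type_table Optional path to, or result of, [read_type_table()].
#' @param params [align_params()] used for all alignments.
#' @param trust_heuristic Commit heuristic type calls to P/S letters
#'   (default FALSE: heuristic-only introns stay U).
#' @param registry An [abbrev_registry()] (updated in place).
#' @param variant_identity Single-link identity threshold for strain
#'   variant clustering (default 0.90).
#' @param gene_filter Optional canonical gene names to keep.
#' @return An object of class `intron_naming`: list with `records`,
#'   `names` (list of [intron_name] aligned with the flattened introns),
#'   `table` (see [intron_table()]), and `mapping` (per-intron liftover
#'   confidence).
#' @export
name_introns <- function(inputs, reference = bundled_reference(),
                         type_table = NULL, params = align_params(),
                         trust_heuristic = FALSE,
                         registry = abbrev_registry(),
                         variant_identity = 0.90, gene_filter = NULL) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (!is.list(inputs)) inputs <- list(inputs)
  records <- list()
  for (x in inputs) {
    if (is.character(x)) {
      first <- readLines(x, n = 1L)
      if (!grepl("^LOCUS", first))
        stop("raw FASTA input must be wrapped in read_fasta_region() ",
             "so species and gene are declared: ", x, call. = FALSE)
      records <- c(records, read_genbank_genes(x, gene_filter = gene_filter))
    } else if (inherits(x, "region")) {
      rg <- reference$genes[[x$gene_name]]
      if (is.null(rg)) stop("no reference gene for region: ", x$gene_name, call. = FALSE)
      rec <- infer_introns(x, rg, params)
      records <- c(records, list(rec))
    } else if (inherits(x, "gene_record")) {
      records <- c(records, list(x))
    } else stop("unsupported input of class ", paste(class(x), collapse = "/"),
                call. = FALSE)
  }
  if (!is.null(type_table) && is.character(type_table))
    type_table <- read_type_table(type_table)
  records <- apply_type_evidence(records, type_table, trust_heuristic)

  # lift all insertion points
  mapping <- list()
  sites <- vector("list", length(records))
  for (ri in seq_along(records)) {
    r <- records[[ri]]
    if (!length(r$introns)) { sites[[ri]] <- data.frame(); next }
    rg <- reference$genes[[r$gene_name]]
    if (is.null(rg)) stop("no reference gene for ", r$gene_name, call. = FALSE)
    aln <- align_to_reference(r$spliced_cds, rg, params,
                              host_id = paste(r$accession, r$gene_name))
    offs <- vapply(r$introns, `[[`, 0L, "host_offset")
    m <- map_insertion_site(aln, offs)
    m$identity <- aln$identity
    sites[[ri]] <- m
    mapping[[ri]] <- m
  }

  abbrevs <- vapply(records, function(r) make_abbrev(r$species_name, registry), "")

  # flatten intron-level info
  flat <- list()
  idx <- 0L
  for (ri in seq_along(records)) {
    r <- records[[ri]]
    for (k in seq_along(r$introns)) {
      idx <- idx + 1L
      flat[[idx]] <- list(ri = ri, k = k, species = r$species_name,
                          genome = paste(r$accession, r$strain),
                          gene = r$gene_name,
                          site = sites[[ri]]$site[k],
                          declared = r$introns[[k]]$declared_type)
    }
  }

  suffixes <- rep("", length(flat))
  variants <- rep(NA_integer_, length(flat))
  if (length(flat)) {
    site_key <- vapply(flat, function(f) paste(f$species, f$gene, f$site, sep = "\r"), "")
    genome_key <- vapply(flat, function(f) f$genome, "")
    # twintron letters: members of one genome at one site
    for (key in unique(paste(site_key, genome_key, sep = "\r"))) {
      at <- which(paste(site_key, genome_key, sep = "\r") == key)
      if (length(at) > 1L) {
        obs <- lapply(at, function(i) records[[flat[[i]]$ri]]$introns[[flat[[i]]$k]])
        suffixes[at] <- assign_twintron_suffixes(obs)
      }
    }
    # strain variants: one intron per genome, several genomes at one site
    for (key in unique(site_key)) {
      at <- which(site_key == key)
      if (length(at) > 1L && length(unique(genome_key[at])) > 1L &&
          !any(nzchar(suffixes[at]))) {
        obs <- lapply(at, function(i) records[[flat[[i]]$ri]]$introns[[flat[[i]]$k]])
        variants[at] <- assign_variant_numbers(obs, variant_identity, params)
      }
    }
  }

  names_out <- vector("list", length(flat))
  for (i in seq_along(flat)) {
    f <- flat[[i]]
    names_out[[i]] <- intron_name(
      type_letter = letter_for(f$declared), site = f$site,
      abbrev = abbrevs[f$ri], gene_name = f$gene,
      suffix = suffixes[i], variant = variants[i]
    )
  }

  structure(list(
    records = records, names = names_out,
    table = intron_table(records, names_out),
    mapping = mapping, registry = registry
  ), class = "intron_naming")
}

#' @export
print.intron_naming <- function(x, ...) {
  cat(sprintf("<intron_naming> %d record(s), %d intron(s)\n",
              length(x$records), length(x$names)))
  if (nrow(x$table)) print(x$table[, c("species", "gene", "full_name", "intron_length")])
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `reference_path`, `match`, `mismatch`, `gap_open`,
#' `gap_extend`, `min_identity`, `min_intron`, `variant_identity`,
#' `trust_heuristic`, `abbreviations` (map species -> abbrev), `out_dir`.
#'
#' @param path YAML file (NULL for all defaults).
#' @return List with `reference`, `params`, `variant_identity`,
#'   `trust_heuristic`, `registry`, `out_dir`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  params <- align_params(
    match = cfg$match %||% 2, mismatch = cfg$mismatch %||% -3,
    gap_open = cfg$gap_open %||% 10, gap_extend = cfg$gap_extend %||% 1,
    min_identity = cfg$min_identity %||% 0.30,
    min_intron = cfg$min_intron %||% 30L
  )
  vi <- cfg$variant_identity %||% 0.90
  stopifnot(vi > 0, vi <= 1)
  reference <- if (!is.null(cfg$reference_path))
    load_reference(cfg$reference_path) else bundled_reference()
  overrides <- unlist(cfg$abbreviations %||% list())
  list(reference = reference, params = params, variant_identity = vi,
       trust_heuristic = isTRUE(cfg$trust_heuristic),
       registry = abbrev_registry(if (length(overrides)) overrides else character(0)),
       out_dir = cfg$out_dir %||% ".")
}
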