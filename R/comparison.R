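#' Build a cross-species intron-site matrix
#'
#' Rows are species, columns the 15 canonical genes; each cell holds the
#' site labels (type letter + site + optional twintron letter) of that
#' species' introns in that gene, sorted by site. Gene presence
#' distinguishes genuinely absent genes from genes without data.
#'
#' @param all_names data.frame with columns `species`, `gene`, `label`
#'   (e.g. `"P393"`), or columns `species`, `gene`, `type_letter`, `site`
#'   (+ optional `suffix`). One row per intron.
#' @param gene_presence Optional data.frame with columns `species`, `gene`,
#'   `status` (`"absent"`, `"not_available"` or `"present"`); genes not
#'   listed are `"present"`. A `"present"` row also serves to register an
#'   intron-free species so it appears in the matrix.
#' @return An object of class `site_matrix`.
#' @export
build_site_matrix <- function(all_names, gene_presence = NULL) {
  if (nrow(all_names) && !"label" %in% names(all_names)) {
    suffix <- if ("suffix" %in% names(all_names)) all_names$suffix else ""
    all_names$label <- paste0(all_names$type_letter, all_names$site, suffix)
  }
  if (nrow(all_names)) {
    parsed <- lapply(all_names$label, parse_name)  # validates the grammar
    all_names$site <- vapply(parsed, `[[`, 0L, "site")
    all_names$suffix <- vapply(parsed, `[[`, "", "suffix")
    gene <- normalize_gene_name(all_names$gene)
    if (anyNA(gene)) stop("unknown gene name(s): ",
                          paste(unique(all_names$gene[is.na(gene)]), collapse = ", "),
                          call. = FALSE)
    all_names$gene <- gene
    dupkey <- paste(all_names$species, all_names$gene, all_names$site, all_names$suffix)
    if (anyDuplicated(dupkey))
      stop("duplicate intron name within one genome: ",
           paste(unique(dupkey[duplicated(dupkey)]), collapse = "; "), call. = FALSE)
  }
  species <- unique(all_names$species)
  presence <- list()
  if (!is.null(gene_presence) && nrow(gene_presence)) {
    gene_presence$gene <- normalize_gene_name(gene_presence$gene)
    species <- unique(c(species, gene_presence$species))
    for (i in seq_len(nrow(gene_presence))) {
      if (gene_presence$status[i] == "present") next
      presence[[paste(gene_presence$species[i], gene_presence$gene[i], sep = "\r")]] <-
        gene_presence$status[i]
    }
  }
  species <- sort(species)
  cells <- list()
  if (nrow(all_names)) {
    all_names <- all_names[order(all_names$species, all_names$gene,
                                 all_names$site, all_names$suffix), ]
    key <- paste(all_names$species, all_names$gene, sep = "\r")
    cells <- split(all_names$label, key)
    sites <- split(all_names$site, key)
    bad <- names(presence)[names(presence) %in% names(cells) &
                             unlist(presence[names(presence)]) == "absent"]
    if (length(bad))
      stop("introns recorded in a gene flagged absent: ",
           gsub("\r", "/", paste(bad, collapse = "; ")), call. = FALSE)
  } else {
    sites <- list()
  }
  structure(list(species = species, genes = CANONICAL_GENES,
                 cells = cells, sites = sites, presence = presence),
            class = "site_matrix")
}

.cell_key <- function(species, gene) paste(species, gene, sep = "\r")

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("<site_matrix> %d species x %d genes, %d introns\n",
              length(x$species), length(x$genes),
              sum(lengths(x$cells))))
  invisible(x)
}

#' Summarize an intron-site matrix
#'
#' Per gene: total introns (labels counted with multiplicity), number of
#' species carrying at least one intron in the gene, and number of distinct
#' insertion points. An insertion point is the site integer: the type
#' letter and twintron suffixes are ignored, so a P and a U at one site are
#' one insertion point, and twintron members count as multiple introns at
#' one point. Per species: total introns and number of intron-containing
#' genes.
#'
#' @param matrix A `site_matrix`.
#' @return List with data.frames `per_gene`, `per_species` and a `totals`
#'   row (grand totals across genes).
#' @export
summarize_sites <- function(matrix) {
  stopifnot(inherits(matrix, "site_matrix"))
  per_gene <- do.call(rbind, lapply(matrix$genes, function(g) {
    keys <- .cell_key(matrix$species, g)
    have <- keys %in% names(matrix$cells)
    n_introns <- sum(lengths(matrix$cells[keys[have]]))
    n_species <- sum(vapply(matrix$cells[keys[have]], length, 0L) > 0L)
    n_sites <- length(unique(unlist(matrix$sites[keys[have]])))
    data.frame(gene = g, n_introns = n_introns, n_species = n_species,
               n_sites = n_sites, stringsAsFactors = FALSE)
  }))
  per_species <- do.call(rbind, lapply(matrix$species, function(sp) {
    keys <- .cell_key(sp, matrix$genes)
    have <- keys %in% names(matrix$cells)
    data.frame(species = sp,
               n_introns = sum(lengths(matrix$cells[keys[have]])),
               n_genes = sum(vapply(matrix$cells[keys[have]], length, 0L) > 0L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_species))
    per_species <- data.frame(species = character(), n_introns = integer(),
                              n_genes = integer(), stringsAsFactors = FALSE)
  list(per_gene = per_gene, per_species = per_species,
       totals = data.frame(n_introns = sum(per_gene$n_introns),
                           n_sites = sum(per_gene$n_sites)))
}

#' Insertion points shared across species
#'
#' @param matrix A `site_matrix`.
#' @param min_species Minimum number of species carrying an intron at the
#'   point (>= 2).
#' @return data.frame with columns `gene`, `site`, `n_species`, `species`
#'   (comma-joined), sorted by species count descending then gene/site.
#' @export
shared_sites <- function(matrix, min_species = 2L) {
  stopifnot(inherits(matrix, "site_matrix"), min_species >= 2L)
  rows <- list()
  for (g in matrix$genes) {
    keys <- .cell_key(matrix$species, g)
    have <- which(keys %in% names(matrix$sites))
    if (!length(have)) next
    site_by_sp <- lapply(matrix$sites[keys[have]], unique)
    tab <- table(unlist(site_by_sp))
    for (s in names(tab[tab >= min_species])) {
      carriers <- matrix$species[have][vapply(site_by_sp, function(x) as.integer(s) %in% x, TRUE)]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, site = as.integer(s), n_species = length(carriers),
        species = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), site = integer(), n_species = integer(),
               species = character(), stringsAsFactors = FALSE)
  out[order(-out$n_species, out$gene, out$site), , drop = FALSE]
}

#' Write a site matrix (and optionally its summary) to TSV or JSON
#'
#' Cells are comma-joined labels; absent genes are rendered `--` and genes
#' without data `NA`, introns-free present genes `0`.
#'
#' @param matrix A `site_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The rendered data.frame, invisibly.
#' @export
write_site_matrix <- function(matrix, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  render <- function(sp, g) {
    key <- .cell_key(sp, g)
    st <- matrix$presence[[key]]
    if (!is.null(st)) {
      if (st == "absent") return("--")
      if (st == "not_available") return("NA")
    }
    cell <- matrix$cells[[key]]
    if (is.null(cell) || !length(cell)) "0" else paste(cell, collapse = ", ")
  }
  df <- data.frame(species = matrix$species, stringsAsFactors = FALSE)
  for (g in matrix$genes)
    df[[g]] <- vapply(matrix$species, render, "", g = g)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(df)
}
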