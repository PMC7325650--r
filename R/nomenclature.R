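#' Construct an intron name
#'
#' The structured name behind strings such as `Sce.cox1S169`,
#' `Hau.cox3P640a` or `Hth.cobP429-1`: species abbreviation, host gene,
#' one capital letter P (group I), S (group II) or U (undetermined type),
#' the insertion site on the reference gene, an optional lowercase twintron
#' letter, and an optional numeric strain-variant suffix. The type letter
#' and the site are mandatory; abbreviation and gene may be omitted when
#' context makes them unambiguous.
#'
#' @param type_letter `"P"`, `"S"` or `"U"`.
#' @param site Insertion site (reference coordinate, >= 1).
#' @param abbrev Species abbreviation (`"[A-Z][a-z]{2,}"`) or `""`.
#' @param gene_name Canonical gene name or `""`.
#' @param suffix Single lowercase twintron letter or `""`.
#' @param variant Strain-variant number (>= 1) or `NA`.
#' @return An object of class `intron_name`.
#' @export
intron_name <- function(type_letter, site, abbrev = "", gene_name = "",
                        suffix = "", variant = NA_integer_) {
  if (!type_letter %in% c("P", "S", "U"))
    stop("type letter must be P, S or U", call. = FALSE)
  site <- as.integer(site)
  if (is.na(site) || site < 1L) stop("site must be an integer >= 1", call. = FALSE)
  if (nzchar(abbrev) && !grepl("^[A-Z][a-z]{2,}$", abbrev))
    stop("abbreviation must match [A-Z][a-z]{2,}: ", abbrev, call. = FALSE)
  if (nzchar(gene_name)) {
    g <- normalize_gene_name(gene_name)
    if (is.na(g)) stop("unknown gene name '", gene_name, "'; canonical names are: ",
                       paste(CANONICAL_GENES, collapse = ", "), call. = FALSE)
    gene_name <- g
  }
  if (nzchar(suffix) && !grepl("^[a-z]$", suffix))
    stop("twintron suffix must be a single lowercase letter", call. = FALSE)
  variant <- as.integer(variant)
  if (!is.na(variant) && variant < 1L) stop("variant number must be >= 1", call. = FALSE)
  structure(list(abbrev = abbrev, gene_name = gene_name,
                 type_letter = type_letter, site = site,
                 suffix = suffix, variant = variant),
            class = "intron_name")
}

#' Format an intron name
#'
#' Canonical form `Abbrev.geneXsite[suffix][-variant]`, with an ASCII
#' hyphen before the variant number. The type letter and site are never
#' omitted.
#'
#' @param name An [intron_name].
#' @param omit_abbrev,omit_gene Drop the species abbreviation / gene name
#'   (legal whenever context disambiguates).
#' @return The name as a character scalar.
#' @examples
#' format_name(intron_name("S", 169, "Sce", "cox1"))
#' @export
format_name <- function(name, omit_abbrev = FALSE, omit_gene = FALSE) {
  stopifnot(inherits(name, "intron_name"))
  paste0(
    if (nzchar(name$abbrev) && !omit_abbrev) paste0(name$abbrev, ".") else "",
    if (nzchar(name$gene_name) && !omit_gene) name$gene_name else "",
    name$type_letter, name$site, name$suffix,
    if (!is.na(name$variant)) paste0("-", name$variant) else ""
  )
}

#' @export
print.intron_name <- function(x, ...) {
  cat(format_name(x), "\n")
  invisible(x)
}

#' @export
format.intron_name <- function(x, ...) format_name(x)

#' @export
as.character.intron_name <- function(x, ...) format_name(x)

.NAME_REGEX <- paste0(
  "^(?:([A-Z][a-z]{2,})\\.)?",                       # abbreviation + dot
  "(atp[689]|cob|cox[123]|nad4L|nad4l|nad[1-6]|rps3)?",  # gene
  "([PSU])([0-9]+)([a-z]?)",                         # type letter + site + twintron
  "(?:[-\u2013]([0-9]+))?$"          # variant (hyphen or en-dash)
)

#' Parse an intron name string
#'
#' Inverse of [format_name()]. Accepts names lacking the abbreviation
#' and/or gene (`"cobP490"`, `"P717"`), a hyphen or en-dash before the
#' variant number, and `nad4l` as a spelling of `nad4L`; otherwise
#' case-sensitive.
#'
#' @param text Character scalar.
#' @return An [intron_name].
#' @examples
#' parse_name("Cgl.cox1P240")
#' parse_name("Hth.cobP429-1")
#' @export
parse_name <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec(.NAME_REGEX, text))[[1]]
  if (length(m) == 0L) {
    if (!grepl("[PSU][0-9]", text))
      stop("cannot parse intron name '", text,
           "': the type letter (P/S/U) and insertion site are mandatory",
           call. = FALSE)
    stop("cannot parse intron name '", text, "'", call. = FALSE)
  }
  gene <- m[3]
  if (nzchar(gene)) gene <- normalize_gene_name(gene)
  intron_name(
    type_letter = m[4], site = as.integer(m[5]),
    abbrev = m[2], gene_name = if (nzchar(m[3])) gene else "",
    suffix = m[6],
    variant = if (nzchar(m[7])) as.integer(m[7]) else NA_integer_
  )
}

#' Intron phase from the insertion site
#'
#' Phase 0 means the intron inserts between two codons (site divisible by
#' three, e.g. cobP393); phases 1 and 2 mean insertion after the first or
#' second position of a codon.
#'
#' @param site Integer vector of insertion sites (>= 1).
#' @return Integer vector of phases in `{0, 1, 2}`.
#' @examples
#' compute_phase(c(393, 205, 386))
#' @export
compute_phase <- function(site) {
  site <- as.integer(site)
  if (anyNA(site) || any(site < 1L)) stop("site must be >= 1", call. = FALSE)
  site %% 3L
}

#' Create a species-abbreviation registry
#'
#' Holds the mapping from species binomials to their name abbreviations and
#' guarantees injectivity. Manual overrides always win over the automatic
#' rule.
#'
#' @param overrides Named character vector: `c("Genus epithet" = "Abbr")`.
#' @return An object of class `abbrev_registry` (environment-backed; calls
#'   to [make_abbrev()] update it in place).
#' @export
abbrev_registry <- function(overrides = character(0)) {
  if (length(overrides) && anyDuplicated(unname(overrides)))
    stop("override abbreviations must be distinct", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$entries <- character(0)             # names = species, values = abbrev
  env$override <- logical(0)
  if (length(overrides)) {
    env$entries <- unname(overrides)
    names(env$entries) <- names(overrides)
    env$override <- rep(TRUE, length(overrides))
    names(env$override) <- names(overrides)
  }
  structure(env, class = "abbrev_registry")
}

#' @export
print.abbrev_registry <- function(x, ...) {
  cat("<abbrev_registry>", length(x$entries), "entries\n")
  if (length(x$entries))
    cat(sprintf("  %-5s %s%s\n", unname(x$entries), names(x$entries),
                ifelse(x$override, " (override)", "")), sep = "")
  invisible(x)
}

#' @export
as.data.frame.abbrev_registry <- function(x, ...) {
  data.frame(species = names(x$entries), abbrev = unname(x$entries),
             override = unname(x$override), stringsAsFactors = FALSE)
}

.default_abbrev <- function(genus, epithet, k) {
  if (nchar(epithet) < k)
    stop("epithet '", epithet, "' too short to disambiguate; supply a manual override",
         call. = FALSE)
  paste0(toupper(substr(genus, 1L, 1L)), tolower(substr(epithet, 1L, k)))
}

#' Abbreviate a species name, resolving collisions
#'
#' Default rule: uppercase genus initial plus the first two lowercase
#' epithet letters (`"Saccharomyces cerevisiae"` -> `"Sce"`). When the
#' three-letter form cannot discriminate between species already in the
#' registry, all colliding species are re-abbreviated with further epithet
#' letters (the smallest k making them all distinct), e.g. *Candida
#' pseudojiufengensis* / *Candida psychrophila* -> `Cpse` / `Cpsy`.
#' Registered overrides win and are never re-abbreviated.
#'
#' @param species_name Binomial (`"Genus epithet"`, optionally with a
#'   strain suffix, which is ignored for abbreviation).
#' @param registry An [abbrev_registry()]; updated in place.
#' @return The abbreviation for `species_name`.
#' @export
make_abbrev <- function(species_name, registry = abbrev_registry()) {
  stopifnot(inherits(registry, "abbrev_registry"))
  if (species_name %in% names(registry$entries))
    return(unname(registry$entries[[species_name]]))
  parts <- strsplit(trimws(species_name), "[[:space:]]+")[[1]]
  if (length(parts) < 2L)
    stop("species name must be a binomial (Genus epithet): ", species_name,
         call. = FALSE)
  genus <- parts[1]; epithet <- parts[2]

  cand <- .default_abbrev(genus, epithet, 2L)
  entries <- registry$entries
  clash <- names(entries)[entries == cand & !registry$override]
  if (!cand %in% entries) {
    registry$entries[species_name] <- cand
    registry$override[species_name] <- FALSE
    return(cand)
  }
  if (length(clash) == 0L)
    stop("abbreviation '", cand, "' is taken by an override; supply a manual override for ",
         species_name, call. = FALSE)

  group <- c(clash, species_name)
  split2 <- function(sp) strsplit(trimws(sp), "[[:space:]]+")[[1]]
  for (k in 3:12) {
    abbrs <- vapply(group, function(sp) {
      p <- split2(sp); .default_abbrev(p[1], p[2], k)
    }, "")
    taken <- setdiff(unname(registry$entries), registry$entries[clash])
    if (!anyDuplicated(abbrs) && !any(abbrs %in% taken)) {
      for (i in seq_along(group)) {
        registry$entries[group[i]] <- abbrs[[i]]
        if (!group[i] %in% names(registry$override))
          registry$override[group[i]] <- FALSE
      }
      return(unname(abbrs[[length(group)]]))
    }
  }
  stop("cannot disambiguate abbreviations for: ", paste(group, collapse = ", "),
       "; supply manual overrides", call. = FALSE)
}

#' Assign twintron suffixes
#'
#' For two or more introns of one genome sharing (species, gene, site):
#' letters a, b, c, ... in 5'-to-3' order of the genomic start coordinate
#' in transcription orientation; for nested introns the outer member
#' precedes the inner.
#'
#' @param introns_at_site List of [intron_obs] sharing one insertion site.
#' @return Character vector of suffixes aligned with the input (all `""`
#'   when only one intron is given).
#' @export
assign_twintron_suffixes <- function(introns_at_site) {
  n <- length(introns_at_site)
  if (n == 1L) return("")
  if (n > 26L) stop("more than 26 twintron members at one site", call. = FALSE)
  strand <- vapply(introns_at_site, function(x) x$strand %||% "+", "")
  s <- vapply(introns_at_site, `[[`, 0L, "genomic_start")
  e <- vapply(introns_at_site, `[[`, 0L, "genomic_end")
  five_prime <- ifelse(strand == "+", s, -e)
  span <- e - s
  ord <- order(five_prime, -span)
  letters[order(ord)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign strain-variant numbers to same-site introns
#'
#' Introns occupying one (species, gene, site) in different strains are
#' clustered by single linkage on pairwise global-alignment identity;
#' clusters meeting `identity_threshold` share a variant number, numbered
#' in first-registration order. A single cluster yields no numbers (the
#' common case of a conserved intron).
#'
#' @param same_site_introns List of [intron_obs] (or plain sequences) from
#'   different strains/genomes at one site.
#' @param identity_threshold Fraction in (0,1]; default 0.90.
#' @param params Alignment scoring used for the pairwise identities.
#' @return Integer vector of variant numbers (all `NA` when one cluster).
#' @export
assign_variant_numbers <- function(same_site_introns, identity_threshold = 0.90,
                                   params = align_params()) {
  seqs <- vapply(same_site_introns, function(x) {
    if (inherits(x, "intron_obs")) x$sequence else .as_seq(x)
  }, "")
  n <- length(seqs)
  if (n <= 1L) return(rep(NA_integer_, n))
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (.pair_identity(seqs[i], seqs[j], params) >= identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  cluster <- match(roots, unique(roots))  # first-registration order
  if (max(cluster) == 1L) rep(NA_integer_, n) else cluster
}

# identity over alignment columns (matches / alignment length), so length
# variation between distantly related introns depresses the value
.pair_identity <- function(a, b, params = align_params()) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Build a renaming table from serial intron names
#'
#' Maps previously published serial names (``cox1-i1`` style by default, or
#' supplied old names such as yeast ``aI1``) to the standard names.
#'
#' @param records List of [gene_record]; introns may carry an `old_name`.
#' @param names List of [intron_name], aligned 1:1 with the introns of
#'   `records` flattened in record order.
#' @return data.frame with columns `old_name`, `new_name`, `species`,
#'   `accession`.
#' @export
build_rename_table <- function(records, names) {
  n_introns <- sum(vapply(records, function(r) length(r$introns), 0L))
  if (n_introns != length(names))
    stop("records carry ", n_introns, " intron(s) but ", length(names),
         " name(s) were supplied", call. = FALSE)
  rows <- list()
  i <- 0L
  for (r in records) {
    for (k in seq_along(r$introns)) {
      i <- i + 1L
      old <- r$introns[[k]]$old_name
      if (is.na(old)) old <- sprintf("%s-i%d", r$gene_name, k)
      rows[[i]] <- data.frame(old_name = old, new_name = format_name(names[[i]]),
                              species = r$species_name, accession = r$accession,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(old_name = character(), new_name = character(),
               species = character(), accession = character(),
               stringsAsFactors = FALSE)
}
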