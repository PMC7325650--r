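# Shared helpers for the test suite. Everything is generated in code; no
# binary fixtures.

ref_set_fixture <- function() bundled_reference()

# a tiny two-gene reference handy for fast unit tests
tiny_ref <- function() {
  seqs <- c(
    cox1 = paste0("ATG", strrep("GATTACAGGT", 30), "TAA"),
    cob  = paste0("ATG", strrep("TTAGCAATGG", 24), "TAA")
  )
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(g) c(paste0(">", g), seqs[[g]]))), path)
  load_reference(path, format = "fasta", source_accession = "TINY")
}

# write a GenBank file with one cox1 CDS join(1..300,801..1100) on the
# given strand, over a deterministic genome
simple_join_gb <- function(strand = "+", path = tempfile(fileext = ".gb")) {
  set.seed(99L)
  genome <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE), collapse = "")
  mitonom:::write_genbank(
    path, locus = "TEST01", accession = "TEST01",
    organism = "Simulata ficta", strain = "",
    sequence = genome,
    cds = list(list(gene = "cox1",
                    segments = data.frame(start = c(1L, 801L), end = c(300L, 1100L)),
                    strand = strand))
  )
  list(path = path, genome = genome)
}

revcomp <- function(x) mitonom:::.revcomp(x)

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at the given rate; no indels
mutate_subs <- function(seq, rate, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(ch, collapse = "")
}

# random valid intron name under the grammar
random_intron_name <- function() {
  abbrev <- if (runif(1) < 0.7) {
    paste0(sample(LETTERS, 1),
           paste(sample(letters, sample(2:5, 1), replace = TRUE), collapse = ""))
  } else ""
  gene <- if (runif(1) < 0.8) sample(CANONICAL_GENES, 1) else ""
  intron_name(
    type_letter = sample(c("P", "S", "U"), 1),
    site = sample(1:5000, 1),
    abbrev = abbrev, gene_name = gene,
    suffix = if (runif(1) < 0.2) sample(letters, 1) else "",
    variant = if (runif(1) < 0.2) sample(1:9, 1) else NA_integer_
  )
}

survey_tables <- function() {
  list(
    introns = read.table(system.file("extdata", "fungal_intron_survey.tsv",
                                     package = "mitonom"),
                         sep = "\t", header = TRUE, stringsAsFactors = FALSE),
    presence = read.table(system.file("extdata", "fungal_intron_gene_presence.tsv",
                                      package = "mitonom"),
                          sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  )
}
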