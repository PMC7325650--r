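test_that("published example names format exactly", {
  expect_identical(format_name(intron_name("S", 169, "Sce", "cox1")), "Sce.cox1S169")
  expect_identical(format_name(intron_name("P", 640, "Hau", "cox3", suffix = "a")),
                   "Hau.cox3P640a")
  expect_identical(format_name(intron_name("P", 429, "Hth", "cob", variant = 1L)),
                   "Hth.cobP429-1")
  nm <- intron_name("P", 393, "Cme", "cob")
  expect_identical(format_name(nm, omit_abbrev = TRUE), "cobP393")
  expect_identical(format_name(nm, omit_abbrev = TRUE, omit_gene = TRUE), "P393")
})

test_that("parser inverts the formatter and accepts en-dash variants", {
  p <- parse_name("Cgl.cox1P240")
  expect_identical(p$abbrev, "Cgl")
  expect_identical(p$gene_name, "cox1")
  expect_identical(p$type_letter, "P")
  expect_identical(p$site, 240L)

  p2 <- parse_name("Cpse.nad5U717")
  expect_identical(p2$abbrev, "Cpse")
  expect_identical(p2$type_letter, "U")

  # en-dash (as printed) normalizes to canonical hyphen
  expect_identical(format_name(parse_name("Hth.cobP429–1")), "Hth.cobP429-1")
  # nad4l spelling is accepted and canonicalized
  expect_identical(parse_name("nad4lP99")$gene_name, "nad4L")
  # bare forms
  expect_identical(parse_name("cobP490")$gene_name, "cob")
  expect_identical(parse_name("P717")$site, 717L)
})

test_that("names missing the mandatory letter or site fail to parse", {
  expect_error(parse_name("cox1169"), "mandatory")
  expect_error(parse_name("Sce.cox1"), "mandatory")
  expect_error(parse_name(""), "mandatory")
  expect_error(parse_name("Sce.cox1Q169"), "mandatory|parse")
  expect_error(intron_name("P", 0), ">= 1")
  expect_error(intron_name("X", 5), "P, S or U")
})

test_that("parse/format round-trips over a generated battery", {
  set.seed(42)
  for (i in 1:500) {
    nm <- random_intron_name()
    s <- format_name(nm)
    back <- parse_name(s)
    expect_identical(format_name(back), s)
    expect_identical(unclass(back), unclass(nm))
  }
})

test_that("phase follows site mod 3 and is shift-invariant", {
  expect_identical(compute_phase(393L), 0L)
  expect_identical(compute_phase(205L), 1L)
  expect_identical(compute_phase(386L), 2L)
  sites <- sample(1:5000, 200)
  expect_true(all(compute_phase(sites) %in% 0:2))
  expect_identical(compute_phase(sites), compute_phase(sites + 3L))
  expect_error(compute_phase(0L), ">= 1")
})

test_that("abbreviations follow genus initial + epithet letters with collision extension", {
  reg <- abbrev_registry()
  expect_identical(make_abbrev("Saccharomyces cerevisiae", reg), "Sce")
  expect_identical(make_abbrev("Xx yy", abbrev_registry()), "Xyy")
  make_abbrev("Candida pseudojiufengensis", reg)
  make_abbrev("Candida psychrophila", reg)
  df <- as.data.frame(reg)
  expect_identical(df$abbrev[df$species == "Candida pseudojiufengensis"], "Cpse")
  expect_identical(df$abbrev[df$species == "Candida psychrophila"], "Cpsy")
  # injectivity after arbitrary registration sequences
  set.seed(9)
  reg2 <- abbrev_registry()
  species <- c("Aa bcaaa", "Ab bcbbb", "Ac bcccc", "Ad bzzz", "Ae qqqq")
  for (sp in sample(species)) make_abbrev(sp, reg2)
  abbrs <- as.data.frame(reg2)$abbrev
  expect_identical(anyDuplicated(abbrs), 0L)
})

test_that("abbreviation edge cases error with guidance", {
  expect_error(make_abbrev("Monomial", abbrev_registry()), "binomial")
  reg <- abbrev_registry()
  make_abbrev("Aus bc", reg)
  expect_error(make_abbrev("Azz bc", reg), "override")  # identical short epithets
  reg2 <- abbrev_registry(overrides = c("Saccharomyces cerevisiae" = "Scer"))
  expect_identical(make_abbrev("Saccharomyces cerevisiae", reg2), "Scer")
})

test_that("twintron suffixes are alphabetical from 'a', outer first for nested pairs", {
  side_by_side <- list(
    intron_obs(640, "TAAAG", genomic_start = 700, genomic_end = 704),
    intron_obs(640, "TCCCG", genomic_start = 705, genomic_end = 709)
  )
  expect_identical(assign_twintron_suffixes(side_by_side), c("a", "b"))
  expect_identical(assign_twintron_suffixes(rev(side_by_side)), c("b", "a"))
  expect_identical(assign_twintron_suffixes(side_by_side[1]), "")

  nested <- list(
    intron_obs(640, strrep("A", 50), genomic_start = 705, genomic_end = 754),  # inner
    intron_obs(640, strrep("A", 200), genomic_start = 700, genomic_end = 899)  # outer
  )
  expect_identical(assign_twintron_suffixes(nested), c("b", "a"))

  # minus strand: 5' in transcription orientation = larger genomic coordinate
  minus <- list(
    intron_obs(640, "TAAAG", genomic_start = 700, genomic_end = 704, strand = "-"),
    intron_obs(640, "TCCCG", genomic_start = 705, genomic_end = 709, strand = "-")
  )
  expect_identical(assign_twintron_suffixes(minus), c("b", "a"))
})

test_that("variant numbers cluster same-site introns by identity in registration order", {
  set.seed(12)
  core_a <- random_dna(300)
  core_b <- random_dna(300)
  a1 <- mutate_subs(core_a, 0.02, seed = 1)
  a2 <- mutate_subs(core_a, 0.02, seed = 2)
  b1 <- mutate_subs(core_b, 0.02, seed = 3)
  expect_identical(assign_variant_numbers(list(a1, a2, b1)), c(1L, 1L, 2L))
  expect_identical(assign_variant_numbers(list(b1, a1, a2)), c(1L, 2L, 2L))
  # a single cluster yields no numbers at all
  expect_identical(assign_variant_numbers(list(a1, a2)), rep(NA_integer_, 2))
  expect_identical(assign_variant_numbers(list(core_a, core_a)), rep(NA_integer_, 2))
})

test_that("rename tables pair serial old names with standard names", {
  exons <- data.frame(genomic_start = c(1L, 501L), genomic_end = c(300L, 800L),
                      sequence = c(strrep("A", 300), strrep("G", 300)))
  rec <- gene_record("Saccharomyces cerevisiae", "cox1", exons,
                     introns = list(intron_obs(300, strrep("T", 200),
                                               genomic_start = 301, genomic_end = 500,
                                               old_name = "aI1")),
                     accession = "NC_001224")
  tab <- build_rename_table(list(rec), list(intron_name("S", 169, "Sce", "cox1")))
  expect_identical(tab$old_name, "aI1")
  expect_identical(tab$new_name, "Sce.cox1S169")

  rec2 <- rec
  rec2$introns[[1]]$old_name <- NA_character_
  rec2$gene_name <- "atp9"
  tab2 <- build_rename_table(list(rec2), list(intron_name("P", 181, "Ici", "atp9")))
  expect_identical(tab2$old_name, "atp9-i1")

  rec0 <- gene_record("Simulata ficta", "cob",
                      data.frame(genomic_start = 1L, genomic_end = 9L, sequence = "ATGCCCTAA"))
  expect_identical(nrow(build_rename_table(list(rec0), list())), 0L)
})
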