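test_that("identical spec + seed give byte-identical fixture files", {
  ref <- ref_set_fixture()
  spec <- fixture_spec(seed = 42, plants = data.frame(gene = "cox1", ref_site = 169,
    intron_length = 500, group = "II"), divergence = 0.15, indel_rate = 0.01)
  d1 <- file.path(tempdir(), "fx_a"); d2 <- file.path(tempdir(), "fx_b")
  f1 <- generate_fixture(spec, ref, dir = d1)
  f2 <- generate_fixture(spec, ref, dir = d2)
  expect_identical(readLines(f1$path)[-1], readLines(f2$path)[-1])  # LOCUS holds a date
  expect_identical(f1$truth, f2$truth)
})

test_that("zero-divergence plant at a published site round-trips to its exact label", {
  ref <- ref_set_fixture()
  spec <- fixture_spec(seed = 1, plants = data.frame(gene = "cox1", ref_site = 169,
    intron_length = 2000, group = "II"), divergence = 0, indel_rate = 0)
  fx <- generate_fixture(spec, ref, dir = tempdir())
  expect_identical(fx$truth$host_offset, 169)
  res <- name_introns(fx$path, reference = ref, trust_heuristic = TRUE)
  expect_identical(res$table$full_name, "Sfi.cox1S169")
})

test_that("planted terminal signatures follow the group conventions", {
  ref <- ref_set_fixture()
  spec <- fixture_spec(seed = 2, plants = data.frame(
    gene = c("cob", "nad5"), ref_site = c(393, 717),
    intron_length = c(150, 180), group = c("I", "II")), divergence = 0.1)
  fx <- generate_fixture(spec, ref, dir = tempdir())
  i1 <- fx$truth$intron_seq[fx$truth$group == "I"]
  expect_identical(substr(i1, 1, 1), "T")
  expect_identical(substr(i1, nchar(i1), nchar(i1)), "G")
  i2 <- fx$truth$intron_seq[fx$truth$group == "II"]
  expect_identical(substr(i2, 1, 5), "GTGCG")
  expect_identical(substr(i2, nchar(i2) - 1, nchar(i2)), "AT")
})

test_that("mutations respect the guard window around planted sites", {
  ref <- ref_set_fixture()
  rg <- ref$genes$cob
  spec <- fixture_spec(seed = 30, plants = data.frame(gene = "cob", ref_site = 490,
    intron_length = 100, group = "I"), divergence = 0.3, indel_rate = 0.02)
  fx <- generate_fixture(spec, ref, dir = tempdir())
  rec <- read_genbank_genes(fx$path)[[1]]
  off <- rec$introns[[1]]$host_offset
  # the 20 nt flanks around the insertion point are untouched reference
  expect_identical(substr(rec$spliced_cds, off - 19L, off),
                   substr(rg$sequence, 490 - 19L, 490))
  expect_identical(substr(rec$spliced_cds, off + 1L, off + 20L),
                   substr(rg$sequence, 491L, 510L))
})

test_that("side-by-side twintron plants read back as two introns at one offset", {
  ref <- ref_set_fixture()
  spec <- fixture_spec(seed = 3, plants = data.frame(gene = c("cox3", "cox3"),
    ref_site = c(640, 640), intron_length = c(200, 220), group = c("I", "I")),
    divergence = 0.1, species_label = "Hypomyces aurantius")
  fx <- generate_fixture(spec, ref, dir = tempdir())
  rec <- read_genbank_genes(fx$path)[[1]]
  expect_length(rec$introns, 2L)
  offs <- vapply(rec$introns, `[[`, 0L, "host_offset")
  expect_identical(offs[1], offs[2])
  expect_identical(vapply(rec$introns, `[[`, "", "sequence"),
                   fx$truth$intron_seq)
  res <- name_introns(fx$path, reference = ref, trust_heuristic = TRUE)
  expect_identical(res$table$full_name, c("Hau.cox3P640a", "Hau.cox3P640b"))
})

test_that("spec validation refuses bad plants", {
  ref <- ref_set_fixture()
  expect_error(fixture_spec(seed = 1, plants = data.frame(gene = "cox1",
    ref_site = 10, intron_length = 20, group = "I")), "50 nt")
  expect_error(fixture_spec(seed = 1, plants = data.frame(gene = "cox1",
    ref_site = 10, intron_length = 100, group = "III")), "group")
  spec <- fixture_spec(seed = 1, plants = data.frame(gene = "cox1",
    ref_site = 5000, intron_length = 100, group = "I"))
  expect_error(generate_fixture(spec, ref), "outside")
  spec2 <- fixture_spec(seed = 1, plants = data.frame(gene = "cox1",
    ref_site = c(100, 110), intron_length = 100, group = "I"))
  expect_error(generate_fixture(spec2, ref), "guard")
})

test_that("recovery degrades monotonically with divergence", {
  ref <- ref_set_fixture()
  recover_rate <- function(div) {
    ok <- 0L
    for (s in 1:8) {
      spec <- fixture_spec(seed = 500L + s, plants = data.frame(gene = "cob",
        ref_site = 490, intron_length = 150, group = "I"),
        divergence = div, indel_rate = 0.01)
      fx <- generate_fixture(spec, ref, dir = tempdir())
      res <- name_introns(fx$path, reference = ref, trust_heuristic = TRUE)
      if (nrow(res$table) == 1L && res$table$site == 490L) ok <- ok + 1L
    }
    ok / 8
  }
  rates <- vapply(c(0.1, 0.2, 0.3, 0.4), recover_rate, 0)
  expect_true(all(diff(rates) <= 0))
  expect_identical(rates[1], 1)
})

test_that("strain-variant fixtures encode the expected numbering", {
  ref <- ref_set_fixture()
  base <- fixture_spec(seed = 11, plants = data.frame(gene = "cob", ref_site = 429,
    intron_length = 400, group = "I"), divergence = 0.1, indel_rate = 0.005,
    species_label = "Hirsutella thompsonii", accession = "SYNHT")
  sv <- generate_strain_variants(base, n_strains = 4, variant_groups = 2,
                                 ref = ref, dir = tempdir())
  expect_identical(sv$truth$expected_variant, c(1L, 1L, 2L, 2L))
  res <- name_introns(as.list(sv$paths), reference = ref, trust_heuristic = TRUE)
  expect_identical(res$table$variant_number, c("1", "1", "2", "2"))
  expect_identical(unique(res$table$site), 429L)

  sv1 <- generate_strain_variants(base, n_strains = 3, variant_groups = 1,
                                  ref = ref, dir = tempdir())
  expect_true(all(is.na(sv1$truth$expected_variant)))
  res1 <- name_introns(as.list(sv1$paths), reference = ref, trust_heuristic = TRUE)
  expect_identical(unique(res1$table$variant_number), "")
  expect_identical(unique(res1$table$full_name), "Hth.cobP429")
})
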