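test_that("self-alignment is gapless with identity 1 and maps every offset to itself", {
  ref <- tiny_ref()
  rg <- ref$genes$cox1
  aln <- align_to_reference(rg$sequence, rg)
  expect_identical(aln$aligned_host, rg$sequence)
  expect_identical(aln$aligned_ref, rg$sequence)
  expect_equal(aln$identity, 1)
  offs <- seq_len(rg$length_nt - 1L)
  m <- map_insertion_site(aln, offs)
  expect_identical(m$site, offs)
  expect_true(all(m$confidence == "ok"))
})

test_that("substitution-only divergence leaves every mapped site unchanged", {
  ref <- ref_set_fixture()
  rg <- ref$genes$cob
  host <- mutate_subs(rg$sequence, 0.10, seed = 123)
  aln <- align_to_reference(host, rg)
  expect_identical(nchar(aln$aligned_host), rg$length_nt)  # gapless
  expect_gt(aln$identity, 0.85)
  expect_lt(aln$identity, 0.95)
  m <- map_insertion_site(aln, c(240L, 393L, 490L))
  expect_identical(m$site, c(240L, 393L, 490L))
})

test_that("a host deletion shows as one gap and shifts offsets as hand-computed", {
  ref <- ref_set_fixture()
  rg <- ref$genes$cob
  # delete 30 nt well 5' of the site of interest: ref 101..130
  host <- paste0(substr(rg$sequence, 1, 100), substr(rg$sequence, 131, rg$length_nt))
  aln <- align_to_reference(host, rg)
  hc <- strsplit(aln$aligned_host, "")[[1]]
  runs <- rle(hc == "-")
  expect_identical(sum(runs$lengths[runs$values]), 30L)
  expect_identical(sum(runs$values), 1L)  # a single 30-column gap
  # planted reference site 393 now sits at host offset 363
  m <- map_insertion_site(aln, 363L)
  expect_identical(m$site, 393L)
  expect_identical(m$confidence, "ok")
})

test_that("offsets landing against a reference gap are flagged gap_adjacent", {
  ref <- tiny_ref()
  rg <- ref$genes$cob
  # host with a 12 nt insertion after position 60
  host <- paste0(substr(rg$sequence, 1, 60), strrep("CCTTCCAAGGTT", 1),
                 substr(rg$sequence, 61, rg$length_nt))
  aln <- align_to_reference(host, rg)
  m <- map_insertion_site(aln, 66L)  # inside the inserted block
  expect_match(m$confidence, "gap_adjacent")
  expect_identical(m$site, 60L)     # 5'-nearest reference coordinate
})

test_that("mapping errors on out-of-range offsets and empty sequences", {
  ref <- tiny_ref()
  rg <- ref$genes$cox1
  aln <- align_to_reference(rg$sequence, rg)
  expect_error(map_insertion_site(aln, 0L), "out of range")
  expect_error(map_insertion_site(aln, rg$length_nt), "out of range")
  expect_error(align_to_reference("", rg), "empty")
})

test_that("low identity flags the alignment instead of raising", {
  ref <- tiny_ref()
  rg <- ref$genes$cox1
  set.seed(5)
  junk <- random_dna(rg$length_nt)
  # optimal global alignment of unrelated DNA still pairs ~40-50% of
  # columns, so exercise the floor at a stringent setting
  aln <- align_to_reference(junk, rg, align_params(min_identity = 0.60))
  expect_true(aln$low_confidence)
  m <- map_insertion_site(aln, 50L)
  expect_match(m$confidence, "low_identity")
})

test_that("production aligner score equals the quadratic DP oracle", {
  params <- align_params()
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    a <- random_dna(n)
    b <- if (i %% 2 == 0) mutate_subs(a, 0.2, seed = i) else random_dna(sample(50:400, 1))
    ref <- ref_gene("cox1", b)
    aln <- align_to_reference(a, ref, params)
    expect_equal(aln$score, alignment_score_dp(a, b, params), tolerance = 1e-9)
  }
})

test_that("substitution invariance: mapped site equals planted site over a seed battery", {
  ref <- ref_set_fixture()
  genes <- c("cob", "cox1", "nad1", "atp9")
  set.seed(77)
  n_ok <- 0L; n_tot <- 0L
  for (i in 1:100) {
    g <- sample(genes, 1)
    rg <- ref$genes[[g]]
    site <- sample(seq(30L, rg$length_nt - 30L), 1)
    div <- runif(1, 0, 0.30)
    host <- mutate_subs(rg$sequence, div, seed = 1000L + i)
    aln <- align_to_reference(host, rg)
    m <- map_insertion_site(aln, site)
    n_tot <- n_tot + 1L
    if (m$site == site) n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, n_tot)
})

test_that("indels at least 20 nt from the insertion point do not move the mapped site", {
  ref <- ref_set_fixture()
  rg <- ref$genes$nad5
  set.seed(31)
  for (i in 1:20) {
    site <- sample(seq(60L, rg$length_nt - 60L), 1)
    # one deletion and one insertion, both > 20 nt away from the site
    del_at <- if (site > 140L) site - sample(40:100, 1) else site + sample(40:100, 1)
    host <- paste0(substr(rg$sequence, 1, del_at - 1L),
                   substr(rg$sequence, del_at + 5L, rg$length_nt))
    ins_at <- if (site > 140L) site + sample(40:100, 1) - 5L else site + sample(150:200, 1) - 5L
    host <- paste0(substr(host, 1, ins_at), random_dna(7), substr(host, ins_at + 1L, nchar(host)))
    host_offset <- site - (if (del_at < site) 5L else 0L) + (if (ins_at < site) 7L else 0L)
    aln <- align_to_reference(host, rg)
    m <- map_insertion_site(aln, host_offset)
    expect_identical(m$site, site)
  }
})

test_that("de novo inference: verbatim reference gives one exon, planted intron is recovered", {
  ref <- ref_set_fixture()
  rg <- ref$genes$cob
  rec0 <- infer_introns(rg$sequence, rg)
  expect_identical(nrow(rec0$exons), 1L)
  expect_length(rec0$introns, 0L)

  spec <- fixture_spec(seed = 5, plants = data.frame(gene = "cob", ref_site = 490,
    intron_length = 1200, group = "I"), divergence = 0.15, indel_rate = 0.01,
    emit_annotation = FALSE)
  fx <- generate_fixture(spec, ref, dir = tempdir())
  region <- read_fasta_region(fx$path, "Simulata ficta", "cob")
  rec <- infer_introns(region, rg)
  expect_length(rec$introns, 1L)
  aln <- align_to_reference(rec$spliced_cds, rg)
  m <- map_insertion_site(aln, rec$introns[[1]]$host_offset)
  expect_identical(m$site, 490L)
  # group I signature survives boundary refinement
  io <- rec$introns[[1]]
  expect_identical(substr(io$sequence, io$length_nt, io$length_nt), "G")
})

test_that("inference handles a short middle exon between two introns", {
  ref <- ref_set_fixture()
  rg <- ref$genes$cox1
  spec <- fixture_spec(seed = 6, plants = data.frame(
    gene = "cox1", ref_site = c(700, 725), intron_length = c(400, 380), group = "I"),
    divergence = 0.10, emit_annotation = FALSE)
  fx <- generate_fixture(spec, ref, dir = tempdir())
  region <- read_fasta_region(fx$path, "Simulata ficta", "cox1")
  rec <- infer_introns(region, rg)
  expect_length(rec$introns, 2L)
  aln <- align_to_reference(rec$spliced_cds, rg)
  offs <- vapply(rec$introns, `[[`, 0L, "host_offset")
  expect_identical(map_insertion_site(aln, offs)$site, c(700L, 725L))
})

test_that("inference length conservation and named failures", {
  ref <- ref_set_fixture()
  rg <- ref$genes$cob
  spec <- fixture_spec(seed = 13, plants = data.frame(gene = "cob", ref_site = 393,
    intron_length = 300, group = "II"), divergence = 0.12, indel_rate = 0.01,
    emit_annotation = FALSE)
  fx <- generate_fixture(spec, ref, dir = tempdir())
  region <- read_fasta_region(fx$path, "Simulata ficta", "cob")
  rec <- infer_introns(region, rg)
  span <- max(rec$exons$genomic_end) - min(rec$exons$genomic_start) + 1L
  expect_identical(sum(nchar(rec$exons$sequence)) +
                     sum(vapply(rec$introns, `[[`, 0L, "length_nt")), span)

  set.seed(44)
  expect_error(infer_introns(random_dna(800), rg), "gene_not_found")
  # a rearranged region: two halves of the gene swapped
  half <- nchar(rg$sequence) %/% 2L
  swapped <- paste0(substr(rg$sequence, half + 1L, rg$length_nt),
                    substr(rg$sequence, 1L, half))
  expect_error(infer_introns(swapped, rg), "rearrangement_suspected")
})
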