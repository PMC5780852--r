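test_that("read_fasta parses headers, joins lines and validates ids", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1 some description", "MKV", "LA", ">g2", "macde*"), fa)
  rec <- read_fasta(fa, genome_id = "G1")
  expect_equal(rec$gene_id, c("g1", "g2"))
  expect_equal(rec$residues, c("MKVLA", "MACDE"))
  expect_equal(unique(rec$genome_id), "G1")

  dup <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "M", ">a", "K"), dup)
  expect_error(read_fasta(dup), "duplicate.*a")

  empty <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no sequences")
})

test_that("input kind uses the pooled 95% nucleotide-alphabet rule", {
  expect_equal(detect_input_kind("ACGTACGT"), "nucleotide")
  expect_equal(detect_input_kind("MKVLAWHE"), "protein")
  # pooled across records: 8 DNA + 3 protein residues is below 0.95
  expect_equal(detect_input_kind(c("ACGTACGT", "MKV")), "protein")
  # boundary: exactly 19/20 hits the threshold, 18/20 does not
  expect_equal(detect_input_kind(c(strrep("A", 19), "W")), "nucleotide")
  expect_equal(detect_input_kind(c(strrep("A", 18), "WW")), "protein")
  expect_error(detect_input_kind(character(0)), "no sequences")
})

test_that("domtblout parsing maps documented columns and strips versions", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(domtblout_fixture_text(), path)
  hits <- parse_domtblout(path, genome_id = "G1")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$gene_id, c("geneA", "geneA", "geneB"))
  expect_equal(hits$profile_acc[1], "PF00012")
  expect_equal(hits$full_evalue[1], 1.2e-30)
  expect_equal(hits$full_score[1], 210.5)
  # accession "-" falls back to the query name
  expect_equal(hits$profile_acc[3], "RiboS7")
  # multiple rows per gene preserved at parse time
  expect_equal(sum(hits$gene_id == "geneA"), 2)

  only_comments <- withr::local_tempfile()
  writeLines(c("# header", "#"), only_comments)
  expect_equal(nrow(parse_domtblout(only_comments, "G1")), 0)

  bad <- withr::local_tempfile()
  writeLines("gene - 10 name PF00001.1 10 not-a-number 5 0", bad)
  expect_error(parse_domtblout(bad, "G1"), "line 1")
})

test_that("top-hit selection applies the cutoff and deterministic tie rules", {
  hits <- tibble::tibble(
    genome_id = "G1",
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    profile_acc = c("PF00001", "PF00002", "PF00005", "PF00010", "PF00020"),
    profile_name = "x",
    full_evalue = c(1e-20, 1e-5, 1e-8, 1e-30, 1e-30),
    full_score = c(50, 60, 40, 100, 120))
  top <- select_top_hits(hits, 1e-10)
  expect_equal(top$profile_acc[top$gene_id == "g1"], "PF00001")
  expect_false("g2" %in% top$gene_id)      # 1e-8 above the cutoff
  expect_equal(top$profile_acc[top$gene_id == "g3"], "PF00020") # score tie-break
  # a hit exactly at the cutoff is kept
  at <- select_top_hits(
    tibble::tibble(genome_id = "G1", gene_id = "g", profile_acc = "PF1",
                   profile_name = "x", full_evalue = 1e-10, full_score = 1),
    1e-10)
  expect_equal(nrow(at), 1)
  expect_error(
    select_top_hits(dplyr::mutate(hits, genome_id = c("G1", "G2", "G1", "G1", "G1"))),
    "single genome")
})

test_that("top-hit selection is order-independent and cutoff-monotone", {
  set.seed(401)
  for (rep in 1:20) {
    n <- 60
    hits <- tibble::tibble(
      genome_id = "G1",
      gene_id = sample(sprintf("g%d", 1:15), n, replace = TRUE),
      profile_acc = sample(sprintf("PF%05d", 1:10), n, replace = TRUE),
      profile_name = "x",
      full_evalue = 10^stats::runif(n, -40, -2),
      full_score = sample(c(10, 50, 50, 90), n, replace = TRUE))
    base <- select_top_hits(hits, 1e-10)
    perm <- select_top_hits(hits[sample(n), ], 1e-10)
    expect_equal(perm, base, ignore_attr = TRUE)
    # idempotence
    expect_equal(select_top_hits(base, 1e-10), base, ignore_attr = TRUE)
    # smaller cutoff assigns a subset of genes
    strict <- select_top_hits(hits, 1e-20)
    expect_true(all(strict$gene_id %in% base$gene_id))
    # brute force: no surviving hit beats the chosen one
    surv <- hits[hits$full_evalue <= 1e-10, ]
    for (g in base$gene_id) {
      expect_equal(base$full_evalue[base$gene_id == g],
                   min(surv$full_evalue[surv$gene_id == g]))
    }
  }
})

test_that("profile counting tallies assignments per genome", {
  annot <- tibble::tibble(
    genome_id = c("G1", "G1", "G1", "G2"),
    gene_id = c("g1", "g2", "g3", "h1"),
    profile_acc = c("PF1", "PF1", "PF2", "PF1"))
  counts <- count_profiles(annot)
  expect_equal(counts$n[counts$genome_id == "G1" & counts$profile_acc == "PF1"], 2L)
  expect_equal(counts$n[counts$genome_id == "G1" & counts$profile_acc == "PF2"], 1L)
  expect_equal(nrow(count_profiles(annot[0, ])), 0)
})
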