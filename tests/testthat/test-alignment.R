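test_that("pairwise alignment matches identity and enumeration oracles", {
  S <- markertree:::scoring_matrix("BLOSUM62")
  id <- pairwise_global_align("MKV", "MKV")
  expect_equal(id$a, "MKV")
  expect_equal(id$score, S["M", "M"] + S["K", "K"] + S["V", "V"])

  set.seed(21)
  for (rep in 1:15) {
    a <- paste(sample(markertree:::AA20, sample(2:6, 1), TRUE), collapse = "")
    b <- paste(sample(markertree:::AA20, sample(2:6, 1), TRUE), collapse = "")
    got <- pairwise_global_align(a, b)
    expect_equal(got$score, enum_pairwise_score(a, b))
    # de-gapped output reproduces the inputs
    expect_equal(gsub("-", "", got$a), a)
    expect_equal(gsub("-", "", got$b), b)
    # score symmetry
    expect_equal(pairwise_global_align(b, a)$score, got$score)
  }
})

test_that("progressive alignment preserves sequences and beats staggering", {
  fam <- evolve_family(simulate_species_tree(6, depth = 0.4, seed = 31), 80)
  aln <- progressive_align(fam)
  expect_length(unique(nchar(aln)), 1)
  expect_equal(gsub("-", "", aln[names(fam)]), fam)
  # order independence
  perm <- progressive_align(fam[sample(length(fam))])
  expect_identical(aln, perm)
  # identical members align without gaps
  same <- setNames(rep(substr(fam[[1]], 1, 40), 3), c("a", "b", "c"))
  expect_false(any(grepl("-", progressive_align(same), fixed = TRUE)))
  # two-member family reduces to the pairwise aligner
  two <- fam[1:2]
  pw <- pairwise_global_align(two[[1]], two[[2]])
  expect_equal(unname(progressive_align(two)), c(pw$a, pw$b))
  # sum-of-pairs column score at least that of the fully staggered layout
  total <- sum(nchar(fam))
  offs <- cumsum(c(0, nchar(fam)[-length(fam)]))
  staggered <- setNames(mapply(function(s, o) {
    paste0(strrep("-", o), s, strrep("-", total - o - nchar(s)))
  }, fam, offs), names(fam))
  expect_gte(alignment_sp_score(aln), alignment_sp_score(staggered))
})

test_that("the external-aligner adapter validates stub output", {
  fam <- c(g1 = "MKVLA", g2 = "MKV-A", g3 = "MK-LA")
  # a stub "aligner" that copies pre-aligned input through unchanged
  out <- external_aligner_adapter(fam, "cp {input} {output}")
  expect_equal(out, fam[sort(names(fam))])
  expect_error(
    external_aligner_adapter(c(a = "MKV", b = "ML"), "false"),
    "external aligner failed")
  # unaligned (unequal-length) output violates the invariant
  expect_error(
    external_aligner_adapter(c(a = "MKV", b = "ML"), "cp {input} {output}"),
    "unequal length")
  expect_error(
    external_aligner_adapter(c(a = "MKV", b = "ML"),
                             "this-command-does-not-exist {input} {output}"),
    "external aligner failed")
})

test_that("concatenation tiles partitions and is associative", {
  a1 <- c(G1 = "MKVLA", G2 = "MKV-A")
  a2 <- c(G1 = "WHEACDE", G2 = "WHEACD-")
  cc <- concatenate_alignments(list(PF00001 = a1, PF00002 = a2))
  expect_equal(nchar(cc$rows[["G1"]]), 12)
  expect_equal(cc$partitions$start, c(1L, 6L))
  expect_equal(cc$partitions$end, c(5L, 12L))
  single <- concatenate_alignments(list(PF00001 = a1))
  expect_equal(single$rows, a1[order(names(a1))])
  expect_equal(nrow(single$partitions), 1)
  expect_error(
    concatenate_alignments(list(a = a1, b = c(G1 = "MK", G3 = "MK"))),
    "G2|G3")

  # positional cross-check on random alignments + associativity
  set.seed(61)
  alns <- lapply(1:5, function(i) {
    L <- sample(4:12, 1)
    rows <- vapply(1:3, function(j) {
      paste(sample(c(markertree:::AA20, "-"), L, TRUE), collapse = "")
    }, "")
    setNames(rows, c("G1", "G2", "G3"))
  })
  names(alns) <- sprintf("PF%05d", 1:5)
  cc <- concatenate_alignments(alns)
  expect_equal(nchar(cc$rows[["G1"]]), sum(vapply(alns, function(a) nchar(a[[1]]), 0)))
  for (k in seq_along(alns)) {
    part <- cc$partitions[k, ]
    expect_equal(substr(cc$rows[["G2"]], part$start, part$end),
                 alns[[k]][["G2"]])
  }
  ab <- concatenate_alignments(alns[1:2])
  ab_c <- concatenate_alignments(c(list(AB = ab$rows), alns[3]))
  flat <- concatenate_alignments(alns[1:3])
  expect_equal(ab_c$rows, flat$rows)
})

test_that("marker families collect the assigned full-length proteins", {
  proteomes <- tibble::tibble(
    genome_id = rep(c("G1", "G2"), each = 2),
    gene_id = c("a1", "a2", "b1", "b2"),
    residues = c("MKV", "WHE", "MKL", "WHD"))
  assignments <- tibble::tibble(
    genome_id = c("G1", "G2", "G1", "G2"),
    gene_id = c("a1", "b1", "a2", "b2"),
    profile_acc = rep(c("PF00001", "PF00002"), each = 2))
  fams <- collect_marker_families(c("PF00001", "PF00002"), proteomes,
                                  assignments)
  expect_equal(nrow(fams), 4)
  expect_equal(fams$residues[fams$gene_id == "b1"], "MKL")
  broken <- assignments
  broken$gene_id[1] <- "missing_gene"
  expect_error(
    collect_marker_families("PF00001", proteomes, broken),
    "missing_gene")
})
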