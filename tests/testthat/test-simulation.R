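test_that("simulated species trees have the right shape and reproduce", {
  t2 <- simulate_species_tree(2, depth = 0.5, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(nrow(t2$edge), 2)
  t8a <- simulate_species_tree(8, depth = 0.5, seed = 3)
  t8b <- simulate_species_tree(8, depth = 0.5, seed = 3)
  expect_identical(write_newick(t8a), write_newick(t8b))
  expect_equal(length(t8a$tip.label), 8)
  # rooted binary: 2n - 2 edges, n - 1 internal nodes
  expect_equal(nrow(t8a$edge), 14)
  expect_equal(t8a$Nnode, 7)
  expect_true(ape::is.binary(t8a))
  expect_true(all(t8a$edge.length >= 0))
})

test_that("expected root-to-leaf depth is calibrated to the requested value", {
  set.seed(10)
  depths <- replicate(200, {
    tr <- simulate_species_tree(8, depth = 0.5)
    mean(ape::node.depth.edgelength(tr)[1:8])
  })
  expect_equal(mean(depths), 0.5, tolerance = 0.1)
})

test_that("sequence evolution follows the 20-state symmetric model", {
  tr <- simulate_species_tree(4, depth = 0.3, seed = 6)
  # zero-length branches copy the parent sequence
  tr0 <- tr
  tr0$edge.length[] <- 0
  fam0 <- evolve_family(tr0, 100, seed = 7)
  expect_equal(length(unique(fam0)), 1)
  # fixed seed reproduces leaf sequences exactly
  expect_identical(evolve_family(tr, 50, seed = 8),
                   evolve_family(tr, 50, seed = 8))
  # observed mismatch between two leaves matches the closed form
  # q = (19/20) (1 - exp(-t * 20/19)) within 3 binomial SEs at L = 5000
  two <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                        tip.label = c("x", "y"),
                        edge.length = c(0.25, 0.25),
                        Nnode = 1L),
                   class = "phylo")
  L <- 5000
  fam <- evolve_family(two, L, seed = 11)
  p_obs <- mean(strsplit(fam[["x"]], "")[[1]] != strsplit(fam[["y"]], "")[[1]])
  q <- (19 / 20) * (1 - exp(-0.5 * 20 / 19))
  se <- sqrt(q * (1 - q) / L)
  expect_lt(abs(p_obs - q), 3 * se)
})

test_that("fixtures plant the advertised marker structure", {
  cfg <- sim_config(n_genomes = 5, n_marker_families = 10,
                    n_multicopy_families = 3, n_patchy_families = 2,
                    seq_length = 60, tree_depth = 0.3, seed = 99)
  fx <- generate_fixture(cfg)
  fams <- fx$truth$families
  expect_equal(sum(fams$status == "marker"), 10)
  planted <- sort(fams$profile_acc[fams$status == "marker"])
  # run annotation + selection on the in-memory hits
  assignments <- fx$hits |>
    dplyr::group_split(genome_id) |>
    purrr::map(select_top_hits, evalue_cutoff = 1e-10) |>
    dplyr::bind_rows()
  m <- build_copy_matrix(assignments, genome_ids = unique(fx$proteomes$genome_id))
  expect_equal(as.character(select_markers(m)), planted)
  # multicopy families really are duplicated somewhere, patchy really absent
  counts <- count_profiles(fx$truth$assignments |>
                             dplyr::mutate(gene_id = gene_id))
  for (acc in fams$profile_acc[fams$status == "multicopy"]) {
    expect_true(any(counts$n[counts$profile_acc == acc] > 1))
  }
  for (acc in fams$profile_acc[fams$status == "patchy"]) {
    expect_lt(sum(counts$profile_acc == acc), cfg$n_genomes)
  }
  # every true gene has a strong hit row; decoy rows sit at the weak e-value
  expect_true(all(fx$hits$full_evalue %in% c(1e-50, cfg$decoy_evalue)))
})

test_that("fixture files are bit-reproducible and read back identically", {
  cfg <- sim_config(n_genomes = 4, seq_length = 40, seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- generate_fixture(cfg, dir = d1)
  fx2 <- generate_fixture(cfg, dir = d2)
  for (g in names(fx1$files)) {
    expect_identical(readLines(fx1$files[[g]]$proteins),
                     readLines(fx2$files[[g]]$proteins))
    expect_identical(readLines(fx1$files[[g]]$domtblout),
                     readLines(fx2$files[[g]]$domtblout))
  }
  # FASTA and domtblout round-trip through the parsers
  g <- names(fx1$files)[[1]]
  prot <- read_fasta(fx1$files[[g]]$proteins, genome_id = g)
  expect_equal(prot,
               dplyr::filter(fx1$proteomes, genome_id == g),
               ignore_attr = TRUE)
  hits <- parse_domtblout(fx1$files[[g]]$domtblout, genome_id = g)
  want <- dplyr::filter(fx1$hits, genome_id == g)
  ord <- function(x) dplyr::arrange(x, gene_id, profile_acc, full_evalue)
  expect_equal(ord(hits), ord(want), ignore_attr = TRUE)
})
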