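test_that("external2go parsing aggregates GO ids per source", {
  path <- withr::local_tempfile()
  writeLines(c(
    "!comment line",
    "Pfam:PF00012 HSP70 > GO:protein folding ; GO:0006457",
    "Pfam:PF00012 HSP70 > GO:ATP binding ; GO:0005524",
    "Pfam:PF00099.7 Other > GO:something ; GO:0000001"), path)
  refs <- parse_go_mapping(path)
  expect_equal(sort(refs$go_id[refs$source_id == "PF00012"]),
               c("GO:0005524", "GO:0006457"))
  expect_equal(refs$source_id[refs$go_id == "GO:0000001"], "PF00099")

  empty <- withr::local_tempfile()
  writeLines("!only comments", empty)
  expect_equal(nrow(parse_go_mapping(empty)), 0)

  bad <- withr::local_tempfile()
  writeLines("Pfam:PF00012 no separator here", bad)
  expect_error(parse_go_mapping(bad), "line 1")
})

test_that("PFAM-to-COG mapping equals pairwise GO-intersection brute force", {
  pf <- tibble::tibble(source_id = c("PF1", "PF1", "PF2", "PF3"),
                       go_id = c("GO:0000001", "GO:0000002", "GO:0000002",
                                 "GO:0000009"))
  cg <- tibble::tibble(source_id = c("COGX", "COGY", "COGY"),
                       go_id = c("GO:0000001", "GO:0000002", "GO:0000003"))
  got <- map_pfam_to_cog(pf, cg)
  expect_equal(got$cog_id[got$profile_acc == "PF1"], c("COGX", "COGY"))
  expect_equal(got$cog_id[got$profile_acc == "PF2"], "COGY")
  expect_false("PF3" %in% got$profile_acc)

  set.seed(31)
  for (rep in 1:20) {
    pf <- tibble::tibble(
      source_id = sample(sprintf("PF%d", 1:8), 25, TRUE),
      go_id = sample(sprintf("GO:%07d", 1:12), 25, TRUE)) |>
      dplyr::distinct()
    cg <- tibble::tibble(
      source_id = sample(sprintf("COG%04d", 1:6), 20, TRUE),
      go_id = sample(sprintf("GO:%07d", 1:12), 20, TRUE)) |>
      dplyr::distinct()
    got <- map_pfam_to_cog(pf, cg)
    want <- list()
    for (p in unique(pf$source_id)) {
      for (co in unique(cg$source_id)) {
        shared <- intersect(pf$go_id[pf$source_id == p],
                            cg$go_id[cg$source_id == co])
        if (length(shared) > 0) {
          want[[length(want) + 1]] <- tibble::tibble(profile_acc = p,
                                                     cog_id = co)
        }
      }
    }
    want <- dplyr::arrange(dplyr::bind_rows(want), profile_acc, cog_id)
    expect_equal(as.data.frame(got), as.data.frame(want))
    # monotonicity: adding GO ids to a PFAM never shrinks its image
    extra <- dplyr::bind_rows(pf, tibble::tibble(source_id = "PF1",
                                                 go_id = "GO:0000099"))
    got2 <- map_pfam_to_cog(extra, cg)
    expect_true(all(got$cog_id[got$profile_acc == "PF1"] %in%
                      got2$cog_id[got2$profile_acc == "PF1"]))
  }
})

test_that("marker categorization takes per-marker category unions", {
  p2c <- tibble::tibble(profile_acc = c("PF1", "PF2", "PF2"),
                        cog_id = c("COGA", "COGA", "COGB"))
  cats <- tibble::tibble(cog_id = c("COGA", "COGB"),
                         categories = c("J", "JL"),
                         description = c("ribosome", "gyrase"))
  res <- categorize_markers(c("PF1", "PF2", "PF9"), p2c, cats)
  # PF2 maps to {J} union {J,L}: J once, L once
  expect_equal(res$marker_cogs$categories[res$marker_cogs$profile_acc == "PF2"],
               "JL")
  expect_equal(res$category_counts$n_markers[res$category_counts$category == "J"], 2L)
  expect_equal(res$category_counts$n_markers[res$category_counts$category == "L"], 1L)
  expect_equal(res$unmapped, "PF9")
  # mapped + unmapped = total; category totals reach at least the mapped count
  expect_equal(nrow(res$marker_cogs) + length(res$unmapped), 3)
  expect_gte(sum(res$category_counts$n_markers), nrow(res$marker_cogs))
})

test_that("the shipped synthetic mapping fixtures drive the full COG path", {
  pf <- parse_go_mapping(system.file("extdata/synthetic_pfam2go.txt",
                                     package = "markertree"))
  cg <- parse_go_mapping(system.file("extdata/synthetic_cog2go.txt",
                                     package = "markertree"))
  defs <- parse_cognames(system.file("extdata/synthetic_cognames.tsv",
                                     package = "markertree"))
  res <- categorize_markers(sprintf("PF%05d", 1:8), map_pfam_to_cog(pf, cg),
                            defs)
  expect_equal(res$category_counts$category[[1]], "J")
  expect_true("PF00007" %in% res$unmapped)
  expect_gte(sum(res$category_counts$n_markers), nrow(res$marker_cogs))
})
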