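chma_table <- function() {
  readr::read_tsv(extdata_path("chma_miniturboid_top25.tsv"),
                  show_col_types = FALSE)
}
reca_table <- function() {
  readr::read_tsv(extdata_path("reca_miniturboid_top25.tsv"),
                  show_col_types = FALSE)
}

test_that("the two published top-25 lists pool to 42 candidates, 8 shared", {
  cs <- build_candidate_set(
    list(chma = chma_table(), reca = reca_table()),
    top_n = 25, exclude = c("gp53", "gp175")
  )
  expect_equal(nrow(cs), 42L)
  shared <- sort(cs$protein[cs$n_baits == 2])
  expect_equal(shared, c("gp12", "gp131", "gp166", "gp222", "gp247",
                         "gp257", "gp358", "gp62"))
  # size bound: union is at most the sum of the truncated lists
  expect_lte(nrow(cs), 50L)
  expect_equal(nrow(cs), 50L - length(shared))
  # neither bait survives its own exclusion
  expect_false(any(c("gp53", "gp175") %in% cs$protein))
})

test_that("candidate pooling handles degenerate inputs", {
  empty <- tibble::tibble(protein = character())
  expect_equal(nrow(build_candidate_set(list(a = empty))), 0L)
  expect_error(build_candidate_set(list()), "non-empty")
  expect_error(build_candidate_set(list(a = chma_table()), top_n = 0),
               "top_n")
  # disjoint lists: union size equals the sum
  t1 <- tibble::tibble(protein = c("x1", "x2"))
  t2 <- tibble::tibble(protein = c("y1", "y2"))
  expect_equal(nrow(build_candidate_set(list(a = t1, b = t2), top_n = 2)),
               4L)
})

test_that("duplicate bait-prey edges merge with their evidence united", {
  edges <- evidence_edges(
    source = c("ChmA", "ChmA", "ChmA", "gp2"),
    target = c("gp2", "gp2", "gp63", "gp148"),
    evidence = c("proximity_labeling", "gfp_pulldown",
                 "proximity_labeling", "coexpression_pulldown"),
    dataset_id = c("mt", "gfp", "mt", "coexp")
  )
  net <- assemble_network(edges)
  expect_equal(nrow(net$edges), 3L)
  merged <- net$edges[net$edges$source == "ChmA" &
                        net$edges$target == "gp2", ]
  expect_equal(merged$evidence[[1]],
               c("gfp_pulldown", "proximity_labeling"))
  expect_setequal(net$nodes$protein, c("ChmA", "gp2", "gp63", "gp148"))

  # order independence
  perm <- edges[c(4, 2, 3, 1), ]
  expect_equal(assemble_network(perm), net)

  # brute-force merge oracle on the bundled 19-edge fixture
  fixture <- read_evidence_edges(extdata_path("shell_network_edges.tsv"))
  net2 <- assemble_network(fixture)
  pairs <- unique(paste(fixture$source, fixture$target))
  expect_equal(nrow(net2$edges), length(pairs))
  for (i in seq_len(nrow(net2$edges))) {
    want <- sort(unique(fixture$evidence[
      fixture$source == net2$edges$source[i] &
        fixture$target == net2$edges$target[i]
    ]))
    expect_equal(net2$edges$evidence[[i]], want)
  }

  # self edges are rejected with a warning; empty input is legal
  expect_warning(
    self <- assemble_network(evidence_edges("a", "a", "gfp_pulldown")),
    "self-edge"
  )
  expect_equal(nrow(self$edges), 0L)
  expect_equal(nrow(assemble_network(evidence_edges(
    character(), character(), character()
  ))$edges), 0L)
})

test_that("localization summaries count every category, zeros included", {
  loc <- read_localization(extdata_path("localization_assignments.tsv"))
  counts <- localization_summary(loc)
  expect_equal(counts[["nucleus"]], 8L)
  expect_equal(counts[["shell"]], 6L)
  expect_equal(counts[["bouquet"]], 5L)
  expect_equal(counts[["cytoplasm"]], 0L)
  expect_equal(sum(counts), nrow(loc))

  expect_equal(sum(localization_summary(
    tibble::tibble(protein = character(), category = character())
  )), 0L)

  # moving one protein shifts exactly two counts by one
  moved <- loc
  moved$category[moved$protein == "gp62"] <- "shell"
  counts2 <- localization_summary(moved)
  expect_equal(counts2[["nucleus"]], counts[["nucleus"]] - 1L)
  expect_equal(counts2[["shell"]], counts[["shell"]] + 1L)
  expect_equal(counts2[["bouquet"]], counts[["bouquet"]])

  # conflicting duplicate assignment is an error
  conflict <- rbind(loc, data.frame(protein = "gp62", category = "shell"))
  expect_error(localization_summary(conflict), "gp62")
  expect_error(
    localization_summary(data.frame(protein = "p", category = "membrane")),
    "categor"
  )
})

test_that("network exports follow each format's shape and round-trip", {
  edges <- read_evidence_edges(extdata_path("shell_network_edges.tsv"))
  loc <- read_localization(extdata_path("localization_assignments.tsv"))
  net <- assemble_network(edges, loc)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_length(lines, sum(lengths(net$edges$evidence)))
  expect_true(all(lengths(strsplit(lines, "\t")) == 3L))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, format = "tsv")
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml", directed = TRUE)
  reimported <- import_network_graphml(gml)
  # dataset ids are not part of the GraphML export; the graph itself is
  expect_equal(reimported$edges[c("source", "target", "evidence")],
               net$edges[c("source", "target", "evidence")])
  expect_equal(
    reimported$nodes[order(reimported$nodes$protein), ],
    net$nodes[order(net$nodes$protein), ]
  )

  # empty network gives a header-only TSV
  empty <- assemble_network(evidence_edges(character(), character(),
                                           character()))
  export_network(empty, tsv, format = "tsv")
  expect_length(readLines(tsv), 1L)
})
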