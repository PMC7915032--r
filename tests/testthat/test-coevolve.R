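idr_row <- function(seq_id, start, end, species = NULL) {
  df <- data.frame(seq_id = seq_id, kind = "IDR", start = start, end = end,
                   score = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(species)) df$species <- species
  df
}

test_that("IDR column profiles mark IDR residues, zero gaps", {
  expect_equal(idr_column_profile("AAAA", idr_row("s", 1L, 4L)),
               rep(1L, 4))
  expect_equal(idr_column_profile("AAAA", empty_features()), rep(0L, 4))
  # gapped: IDR over seq positions 2-3 of "A-CG-T" -> columns 3,4
  prof <- idr_column_profile("A-CG-T", idr_row("s", 2L, 3L))
  expect_equal(prof, c(0L, 0L, 1L, 1L, 0L, 0L))
})

test_that("pair profiles score IDR overlap and mask uninformative pairs", {
  g <- toy_group(list("Homo sapiens"   = strrep("A", 40),
                      "Pan troglodytes" = strrep("A", 40),
                      "Danio rerio"    = strrep("A", 40)))
  feats <- rbind(
    idr_row(g$ids[["Homo sapiens"]], 1L, 30L, "Homo sapiens"),
    idr_row(g$ids[["Pan troglodytes"]], 1L, 30L, "Pan troglodytes"),
    idr_row(g$ids[["Danio rerio"]], 11L, 40L, "Danio rerio"))
  pp <- pair_jaccard_profile(g, feats)
  expect_length(pp, 45L)
  expect_equal(unname(pp["Homo sapiens--Pan troglodytes"]), 1)
  expect_equal(unname(pp["Homo sapiens--Danio rerio"]), 20 / 40)
  # absent species make their pairs non-informative
  expect_true(is.na(pp["Homo sapiens--Mus musculus"]))
  # both members without IDRs: non-informative; one without: zero
  feats2 <- feats[feats$species == "Homo sapiens", , drop = FALSE]
  pp2 <- pair_jaccard_profile(g, feats2)
  expect_true(is.na(pp2["Pan troglodytes--Danio rerio"]))
  expect_equal(unname(pp2["Homo sapiens--Danio rerio"]), 0)
})

test_that("fragment splitting slices alignment columns via the human map", {
  g <- toy_group(list("Homo sapiens" = "AC--GTACGT",
                      "Danio rerio"  = "ACGGGTAC--"))
  spec <- data.frame(label = c("f1", "f2"), start = c(1L, 3L),
                     end = c(2L, 8L), stringsAsFactors = FALSE)
  frags <- split_fragments(g, spec)
  expect_named(frags, c("f1", "f2"))
  # human residues 1-2 sit in columns 1-2; residues 3-8 in columns 5-10
  expect_equal(frags$f1$aligned[["Homo sapiens"]], "AC")
  expect_equal(frags$f2$aligned[["Homo sapiens"]], "GTACGT")
  expect_equal(frags$f2$aligned[["Danio rerio"]], "GTAC--")
  # slices tile the human-spanned columns
  rng <- attr(frags, "col_ranges")
  expect_equal(unname(rng["f1", ]), c(1L, 2L))
  expect_equal(unname(rng["f2", ]), c(5L, 10L))
  expect_error(split_fragments(g, data.frame(label = "x", start = 1L,
                                             end = 99L)),
               "exceeds")
  g2 <- toy_group(list("Danio rerio" = "ACGT"))
  expect_error(split_fragments(g2, spec), "no human")
})

test_that("fully gapped fragment members are retained as empty profiles", {
  g <- toy_group(list("Homo sapiens" = "ACGTACGT",
                      "Danio rerio"  = "----ACGT"))
  frags <- split_fragments(g, data.frame(label = "f1", start = 1L, end = 4L))
  expect_equal(frags$f1$aligned[["Danio rerio"]], "----")
  pp <- pair_jaccard_profile(frags$f1, empty_features())
  expect_true(is.na(pp["Homo sapiens--Danio rerio"]))
})

test_that("default huntingtin fragments tile 1-3142 without overlap", {
  fr <- htt_fragments()
  expect_equal(fr$start[1], 1L)
  expect_equal(fr$end[5], 3142L)
  expect_equal(fr$start[-1], fr$end[-5] + 1L)
})

test_that("pairwise-deletion distance rescales by shared informative cells", {
  p <- rbind(a = c(1, 0.5, 0, 0.2), b = c(1, 0.5, 0, 0.6),
             c = c(NA, 0.5, 0, 0.6))
  d <- as.matrix(profile_distances(p))
  # fully informative pair: plain Euclidean (p = 4 coordinates)
  expect_equal(d["a", "b"], 0.4)
  # one missing cell: rescaled by sqrt(4/3)
  expect_equal(d["b", "c"], 0)
  expect_equal(d["a", "c"], sqrt(0.4^2 * 4 / 3))
  # no shared informative coordinates: maximal distance with a warning
  q <- rbind(a = c(1, NA), b = c(NA, 1))
  expect_warning(dq <- profile_distances(q), "maximal")
  expect_equal(as.matrix(dq)["a", "b"], sqrt(2))
})

test_that("identical profiles merge first; input order does not matter", {
  p <- rbind(x2 = c(0.9, 0.8, 0.1), x1 = c(0.9, 0.8, 0.1),
             y = c(0.1, 0.1, 0.9))
  cl <- cluster_profiles(p, k = 2)
  expect_equal(as.matrix(cl$dist)["x1", "x2"], 0)
  expect_equal(cl$clusters[["x1"]], cl$clusters[["x2"]])
  expect_false(cl$clusters[["x1"]] == cl$clusters[["y"]])
  cl2 <- cluster_profiles(p[c(3, 1, 2), ], k = 2)
  expect_equal(cl2$clusters, cl$clusters)
  # newick export round-trips through ape
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("x1", "x2", "y"))
})

test_that("two planted archetypes separated beyond noise are fully recovered", {
  set.seed(77)
  arch <- rbind(rep(c(0.9, 0.1), length.out = 45),
                rep(c(0.1, 0.9), length.out = 45))
  labels <- rep(1:2, each = 6)
  profiles <- arch[labels, ] + stats::rnorm(12 * 45, sd = 0.05)
  rownames(profiles) <- sprintf("p%02d", 1:12)
  cl <- cluster_profiles(profiles, k = 2)
  expect_equal(rand_index(cl$clusters[rownames(profiles)], labels), 1.0)
})

test_that("rand index agrees with its definition on hand cases", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 2, 3), c(1, 1, 1)), 0)
})
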