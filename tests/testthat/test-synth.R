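# a small corpus exercising every feature kind, species absence and indels
demo_plans <- function() {
  list(
    # HAP40-like: conserved diffuse A-rich CBR + polyP, two species absent
    group_plan("hapish", seed = 101, n_col = 300,
               species = setdiff(species_panel(),
                                 c("Sarcophilus harrisii", "Gallus gallus")),
               plants = data.frame(
                 kind = c("CBR:A", "polyX:P", "IDR"),
                 start = c(40L, 200L, 150L), end = c(120L, 212L, 190L),
                 species = c(
                   "Homo sapiens;Pan troglodytes;Mus musculus;Rattus norvegicus",
                   "Homo sapiens;Pan troglodytes",
                   "Homo sapiens;Pan troglodytes;Mus musculus"),
                 stringsAsFactors = FALSE),
               indels = data.frame(species = "Danio rerio",
                                   start = 250L, end = 269L)),
    # dropped at s3: its conserved A-rich region contains a polyA
    group_plan("polya", seed = 102, n_col = 260,
               plants = data.frame(
                 kind = c("CBR:A", "polyX:A", "polyX:P"),
                 start = c(30L, 60L, 200L), end = c(110L, 71L, 211L),
                 species = c(
                   "Homo sapiens;Pan troglodytes;Mus musculus;Danio rerio",
                   "Homo sapiens",
                   "Homo sapiens"),
                 stringsAsFactors = FALSE)),
    # background-only group with a CC annotation plant
    group_plan("plain", seed = 103, n_col = 200,
               plants = data.frame(kind = "CC", start = 50L, end = 90L,
                                   species = "Homo sapiens",
                                   stringsAsFactors = FALSE))
  )
}

test_that("generation is byte-deterministic under the seed", {
  a <- gen_group(demo_plans()[[1]])
  b <- gen_group(demo_plans()[[1]])
  expect_identical(a$group$aligned, b$group$aligned)
  expect_identical(a$disorder, b$disorder)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(demo_plans()[1], d1); run_simulate(demo_plans()[1], d2)
  f1 <- file.path(d1, "alignments", "hapish.fasta")
  f2 <- file.path(d2, "alignments", "hapish.fasta")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("contradictory plans are rejected", {
  expect_error(group_plan("g", 1, plants = data.frame(
    kind = c("IDR", "IDR"), start = c(10L, 30L), end = c(50L, 60L),
    species = "Homo sapiens", stringsAsFactors = FALSE)),
    "overlapping plants")
  expect_error(group_plan("g", 1, species = "Homo sapiens",
                          plants = data.frame(kind = "IDR", start = 10L,
                                              end = 50L,
                                              species = "Danio rerio")),
               "not present")
  expect_error(group_plan("g", 1, plants = data.frame(
    kind = "polyX:Q", start = 10L, end = 30L, species = "Homo sapiens"),
    indels = data.frame(species = "Homo sapiens", start = 20L, end = 25L)),
    "indel intersects")
  expect_error(group_plan("g", 1, plants = data.frame(
    kind = "polyX:Q", start = 10L, end = 999L, species = "Homo sapiens")))
})

test_that("a noiseless corpus is recovered perfectly at every stage", {
  cfg <- detector_config(disorder_source = "adapter")
  all_truth_cons <- list(); all_obs_cons <- list()
  cascade_truth <- list(); cascade_obs <- list()
  for (plan in demo_plans()) {
    sim <- gen_group(plan)
    paths <- vapply(names(sim$disorder), function(id) {
      sp <- names(sim$group$ids)[match(id, sim$group$ids)]
      seq <- gsub("-", "", sim$group$aligned[[sp]], fixed = TRUE)
      p <- tempfile(fileext = ".scores")
      write_disorder_profile(sim$disorder[[id]], seq, p)
      p
    }, character(1))
    feats <- detect_features(sim$group, cfg, annotations = sim$annotations,
                             disorder_paths = paths)
    cons <- consolidate_group(sim$group, feats)
    pm <- presence_matrix(feats, seq_ids = colnames(sim$truth$presence))
    rec <- evaluate_recovery(sim$truth,
                             list(features = feats, consolidated = cons,
                                  presence = pm))
    expect_equal(rec$detection$precision, 1, info = plan$group_id)
    expect_equal(rec$detection$recall, 1, info = plan$group_id)
    expect_equal(rec$consolidation$precision, 1, info = plan$group_id)
    expect_equal(rec$consolidation$recall, 1, info = plan$group_id)
    expect_equal(rec$consolidation$profile_match, 1, info = plan$group_id)
    expect_equal(rec$presence$agreement, 1, info = plan$group_id)
    cascade_truth[[plan$group_id]] <- sim$truth$cascade
    all_obs_cons[[plan$group_id]] <- cons
    unlink(paths)
  }
  # cascade over the whole corpus agrees with the planted stage membership
  casc <- hap40_like_filter(do.call(rbind, all_obs_cons))
  tr <- do.call(rbind, cascade_truth)
  for (s in colnames(tr))
    expect_setequal(casc$stages[[s]], rownames(tr)[tr[, s]])
  expect_equal(casc$stages$s4, "hapish")
})

test_that("noiseless exact recovery includes planted intervals verbatim", {
  sim <- gen_group(demo_plans()[[1]])
  feats <- detect_features(sim$group, detector_config(), annotations = NULL)
  # purity-1 polyP plants are recovered at exactly the planted columns
  pp <- feats[feats$kind == "polyX:P", ]
  tt <- sim$truth$features[sim$truth$features$kind == "polyX:P", ]
  expect_equal(nrow(pp), nrow(tt))
  expect_equal(pp[order(pp$seq_id), c("seq_id", "start", "end")],
               tt[order(tt$seq_id), c("seq_id", "start", "end")],
               ignore_attr = TRUE)
})

test_that("polyX recall degrades monotonically with plant purity", {
  recall_at <- function(purity) {
    plan <- group_plan("p", seed = 500, n_col = 400,
                       species = species_panel()[1:6],
                       plants = data.frame(
                         kind = "polyX:Q", start = 100L, end = 119L,
                         species = paste(species_panel()[1:6], collapse = ";"),
                         purity = purity, stringsAsFactors = FALSE))
    sim <- gen_group(plan)
    feats <- detect_features(sim$group, detector_config())
    m <- evaluate_recovery(sim$truth,
                           list(features = feats), min_overlap = 0.5)
    m$detection$recall
  }
  r <- vapply(c(0.5, 0.8, 1.0), recall_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_equal(r[3], 1)
  expect_lt(r[1], 1)
})

test_that("a disabled detector shows up as zero recall", {
  sim <- gen_group(demo_plans()[[2]])
  rec <- evaluate_recovery(sim$truth, list(features = empty_features()))
  expect_equal(rec$detection$recall, 0)
})

test_that("presence-matrix targets respect Frechet feasibility", {
  expect_error(gen_presence_matrix(c("a", "b"), 100,
                                   marginals = c(0.05, 0.9),
                                   pairs = data.frame(kind1 = "a", kind2 = "b",
                                                      jaccard = 0.9)),
               "infeasible")
  sim <- gen_presence_matrix(c("a", "b"), 500, marginals = 0.5,
                             pairs = data.frame(kind1 = "a", kind2 = "b",
                                                jaccard = 1))
  expect_equal(sim$matrix["a", ], sim$matrix["b", ])
  sim0 <- gen_presence_matrix(c("a", "b"), 500, marginals = 0.4,
                              pairs = data.frame(kind1 = "a", kind2 = "b",
                                                 jaccard = 0))
  expect_equal(sum(sim0$matrix["a", ] & sim0$matrix["b", ]), 0L)
})
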