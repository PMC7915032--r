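test_that("polyX scan calls the canonical cases", {
  # the proline decamer: 8 P in a 10-window, endpoints P
  hit <- scan_polyx("PPPPPPAPQP", seq_id = "x")
  expect_equal(hit$kind, "polyX:P")
  expect_equal(c(hit$start, hit$end), c(1L, 10L))
  # exactly at threshold, sequence shorter than the window
  hit <- scan_polyx("QQQQQQQQ")
  expect_equal(c(hit$kind, hit$start, hit$end), c("polyX:Q", "1", "8"))
  expect_equal(nrow(scan_polyx("QQQQQQQ")), 0L)      # 7 < 8
  expect_equal(nrow(scan_polyx("ACDEFGHIKLMNPQRSTVWY")), 0L)
  expect_equal(nrow(scan_polyx("AA")), 0L)
})

test_that("polyX scan equals the brute-force window oracle", {
  set.seed(7)
  for (rep in 1:300) {
    n <- sample(8:50, 1)
    # biased alphabet so features actually occur
    s <- random_seq(n, c("P", "P", "P", "P", "Q", "A"))
    got <- scan_polyx(s)
    want <- oracle_polyx(s)
    expect_equal(got[, c("kind", "start", "end")],
                 want[, c("kind", "start", "end")], ignore_attr = TRUE)
  }
})

test_that("every emitted polyX interval satisfies the window rule and ends on X", {
  set.seed(11)
  for (rep in 1:100) {
    s <- random_seq(sample(10:80, 1), c("S", "S", "S", "G", "A"))
    chars <- strsplit(s, "")[[1]]
    feats <- scan_polyx(s)
    for (i in seq_len(nrow(feats))) {
      x <- sub("polyX:", "", feats$kind[i])
      expect_identical(chars[feats$start[i]], x)
      expect_identical(chars[feats$end[i]], x)
      # some 10-window inside the merged span held >= 8 copies
      w <- min(10L, nchar(s))
      counts <- vapply(1:(nchar(s) - w + 1),
                       function(p) sum(chars[p:(p + w - 1)] == x), 1L)
      expect_true(any(counts >= 8))
    }
  }
})

test_that("maximal homopolymer segment matches the O(n^2) oracle", {
  b62 <- blosum62()
  expect_equal(max_homopolymer_segment("AAAA", "A"),
               list(score = 16, start = 1L, end = 4L))
  expect_equal(max_homopolymer_segment(strrep("A", 10), "A")$score, 40)
  expect_null(max_homopolymer_segment("DDDD", "A"))
  expect_error(max_homopolymer_segment("AAAA", "B"), "standard amino acid")
  set.seed(3)
  for (rep in 1:200) {
    s <- random_seq(sample(3:40, 1), c("A", "E", "P", "D", "G", "K"))
    chars <- strsplit(s, "")[[1]]
    for (x in c("A", "E")) {
      got <- max_homopolymer_segment(s, x, b62)
      want <- oracle_max_segment(s, x, b62)
      if (is.null(want)) {
        expect_null(got)
      } else {
        # the achieved maximum is unique even when the interval is tied
        expect_equal(got$score, want$score)
        sc <- unname(b62[chars, x])
        expect_equal(sum(sc[got$start:got$end]), got$score)
        # emitted endpoints contribute positively (no slack residues)
        expect_gt(sc[got$start], 0)
        expect_gt(sc[got$end], 0)
      }
    }
  }
})

test_that("CAST iteration emits at the threshold and terminates by masking", {
  # 10 alanines score exactly 40: one emission, then no signal remains
  res <- scan_cbr_cast(strrep("A", 10), seq_id = "s")
  expect_equal(nrow(res), 1L)
  expect_equal(res$kind, "CBR:A")
  expect_equal(c(res$start, res$end), c(1L, 10L))
  expect_equal(res$score, 40)
  # 9 glutamates score 9 * 5 = 45 >= 40 (matrix lookup decides emission)
  b62 <- blosum62()
  expect_equal(unname(9 * b62["E", "E"]), 45)
  res <- scan_cbr_cast(strrep("E", 9))
  expect_equal(res$kind, "CBR:E")
  expect_equal(res$score, 45)
  # no run, nothing biased
  expect_equal(nrow(scan_cbr_cast("ACDEFGHIKLMNPQRSTVWY")), 0L)
})

test_that("CAST repeated emissions for one residue type do not overlap", {
  # two alanine-rich islands split by a diverse spacer: the spacer is
  # penalized more against alanine than either island scores (so no
  # segment bridges it) and is itself below threshold for every residue
  # type (so it is never emitted and masked away)
  spacer <- strrep("WDNKREQH", 4)
  s <- paste0(strrep("A", 12), spacer, strrep("A", 12))
  res <- scan_cbr_cast(s)
  expect_equal(res$kind, c("CBR:A", "CBR:A"))
  res_a <- res[res$kind == "CBR:A", ]
  expect_equal(nrow(res_a), 2L)
  expect_true(res_a$end[1] < res_a$start[2])
  expect_true(all(res_a$score >= 40))
})

test_that("disorder profile files round-trip and are cross-checked", {
  seq <- strrep("MKTAY", 8)
  scores <- round(seq(0, 1, length.out = 40), 4)
  path <- withr::local_tempfile(fileext = ".scores")
  write_disorder_profile(scores, seq, path)
  expect_equal(read_disorder_profile(path, seq), scores)
  expect_error(read_disorder_profile(path, strrep("AAAAA", 8)), "mismatch")
  expect_error(read_disorder_profile(path, strrep("MKTAY", 7)), "length")
})

test_that("fallback disorder scores smooth the propensity scale", {
  # homopolymer of a disorder-promoting residue: uniformly high
  expect_true(all(fallback_disorder_scores(strrep("P", 50)) > 0.8))
  expect_true(all(fallback_disorder_scores(strrep("W", 50)) < 0.2))
  # alternating high/low 30-mer: interior plateau equals the hand-computed
  # moving average of the two propensities
  s <- strrep("PW", 15)
  sc <- fallback_disorder_scores(s)
  expected_mid <- (11 * 0.88 + 10 * 0.05) / 21  # 11 P, 10 W in a 21-window
  expect_equal(sc[15], expected_mid, tolerance = 1e-12)
  expect_error(fallback_disorder_scores("MKB"), "missing from")
})

test_that("IDR calling keeps only thresholded runs of at least 30", {
  cfg <- detector_config()
  hit <- predict_idr(rep(0.9, 40), cfg, "s")
  expect_equal(c(hit$start, hit$end), c(1L, 40L))
  expect_equal(nrow(predict_idr(rep(0.9, 29), cfg)), 0L)
  set.seed(5)
  for (rep in 1:100) {
    scores <- stats::runif(sample(30:200, 1))
    # block structure so long runs exist
    scores[10:60] <- 0.8
    got <- predict_idr(scores, cfg)
    want <- oracle_idr_runs(scores, 0.5, 30)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, unname(want[, 1]))
      expect_equal(got$end, unname(want[, 2]))
    }
  }
})

test_that("detect_features combines scanners, adapter scores and annotations", {
  aligned <- list(
    "Homo sapiens" = paste0(strrep("Q", 12), "MKTAYGDE", strrep("L", 5)),
    "Danio rerio"  = paste0(strrep("Q", 12), "MKTAYGDE", strrep("L", 5)))
  g <- toy_group(aligned)
  cfg <- detector_config(disorder_source = "adapter")
  ann <- data.frame(seq_id = g$ids[["Homo sapiens"]], kind = "CC",
                    start = 13L, end = 20L, score = NA_real_,
                    stringsAsFactors = FALSE)
  feats <- detect_features(g, cfg, annotations = ann)
  expect_setequal(unique(feats$kind), c("polyX:Q", "CBR:Q", "CC"))
  expect_equal(sum(feats$kind == "polyX:Q"), 2L)
  expect_equal(feats$species[feats$kind == "CC"], "Homo sapiens")
  # unknown annotation ids are skipped with a warning
  bad <- rbind(ann, transform(ann, seq_id = "nobody"))
  expect_warning(f2 <- detect_features(g, cfg, annotations = bad), "skipped")
  expect_equal(sum(f2$kind == "CC"), 1L)
})
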