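#' Detector configuration
#'
#' Holds the thresholds of the four LCR detectors. The defaults are the
#' standard strict settings for this kind of survey: a homorepeat calls
#' for at least 8 identical residues within a 10-residue window; a
#' compositionally biased region (CBR) is a maximal homopolymer-scoring
#' segment reaching a BLOSUM62 score of 40; an intrinsically disordered
#' region (IDR) is a run of at least 30 residues with disorder score at or
#' above 0.5.
#'
#' @param polyx_min_count Minimum identical residues per window.
#' @param polyx_window Window length for the homorepeat scan.
#' @param cast_threshold Minimum maximal-segment score to emit a CBR.
#' @param cast_matrix Substitution matrix (defaults to BLOSUM62).
#' @param idr_min_length Minimum IDR length in residues.
#' @param idr_score_threshold Disorder score cutoff.
#' @param disorder_source "adapter" (per-residue score files from an
#'   external predictor) or "fallback" (the bundled propensity scale).
#' @return A `detector_config` list.
#' @export
detector_config <- function(polyx_min_count = 8L, polyx_window = 10L,
                            cast_threshold = 40, cast_matrix = blosum62(),
                            idr_min_length = 30L, idr_score_threshold = 0.5,
                            disorder_source = c("adapter", "fallback")) {
  stopifnot(polyx_min_count <= polyx_window, cast_threshold > 0,
            idr_min_length >= 1L)
  structure(list(polyx_min_count = as.integer(polyx_min_count),
                 polyx_window = as.integer(polyx_window),
                 cast_threshold = cast_threshold,
                 cast_matrix = cast_matrix,
                 idr_min_length = as.integer(idr_min_length),
                 idr_score_threshold = idr_score_threshold,
                 disorder_source = match.arg(disorder_source)),
            class = "detector_config")
}

#' The BLOSUM62 substitution matrix
#' @return Numeric matrix over the 20 standard residues (plus ambiguity
#'   rows as shipped by Biostrings).
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

.runs_from_logical <- function(keep) {
  # maximal runs of TRUE as a 2-column (start, end) matrix
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Sliding-window homorepeat (polyX) scan
#'
#' For each residue type X, every window of `polyx_window` consecutive
#' residues containing at least `polyx_min_count` copies of X is a
#' candidate; overlapping or adjacent candidate windows are merged, and
#' each merged span is trimmed so that it starts and ends on X. Sequences
#' shorter than the window are scanned as one truncated window when they
#' are at least `polyx_min_count` long. Homorepeats of different residues
#' may overlap and are never merged across residue types.
#'
#' @param seq Ungapped residue string.
#' @param cfg A [detector_config()].
#' @param seq_id Identifier attached to emitted features.
#' @return Feature data.frame with kinds `polyX:X`, sorted by start.
#' @export
scan_polyx <- function(seq, cfg = detector_config(), seq_id = NA_character_) {
  chars <- .chars(seq)
  n <- length(chars)
  w <- cfg$polyx_window
  k <- cfg$polyx_min_count
  if (n < k) return(empty_features())
  w_eff <- min(w, n)
  out <- list()
  for (x in intersect(unique(chars), AA20)) {
    is_x <- chars == x
    cs <- c(0L, cumsum(is_x))
    starts <- seq_len(n - w_eff + 1L)
    counts <- cs[starts + w_eff] - cs[starts]
    cand <- starts[counts >= k]
    if (length(cand) == 0L) next
    # union of candidate-window positions -> merged spans
    covered <- rep(FALSE, n)
    for (s in cand) covered[s:(s + w_eff - 1L)] <- TRUE
    spans <- .runs_from_logical(covered)
    for (i in seq_len(nrow(spans))) {
      span <- spans[i, ]
      xs <- which(is_x[span[1L]:span[2L]]) + span[1L] - 1L
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, kind = paste0("polyX:", x),
        start = min(xs), end = max(xs), score = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_features())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$kind), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Best-scoring segment of a sequence against a homopolymer
#'
#' Scores every residue against the target residue with the substitution
#' matrix and returns the maximal-scoring contiguous segment (running sum
#' reset at zero). This is the core primitive of CAST-style compositional
#' bias detection. Ties are resolved to the leftmost maximal segment.
#'
#' @param seq Ungapped residue string.
#' @param residue Target residue (one of the 20 standard amino acids).
#' @param matrix Substitution matrix.
#' @param masked Optional logical vector: positions scoring 0 against
#'   every target (already emitted and neutralized).
#' @return `list(score=, start=, end=)`, or `NULL` if no positive segment.
#' @export
max_homopolymer_segment <- function(seq, residue, matrix = blosum62(),
                                    masked = NULL) {
  if (!residue %in% AA20) stop("not a standard amino acid: ", residue)
  chars <- .chars(seq)
  sc <- unname(matrix[match(chars, rownames(matrix)), residue])
  sc[is.na(sc)] <- 0          # ambiguity codes outside the matrix: neutral
  if (!is.null(masked)) sc[masked] <- 0
  best <- 0; b_start <- 0L; b_end <- 0L
  run <- 0; r_start <- 1L
  for (i in seq_along(sc)) {
    if (run <= 0) { run <- 0; r_start <- i }
    run <- run + sc[i]
    if (run > best) { best <- run; b_start <- r_start; b_end <- i }
  }
  if (best <= 0) return(NULL)
  list(score = best, start = b_start, end = b_end)
}

#' CAST-style compositionally biased region scan
#'
#' Iteratively: the maximal homopolymer segment is computed for every
#' residue type and the best-scoring (residue, segment) is taken; if its
#' score reaches `cast_threshold` a `CBR:X` feature is emitted, all
#' occurrences of X inside the emitted interval are masked (they then
#' score 0 against every target) and the search repeats over all residue
#' types; the scan stops when the best remaining score falls below the
#' threshold. Taking the globally best residue first means a region is
#' attributed to the residue that dominates it, not to every residue it
#' scores weakly positive against, and every emission masks at least one
#' residue so the iteration terminates. Features are returned sorted by
#' (start, residue).
#'
#' @inheritParams scan_polyx
#' @return Feature data.frame with kinds `CBR:X` and segment scores.
#' @export
scan_cbr_cast <- function(seq, cfg = detector_config(), seq_id = NA_character_) {
  chars <- .chars(seq)
  n <- length(chars)
  if (n == 0L) return(empty_features())
  out <- list()
  masked <- rep(FALSE, n)
  targets <- intersect(unique(chars), AA20)
  repeat {
    best <- NULL; best_x <- NULL
    for (x in targets) {
      seg <- max_homopolymer_segment(seq, x, cfg$cast_matrix, masked = masked)
      if (!is.null(seg) && (is.null(best) || seg$score > best$score)) {
        best <- seg; best_x <- x
      }
    }
    if (is.null(best) || best$score < cfg$cast_threshold) break
    out[[length(out) + 1L]] <- data.frame(
      seq_id = seq_id, kind = paste0("CBR:", best_x),
      start = best$start, end = best$end, score = best$score,
      stringsAsFactors = FALSE)
    hit <- seq(best$start, best$end)
    hit <- hit[chars[hit] == best_x & !masked[hit]]
    if (length(hit) == 0L) break   # defensive: no progress possible
    masked[hit] <- TRUE
  }
  if (length(out) == 0L) return(empty_features())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$kind), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a per-residue disorder score file (external predictor output)
#'
#' Whitespace-separated lines `position residue score`, the common output
#' layout of per-residue disorder predictors; `#` comment lines are
#' ignored. The residue column is cross-checked against the sequence.
#'
#' @param path Score file path.
#' @param seq Ungapped residue string the profile belongs to.
#' @return Numeric vector of scores in `[0, 1]`, one per residue.
#' @export
read_disorder_profile <- function(path, seq) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("pos", "residue", "score"),
                          stringsAsFactors = FALSE)
  chars <- .chars(seq)
  if (nrow(df) != length(chars))
    stop("disorder profile length ", nrow(df),
         " does not match sequence length ", length(chars))
  if (!all(df$pos == seq_along(chars)))
    stop("disorder profile positions are not 1..n")
  mism <- which(toupper(df$residue) != chars)
  if (length(mism) > 0L)
    stop("disorder profile residue mismatch at position(s) ",
         paste(utils::head(mism, 5L), collapse = ", "))
  if (any(df$score < 0 | df$score > 1)) stop("disorder scores outside [0,1]")
  df$score
}

#' Write a disorder profile in the 3-column layout
#' @param scores Numeric scores, one per residue.
#' @param seq Ungapped residue string.
#' @param path Output path.
#' @export
write_disorder_profile <- function(scores, seq, path) {
  chars <- .chars(seq)
  stopifnot(length(scores) == length(chars))
  writeLines(sprintf("%d\t%s\t%.4f", seq_along(chars), chars, scores), path)
  invisible(path)
}

# In-package residue disorder-propensity scale in [0,1]; order-preserving
# rearrangement of published propensity rankings (aromatics/branched
# hydrophobics order-promoting, P/E/S/K/Q disorder-promoting). This is a
# simple testing stand-in, not a reimplementation of any energy-based
# predictor.
DISORDER_SCALE <- c(
  W = 0.05, C = 0.10, F = 0.12, I = 0.15, Y = 0.20, V = 0.22, L = 0.25,
  M = 0.30, H = 0.45, T = 0.50, A = 0.52, R = 0.55, G = 0.58, N = 0.60,
  D = 0.65, Q = 0.68, S = 0.70, K = 0.75, E = 0.80, P = 0.88, X = 0.50)

#' Fallback per-residue disorder scores from a propensity scale
#'
#' Looks up each residue in the bundled disorder-propensity scale and
#' smooths with a centered moving average of width 21 (truncated at the
#' sequence ends), clamping to `[0, 1]`. Intended for testing and for
#' corpora without external predictor output; its scores are not
#' comparable to energy-based predictors.
#'
#' @param seq Ungapped residue string.
#' @param window Moving-average width (odd).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
fallback_disorder_scores <- function(seq, window = 21L) {
  chars <- .chars(seq)
  raw <- unname(DISORDER_SCALE[chars])
  if (anyNA(raw))
    stop("residue(s) missing from the disorder-propensity scale: ",
         paste(unique(chars[is.na(raw)]), collapse = ", "))
  half <- (window - 1L) %/% 2L
  n <- length(raw)
  cs <- c(0, cumsum(raw))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  pmin(pmax(sm, 0), 1)
}

#' Call intrinsically disordered regions from a disorder profile
#'
#' Maximal runs of consecutive residues with score at or above the
#' threshold; runs shorter than `idr_min_length` are discarded.
#'
#' @param scores Per-residue disorder scores.
#' @param cfg A [detector_config()].
#' @param seq_id Identifier attached to emitted features.
#' @return Feature data.frame with kind `IDR`.
#' @export
predict_idr <- function(scores, cfg = detector_config(), seq_id = NA_character_) {
  keep <- scores >= cfg$idr_score_threshold
  if (!any(keep)) return(empty_features())
  runs <- .runs_from_logical(keep)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= cfg$idr_min_length, ,
               drop = FALSE]
  if (nrow(runs) == 0L) return(empty_features())
  data.frame(seq_id = seq_id, kind = "IDR",
             start = runs[, "start"], end = runs[, "end"],
             score = NA_real_, stringsAsFactors = FALSE)
}

#' Detect all LCR classes in every sequence of an ortholog group
#'
#' polyX and CBR features are computed on the ungapped residues; IDRs come
#' either from external per-residue score files (`disorder_source =
#' "adapter"`, via `disorder_paths`) or from the fallback propensity
#' scale; coiled-coil features are passed through from `annotations`.
#' Annotations whose `seq_id` does not occur in the group are skipped with
#' a warning.
#'
#' @param group An `ortholog_group`.
#' @param cfg A [detector_config()].
#' @param annotations Optional feature data.frame of ingested features
#'   (e.g. CC ranges), `seq_id` matching the group's sequence ids.
#' @param disorder_paths Optional named character vector (names = sequence
#'   ids) of per-residue disorder score files for the adapter source.
#' @return Feature data.frame over all sequences of the group, in
#'   sequence coordinates, with columns `seq_id`, `species`, `kind`,
#'   `start`, `end`, `score`.
#' @export
detect_features <- function(group, cfg = detector_config(),
                            annotations = NULL, disorder_paths = NULL) {
  stopifnot(inherits(group, "ortholog_group"))
  out <- list()
  for (sp in group_species(group)) {
    id <- group$ids[[sp]]
    seq <- gsub("-", "", group$aligned[[sp]], fixed = TRUE)
    if (nchar(seq) == 0L) next
    feats <- rbind(scan_polyx(seq, cfg, id), scan_cbr_cast(seq, cfg, id))
    scores <- if (cfg$disorder_source == "adapter") {
      if (!is.null(disorder_paths) && !is.na(disorder_paths[id]))
        read_disorder_profile(disorder_paths[[id]], seq)
      else NULL
    } else fallback_disorder_scores(seq)
    if (!is.null(scores)) feats <- rbind(feats, predict_idr(scores, cfg, id))
    if (nrow(feats) > 0L) feats$species <- sp
    out[[sp]] <- feats
  }
  res <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(res)) res <- cbind(empty_features(), species = character())
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    known <- annotations$seq_id %in% group$ids
    if (any(!known))
      warning("annotation(s) for unknown sequence id(s) skipped: ",
              paste(unique(annotations$seq_id[!known]), collapse = ", "))
    ann <- annotations[known, , drop = FALSE]
    if (nrow(ann) > 0L) {
      ann$species <- names(group$ids)[match(ann$seq_id, group$ids)]
      res <- rbind(res, ann[, names(res)])
    }
  }
  rownames(res) <- NULL
  res[order(res$seq_id, res$kind, res$start), , drop = FALSE]
}
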