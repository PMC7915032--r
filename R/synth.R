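#' Plan a synthetic ortholog group
#'
#' Synthetic groups are built directly in a shared column frame: planted
#' features are specified in alignment columns, indels are realized as gap
#' blocks, and the "alignment" is therefore exact by construction (no
#' aligner is run). Flanking columns of polyX/CBR plants are forced to
#' residues scoring negatively against the planted residue so that, at
#' purity 1, detectors recover exactly the planted interval.
#'
#' @param group_id Group identifier.
#' @param seed Integer seed; generation is byte-deterministic under it.
#' @param n_col Number of alignment columns.
#' @param species Species present in the group (subset of the panel).
#' @param plants data.frame with columns `kind` (feature kind), `start`,
#'   `end` (alignment columns), `species` (semicolon-separated carriers),
#'   and optionally `purity` (fraction of the biased residue for
#'   polyX/CBR plants, disorder level irrelevant for IDR; default 1).
#' @param indels data.frame (`species`, `start`, `end`): gap blocks, must
#'   not intersect that species' planted columns.
#' @param background "uniform" over the 20 residues or "human" (rough
#'   human-proteome residue frequencies).
#' @param idr_level,idr_flank Disorder scores emitted inside and outside
#'   planted IDRs.
#' @return A `group_plan` list.
#' @export
group_plan <- function(group_id, seed, n_col = 600L,
                       species = species_panel(),
                       plants = NULL, indels = NULL,
                       background = c("uniform", "human"),
                       idr_level = 0.9, idr_flank = 0.1) {
  background <- match.arg(background)
  stopifnot(all(species %in% species_panel()), n_col >= 1L)
  if (is.null(plants))
    plants <- data.frame(kind = character(), start = integer(),
                         end = integer(), species = character(),
                         purity = numeric(), stringsAsFactors = FALSE)
  if (is.null(plants$purity)) plants$purity <- 1
  if (is.null(indels))
    indels <- data.frame(species = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  .check_kind(plants$kind)
  stopifnot(all(plants$start >= 1L), all(plants$end <= n_col),
            all(plants$start <= plants$end),
            all(plants$purity > 0), all(plants$purity <= 1))
  carriers <- strsplit(plants$species, ";", fixed = TRUE)
  for (cs in carriers)
    if (!all(cs %in% species))
      stop("plant carrier species not present in the group: ",
           paste(setdiff(cs, species), collapse = ", "))
  # overlapping plants of the same kind for the same species are
  # contradictory (their union would not be the planted truth)
  if (nrow(plants) > 1L) {
    for (i in seq_len(nrow(plants) - 1L)) for (j in seq(i + 1L, nrow(plants))) {
      if (plants$kind[i] == plants$kind[j] &&
          length(intersect(carriers[[i]], carriers[[j]])) > 0L &&
          plants$start[i] <= plants$end[j] && plants$end[i] >= plants$start[j])
        stop("overlapping plants of kind ", plants$kind[i],
             " for a shared species")
    }
  }
  for (r in seq_len(nrow(indels))) {
    sp <- indels$species[r]
    if (!sp %in% species) stop("indel for absent species: ", sp)
    for (i in seq_len(nrow(plants))) {
      if (sp %in% carriers[[i]] &&
          indels$start[r] <= plants$end[i] && indels$end[r] >= plants$start[i])
        stop("indel intersects a planted feature for species ", sp)
    }
  }
  structure(list(group_id = group_id, seed = as.integer(seed),
                 n_col = as.integer(n_col), species = species,
                 plants = plants, carriers = carriers, indels = indels,
                 background = background,
                 idr_level = idr_level, idr_flank = idr_flank),
            class = "group_plan")
}

.bg_probs <- function(background) {
  if (background == "uniform") return(rep(1 / 20, 20))
  # rough human proteome residue frequencies
  p <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7)
  p / sum(p)
}

# residues scoring strictly negatively against x: used for plant flanks and
# the off-residues of diffuse CBR plants. W and C are excluded because
# their large self-scores could let scattered guards accumulate their own
# biased segment once emitted regions are masked to neutral; drawing the
# rest diversely prevents any single residue type from doing the same.
.neutral_pool <- function(x, matrix) {
  cand <- setdiff(AA20, c(x, "W", "C"))
  pool <- cand[matrix[cand, x] <= -1]
  if (length(pool) == 0L) pool <- cand[matrix[cand, x] <= 0]
  pool
}

.plant_residue <- function(kind) sub("^(CBR|polyX):", "", kind)

#' Generate a synthetic ortholog group with ground truth
#'
#' Deterministic under the plan's seed. Returns the group, the per-species
#' disorder score vectors (over ungapped positions, `idr_level` inside
#' planted IDRs and `idr_flank` outside), coiled-coil annotations for CC
#' plants, and a truth table holding the expected per-sequence features,
#' consolidated intervals and profiles, presence entries and
#' filter-cascade stage membership, all derived from the plan alone.
#'
#' @param plan A [group_plan()].
#' @return List `group`, `disorder` (named list of numeric vectors),
#'   `annotations` (CC feature data.frame), `truth`.
#' @export
gen_group <- function(plan) {
  stopifnot(inherits(plan, "group_plan"))
  set.seed(plan$seed)
  b62 <- blosum62()
  probs <- .bg_probs(plan$background)
  n <- plan$n_col
  rows <- list()
  for (sp in plan$species) {
    res <- sample(AA20, n, replace = TRUE, prob = probs)
    for (i in seq_len(nrow(plan$plants))) {
      if (!sp %in% plan$carriers[[i]]) next
      kind <- plan$plants$kind[i]
      cols <- seq(plan$plants$start[i], plan$plants$end[i])
      if (grepl("^(polyX|CBR):", kind)) {
        x <- .plant_residue(kind)
        pool <- .neutral_pool(x, b62)
        if (grepl("^polyX:", kind)) {
          pur <- plan$plants$purity[i]
          hit <- stats::runif(length(cols)) <= pur
          res[cols[hit]] <- x
          res[cols[!hit]] <- sample(setdiff(AA20, x), sum(!hit),
                                    replace = TRUE)
        } else {
          # diffuse bias: every m-th column is a diverse neutral residue,
          # capping the local density below the homorepeat rule
          m <- if (plan$plants$purity[i] <= 0.5) 2L else 3L
          rel <- seq_along(cols)
          off <- rel[rel %% m == 0L & rel < length(cols)]
          res[cols] <- x
          res[cols[off]] <- sample(pool, length(off), replace = TRUE)
        }
        # a 3-column flank: a 10-window reaching past it can hold at most
        # 7 plant residues, so the homorepeat rule cannot recruit flanking
        # background, and the negative scores stop maximal-segment creep
        flank <- setdiff(c(cols[1L] - (1:3), cols[length(cols)] + (1:3)),
                         cols)
        flank <- flank[flank >= 1L & flank <= n]
        res[flank] <- sample(pool, length(flank), replace = TRUE)
      }
    }
    rows[[sp]] <- res
  }
  # apply indels as gap blocks
  for (r in seq_len(nrow(plan$indels))) {
    sp <- plan$indels$species[r]
    rows[[sp]][seq(plan$indels$start[r], plan$indels$end[r])] <- "-"
  }
  # scrub the background: resample any columns where the realized sequence
  # would yield a polyX/CBR call outside the planted (plus flank) columns,
  # so that the planted truth is exhaustive for a noiseless plan
  protected <- rep(FALSE, n)
  for (i in seq_len(nrow(plan$plants))) {
    lo <- max(1L, plan$plants$start[i] - 3L)
    hi <- min(n, plan$plants$end[i] + 3L)
    protected[lo:hi] <- TRUE
  }
  cfg0 <- detector_config()
  for (sp in plan$species) {
    for (pass in 1:30) {
      keep <- which(rows[[sp]] != "-")
      seq_sp <- paste(rows[[sp]][keep], collapse = "")
      det <- rbind(scan_polyx(seq_sp, cfg0), scan_cbr_cast(seq_sp, cfg0))
      bad <- integer()
      for (i in seq_len(nrow(det))) {
        cols_i <- keep[det$start[i]:det$end[i]]
        bad <- c(bad, cols_i[!protected[cols_i]])
      }
      if (length(bad) == 0L) break
      rows[[sp]][bad] <- sample(AA20, length(bad), replace = TRUE,
                                prob = probs)
    }
  }
  seqs <- data.frame(id = paste0(plan$group_id, "_",
                                 gsub(" ", "_", plan$species)),
                     species = plan$species,
                     residues = vapply(rows, paste, character(1L),
                                       collapse = ""),
                     stringsAsFactors = FALSE)
  # keep human (panel) ordering with human leading when present
  seqs <- seqs[order(match(seqs$species, species_panel())), , drop = FALSE]
  group <- ortholog_group(plan$group_id, seqs)
  maps <- lapply(group$aligned, build_coordinate_map)

  # a pure homorepeat plant long enough to clear the CBR threshold is, by
  # definition, also a compositionally biased region: the truth table must
  # expect the co-detection (unless a wider CBR plant already covers it)
  aug <- .augment_plants(plan, b62)
  tplan <- plan
  tplan$plants <- aug$plants
  tplan$carriers <- aug$carriers

  # expected per-sequence features, disorder scores, CC annotations
  feats <- list(); ann <- list()
  disorder <- lapply(stats::setNames(plan$species, plan$species), function(sp) {
    rep(plan$idr_flank, maps[[sp]]$seq_length)
  })
  for (i in seq_len(nrow(tplan$plants))) {
    kind <- tplan$plants$kind[i]
    for (sp in tplan$carriers[[i]]) {
      cm <- maps[[sp]]
      s <- cm$col_to_seq[tplan$plants$start[i]]
      e <- cm$col_to_seq[tplan$plants$end[i]]
      id <- group$ids[[sp]]
      row <- data.frame(seq_id = id, kind = kind, start = s, end = e,
                        score = NA_real_, species = sp,
                        stringsAsFactors = FALSE)
      if (kind == "IDR") disorder[[sp]][s:e] <- plan$idr_level
      if (kind == "CC") ann[[length(ann) + 1L]] <- row
      feats[[length(feats) + 1L]] <- row
    }
  }
  truth_features <- if (length(feats)) do.call(rbind, feats) else
    cbind(empty_features(), species = character())
  annotations <- if (length(ann))
    do.call(rbind, ann)[, c("seq_id", "kind", "start", "end", "score")] else
    empty_features()

  truth <- list(
    features = truth_features,
    consolidated = .expected_consolidated(tplan, group),
    presence = .expected_presence(tplan, group),
    cascade = .expected_cascade(tplan))
  names(disorder) <- group$ids[names(disorder)]
  list(group = group, disorder = disorder, annotations = annotations,
       truth = truth)
}

# extend the plan with the CBR:X features implied by pure polyX:X plants
# whose homopolymer score clears the default CAST threshold; carriers
# already covered by a wider overlapping CBR:X plant are excluded
.augment_plants <- function(plan, b62, cast_threshold = 40) {
  plants <- plan$plants
  carriers <- plan$carriers
  for (i in seq_len(nrow(plan$plants))) {
    kind <- plan$plants$kind[i]
    if (!grepl("^polyX:", kind) || plan$plants$purity[i] < 1) next
    x <- .plant_residue(kind)
    len <- plan$plants$end[i] - plan$plants$start[i] + 1L
    if (len * b62[x, x] < cast_threshold) next
    covered_by_cbr <- function(sp) {
      any(vapply(seq_len(nrow(plan$plants)), function(j) {
        plan$plants$kind[j] == paste0("CBR:", x) &&
          sp %in% plan$carriers[[j]] &&
          plan$plants$start[j] <= plan$plants$end[i] &&
          plan$plants$end[j] >= plan$plants$start[i]
      }, logical(1L)))
    }
    free <- Filter(Negate(covered_by_cbr), plan$carriers[[i]])
    if (length(free) == 0L) next
    plants <- rbind(plants,
                    data.frame(kind = paste0("CBR:", x),
                               start = plan$plants$start[i],
                               end = plan$plants$end[i],
                               species = paste(free, collapse = ";"),
                               purity = 1, stringsAsFactors = FALSE))
    carriers <- c(carriers, list(free))
  }
  list(plants = plants, carriers = carriers)
}

# union of planted columns per kind -> expected consolidated table
.expected_consolidated <- function(plan, group) {
  out <- list()
  for (kind in sort(unique(plan$plants$kind))) {
    sel <- which(plan$plants$kind == kind)
    covered <- rep(FALSE, plan$n_col)
    for (i in sel) covered[plan$plants$start[i]:plan$plants$end[i]] <- TRUE
    runs <- .runs_from_logical(covered)
    for (r in seq_len(nrow(runs))) {
      prof <- vapply(group$panel, function(sp) {
        if (!sp %in% plan$species) return("-")
        hit <- any(vapply(sel, function(i) {
          sp %in% plan$carriers[[i]] &&
            plan$plants$start[i] <= runs[r, 2L] &&
            plan$plants$end[i] >= runs[r, 1L]
        }, logical(1L)))
        if (hit) "1" else "0"
      }, character(1L))
      out[[length(out) + 1L]] <- data.frame(
        group = plan$group_id, kind = kind,
        start = unname(runs[r, 1L]), end = unname(runs[r, 2L]),
        profile = paste(prof, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(), kind = character(),
                      start = integer(), end = integer(),
                      profile = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$kind, res$start), , drop = FALSE]
}

.expected_presence <- function(plan, group) {
  ids <- unname(group$ids)
  m <- matrix(0L, length(feature_kinds()), length(ids),
              dimnames = list(feature_kinds(), ids))
  for (i in seq_len(nrow(plan$plants)))
    m[plan$plants$kind[i], group$ids[plan$carriers[[i]]]] <- 1L
  m
}

# cascade membership derived straight from the plan (independent of the
# consolidation and filter implementations)
.expected_cascade <- function(plan) {
  p <- plan$plants
  a <- which(p$kind == "CBR:A")
  s1 <- length(a) > 0L
  conserved <- a[vapply(a, function(i) length(plan$carriers[[i]]) >= 4L,
                        logical(1L))]
  s2 <- length(conserved) > 0L
  clean <- conserved[vapply(conserved, function(i) {
    pa <- which(p$kind == "polyX:A")
    !any(p$start[pa] <= p$end[i] & p$end[pa] >= p$start[i])
  }, logical(1L))]
  s3 <- length(clean) > 0L
  s4 <- s3 && any(p$kind == "polyX:P")
  c(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
}

#' Generate a synthetic presence matrix with target pairwise co-occurrence
#'
#' Draws 0/1 entries per sequence so that each kind has the requested
#' marginal presence probability and each targeted pair of kinds has the
#' requested expected Jaccard score, using the exact relation
#' `P(both) = J * (p1 + p2) / (1 + J)`. Targets violating the Frechet
#' bounds are rejected.
#'
#' @param kinds Row names (feature kinds or arbitrary labels).
#' @param n_seqs Number of columns.
#' @param marginals Presence probability per kind (recycled).
#' @param pairs Optional data.frame (`kind1`, `kind2`, `jaccard`); each
#'   kind may appear in at most one pair.
#' @param seed Integer seed.
#' @return List `matrix` (0/1, kinds x sequences) and `truth` (the
#'   expected marginals and pair Jaccard targets).
#' @export
gen_presence_matrix <- function(kinds, n_seqs, marginals = 0.3, pairs = NULL,
                                seed = 1L) {
  set.seed(seed)
  marg <- stats::setNames(rep_len(marginals, length(kinds)), kinds)
  m <- matrix(0L, length(kinds), n_seqs, dimnames = list(kinds, NULL))
  paired <- character()
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    if (any(duplicated(c(pairs$kind1, pairs$kind2))))
      stop("each kind may appear in at most one targeted pair")
    for (r in seq_len(nrow(pairs))) {
      k1 <- pairs$kind1[r]; k2 <- pairs$kind2[r]; j <- pairs$jaccard[r]
      p1 <- marg[[k1]]; p2 <- marg[[k2]]
      p11 <- j * (p1 + p2) / (1 + j)
      if (p11 > min(p1, p2) + 1e-12 || p11 < max(0, p1 + p2 - 1) - 1e-12)
        stop("infeasible Jaccard target ", j, " for marginals ",
             p1, ", ", p2)
      cell <- sample(4L, n_seqs, replace = TRUE,
                     prob = c(p11, p1 - p11, p2 - p11,
                              1 - p1 - p2 + p11))
      m[k1, ] <- as.integer(cell %in% c(1L, 2L))
      m[k2, ] <- as.integer(cell %in% c(1L, 3L))
      paired <- c(paired, k1, k2)
    }
  }
  for (k in setdiff(kinds, paired))
    m[k, ] <- stats::rbinom(n_seqs, 1L, marg[[k]])
  colnames(m) <- paste0("seq", seq_len(n_seqs))
  list(matrix = m, truth = list(marginals = marg, pairs = pairs))
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

.match_intervals <- function(truth, obs, min_overlap = 0.9) {
  # rows matched by (seq scope columns present in both) kind + overlap
  key_cols <- intersect(c("seq_id", "group", "kind"), names(truth))
  hit_t <- rep(FALSE, nrow(truth)); hit_o <- rep(FALSE, nrow(obs))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(obs))) {
      if (hit_o[j]) next
      if (!all(truth[i, key_cols] == obs[j, key_cols])) next
      if (.reciprocal_overlap(truth$start[i], truth$end[i],
                              obs$start[j], obs$end[j]) >= min_overlap) {
        hit_t[i] <- TRUE; hit_o[j] <- TRUE; break
      }
    }
  }
  list(recall = if (nrow(truth)) mean(hit_t) else 1,
       precision = if (nrow(obs)) mean(hit_o) else 1,
       matched_truth = hit_t, matched_obs = hit_o)
}

#' Score pipeline outputs against a synthetic truth table
#'
#' Interval-level precision/recall for detection and consolidation (a
#' match requires the same sequence/group and kind and reciprocal overlap
#' of at least `min_overlap`), exact-profile agreement on matched
#' consolidated features, presence-matrix agreement, cascade stage
#' agreement, and a Rand index for cluster labels.
#'
#' @param truth Truth table from [gen_group()] (or a corpus-level merge).
#' @param observed List with any of `features`, `consolidated`,
#'   `presence`, `cascade`, `clusters`.
#' @param min_overlap Reciprocal-overlap threshold for interval matches.
#' @return List of per-stage metrics (only stages present in `observed`).
#' @export
evaluate_recovery <- function(truth, observed, min_overlap = 0.9) {
  out <- list()
  if (!is.null(observed$features)) {
    out$detection <- .match_intervals(truth$features, observed$features,
                                      min_overlap)[c("precision", "recall")]
  }
  if (!is.null(observed$consolidated)) {
    m <- .match_intervals(truth$consolidated, observed$consolidated,
                          min_overlap)
    prof_ok <- NA_real_
    if (any(m$matched_truth)) {
      # profile agreement on the truth rows that found a match
      tt <- truth$consolidated[m$matched_truth, , drop = FALSE]
      oo <- observed$consolidated
      prof_ok <- mean(vapply(seq_len(nrow(tt)), function(i) {
        cand <- oo[oo$group == tt$group[i] & oo$kind == tt$kind[i], ,
                   drop = FALSE]
        any(cand$profile == tt$profile[i] &
              vapply(seq_len(nrow(cand)), function(j)
                .reciprocal_overlap(tt$start[i], tt$end[i],
                                    cand$start[j], cand$end[j]) >= min_overlap,
                logical(1L)))
      }, logical(1L)))
    }
    out$consolidation <- list(precision = m$precision, recall = m$recall,
                              profile_match = prof_ok)
  }
  if (!is.null(observed$presence)) {
    tp <- truth$presence
    op <- observed$presence[rownames(tp), colnames(tp), drop = FALSE]
    out$presence <- list(agreement = mean(tp == op))
  }
  if (!is.null(observed$cascade)) {
    out$cascade <- list(agreement = mean(truth$cascade == observed$cascade))
  }
  if (!is.null(observed$clusters)) {
    ids <- names(truth$clusters)
    out$clustering <- list(rand = rand_index(truth$clusters[ids],
                                             observed$clusters[ids]))
  }
  out
}
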