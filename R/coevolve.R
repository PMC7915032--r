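#' Default fragment specification for huntingtin
#'
#' The five large regions of the human protein delimited by its long
#' disordered insertions: 1-402, 403-970, 971-1330, 1331-2080, 2081-3142
#' (1-based inclusive, human sequence coordinates; full length 3142).
#'
#' @return data.frame (`label`, `start`, `end`).
#' @export
htt_fragments <- function() {
  data.frame(label = paste0("fragm", 1:5),
             start = c(1L, 403L, 971L, 1331L, 2081L),
             end = c(402L, 970L, 1330L, 2080L, 3142L),
             stringsAsFactors = FALSE)
}

.validate_fragments <- function(spec, seq_length) {
  stopifnot(all(c("label", "start", "end") %in% names(spec)))
  spec <- spec[order(spec$start), , drop = FALSE]
  if (any(spec$start < 1L) || any(spec$start > spec$end))
    stop("invalid fragment interval(s)")
  if (any(spec$end > seq_length))
    stop("fragment spec exceeds the human sequence length (", seq_length, ")")
  if (nrow(spec) > 1L && any(spec$start[-1L] <= spec$end[-nrow(spec)]))
    stop("fragment intervals overlap")
  spec
}

#' Binary IDR profile of one aligned sequence over alignment columns
#'
#' 1 at columns holding a residue predicted to be inside an IDR, 0 at
#' non-IDR residues and at gap columns.
#'
#' @param aligned Aligned residue string.
#' @param idr_features Feature data.frame rows of kind `IDR` for this
#'   sequence, in sequence coordinates.
#' @return Integer 0/1 vector, one entry per alignment column.
#' @export
idr_column_profile <- function(aligned, idr_features) {
  n_col <- nchar(aligned)
  prof <- integer(n_col)
  idr <- idr_features[idr_features$kind == "IDR", , drop = FALSE]
  if (nrow(idr) == 0L) return(prof)
  map <- build_coordinate_map(aligned)
  for (i in seq_len(nrow(idr))) {
    pos <- seq(idr$start[i], idr$end[i])
    prof[map$seq_to_col[pos]] <- 1L
  }
  prof
}

#' Fixed ordering of the 45 unordered species pairs
#' @param panel Species panel.
#' @return Character vector like "Homo sapiens--Pan troglodytes".
#' @export
species_pairs <- function(panel = species_panel()) {
  idx <- utils::combn(length(panel), 2L)
  paste(panel[idx[1L, ]], panel[idx[2L, ]], sep = "--")
}

#' Cross-species IDR overlap profile of one group (or fragment)
#'
#' For every unordered pair of panel species the Jaccard similarity of the
#' two binary IDR column profiles. A pair is non-informative (`NA`) when
#' either species is absent from the group or both profiles are all-zero
#' (nothing disordered to compare).
#'
#' @param group An `ortholog_group`.
#' @param features Per-sequence feature data.frame for the group (kind
#'   `IDR` rows are used), in sequence coordinates.
#' @return Named numeric vector over [species_pairs()], values in
#'   `[0, 1]` or `NA`.
#' @export
pair_jaccard_profile <- function(group, features) {
  stopifnot(inherits(group, "ortholog_group"))
  panel <- group$panel
  profs <- lapply(stats::setNames(panel, panel), function(sp) {
    if (!sp %in% names(group$aligned)) return(NULL)
    aligned <- group$aligned[[sp]]
    if (!grepl("[^-]", aligned)) return(integer(nchar(aligned)))
    idr <- features[features$species == sp & features$kind == "IDR", ,
                    drop = FALSE]
    idr_column_profile(aligned, idr)
  })
  idx <- utils::combn(length(panel), 2L)
  out <- vapply(seq_len(ncol(idx)), function(j) {
    a <- profs[[panel[idx[1L, j]]]]
    b <- profs[[panel[idx[2L, j]]]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    if (sum(a) == 0L && sum(b) == 0L) return(NA_real_)
    jaccard(a, b)
  }, numeric(1L))
  stats::setNames(out, species_pairs(panel))
}

#' Slice an ortholog group into fragment groups
#'
#' Fragment intervals are given in human sequence coordinates, translated
#' to alignment columns through the human coordinate map; each fragment
#' group is the corresponding column slice of the alignment with all
#' species retained (a species fully gapped in the slice stays as an
#' empty-profile member).
#'
#' @param group An `ortholog_group` containing the human sequence.
#' @param spec Fragment data.frame (`label`, `start`, `end`), human
#'   sequence coordinates; default [htt_fragments()].
#' @return Named list of `ortholog_group`s, one per fragment, plus a
#'   `col_ranges` attribute with the column slice of each fragment.
#' @export
split_fragments <- function(group, spec = htt_fragments()) {
  stopifnot(inherits(group, "ortholog_group"))
  hs <- human_species()
  if (!hs %in% names(group$aligned))
    stop("group '", group$group_id, "' has no human sequence to fragment")
  hmap <- build_coordinate_map(group$aligned[[hs]])
  spec <- .validate_fragments(spec, hmap$seq_length)
  ranges <- matrix(0L, nrow(spec), 2L,
                   dimnames = list(spec$label, c("start", "end")))
  out <- vector("list", nrow(spec))
  names(out) <- spec$label
  for (i in seq_len(nrow(spec))) {
    cols <- map_interval_to_alignment(hmap, spec$start[i], spec$end[i])
    ranges[i, ] <- cols
    sliced <- vapply(group$aligned, function(s) {
      substr(s, cols[1L], cols[2L])
    }, character(1L))
    seqs <- data.frame(id = paste0(group$ids[names(sliced)], "_", spec$label[i]),
                       species = names(sliced),
                       residues = unname(sliced), stringsAsFactors = FALSE)
    out[[i]] <- ortholog_group(paste0(group$group_id, "_", spec$label[i]),
                               seqs, group$panel)
  }
  attr(out, "col_ranges") <- ranges
  out
}

#' Pairwise distance between IDR overlap profiles with missing cells
#'
#' Euclidean distance over the coordinates informative in both profiles,
#' rescaled by `sqrt(n_pairs / n_shared)` so that profiles compared over
#' few shared informative cells are not artificially close (the standard
#' pairwise-deletion convention). A pair of profiles with no shared
#' informative coordinate gets the maximal attainable distance
#' `sqrt(n_pairs)` with a warning.
#'
#' @param profiles Numeric matrix, rows = proteins/fragments, columns =
#'   species pairs, `NA` = non-informative.
#' @return A `dist` object.
#' @export
profile_distances <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  n <- nrow(profiles)
  p <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  none_shared <- FALSE
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- !is.na(profiles[i, ]) & !is.na(profiles[j, ])
    ns <- sum(shared)
    if (ns == 0L) {
      none_shared <- TRUE
      dij <- sqrt(p)
    } else {
      dij <- sqrt(sum((profiles[i, shared] - profiles[j, shared])^2) * p / ns)
    }
    d[i, j] <- d[j, i] <- dij
  }
  if (none_shared)
    warning("profile pair(s) without shared informative coordinates ",
            "assigned the maximal distance")
  stats::as.dist(d)
}

#' Hierarchically cluster IDR overlap profiles
#'
#' Complete-linkage agglomeration on the pairwise-deletion distance of
#' [profile_distances()]. Rows are sorted by id first so the result does
#' not depend on input order.
#'
#' @param profiles Numeric matrix as for [profile_distances()].
#' @param k Number of flat clusters to cut.
#' @return List with `hclust` (the tree), `clusters` (named integer
#'   vector), and `dist`.
#' @export
cluster_profiles <- function(profiles, k = 2L) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("profile", seq_len(nrow(profiles)))
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- profile_distances(profiles)
  hc <- stats::hclust(d, method = "complete")
  list(hclust = hc,
       clusters = stats::cutree(hc, k = min(k, nrow(profiles))),
       dist = d)
}

#' Export a profile clustering as a Newick tree
#' @param clustering Result of [cluster_profiles()].
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Rand index between two flat partitions
#'
#' Fraction of object pairs on which two partitions agree (same cluster in
#' both, or different in both); 1 for identical partitions.
#'
#' @param a,b Cluster label vectors over the same objects.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  n <- length(a)
  same_a <- outer(a, a, "==")[lower.tri(diag(n))]
  same_b <- outer(b, b, "==")[lower.tri(diag(n))]
  mean(same_a == same_b)
}
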