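#' Presence/absence matrix of feature kinds across individual sequences
#'
#' One row per feature kind (all 42: IDR, CC, 20 CBR:X, 20 polyX:X), one
#' column per individual sequence (each interactor and each ortholog);
#' entry 1 when the sequence carries at least one raw (non-consolidated)
#' feature of the kind.
#'
#' @param features Per-sequence feature data.frame over the whole corpus
#'   (column `seq_id` identifies the sequence, `kind` the feature kind).
#' @param seq_ids Column universe; default: the distinct `seq_id`s in
#'   `features`. Supply the full corpus id list so that feature-free
#'   sequences appear as all-zero columns.
#' @return Integer 0/1 matrix, 42 x n_sequences.
#' @export
presence_matrix <- function(features, seq_ids = NULL) {
  if (is.null(seq_ids)) seq_ids <- sort(unique(features$seq_id))
  kinds <- feature_kinds()
  m <- matrix(0L, nrow = length(kinds), ncol = length(seq_ids),
              dimnames = list(kinds, seq_ids))
  if (nrow(features) > 0L) {
    .check_kind(features$kind)
    keep <- features$seq_id %in% seq_ids
    idx <- cbind(match(features$kind[keep], kinds),
                 match(features$seq_id[keep], seq_ids))
    m[idx] <- 1L
  }
  m
}

#' Jaccard similarity of two binary vectors
#'
#' Intersection over union of the supports; 0 when the union is empty.
#'
#' @param u,v Equal-length binary (0/1 or logical) vectors.
#' @return Score in `[0, 1]`.
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors differ in length (", length(u), " vs ", length(v), ")")
  u <- u > 0; v <- v > 0
  uni <- sum(u | v)
  if (uni == 0L) return(0)
  sum(u & v) / uni
}

#' All-pairs Jaccard co-occurrence between feature kinds
#'
#' @param pm A presence matrix from [presence_matrix()].
#' @return Symmetric matrix of Jaccard scores between the rows of `pm`;
#'   the diagonal is 1 for any kind present at least once and 0 for
#'   all-absent kinds.
#' @export
cooccurrence_matrix <- function(pm) {
  pm <- pm > 0
  inter <- tcrossprod(pm * 1)                      # |u & v|
  sums <- rowSums(pm)
  uni <- outer(sums, sums, "+") - inter            # |u | v|
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(rownames(pm), rownames(pm))
  out
}

#' Conserved A-rich filter cascade (HAP40-likeness)
#'
#' Stage-by-stage narrowing of ortholog groups towards the profile of a
#' diffusely alanine-rich, proline-punctuated interactor:
#' \describe{
#'   \item{s1}{groups with at least one consolidated A-rich CBR;}
#'   \item{s2}{those in which some A-rich CBR is conserved in at least
#'     `min_conserved_species` species (count of `1` in its profile,
#'     human included);}
#'   \item{s3}{those retaining a qualifying A-rich CBR that overlaps no
#'     consolidated polyA by even one column, however conserved the polyA
#'     is (this removes regions whose bias is just a homorepeat);}
#'   \item{s4}{those additionally containing at least one consolidated
#'     polyP anywhere in the group, however conserved.}
#' }
#'
#' @param consolidated Consolidated feature table over all groups (columns
#'   `group`, `kind`, `start`, `end`, `profile`).
#' @param min_conserved_species Minimum `1` count in the A-rich profile.
#' @return List with `stages` (named list s1..s4 of group id vectors),
#'   `counts` (stage, n data.frame) and `candidates` (the qualifying
#'   A-rich CBR rows of the s4 groups).
#' @export
hap40_like_filter <- function(consolidated, min_conserved_species = 4L) {
  need <- c("group", "kind", "start", "end", "profile")
  if (!all(need %in% names(consolidated)))
    stop("consolidated table must have columns ",
         paste(need, collapse = ", "))
  cbr_a <- consolidated[consolidated$kind == "CBR:A", , drop = FALSE]
  poly_a <- consolidated[consolidated$kind == "polyX:A", , drop = FALSE]
  poly_p <- consolidated[consolidated$kind == "polyX:P", , drop = FALSE]

  n_ones <- function(profile) {
    vapply(strsplit(profile, ""), function(x) sum(x == "1"), integer(1L))
  }
  s1 <- sort(unique(cbr_a$group))
  conserved <- cbr_a[n_ones(cbr_a$profile) >= min_conserved_species, ,
                     drop = FALSE]
  s2 <- sort(unique(conserved$group))
  clean <- conserved[!vapply(seq_len(nrow(conserved)), function(i) {
    pa <- poly_a[poly_a$group == conserved$group[i], , drop = FALSE]
    any(pa$start <= conserved$end[i] & pa$end >= conserved$start[i])
  }, logical(1L)), , drop = FALSE]
  s3 <- sort(unique(clean$group))
  s4 <- sort(intersect(s3, unique(poly_p$group)))

  stages <- list(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
  list(stages = stages,
       counts = data.frame(stage = names(stages),
                           n = lengths(stages), row.names = NULL),
       candidates = clean[clean$group %in% s4, , drop = FALSE])
}
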