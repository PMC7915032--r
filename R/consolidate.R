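#' Consolidate per-sequence features onto alignment coordinates
#'
#' For one ortholog group and one feature kind, every per-sequence feature
#' interval is translated to alignment columns (interior gaps spanned) and
#' the union of covered columns is taken. Each maximal contiguous covered
#' run becomes one consolidated feature carrying a per-species conservation
#' profile over the fixed panel: `1` if that species has a feature of the
#' kind overlapping the run by at least one column, `0` if the species is
#' present in the group without such an overlap, `-` if the species is
#' absent from the group.
#'
#' @param group An `ortholog_group`.
#' @param features Per-sequence feature data.frame for this group (as from
#'   [detect_features()]), in sequence coordinates.
#' @param kinds Kinds to consolidate; default: every kind in `features`.
#' @return Consolidated data.frame (`group`, `kind`, `start`, `end`,
#'   `profile`), columns in alignment coordinates, sorted by (kind, start).
#' @export
consolidate_group <- function(group, features, kinds = NULL) {
  stopifnot(inherits(group, "ortholog_group"))
  present <- group_species(group)
  if (nrow(features) > 0L) {
    bad <- setdiff(features$seq_id, group$ids)
    if (length(bad) > 0L)
      stop("feature(s) for sequence(s) not in group '", group$group_id,
           "': ", paste(unique(bad), collapse = ", "))
  }
  if (is.null(kinds)) kinds <- unique(features$kind)
  maps <- lapply(group$aligned, build_coordinate_map)
  out <- list()
  for (kind in sort(kinds)) {
    fk <- features[features$kind == kind, , drop = FALSE]
    if (nrow(fk) == 0L) next
    sp_of <- names(group$ids)[match(fk$seq_id, group$ids)]
    cols <- t(vapply(seq_len(nrow(fk)), function(i) {
      map_interval_to_alignment(maps[[sp_of[i]]], fk$start[i], fk$end[i])
    }, integer(2L)))
    covered <- rep(FALSE, group$width)
    for (i in seq_len(nrow(cols))) covered[cols[i, 1L]:cols[i, 2L]] <- TRUE
    runs <- .runs_from_logical(covered)
    for (r in seq_len(nrow(runs))) {
      run <- runs[r, ]
      prof <- vapply(group$panel, function(sp) {
        if (!sp %in% present) return("-")
        mine <- which(sp_of == sp)
        hit <- any(cols[mine, 1L] <= run[2L] & cols[mine, 2L] >= run[1L])
        if (hit) "1" else "0"
      }, character(1L))
      out[[length(out) + 1L]] <- data.frame(
        group = group$group_id, kind = kind,
        start = unname(run[1L]), end = unname(run[2L]),
        profile = paste(prof, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(group = character(), kind = character(),
                      start = integer(), end = integer(),
                      profile = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$kind, res$start), , drop = FALSE]
}

#' Conservation pattern of a consolidated feature
#'
#' The profile string in fixed panel order, e.g. `"1111--1000"` for a
#' feature conserved in the first four species of a group missing two.
#'
#' @param consolidated One row (or several) of a consolidated table.
#' @return Character vector of profile strings.
#' @export
conservation_pattern <- function(consolidated) consolidated$profile

#' Count consolidated features per kind
#'
#' @param consolidated Consolidated table over one or more groups.
#' @return List with `per_kind` (kind, n) and `per_group` (group, kind, n)
#'   count data.frames; kinds with no features are absent (count zero).
#' @export
count_consolidated <- function(consolidated) {
  if (nrow(consolidated) == 0L) {
    return(list(per_kind = data.frame(kind = character(), n = integer()),
                per_group = data.frame(group = character(), kind = character(),
                                       n = integer())))
  }
  per_kind <- as.data.frame(table(kind = consolidated$kind),
                            responseName = "n", stringsAsFactors = FALSE)
  per_group <- as.data.frame(table(group = consolidated$group,
                                   kind = consolidated$kind),
                             responseName = "n", stringsAsFactors = FALSE)
  per_group <- per_group[per_group$n > 0L, , drop = FALSE]
  rownames(per_group) <- NULL
  list(per_kind = per_kind, per_group = per_group)
}

#' Frequency census of conservation patterns
#'
#' How often each distinct profile string occurs, overall and per kind.
#'
#' @param consolidated Consolidated table.
#' @return List with `overall` (profile, n) and `per_kind`
#'   (kind, profile, n) data.frames sorted by decreasing frequency.
#' @export
pattern_census <- function(consolidated) {
  if (nrow(consolidated) == 0L) {
    return(list(overall = data.frame(profile = character(), n = integer()),
                per_kind = data.frame(kind = character(), profile = character(),
                                      n = integer())))
  }
  overall <- as.data.frame(table(profile = consolidated$profile),
                           responseName = "n", stringsAsFactors = FALSE)
  overall <- overall[order(-overall$n, overall$profile), , drop = FALSE]
  per_kind <- as.data.frame(table(kind = consolidated$kind,
                                  profile = consolidated$profile),
                            responseName = "n", stringsAsFactors = FALSE)
  per_kind <- per_kind[per_kind$n > 0L, , drop = FALSE]
  per_kind <- per_kind[order(per_kind$kind, -per_kind$n, per_kind$profile), ,
                       drop = FALSE]
  rownames(overall) <- rownames(per_kind) <- NULL
  list(overall = overall, per_kind = per_kind)
}
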