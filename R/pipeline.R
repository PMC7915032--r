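#' Synthetic stand-in for the HAP40 sequence
#'
#' A constructed 371-residue sequence reproducing the printed landmarks of
#' UniProt P23610 (HAP40) needed by the worked examples: a diffuse A-rich
#' region at positions 43-261 opening with VAEAG and closing with AALGA,
#' and the proline decamer PPPPPPAPQP at positions 223-232. Everything
#' else is deterministic filler; this is NOT the database sequence (which
#' cannot be redistributed here) and is labelled synthetic wherever it is
#' used.
#'
#' @return A single residue string of length 371.
#' @export
synthetic_hap40_sequence <- function() {
  filler <- function(n) substr(strrep("SGDKEQLNRT", ceiling(n / 10)), 1L, n)
  arich <- function(n) substr(strrep("AALGA", ceiling(n / 5)), 1L, n)
  s <- paste0(filler(42L), arich(219L), filler(110L))
  substr(s, 43L, 47L) <- "VAEAG"
  substr(s, 223L, 232L) <- "PPPPPPAPQP"
  substr(s, 257L, 261L) <- "AALGA"
  stopifnot(nchar(s) == 371L)
  s
}

.stage_file <- function(out_dir, name) file.path(out_dir, name)

.write_manifest <- function(out_dir, stage, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config, file = tmp)
  lines <- c(paste0("stage: ", stage),
             paste0("package: lcrevol ",
                    as.character(utils::packageVersion("lcrevol"))),
             paste0("config_md5: ", unname(tools::md5sum(tmp))))
  writeLines(lines, .stage_file(out_dir, paste0("manifest_", stage, ".txt")))
}

.read_corpus <- function(alignment_dir, species_regex = "^[^|]*\\|(.+)$") {
  paths <- sort(list.files(alignment_dir, pattern = "\\.(fa|fasta)$",
                           full.names = TRUE))
  if (length(paths) == 0L)
    stop("no alignment FASTA files in ", alignment_dir,
         "; run the simulate stage or point to a corpus directory")
  stats::setNames(lapply(paths, read_alignment, species_regex = species_regex),
                  vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)),
                         character(1L)))
}

#' Detect LCRs across a corpus of ortholog-group alignments
#'
#' Reads every aligned FASTA in `alignment_dir`, runs the polyX and CBR
#' scanners plus the configured IDR source on the ungapped sequences,
#' ingests coiled-coil annotations when given, and writes one sorted
#' feature table for the corpus.
#'
#' @param alignment_dir Directory of per-group aligned FASTA files.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [detector_config()].
#' @param annotation_file Optional TSV of ingested features (e.g. CC).
#' @param disorder_dir Optional directory of `<seq_id>.scores` files for
#'   the adapter disorder source.
#' @return Invisibly, the corpus feature data.frame (with `group` column);
#'   written to `features.tsv`.
#' @export
run_detect <- function(alignment_dir, out_dir, cfg = detector_config(),
                       annotation_file = NULL, disorder_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- .read_corpus(alignment_dir)
  ann <- if (!is.null(annotation_file)) read_feature_annotations(annotation_file)
  all_feats <- list()
  for (gid in names(groups)) {
    g <- groups[[gid]]
    dpaths <- NULL
    if (!is.null(disorder_dir)) {
      files <- file.path(disorder_dir, paste0(g$ids, ".scores"))
      dpaths <- stats::setNames(ifelse(file.exists(files), files,
                                       NA_character_), g$ids)
    }
    gann <- if (!is.null(ann)) ann[ann$seq_id %in% g$ids, , drop = FALSE]
    f <- detect_features(g, cfg, annotations = gann, disorder_paths = dpaths)
    if (nrow(f) > 0L) f$group <- gid
    all_feats[[gid]] <- f
  }
  feats <- do.call(rbind, all_feats[vapply(all_feats, nrow, 1L) > 0])
  if (is.null(feats))
    feats <- cbind(empty_features(), species = character(),
                   group = character())
  rownames(feats) <- NULL
  write_feature_table(feats, .stage_file(out_dir, "features.tsv"))
  .write_manifest(out_dir, "detect", list(alignment_dir = alignment_dir,
                                          cfg = unclass(cfg)[-4L]))
  invisible(feats)
}

#' Consolidate a corpus feature table onto alignment coordinates
#'
#' @param alignment_dir Directory of per-group aligned FASTA files.
#' @param out_dir Directory holding `features.tsv` from [run_detect()];
#'   receives `consolidated.tsv`, `pattern_census.tsv`, `counts.tsv`.
#' @return Invisibly, the consolidated data.frame.
#' @export
run_consolidate <- function(alignment_dir, out_dir) {
  fpath <- .stage_file(out_dir, "features.tsv")
  if (!file.exists(fpath))
    stop("missing ", fpath, "; run the detect stage first")
  feats <- utils::read.table(fpath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  groups <- .read_corpus(alignment_dir)
  cons <- do.call(rbind, lapply(names(groups), function(gid) {
    consolidate_group(groups[[gid]],
                      feats[feats$group == gid, , drop = FALSE])
  }))
  rownames(cons) <- NULL
  write_feature_table(cons, .stage_file(out_dir, "consolidated.tsv"))
  census <- pattern_census(cons)
  utils::write.table(census$per_kind,
                     .stage_file(out_dir, "pattern_census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- count_consolidated(cons)
  utils::write.table(counts$per_kind, .stage_file(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "consolidate", list(alignment_dir = alignment_dir))
  invisible(cons)
}

#' Enrichment of feature kinds in the human foreground vs a background
#'
#' The foreground is the set of human (leading) sequences of the corpus;
#' presence is protein-level on raw features.
#'
#' @param out_dir Directory holding `features.tsv`; receives
#'   `enrichment.tsv`.
#' @param background_file TSV background presence table
#'   (see [read_background_table()]).
#' @param N_bg Background proteome size.
#' @param human_ids Ids of the foreground (human) sequences.
#' @return Invisibly, the enrichment data.frame.
#' @export
run_enrich <- function(out_dir, background_file, N_bg, human_ids) {
  fpath <- .stage_file(out_dir, "features.tsv")
  if (!file.exists(fpath))
    stop("missing ", fpath, "; run the detect stage first")
  feats <- utils::read.table(fpath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  pm <- presence_matrix(feats[feats$seq_id %in% human_ids, , drop = FALSE],
                        seq_ids = human_ids)
  bg <- read_background_table(background_file)
  res <- enrich_feature_kinds(pm[rownames(pm) %in% bg$kind, , drop = FALSE],
                              bg, N_bg = N_bg)
  utils::write.table(res, .stage_file(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "enrich", list(background_file = background_file,
                                          N_bg = N_bg))
  invisible(res)
}

#' Presence, co-occurrence and the conserved A-rich cascade for a corpus
#'
#' @param out_dir Directory holding `features.tsv` and `consolidated.tsv`;
#'   receives `presence.tsv`, `cooccurrence.tsv`, `cascade.tsv`.
#' @param min_conserved_species Cascade conservation threshold.
#' @return Invisibly, list with `presence`, `cooccurrence`, `cascade`.
#' @export
run_cooccur <- function(out_dir, min_conserved_species = 4L) {
  fpath <- .stage_file(out_dir, "features.tsv")
  cpath <- .stage_file(out_dir, "consolidated.tsv")
  if (!file.exists(fpath))
    stop("missing ", fpath, "; run the detect stage first")
  if (!file.exists(cpath))
    stop("missing ", cpath, "; run the consolidate stage first")
  feats <- utils::read.table(fpath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  cons <- read_consolidated_table(cpath)
  pm <- presence_matrix(feats)
  cm <- cooccurrence_matrix(pm)
  casc <- hap40_like_filter(cons, min_conserved_species)
  utils::write.table(pm, .stage_file(out_dir, "presence.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(round(cm, 6), .stage_file(out_dir, "cooccurrence.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  stage_df <- do.call(rbind, lapply(names(casc$stages), function(s) {
    if (length(casc$stages[[s]]) == 0L) return(NULL)
    data.frame(stage = s, group = casc$stages[[s]], stringsAsFactors = FALSE)
  }))
  utils::write.table(stage_df, .stage_file(out_dir, "cascade.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "cooccur",
                  list(min_conserved_species = min_conserved_species))
  invisible(list(presence = pm, cooccurrence = cm, cascade = casc))
}

#' Cross-species IDR overlap profiles and their clustering
#'
#' Builds the pair-Jaccard profile of every corpus group (optionally
#' splitting one group into fragments first), clusters the profiles with
#' complete linkage on the pairwise-deletion distance, and writes the
#' profile matrix (non-informative cells as NA), flat clusters and a
#' Newick dendrogram.
#'
#' @param alignment_dir Directory of per-group aligned FASTA files.
#' @param out_dir Directory holding `features.tsv`; receives
#'   `idr_profiles.tsv`, `clusters.tsv`, `dendrogram.nwk`.
#' @param k Number of flat clusters.
#' @param fragment_group Optional group id to split with `fragment_spec`.
#' @param fragment_spec Fragment table, default [htt_fragments()].
#' @return Invisibly, list with `profiles` and `clustering`.
#' @export
run_coevolve <- function(alignment_dir, out_dir, k = 5L,
                         fragment_group = NULL,
                         fragment_spec = htt_fragments()) {
  fpath <- .stage_file(out_dir, "features.tsv")
  if (!file.exists(fpath))
    stop("missing ", fpath, "; run the detect stage first")
  feats <- utils::read.table(fpath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  groups <- .read_corpus(alignment_dir)
  if (!is.null(fragment_group)) {
    if (!fragment_group %in% names(groups))
      stop("fragment_group '", fragment_group, "' not in the corpus")
    frags <- split_fragments(groups[[fragment_group]], fragment_spec)
    # fragment features: re-detect IDRs are not needed; slice the parent's
    # IDR features by the fragment column ranges through each species' map
    parent <- groups[[fragment_group]]
    pfeats <- feats[feats$group == fragment_group, , drop = FALSE]
    ranges <- attr(frags, "col_ranges")
    groups <- groups[names(groups) != fragment_group]
    for (fl in names(frags)) {
      groups[[frags[[fl]]$group_id]] <- frags[[fl]]
      feats <- rbind(feats,
                     .slice_features(parent, pfeats, ranges[fl, ],
                                     frags[[fl]]))
    }
  }
  profs <- t(vapply(names(groups), function(gid) {
    pair_jaccard_profile(groups[[gid]],
                         feats[feats$group == gid, , drop = FALSE])
  }, numeric(length(species_pairs()))))
  clustering <- cluster_profiles(profs, k = k)
  utils::write.table(round(profs, 6), .stage_file(out_dir, "idr_profiles.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(data.frame(id = names(clustering$clusters),
                                cluster = clustering$clusters),
                     .stage_file(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram_newick(clustering, .stage_file(out_dir, "dendrogram.nwk"))
  .write_manifest(out_dir, "coevolve", list(k = k,
                                            fragment_group = fragment_group))
  invisible(list(profiles = profs, clustering = clustering))
}

# restrict parent-group features to a fragment column slice, re-expressed
# in the fragment's sequence coordinates
.slice_features <- function(parent, pfeats, cols, frag) {
  if (nrow(pfeats) == 0L) return(pfeats[0L, , drop = FALSE])
  out <- list()
  for (sp in group_species(parent)) {
    pm <- build_coordinate_map(parent$aligned[[sp]])
    sub <- frag$aligned[[sp]]
    fm <- if (grepl("[^-]", sub)) build_coordinate_map(sub) else NULL
    if (is.null(fm)) next
    fs <- pfeats[pfeats$species == sp, , drop = FALSE]
    for (i in seq_len(nrow(fs))) {
      fc <- map_interval_to_alignment(pm, fs$start[i], fs$end[i])
      s <- max(fc[1L], cols[1L]); e <- min(fc[2L], cols[2L])
      if (s > e) next
      # clip to the fragment, then to the species' residues inside it
      rel <- fm$col_to_seq[seq(s, e) - cols[1L] + 1L]
      rel <- rel[!is.na(rel)]
      if (length(rel) == 0L) next
      row <- fs[i, , drop = FALSE]
      row$seq_id <- frag$ids[[sp]]
      row$group <- frag$group_id
      row$start <- min(rel); row$end <- max(rel)
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) return(pfeats[0L, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic corpus with its truth tables
#'
#' @param plans List of [group_plan()]s.
#' @param out_dir Output directory: per-group alignment FASTA under
#'   `alignments/`, disorder score files under `disorder/`, CC annotations
#'   and truth tables at the top level.
#' @return Invisibly, list of [gen_group()] results keyed by group id.
#' @export
run_simulate <- function(plans, out_dir) {
  adir <- file.path(out_dir, "alignments")
  ddir <- file.path(out_dir, "disorder")
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
  sims <- list()
  anns <- list(); truth_feats <- list(); truth_cons <- list()
  for (plan in plans) {
    sim <- gen_group(plan)
    g <- sim$group
    seqs <- data.frame(id = unname(g$ids), species = names(g$ids),
                       residues = unname(g$aligned),
                       stringsAsFactors = FALSE)
    write_fasta(seqs, file.path(adir, paste0(g$group_id, ".fasta")))
    for (id in names(sim$disorder)) {
      sp <- names(g$ids)[match(id, g$ids)]
      ungapped <- gsub("-", "", g$aligned[[sp]], fixed = TRUE)
      write_disorder_profile(sim$disorder[[id]], ungapped,
                             file.path(ddir, paste0(id, ".scores")))
    }
    anns[[g$group_id]] <- sim$annotations
    tf <- sim$truth$features; if (nrow(tf)) tf$group <- g$group_id
    truth_feats[[g$group_id]] <- tf
    truth_cons[[g$group_id]] <- sim$truth$consolidated
    sims[[g$group_id]] <- sim
  }
  ann <- do.call(rbind, anns[vapply(anns, nrow, 1L) > 0])
  if (is.null(ann)) ann <- empty_features()
  write_feature_table(ann, file.path(out_dir, "annotations.tsv"))
  tf <- do.call(rbind, truth_feats[vapply(truth_feats, nrow, 1L) > 0])
  if (!is.null(tf)) write_feature_table(tf, file.path(out_dir,
                                                      "truth_features.tsv"))
  tc <- do.call(rbind, truth_cons[vapply(truth_cons, nrow, 1L) > 0])
  if (!is.null(tc)) write_feature_table(tc, file.path(out_dir,
                                                      "truth_consolidated.tsv"))
  .write_manifest(out_dir, "simulate",
                  list(seeds = vapply(plans, `[[`, 1L, "seed")))
  invisible(sims)
}

#' Recompute the corpus-level reference statistics from a supplementary
#' corpus directory
#'
#' Runs detect, consolidate and cooccur over a directory laid out like the
#' output of [run_simulate()] (`alignments/`, optional `disorder/`,
#' optional `annotations.tsv`) and returns the headline numbers of the
#' analysis: consolidated polyX totals, the conserved A-rich cascade
#' counts and final group set, and selected co-occurrence scores.
#'
#' @param corpus_dir Corpus directory.
#' @param out_dir Work directory for the stage outputs.
#' @param htt_group Optional group id of the huntingtin alignment, for the
#'   per-group polyX count.
#' @return List with `polyx_total`, `polyx_htt`, `cascade_counts`,
#'   `cascade_final`, `cooccurrence` (the full matrix).
#' @export
reproduce_supplementary <- function(corpus_dir, out_dir = tempfile(),
                                    htt_group = NULL) {
  adir <- file.path(corpus_dir, "alignments")
  if (!dir.exists(adir))
    stop("supplementary corpus not found: expected ", adir,
         " with one aligned FASTA per ortholog group")
  ddir <- file.path(corpus_dir, "disorder")
  afile <- file.path(corpus_dir, "annotations.tsv")
  cfg <- detector_config(disorder_source =
                           if (dir.exists(ddir)) "adapter" else "fallback")
  run_detect(adir, out_dir, cfg,
             annotation_file = if (file.exists(afile)) afile,
             disorder_dir = if (dir.exists(ddir)) ddir)
  cons <- run_consolidate(adir, out_dir)
  co <- run_cooccur(out_dir)
  polyx <- cons[grepl("^polyX:", cons$kind), , drop = FALSE]
  list(polyx_total = nrow(polyx),
       polyx_htt = if (!is.null(htt_group))
         sum(polyx$group == htt_group) else NA_integer_,
       cascade_counts = co$cascade$counts,
       cascade_final = co$cascade$stages$s4,
       cooccurrence = co$cooccurrence)
}
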