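#' The fixed ten-species reference panel
#'
#' All conservation profiles produced or parsed by this package are strings
#' with one symbol per panel species, in this exact order, with human first.
#' The panel spans two fish and eight tetrapods (two rodents, two Sauria,
#' two primates, a marsupial, an amphibian) so that feature gain and loss
#' can be read at several independent taxonomic depths.
#'
#' @return Character vector of 10 scientific species names.
#' @export
species_panel <- function() {
  c("Homo sapiens", "Pan troglodytes", "Mus musculus", "Rattus norvegicus",
    "Sarcophilus harrisii", "Gallus gallus", "Anolis carolinensis",
    "Xenopus tropicalis", "Danio rerio", "Takifugu rubripes")
}

#' @rdname species_panel
#' @details `human_species()` returns the leading (human) panel entry.
#' @export
human_species <- function() species_panel()[1L]

# The 20 standard residues, the fixed order used for CBR:X / polyX:X kinds.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' All 42 feature kinds (IDR, CC, 20 CBR:X, 20 polyX:X)
#' @return Character vector of length 42, in fixed order.
#' @export
feature_kinds <- function() {
  c("IDR", "CC", paste0("CBR:", AA20), paste0("polyX:", AA20))
}

.check_kind <- function(kind) {
  bad <- setdiff(kind, feature_kinds())
  if (length(bad) > 0L)
    stop("unknown feature kind(s): ", paste(unique(bad), collapse = ", "))
  invisible(kind)
}

# Default header convention: "id|Species_name" (underscores for spaces).
.parse_species <- function(headers, species_regex = "^[^|]*\\|(.+)$") {
  m <- regmatches(headers, regexec(species_regex, headers))
  sp <- vapply(m, function(x) if (length(x) >= 2L) x[2L] else NA_character_,
               character(1L))
  sp <- gsub("_", " ", sp)
  if (anyNA(sp)) {
    warning("FASTA header(s) lacking a species token assigned species 'unknown'")
    sp[is.na(sp)] <- "unknown"
  }
  trimws(sp)
}

.parse_id <- function(headers) {
  sub("\\|.*$", "", sub("\\s.*$", "", headers))
}

#' Read protein sequences from a FASTA file
#'
#' Residues are upper-cased and the '.' gap character is normalized to '-'.
#' The species is parsed from the header with a configurable regex whose
#' first capture group is the species token (underscores become spaces);
#' records without a species token get species "unknown" with a warning.
#'
#' @param path Path to a FASTA file.
#' @param species_regex Regex with one capture group applied to the full
#'   header to extract the species token.
#' @return A data.frame with columns `id`, `species`, `residues`.
#' @export
read_fasta <- function(path, species_regex = "^[^|]*\\|(.+)$") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  res <- toupper(as.character(set))
  res <- gsub(".", "-", res, fixed = TRUE)
  data.frame(id = .parse_id(headers),
             species = .parse_species(headers, species_regex),
             residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()] under the default header convention
#' (`id|Species_name`); a round-trip is byte-stable.
#'
#' @param seqs data.frame with columns `id`, `species`, `residues`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("id", "species", "residues") %in% names(seqs)))
  headers <- paste0(seqs$id, "|", gsub(" ", "_", seqs$species))
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read one ortholog-group alignment
#'
#' Reads an aligned FASTA (one ortholog group, gap character '-') and maps
#' its records onto the fixed species panel. Species in the panel without a
#' record are recorded as absent, as happens for real groups (e.g. a group
#' covering 8 of the 10 species).
#'
#' @param path Aligned FASTA path.
#' @param group_id Identifier for the group; defaults to the file stem.
#' @param panel Species panel (see [species_panel()]).
#' @inheritParams read_fasta
#' @return An `ortholog_group` object: list with `group_id`, `panel`,
#'   `ids` and `aligned` (named by species), `width`.
#' @export
read_alignment <- function(path, group_id = NULL, panel = species_panel(),
                           species_regex = "^[^|]*\\|(.+)$") {
  seqs <- read_fasta(path, species_regex)
  if (is.null(group_id))
    group_id <- sub("\\.[^.]*$", "", basename(path))
  ortholog_group(group_id, seqs, panel)
}

#' Construct an ortholog group from parsed sequences
#'
#' @param group_id Group identifier.
#' @param seqs data.frame (`id`, `species`, `residues`), aligned residues.
#' @param panel Species panel.
#' @return An `ortholog_group` object.
#' @export
ortholog_group <- function(group_id, seqs, panel = species_panel()) {
  if (any(duplicated(seqs$species)))
    stop("duplicate species in group '", group_id, "': ",
         paste(seqs$species[duplicated(seqs$species)], collapse = ", "))
  unknown <- setdiff(seqs$species, panel)
  if (length(unknown) > 0L)
    stop("species not in panel: ", paste(unknown, collapse = ", "))
  w <- unique(nchar(seqs$residues))
  if (length(w) != 1L)
    stop("ragged alignment in group '", group_id,
         "': record lengths ", paste(sort(w), collapse = ", "))
  aligned <- stats::setNames(seqs$residues, seqs$species)
  ids <- stats::setNames(seqs$id, seqs$species)
  structure(list(group_id = group_id, panel = panel,
                 aligned = aligned, ids = ids, width = w),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat("ortholog_group '", x$group_id, "': ", length(x$aligned),
      " of ", length(x$panel), " species, ", x$width, " columns\n", sep = "")
  invisible(x)
}

#' Species present in an ortholog group
#' @param group An `ortholog_group`.
#' @return Character vector in panel order.
#' @export
group_species <- function(group) {
  intersect(group$panel, names(group$aligned))
}

#' Gap-aware coordinate map for one aligned sequence
#'
#' Maps 1-based gap-free sequence positions to 1-based alignment columns
#' and back; exactly the non-gap columns are covered.
#'
#' @param aligned A single aligned residue string (gap character '-').
#' @return A `coordinate_map`: list with `seq_to_col` (integer vector,
#'   index = sequence position) and `col_to_seq` (integer vector over
#'   columns, NA at gaps).
#' @export
build_coordinate_map <- function(aligned) {
  stopifnot(is.character(aligned), length(aligned) == 1L)
  chars <- strsplit(aligned, "", fixed = TRUE)[[1L]]
  nongap <- chars != "-"
  if (!any(nongap)) stop("all-gap sequence has no coordinate map")
  seq_to_col <- which(nongap)
  col_to_seq <- rep(NA_integer_, length(chars))
  col_to_seq[nongap] <- seq_along(seq_to_col)
  structure(list(seq_to_col = seq_to_col, col_to_seq = col_to_seq,
                 seq_length = length(seq_to_col), n_col = length(chars)),
            class = "coordinate_map")
}

#' Translate a sequence interval into alignment columns
#'
#' Interior gap columns are spanned, so the result is a single contiguous
#' column interval whose endpoints are non-gap columns.
#'
#' @param map A `coordinate_map`.
#' @param start,end 1-based inclusive sequence positions.
#' @return Integer vector `c(start, end)` in alignment columns.
#' @export
map_interval_to_alignment <- function(map, start, end) {
  stopifnot(inherits(map, "coordinate_map"))
  if (start < 1L || end > map$seq_length || start > end)
    stop("interval [", start, ",", end, "] out of range for sequence of length ",
         map$seq_length)
  c(map$seq_to_col[start], map$seq_to_col[end])
}

#' Read externally computed feature annotations
#'
#' Tab-separated file with columns `seq_id`, `kind`, `start`, `end`
#' (1-based inclusive), e.g. coiled-coil ranges taken from a sequence
#' database. A header line is optional and detected by the column names.
#'
#' @param path TSV path.
#' @return Feature data.frame (`seq_id`, `kind`, `start`, `end`, `score`).
#' @export
read_feature_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(empty_features())
  first <- readLines(path, n = 1L)
  has_header <- grepl("seq_id", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("seq_id", "kind", "start", "end")[seq_len(ncol(df))]
  .check_kind(df$kind)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end) || any(df$start < 1L))
    stop("invalid interval(s) in ", path)
  df$score <- if (is.null(df$score)) NA_real_ else as.numeric(df$score)
  df[, c("seq_id", "kind", "start", "end", "score")]
}

#' An empty per-sequence feature table
#' @return Zero-row feature data.frame.
#' @export
empty_features <- function() {
  data.frame(seq_id = character(), kind = character(),
             start = integer(), end = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a feature table as deterministic, sorted TSV
#'
#' Rows are sorted by (group if present, seq_id, kind, start) so repeated
#' runs are byte-identical. Consolidated tables (with a `profile` column)
#' round-trip through [read_consolidated_table()].
#'
#' @param features Feature data.frame.
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  keys <- intersect(c("group", "seq_id", "kind", "start"), names(features))
  ord <- do.call(order, features[keys])
  utils::write.table(features[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consolidated feature table (group, kind, start, end, profile)
#' @param path TSV path written by [write_feature_table()].
#' @return Consolidated feature data.frame.
#' @export
read_consolidated_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(group = "character",
                                         kind = "character",
                                         profile = "character"),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("group", "kind", "start", "end", "profile") %in% names(df)))
  df
}
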