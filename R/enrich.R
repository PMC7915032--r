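#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` from a
#' population of `N` of which `K` carry the feature. Computed via the
#' log-space-stable distribution function, so extreme tails (p ~ 1e-300)
#' are exact to double precision.
#'
#' @param k Observed feature-positive draws.
#' @param n Number of draws (foreground size).
#' @param K Feature-positive population members.
#' @param N Population size.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("impossible hypergeometric counts (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' One-sided enrichment of a feature in a foreground set
#'
#' One-sided Fisher exact test on the 2x2 table
#' `[k, n - k; K - k, N - K]`: the background feature count `K` is taken
#' over the whole proteome (so it includes the foreground's hits, which
#' are subtracted from the background column), while the background total
#' `N` is left as the proteome size. Equivalently, the reported value is
#' `P(X >= k)` for `X ~ Hypergeometric(N + n - k, K, n)`. This is the
#' tabulation convention under which the package's reference statistics
#' were validated (see the methods vignette).
#'
#' @param k_fore Foreground proteins carrying the feature.
#' @param n_fore Foreground size.
#' @param K_bg Proteome-wide count of proteins carrying the feature.
#' @param N_bg Proteome size.
#' @return Upper-tail p-value.
#' @export
enrichment_pvalue <- function(k_fore, n_fore, K_bg, N_bg) {
  if (k_fore > K_bg)
    stop("foreground feature count exceeds the proteome-wide count")
  hypergeom_upper_tail(k_fore, n_fore, K_bg, N_bg + n_fore - k_fore)
}

#' Enrichment of every feature kind in a foreground versus a background
#'
#' Presence is at the protein level (a protein counts once however many
#' features of the kind it has). Raw p-values are reported; a
#' Benjamini-Hochberg column is appended for convenience but the raw
#' values are the primary output.
#'
#' @param fore_presence Logical/0-1 matrix, rows = feature kinds, columns
#'   = foreground proteins (e.g. the human columns of a presence matrix),
#'   or a data.frame with columns `kind`, `k_fore`.
#' @param bg_presence data.frame with columns `kind`, `K_bg` (proteome-wide
#'   protein counts per kind).
#' @param n_fore Foreground size; default: number of columns of
#'   `fore_presence`.
#' @param N_bg Background proteome size.
#' @return data.frame (`kind`, `k_fore`, `n_fore`, `K_bg`, `N_bg`,
#'   `p_value`, `p_adjust`).
#' @export
enrich_feature_kinds <- function(fore_presence, bg_presence, N_bg,
                                 n_fore = NULL) {
  if (is.matrix(fore_presence)) {
    if (is.null(n_fore)) n_fore <- ncol(fore_presence)
    k <- data.frame(kind = rownames(fore_presence),
                    k_fore = as.integer(rowSums(fore_presence > 0)),
                    stringsAsFactors = FALSE)
  } else {
    k <- fore_presence
    if (is.null(n_fore)) stop("n_fore is required with a count data.frame")
  }
  merged <- merge(k, bg_presence, by = "kind", all.x = TRUE)
  if (anyNA(merged$K_bg))
    stop("background counts missing for kind(s): ",
         paste(merged$kind[is.na(merged$K_bg)], collapse = ", "))
  if (any(merged$k_fore > merged$K_bg) || n_fore > N_bg + n_fore)
    stop("foreground is not consistent with the background table")
  merged$n_fore <- n_fore
  merged$N_bg <- N_bg
  merged$p_value <- mapply(enrichment_pvalue, merged$k_fore, n_fore,
                           merged$K_bg, N_bg)
  merged$p_adjust <- stats::p.adjust(merged$p_value, method = "BH")
  merged <- merged[order(merged$p_value, merged$kind), , drop = FALSE]
  rownames(merged) <- NULL
  merged[, c("kind", "k_fore", "n_fore", "K_bg", "N_bg", "p_value", "p_adjust")]
}

#' Enrichment of annotated domain sets (e.g. WW, SH3)
#'
#' Same exact test as [enrich_feature_kinds()], with explicitly supplied
#' contingency counts labeled by domain.
#'
#' @param domains data.frame with columns `domain`, `k_fore`, `n_fore`,
#'   `K_bg`, `N_bg`.
#' @return The input with a `p_value` column appended.
#' @export
enrich_domain_sets <- function(domains) {
  stopifnot(all(c("domain", "k_fore", "n_fore", "K_bg", "N_bg") %in%
                names(domains)))
  domains$p_value <- mapply(enrichment_pvalue, domains$k_fore,
                            domains$n_fore, domains$K_bg, domains$N_bg)
  domains
}

#' Read a background presence table
#'
#' TSV with columns `protein_id`, `kind`, `present` (0/1); returns
#' proteome-wide protein counts per kind.
#'
#' @param path TSV path.
#' @return data.frame (`kind`, `K_bg`).
#' @export
read_background_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "kind", "present") %in% names(df)))
  df <- df[df$present > 0, , drop = FALSE]
  agg <- stats::aggregate(list(K_bg = df$protein_id), by = list(kind = df$kind),
                          FUN = function(x) length(unique(x)))
  agg
}
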