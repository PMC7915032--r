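# Independent brute-force oracles used by the property tests. These are
# written naively (explicit loops, direct definitions) on purpose so that
# they share no code path with the implementations they check.

# every window of length w with >= k copies of x, as union of positions,
# split into runs, trimmed to the first/last x
oracle_polyx <- function(seq, k = 8L, w = 10L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < k) return(empty_features())
  w <- min(w, n)
  rows <- list()
  for (x in unique(chars)) {
    if (!x %in% LETTERS) next
    covered <- rep(FALSE, n)
    for (s in 1:(n - w + 1)) {
      win <- s:(s + w - 1)
      if (sum(chars[win] == x) >= k) covered[win] <- TRUE
    }
    if (!any(covered)) next
    i <- 1
    while (i <= n) {
      if (covered[i]) {
        j <- i
        while (j < n && covered[j + 1]) j <- j + 1
        xs <- which(chars[i:j] == x) + i - 1
        rows[[length(rows) + 1]] <- data.frame(
          kind = paste0("polyX:", x), start = min(xs), end = max(xs),
          stringsAsFactors = FALSE)
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (!length(rows)) return(empty_features())
  out <- do.call(rbind, rows)
  out[order(out$start, out$kind), , drop = FALSE]
}

# maximum-scoring substring against a homopolymer, by trying all O(n^2)
# substrings
oracle_max_segment <- function(seq, residue, mat) {
  chars <- strsplit(seq, "")[[1]]
  sc <- unname(mat[chars, residue])
  best <- 0; iv <- NULL
  for (i in seq_along(sc)) {
    tot <- 0
    for (j in i:length(sc)) {
      tot <- tot + sc[j]
      if (tot > best) { best <- tot; iv <- c(i, j) }
    }
  }
  if (is.null(iv)) return(NULL)
  list(score = best, start = iv[1], end = iv[2])
}

# thresholded runs of minimum length, by direct position-set splitting
oracle_idr_runs <- function(scores, thr, minlen) {
  pos <- which(scores >= thr)
  if (!length(pos)) return(matrix(integer(), ncol = 2))
  splits <- split(pos, cumsum(c(1, diff(pos) != 1)))
  runs <- do.call(rbind, lapply(splits, range))
  runs[runs[, 2] - runs[, 1] + 1 >= minlen, , drop = FALSE]
}

# exact hypergeometric upper tail through Python's rational arithmetic
oracle_hyper_exact <- function(k, n, K, N) {
  code <- sprintf(paste0(
    "from fractions import Fraction\nfrom math import comb\n",
    "k,n,K,N=%d,%d,%d,%d\n",
    "p=sum(Fraction(comb(K,i)*comb(N-K,n-i),comb(N,n)) ",
    "for i in range(k,min(n,K)+1))\n",
    "print(float(p))"), k, n, K, N)
  as.numeric(system2("python", c("-c", shQuote(code)), stdout = TRUE))
}

random_seq <- function(n, alphabet = c("A", "P", "Q", "S", "G"),
                       prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# small hand-made ortholog group from aligned strings named by species
toy_group <- function(aligned, id = "g1") {
  seqs <- data.frame(id = paste0(id, "_", gsub(" ", "_", names(aligned))),
                     species = names(aligned),
                     residues = unname(unlist(aligned)),
                     stringsAsFactors = FALSE)
  ortholog_group(id, seqs)
}
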