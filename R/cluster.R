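# Read clustering: the naive unique-read reduction and a greedy MinHash
# (locality-sensitive hashing) clusterer.

#' Consensus set
#'
#' Consensus sequences padded or trimmed to the design length `L` (several
#' codec decoders require inputs of exactly the designed length), with
#' their cluster sizes.
#'
#' @param sequences Character vector of consensus sequences.
#' @param sizes Total read multiplicity per consensus.
#' @param L Design length; sequences are padded (with `A`) or trimmed.
#' @return A `consensus_set` object.
#' @export
consensus_set <- function(sequences, sizes = rep(1L, length(sequences)),
                          L) {
  stopifnot(length(sequences) == length(sizes), L >= 1)
  sequences <- pad_or_trim(sequences, L)
  structure(list(sequences = sequences, sizes = as.integer(sizes),
                 L = as.integer(L)),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> %d sequences x %d nt\n",
              length(x$sequences), x$L))
  invisible(x)
}

pad_or_trim <- function(seqs, L, pad_base = "A") {
  short <- nchar(seqs) < L
  seqs[short] <- paste0(seqs[short],
                        strrep(pad_base, L - nchar(seqs[short])))
  substr(seqs, 1L, L)
}

# collapse identical reads; descending abundance, ties lexicographic
collapse_reads <- function(readset) {
  ex <- expand_reads(readset)
  tab <- table(ex$sequences)
  ord <- order(-as.integer(tab), names(tab))
  list(sequences = names(tab)[ord], abundance = as.integer(tab)[ord])
}

#' Naive clustering: unique reads by abundance
#'
#' The consensus set is simply the distinct read sequences sorted by
#' descending multiplicity (ties broken lexicographically), each padded
#' or trimmed to the design length.  No alignment is performed; the
#' output is invariant under read permutation.
#'
#' @param readset A [read_set()].
#' @param L Design length in nt.
#' @return A [consensus_set()].
#' @export
#' @examples
#' rs <- read_set(c("AAAA", "AAAA", "AAAA", "AAAT"))
#' naive_cluster(rs, L = 4)$sequences
naive_cluster <- function(readset, L) {
  stopifnot(inherits(readset, "read_set"))
  if (length(readset$sequences) == 0L) stop("empty read set")
  u <- collapse_reads(readset)
  consensus_set(u$sequences, u$abundance, L = L)
}

#' Greedy MinHash (LSH) clustering
#'
#' Each read's MinHash signature (`h` independent hash functions over its
#' k-mer set) is compared against the signatures of existing cluster
#' representatives; the read joins the first cluster (in founding order)
#' whose estimated Jaccard similarity (fraction of agreeing signature
#' components) reaches `tau`, else it founds a new cluster.  Reads are
#' processed in descending abundance, so representatives are the
#' heaviest reads.  Deterministic given `(seed, input)`.
#'
#' The defaults (`k = 6`, `h = 64`, `tau = 0.20`) were selected, in the
#' same spirit as picking clustering parameters that maximize
#' sensitivity/accuracy/specificity on simulated reads, from the Jaccard
#' arithmetic of noisy reads: an error destroys up to `k` k-mers *and*
#' creates up to `k` novel ones, so the Jaccard similarity of two reads
#' at per-nt error rate `r` is roughly `q^2 / (2 - q^2)` with
#' `q = (1-r)^k`; small `k` and a low threshold keep same-origin reads
#' together up to several percent error, while random cross-origin reads
#' still share essentially no k-mers.
#'
#' @param readset A [read_set()].
#' @param k K-mer size (default 6; must be below the read length and at
#'   most 13).
#' @param h Number of hash functions (default 64).
#' @param tau Estimated-Jaccard joining threshold in `[0, 1]`
#'   (default 0.20).
#' @param seed Integer seed for the hash functions.
#' @return A list of clusters, each a list with `members` (sequences),
#'   `abundance`, `representative` and `size`.
#' @export
lsh_cluster <- function(readset, k = 6L, h = 64L, tau = 0.20, seed = 1L) {
  stopifnot(inherits(readset, "read_set"), h >= 1, tau >= 0, tau <= 1)
  u <- collapse_reads(readset)
  if (any(nchar(u$sequences) <= k)) {
    stop("k-mer size must be smaller than the shortest read")
  }
  if (k > 13L) stop("k-mer size above 13 exceeds hashing precision")
  n <- length(u$sequences)
  hp <- with_seed(derive_seed(seed, "lsh"), list(
    a = sample.int(67108863L, h),     # < 2^26, keeps products in double range
    b = sample.int(2147483647L, h) - 1L))
  p <- 2147483647
  sigs <- matrix(0, nrow = h, ncol = n)
  for (i in seq_len(n)) {
    km <- kmer_values(u$sequences[i], k)
    M <- t((km %o% hp$a + rep(hp$b, each = length(km))) %% p)  # h x n_kmer
    sigs[, i] <- M[cbind(seq_len(h),
                         max.col(-M, ties.method = "first"))]
  }
  rep_idx <- integer(0)                # founding read of each cluster
  assign_to <- integer(n)
  rep_sigs <- matrix(0, nrow = h, ncol = n)  # preallocated
  n_rep <- 0L
  for (i in seq_len(n)) {
    joined <- 0L
    if (n_rep) {
      agree <- colSums(rep_sigs[, seq_len(n_rep), drop = FALSE] ==
                         sigs[, i]) / h
      hits <- which(agree >= tau)
      if (length(hits)) joined <- hits[1L]
    }
    if (joined == 0L) {
      n_rep <- n_rep + 1L
      rep_idx[n_rep] <- i
      rep_sigs[, n_rep] <- sigs[, i]
      joined <- n_rep
    }
    assign_to[i] <- joined
  }
  lapply(seq_along(rep_idx), function(cid) {
    m <- which(assign_to == cid)
    list(members = u$sequences[m], abundance = u$abundance[m],
         representative = u$sequences[rep_idx[cid]],
         size = sum(u$abundance[m]))
  })
}

# integer encodings of all k-mers of a sequence (A=0,C=1,G=2,T=3)
kmer_values <- function(seq, k) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  n <- length(codes) - k + 1L
  v <- numeric(n)
  for (j in seq_len(k)) {
    v <- v * 4 + codes[j:(j + n - 1L)]
  }
  unique(v)
}
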