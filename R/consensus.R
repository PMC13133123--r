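# Per-cluster consensus calling: star alignment of members against the
# cluster's heaviest read, followed by an abundance-weighted per-column
# plurality vote (including gaps).

#' Call the consensus sequence of a cluster
#'
#' Members are aligned to the cluster's highest-abundance member by exact
#' edit-distance alignment; votes (weighted by read abundance) are
#' accumulated per representative column and per insertion slot.
#' Gap-majority columns are deleted.  Ties are broken by the fixed base
#' order `A < C < G < T`, and non-gap beats gap on a tie.  The result is
#' padded or trimmed to the design length.
#'
#' @param cluster A cluster as returned by [lsh_cluster()] (list with
#'   `members`, `abundance`), or a character vector of member reads.
#' @param L Design length in nt.
#' @param abundance Multiplicities when `cluster` is a character vector.
#' @return A single consensus DNA string of length `L`.
#' @export
#' @examples
#' call_consensus(c("ACGTAC", "ACGTAC", "ACTTAC"), L = 6)
call_consensus <- function(cluster, L, abundance = NULL) {
  if (is.character(cluster)) {
    cluster <- list(members = cluster,
                    abundance = abundance %||% rep(1L, length(cluster)))
  }
  members <- cluster$members
  ab <- cluster$abundance
  stopifnot(length(members) >= 1L, length(ab) == length(members))
  if (length(members) == 1L) return(pad_or_trim(members, L))
  rep_seq <- members[order(-ab, members)[1L]]
  nrep <- nchar(rep_seq)
  # votes over representative columns: rows A,C,G,T,gap
  votes <- matrix(0, nrow = 5L, ncol = nrep)
  ins_votes <- new.env(parent = emptyenv())   # "col_offset" -> base votes
  total_w <- sum(ab)
  al <- adist(rep_seq, members, counts = TRUE)
  trafos <- attr(al, "trafos")
  for (mi in seq_along(members)) {
    w <- ab[mi]
    ops <- strsplit(trafos[1L, mi], "", fixed = TRUE)[[1L]]
    mem <- strsplit(members[mi], "", fixed = TRUE)[[1L]]
    i <- 0L  # rep position consumed
    j <- 0L  # member position consumed
    off <- 0L
    for (op in ops) {
      if (op == "M" || op == "S") {
        i <- i + 1L; j <- j + 1L; off <- 0L
        b <- match(mem[j], DNA_BASES)
        votes[b, i] <- votes[b, i] + w
      } else if (op == "D") {          # rep char absent from member
        i <- i + 1L; off <- 0L
        votes[5L, i] <- votes[5L, i] + w
      } else {                         # "I": member char absent from rep
        j <- j + 1L; off <- off + 1L
        key <- paste0(i, "_", off)
        cur <- if (is.null(ins_votes[[key]])) numeric(4) else ins_votes[[key]]
        b <- match(mem[j], DNA_BASES)
        cur[b] <- cur[b] + w
        ins_votes[[key]] <- cur
      }
    }
  }
  out <- character(0)
  emit_insertions <- function(col) {
    res <- character(0)
    off <- 1L
    repeat {
      key <- paste0(col, "_", off)
      v <- ins_votes[[key]]
      if (is.null(v)) break
      # reads not inserting here implicitly vote gap
      gap_w <- total_w - sum(v)
      best <- which.max(v)             # ties -> lowest index = base order
      if (v[best] > gap_w || (v[best] == gap_w && v[best] > 0)) {
        res <- c(res, DNA_BASES[best])
      }
      off <- off + 1L
    }
    res
  }
  for (col in seq_len(nrep)) {
    out <- c(out, emit_insertions(col - 1L))
    v <- votes[, col]
    best_base <- which.max(v[1:4])
    if (v[best_base] >= v[5L]) {       # non-gap beats gap on a tie
      out <- c(out, DNA_BASES[best_base])
    }
  }
  out <- c(out, emit_insertions(nrep))
  pad_or_trim(paste(out, collapse = ""), L)
}

#' Reduce a clustering to a consensus set
#'
#' Applies [call_consensus()] to every cluster and orders consensus
#' sequences by descending cluster size.
#'
#' @param clusters List of clusters from [lsh_cluster()].
#' @param L Design length in nt.
#' @return A [consensus_set()].
#' @export
consensus_from_clusters <- function(clusters, L) {
  stopifnot(length(clusters) >= 1L)
  seqs <- vapply(clusters, call_consensus, character(1), L = L)
  sizes <- vapply(clusters, function(cl) sum(cl$abundance), numeric(1))
  ord <- order(-sizes, seqs)
  consensus_set(seqs[ord], sizes[ord], L = L)
}
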