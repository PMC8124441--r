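# Independent brute-force oracles used to validate the fast paths.
# These deliberately re-derive results by the dumbest correct method.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Plain-R Gotoh local alignment: best score only. A gap run of length L
# costs gap_open + L * gap_extend (both negative).
sw_oracle_score <- function(a, b, match = 2, mismatch = -2, gap_open = -5,
                            gap_extend = -2) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0 || m == 0) return(0)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (move along b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (move along a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Dumb six-frame ORF enumerator: for every codon start, if it is a start
# codon, walk to the first in-frame stop; keep the longest ORF per stop.
orf_oracle <- function(seq_id, residues, min_len = 30,
                       start_codons = c("ATG", "GTG", "TTG")) {
  stops <- c("TGA", "TAA", "TAG")
  rows <- list()
  L <- nchar(residues)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") residues else
      selnest::reverse_complement(residues)
    for (i in seq_len(L - 5)) {
      if (!(substr(s, i, i + 2) %in% start_codons)) next
      j <- i
      stop_at <- NA
      while (j + 2 <= L) {
        if (substr(s, j, j + 2) %in% stops) { stop_at <- j; break }
        j <- j + 3
      }
      if (is.na(stop_at)) next
      len <- stop_at + 3 - i
      if (len < min_len) next
      loc <- c(i - 1, stop_at + 2)
      g <- if (strand == "+") loc else c(L - loc[2], L - loc[1])
      rows[[length(rows) + 1]] <- data.frame(
        strand = strand, start = g[1], end = g[2], loc_start = loc[1],
        loc_stop = stop_at - 1)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(), start = integer(),
                      end = integer()))
  }
  df <- do.call(rbind, rows)
  # keep only the most upstream start per (strand, stop)
  df <- df[order(df$strand, df$loc_start), ]
  df <- df[!duplicated(df[, c("strand", "loc_stop")]), ]
  df[order(df$strand, df$start, df$end), c("strand", "start", "end")]
}

# Brute-force sigma-70 box-pair scan over all placements.
promoter_oracle_count <- function(s, spacer_range = 15:19, max_mismatch = 4) {
  n <- nchar(s)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  count <- 0
  if (n < 12) return(0)
  for (i in 1:(n - 5)) {
    for (j in 1:(n - 5)) {
      sp <- j - i - 6
      if (!(sp %in% spacer_range)) next
      mm <- ham(substr(s, i, i + 5), "TTGACA") +
        ham(substr(s, j, j + 5), "TATAAT")
      if (mm <= max_mismatch) count <- count + 1
    }
  }
  count
}

# small convenience: one-row ORF tibble
orf_row <- function(start, end, seq_id = "s", strand = "+") {
  tibble::tibble(seq_id = seq_id, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}
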