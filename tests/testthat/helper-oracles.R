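# Independent oracles used across test files.

# per-base bitmap coverage oracle for interval merging
bitmap_total <- function(starts, ends, L) {
  hit <- logical(L)
  for (i in seq_along(starts)) {
    idx <- seq.int(starts[i] + 1L, ends[i])
    idx <- ((idx - 1L) %% L) + 1L  # wrap for circular coordinates
    hit[idx] <- TRUE
  }
  sum(hit)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# exhaustive-pathway NG86 difference oracle: enumerates position orderings
# explicitly and translates with the standard code
path_oracle <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  dpos <- which(p1 != p2)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  perms <- combinat_perms(dpos)
  rows <- list(); valid <- logical(0)
  for (ord in perms) {
    cur <- p1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- p2[pos]
      if (code[[paste(nxt, collapse = "")]] == "*") ok <- FALSE
      if (code[[paste(cur, collapse = "")]] == code[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    rows[[length(rows) + 1L]] <- c(sd, nd)
    valid <- c(valid, ok)
  }
  m <- do.call(rbind, rows)
  use <- if (any(valid)) valid else rep(TRUE, length(valid))
  c(sd = mean(m[use, 1]), nd = mean(m[use, 2]))
}

combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
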