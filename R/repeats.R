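# Dispersed-repeat discovery by seed-and-extend self-alignment, size/age
# classification and per-genome summaries.

#' Scan parameters for the seed-and-extend aligner
#'
#' Defaults follow the classic blastn small-word configuration: word size 7,
#' E-value cutoff 1e-6, match +2 / mismatch -3, affine gaps (open 5, extend
#' 2, so a length-k gap costs 5 + 2k), x-drop 20. Seeds falling in windows of
#' dinucleotide Shannon entropy below 1 bit (window 12 bp) are skipped, an
#' analogue of DUST that keeps homopolymer and microsatellite runs from
#' flooding the self-scan. `eps_recent` operationalises a "~0" K2P distance
#' for the recent age class.
#'
#' @param word_size exact-match seed length (bp).
#' @param reward,penalty match/mismatch scores.
#' @param gap_open,gap_extend affine gap costs (positive).
#' @param xdrop extension stops when the running score drops this far below
#'   the running best.
#' @param gap_trigger gapped extension runs only when the ungapped x-drop
#'   extension of a seed reaches this score (two-stage extension as in
#'   blastn); seeds below the trigger cannot reach the E-value cutoff at the
#'   genome sizes this scanner targets.
#' @param max_evalue Karlin-Altschul E-value cutoff for reported hits.
#' @param lowcomp_window,min_entropy low-complexity seed guard (bp window,
#'   bits).
#' @param eps_recent K2P threshold of the recent age class.
#' @return Named list of parameters.
#' @export
scanParams <- function(word_size = 7L, reward = 2L, penalty = -3L,
                       gap_open = 5L, gap_extend = 2L, xdrop = 20L,
                       max_evalue = 1e-6, gap_trigger = 25L,
                       lowcomp_window = 12L, min_entropy = 1.0,
                       eps_recent = 0.005) {
  stopifnot(word_size >= 4L, word_size <= 12L, reward > 0, penalty < 0,
            gap_open >= 0, gap_extend > 0, xdrop > 0, max_evalue > 0)
  list(word_size = as.integer(word_size), reward = as.integer(reward),
       penalty = as.integer(penalty), gap_open = as.integer(gap_open),
       gap_extend = as.integer(gap_extend), xdrop = as.integer(xdrop),
       max_evalue = max_evalue, gap_trigger = as.integer(gap_trigger),
       lowcomp_window = as.integer(lowcomp_window),
       min_entropy = min_entropy, eps_recent = eps_recent)
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.aln_identity <- function(aq, as_) {
  a <- strsplit(aq, "", fixed = TRUE)[[1]]
  b <- strsplit(as_, "", fixed = TRUE)[[1]]
  sum(a == b & a != "-" & a != "N") / length(a)
}

#' Kimura 2-parameter distance of an aligned pair
#'
#' With P the transition and Q the transversion fraction over the ungapped
#' alignment columns,
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' Gap columns are excluded entirely (the distance is defined on
#' substitutions only), as are columns containing `N`. When the arguments of
#' either logarithm are non-positive the distance is saturated and `Inf` is
#' returned; saturated values are excluded from density summaries.
#'
#' @param aligned_q,aligned_s equal-length gapped strings over
#'   \{A,C,G,T,N,-\}; at least one ungapped column required.
#' @return Non-negative distance, or `Inf` when saturated.
#' @examples
#' k2pDistance("ACGT", "ACGT")  # 0
#' @export
k2pDistance <- function(aligned_q, aligned_s) {
  if (nchar(aligned_q) != nchar(aligned_s))
    stop("aligned strings must have equal length")
  a <- strsplit(toupper(aligned_q), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_s), "", fixed = TRUE)[[1]]
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  n <- sum(keep)
  if (n == 0L) stop("no ungapped columns in alignment")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  transition <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                        (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Size class of a repeat
#'
#' Small (< 100 bp), medium (100-1,000 bp), large (>= 1,000 bp); a length of
#' exactly 1,000 bp is large.
#'
#' @param length repeat length(s) in bp.
#' @return Character vector over \{"small","medium","large"\}.
#' @export
classifySize <- function(length) {
  ifelse(length < 100, "small", ifelse(length < 1000, "medium", "large"))
}

#' Age class of a repeat pair from its K2P distance
#'
#' Distances of ~0 (at most `eps_recent`) are recent duplications, distances
#' below 0.2 intermediate events, and 0.2 or more ancient insertions.
#'
#' @param k2p finite non-negative K2P distance(s).
#' @param eps_recent the operational "~0" threshold (default 0.005, at most
#'   one substitution per 200 sites).
#' @return Character vector over \{"recent","intermediate","ancient"\}.
#' @export
classifyAge <- function(k2p, eps_recent = 0.005) {
  ifelse(k2p <= eps_recent, "recent", ifelse(k2p < 0.2, "intermediate", "ancient"))
}

#' Gapped x-drop extension of one exact seed
#'
#' Extends an exact `word_size`-mer match at two loci in both directions with
#' affine-gap dynamic programming, stopping when the running score drops more
#' than `xdrop` below the maximum. Always returns a hit containing at least
#' the seed (a seed with immediately non-matching flanks yields a
#' `word_size`-bp hit scoring `word_size * reward`).
#'
#' @param qseq,sseq character sequences (or `GenomeSeq`) containing the two
#'   loci.
#' @param qpos,spos 0-based seed start positions.
#' @param params [scanParams()].
#' @return List with `q_start`, `q_end`, `s_start`, `s_end` (0-based
#'   half-open), `score`, `identity`, `aligned_q`, `aligned_s`.
#' @export
extendSeed <- function(qseq, sseq, qpos, spos, params = scanParams()) {
  if (is(qseq, "GenomeSeq")) qseq <- as.character(genomeSeq(qseq))
  if (is(sseq, "GenomeSeq")) sseq <- as.character(genomeSeq(sseq))
  h <- .Call_extend_seed(qseq, sseq, as.integer(qpos), as.integer(spos),
                         params$word_size, params$reward, params$penalty,
                         params$gap_open, params$gap_extend, params$xdrop)
  h$identity <- .aln_identity(h$aligned_q, h$aligned_s)
  h
}

# Run the C++ scanner over both strand orientations. `self` turns on the
# self-comparison constraints (trivial diagonal excluded, mirrors collapsed).
# Sequences arrive already origin-padded when circular. Returns raw hits with
# s-side coordinates mapped back to the forward strand.
.scan_both_strands <- function(qchr, schr, self, params, min_score) {
  plus <- .Call_scan_pair(qchr, if (self) qchr else schr,
                          self, FALSE,
                          params$word_size, params$reward, params$penalty,
                          params$gap_open, params$gap_extend, params$xdrop,
                          min_score, params$gap_trigger,
                          params$lowcomp_window, params$min_entropy)
  if (nrow(plus)) plus$strand <- "+"
  src <- if (self) qchr else schr
  minus <- .Call_scan_pair(qchr, .revcomp_chr(src),
                           FALSE, self,
                           params$word_size, params$reward, params$penalty,
                           params$gap_open, params$gap_extend, params$xdrop,
                           min_score, params$gap_trigger,
                           params$lowcomp_window, params$min_entropy)
  if (nrow(minus)) {
    slen <- nchar(src)
    ss <- slen - minus$s_end
    se <- slen - minus$s_start
    minus$s_start <- ss
    minus$s_end <- se
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  if (!nrow(out)) {
    out <- data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      score = integer(), aligned_q = character(),
                      aligned_s = character(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

# alignment score recomputed from gapped strings (used when a hit is split)
.aln_score <- function(aq, as_, params) {
  a <- strsplit(aq, "", fixed = TRUE)[[1]]
  b <- strsplit(as_, "", fixed = TRUE)[[1]]
  gap <- a == "-" | b == "-"
  match <- !gap & a == b & a != "N"
  score <- sum(match) * params$reward + sum(!gap & !match) * params$penalty
  runs <- rle(gap)
  glen <- runs$lengths[runs$values]
  score - sum(params$gap_open + params$gap_extend * glen)
}

# A reverse-strand self-hit whose two intervals coincide is a palindrome: the
# first half of the alignment pairs the left arm with the (reverse
# complemented) right arm. Re-anchor such hits to the two arms so an
# inverted repeat with a short spacer is reported as one proper pair.
.split_palindromic_hit <- function(row, params) {
  n <- nchar(row$aligned_q)
  half <- n %/% 2
  if (half < 1L) return(NULL)
  aq <- substr(row$aligned_q, 1L, half)
  as_ <- substr(row$aligned_s, 1L, half)
  cnt_q <- nchar(gsub("-", "", aq, fixed = TRUE))
  cnt_s <- nchar(gsub("-", "", as_, fixed = TRUE))
  if (cnt_q < 1L || cnt_s < 1L) return(NULL)
  row$q_end <- row$q_start + cnt_q
  row$s_start <- row$s_end - cnt_s
  row$aligned_q <- aq
  row$aligned_s <- as_
  row$score <- .aln_score(aq, as_, params)
  if (row$s_start < row$q_end) {  # arms must not overlap after the split
    trim <- row$q_end - row$s_start
    row$s_start <- row$s_start + trim
  }
  if (row$score <= 0 || row$s_end <= row$s_start) return(NULL)
  row
}

# canonical ordering for self-hits: query copy first; swapping a hit keeps
# the alignment readable by reverse-complementing both rows (minus strand)
# or simply exchanging them (plus strand)
.canonicalize_self_hits <- function(h, params) {
  if (!nrow(h)) return(h)
  swap <- (h$s_start < h$q_start) |
          (h$s_start == h$q_start & h$s_end < h$q_end)
  if (any(swap)) {
    qs <- h$q_start[swap]; qe <- h$q_end[swap]
    h$q_start[swap] <- h$s_start[swap]; h$q_end[swap] <- h$s_end[swap]
    h$s_start[swap] <- qs; h$s_end[swap] <- qe
    minus_swap <- swap & h$strand == "-"
    plus_swap <- swap & h$strand == "+"
    if (any(plus_swap)) {
      tmp <- h$aligned_q[plus_swap]
      h$aligned_q[plus_swap] <- h$aligned_s[plus_swap]
      h$aligned_s[plus_swap] <- tmp
    }
    if (any(minus_swap)) {
      rc <- function(x) vapply(x, function(s) {
        s <- chartr("ACGTN", "TGCAN", s)
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      }, "", USE.NAMES = FALSE)
      aq <- h$aligned_q[minus_swap]
      h$aligned_q[minus_swap] <- rc(h$aligned_s[minus_swap])
      h$aligned_s[minus_swap] <- rc(aq)
    }
  }
  # heavily self-overlapping hits are degenerate: on the plus strand they are
  # near-diagonal artifacts (seeds just off the main diagonal rebuilding the
  # trivial self-identity through cheap gaps) and are discarded; on the minus
  # strand they are palindromes (inverted repeats with a short spacer) and
  # are re-anchored to their two arms
  if (nrow(h)) {
    ov <- pmax(0, pmin(h$q_end, h$s_end) - pmax(h$q_start, h$s_start))
    shorter <- pmin(h$q_end - h$q_start, h$s_end - h$s_start)
    heavy <- ov > 0.5 * shorter
    pal <- heavy & h$strand == "-"
    keep <- h[!heavy, , drop = FALSE]
    if (any(pal)) {
      arms <- lapply(which(pal), function(i)
        .split_palindromic_hit(h[i, , drop = FALSE], params))
      arms <- do.call(rbind, arms[!vapply(arms, is.null, TRUE)])
      keep <- rbind(keep, arms)
    }
    h <- keep
  }
  identical_iv <- h$q_start == h$s_start & h$q_end == h$s_end
  h <- h[!identical_iv, , drop = FALSE]
  h[!duplicated(h[, c("q_start", "q_end", "s_start", "s_end", "strand")]), ,
    drop = FALSE]
}

# wrap padded-scan coordinates of a circular genome back into [0, L)
.wrap_coords <- function(h, L) {
  if (!nrow(h)) return(h)
  for (side in c("q", "s")) {
    st <- paste0(side, "_start"); en <- paste0(side, "_end")
    over <- h[[st]] >= L
    h[[st]][over] <- h[[st]][over] - L
    h[[en]][over] <- h[[en]][over] - L
  }
  h
}

#' Discover dispersed repeats by self-alignment
#'
#' Compares a genome against itself on both strands with exact
#' `word_size`-mer seeding and gapped x-drop extension, keeps hits whose
#' Karlin-Altschul E-value is at most `max_evalue`, excludes the trivial
#' full-length diagonal and any hit whose two intervals coincide, and
#' collapses mirror duplicates to one record with the query copy first.
#' Circular genomes are scanned with the first `word_size - 1` bases appended
#' so seeds spanning the origin are found; coordinates are reported modulo
#' the genome length (origin-spanning hits keep `end > length`).
#'
#' Each hit carries its alignment, score, identity, E-value, K2P distance
#' and size/age class.
#'
#' @param genome a [GenomeSeq-class].
#' @param params [scanParams()].
#' @return A [RepeatHits-class] object.
#' @seealso [summarizeRepeats()], [mergedRepetitiveBp()]
#' @export
findDispersedRepeats <- function(genome, params = scanParams()) {
  stopifnot(is(genome, "GenomeSeq"))
  L <- genomeLength(genome)
  empty <- data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), length = integer(),
                      score = integer(), identity = numeric(),
                      evalue = numeric(), k2p = numeric(),
                      size_class = character(), age_class = character(),
                      aligned_q = character(), aligned_s = character(),
                      stringsAsFactors = FALSE)
  kp <- karlinParams(params$reward, params$penalty)
  if (L < params$word_size) {
    warning(sprintf("genome '%s' (%d bp) is shorter than the word size; no scan",
                    genomeId(genome), L))
    return(methods::new("RepeatHits", genomeId = genomeId(genome),
                        genomeLength = L, circular = isCircular(genome),
                        hits = empty, params = c(params, kp)))
  }
  seqchr <- as.character(genomeSeq(genome))
  if (isCircular(genome))
    seqchr <- paste0(seqchr, substr(seqchr, 1L, params$word_size - 1L))
  min_score <- minScoreForEvalue(params$max_evalue, L, L, kp)
  h <- .scan_both_strands(seqchr, seqchr, self = TRUE, params, min_score)
  h <- .canonicalize_self_hits(h, params)
  if (isCircular(genome)) h <- .wrap_coords(h, L)
  if (nrow(h)) {
    h$evalue <- evalueOf(h$score, L, L, kp)
    h <- h[h$evalue <= params$max_evalue, , drop = FALSE]
  }
  if (nrow(h)) {
    h$identity <- mapply(.aln_identity, h$aligned_q, h$aligned_s, USE.NAMES = FALSE)
    h$k2p <- mapply(k2pDistance, h$aligned_q, h$aligned_s, USE.NAMES = FALSE)
    h$length <- pmin(h$q_end - h$q_start, h$s_end - h$s_start)
    h$size_class <- classifySize(h$length)
    h$age_class <- classifyAge(h$k2p, params$eps_recent)
    h <- h[order(h$q_start, h$q_end, h$s_start), , drop = FALSE]
    h <- h[, names(empty)]
    rownames(h) <- NULL
  } else {
    h <- empty
  }
  methods::new("RepeatHits", genomeId = genomeId(genome), genomeLength = L,
               circular = isCircular(genome), hits = h, params = c(params, kp))
}

#' Merged repetitive coverage of a genome
#'
#' Takes the union of the query- and subject-side intervals of all hits
#' jointly (strand ignored) so that overlapping repeat copies are counted
#' only once, and totals the covered bp.
#'
#' @param hits a [RepeatHits-class] object.
#' @return List with `intervals` (disjoint, sorted data.frame) and
#'   `total_bp` (at most the genome length).
#' @export
mergedRepetitiveBp <- function(hits) {
  stopifnot(is(hits, "RepeatHits"))
  h <- hitTable(hits)
  mergeIntervals(c(h$q_start, h$s_start), c(h$q_end, h$s_end),
                 hits@genomeLength, hits@circular)
}

.gc_fraction <- function(seqchr, starts, ends) {
  if (!length(starts)) return(NA_real_)
  pieces <- substring(seqchr, starts + 1L, ends)
  s <- paste(pieces, collapse = "")
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GC]", "", s))
  atgc <- nchar(gsub("[^ACGT]", "", s))
  if (atgc == 0L) return(NA_real_)
  gc / atgc
}

#' Summarize dispersed repeats on one genome
#'
#' Counts of repeat pairs per size class, merged repetitive bp and percent
#' of the genome, GC content per size class (over both copies of every
#' pair), and the K2P distance multiset per size class for density
#' reporting. Saturated (infinite) K2P values are excluded from the
#' multisets.
#'
#' @param genome the scanned [GenomeSeq-class].
#' @param hits [RepeatHits-class] from [findDispersedRepeats()] on this
#'   genome.
#' @return A [RepeatSummary-class] object.
#' @export
summarizeRepeats <- function(genome, hits) {
  stopifnot(is(genome, "GenomeSeq"), is(hits, "RepeatHits"))
  if (genomeId(genome) != hits@genomeId)
    stop("hits were computed on a different genome")
  h <- hitTable(hits)
  L <- genomeLength(genome)
  merged <- mergedRepetitiveBp(hits)
  seqchr <- as.character(genomeSeq(genome))
  if (isCircular(genome)) seqchr <- paste0(seqchr, seqchr)  # wrapped substrings
  classes <- c("small", "medium", "large")
  gc <- vapply(classes, function(cl) {
    sel <- h$size_class == cl
    .gc_fraction(seqchr, c(h$q_start[sel], h$s_start[sel]),
                 c(h$q_end[sel], h$s_end[sel]))
  }, 1.0)
  k2p <- lapply(classes, function(cl) {
    v <- h$k2p[h$size_class == cl]
    v[is.finite(v)]
  })
  names(k2p) <- classes
  np <- c(total = nrow(h), small = sum(h$size_class == "small"),
          medium = sum(h$size_class == "medium"),
          large = sum(h$size_class == "large"))
  methods::new("RepeatSummary", genomeId = genomeId(genome),
               genomeLength = L,
               totalRepetitiveBp = as.integer(merged$total_bp),
               pctGenome = 100 * merged$total_bp / L,
               nPairs = as.integer(np) |> stats::setNames(names(np)),
               gcByClass = gc, k2pByClass = k2p)
}
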