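# Seeded synthetic-data generators. Every generator takes a mandatory seed
# and is a pure function of its arguments (R's RNG is seeded on entry), so
# the whole pipeline is testable with no external data. Truth tables carry
# enough ground truth to score every downstream stage.

.BASES <- c("A", "C", "G", "T")

#' Generate a random genome
#'
#' I.i.d. bases with the stated GC content.
#'
#' @param length genome length in bp (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed (mandatory; generators have no silent
#'   nondeterminism).
#' @param id record id.
#' @param circular topology flag.
#' @return A [GenomeSeq-class].
#' @export
genGenome <- function(length, gc = 0.5, seed, id = "synthetic_genome",
                      circular = FALSE) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- paste(sample(.BASES, length, replace = TRUE, prob = p), collapse = "")
  GenomeSeq(id, seq, circular = circular)
}

# transition/transversion probabilities of the Kimura 2-parameter process at
# divergence d with ts/tv rate ratio kappa: with beta*t = d/(kappa+2) and
# alpha*t = d*kappa/(kappa+2),
#   Q = (1 - exp(-4 beta t)) / 2
#   P = (1 + exp(-4 beta t) - 2 exp(-2 (alpha+beta) t)) / 4
# so that the K2P distance estimator recovers exactly d in expectation.
.k2p_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- d * kappa / (kappa + 2)
  Q <- 0.5 * (1 - exp(-4 * bt))
  P <- 0.25 * (1 + exp(-4 * bt) - 2 * exp(-2 * (at + bt)))
  c(P = P, Q = Q)
}

.TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
.TV_MAP <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))

#' Mutate a sequence under the Kimura 2-parameter model
#'
#' Per-site substitutions at the exact transition/transversion probabilities
#' of the continuous-time K2P model at divergence `d`, so the expected K2P
#' distance between input and output is `d` (and distances are additive
#' along branches). Does not seed the RNG; callers seed.
#'
#' @param seq character sequence over \{A,C,G,T\}.
#' @param d target expected K2P distance (substitutions/site).
#' @param kappa transition/transversion rate ratio (alpha/beta).
#' @return List with `seq`, `n_ts`, `n_tv` (realized substitution counts).
#' @export
mutateSequenceK2P <- function(seq, d, kappa = 2) {
  stopifnot(d >= 0, kappa > 0)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  pq <- .k2p_probs(d, kappa)
  u <- stats::runif(length(chars))
  is_ts <- u < pq[["P"]]
  is_tv <- !is_ts & u < pq[["P"]] + pq[["Q"]]
  if (any(is_ts)) chars[is_ts] <- .TS_MAP[chars[is_ts]]
  if (any(is_tv)) {
    pick <- stats::runif(sum(is_tv)) < 0.5
    chars[is_tv] <- mapply(function(b, first) .TV_MAP[[b]][if (first) 1 else 2],
                           chars[is_tv], pick)
  }
  list(seq = paste(chars, collapse = ""), n_ts = sum(is_ts), n_tv = sum(is_tv))
}

# non-overlapping dense layout: the free space between blocks is partitioned
# by stick-breaking, so any total fraction up to 1 (exact tiling) is placeable
.layout_blocks <- function(L, lens) {
  n <- length(lens)
  free <- L - sum(lens)
  stopifnot(free >= 0)
  cuts <- sort(stats::runif(n, 0, free))
  gaps <- floor(c(cuts, free) - c(0, cuts))
  cumsum(c(0, lens[-n])) + cumsum(gaps[-length(gaps)])
}

# non-overlapping placement by rejection sampling
.place_blocks <- function(L, lens, retries = 1000L) {
  placed <- IRanges::IRanges()
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    ok <- FALSE
    for (try in seq_len(retries)) {
      s <- sample.int(L - lens[i] + 1L, 1L) - 1L
      cand <- IRanges::IRanges(start = s + 1L, width = lens[i])
      if (length(placed) == 0L ||
          !any(IRanges::overlapsAny(cand, placed))) {
        placed <- c(placed, cand)
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place feature ", i, " without overlap after ",
                  retries, " retries")
  }
  starts
}

.splice_in <- function(seqchr, start, piece) {
  paste0(substr(seqchr, 1L, start), piece,
         substr(seqchr, start + nchar(piece) + 1L, nchar(seqchr)))
}

#' Plant a dispersed-repeat family in a genome
#'
#' A random source segment is copied to `n_copies` non-overlapping random
#' loci (random strand unless given); each copy is independently mutated
#' under the K2P process at `target_k2p / 2` from the source, so the
#' expected pairwise K2P distance between copies is `target_k2p` (distances
#' are additive). The truth table records loci, strands and realized
#' substitution counts.
#'
#' @param genome background [GenomeSeq-class] (copies overwrite background
#'   sequence).
#' @param n_copies number of copies (>= 2 for a detectable family).
#' @param length copy length (bp); `n_copies * length` must be at most half
#'   the genome.
#' @param target_k2p expected pairwise K2P distance among copies.
#' @param kappa transition/transversion rate ratio.
#' @param seed RNG seed.
#' @param strands optional character vector over \{"+","-"\} per copy.
#' @return List with `genome` (modified [GenomeSeq-class]) and `truth`
#'   (data.frame: `copy`, `start`, `end`, `strand`, `n_ts`, `n_tv`).
#' @export
plantRepeatFamily <- function(genome, n_copies, length, target_k2p = 0,
                              kappa = 2, seed, strands = NULL) {
  stopifnot(is(genome, "GenomeSeq"), n_copies >= 1, length >= 1)
  L <- genomeLength(genome)
  if (n_copies * length > L / 2)
    stop("family too large for the genome (needs n_copies * length <= length/2)")
  set.seed(seed)
  if (is.null(strands)) strands <- sample(c("+", "-"), n_copies, replace = TRUE)
  stopifnot(length(strands) == n_copies, all(strands %in% c("+", "-")))
  source_seq <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
  starts <- .place_blocks(L, rep(length, n_copies))
  seqchr <- as.character(genomeSeq(genome))
  truth <- data.frame(copy = seq_len(n_copies), start = starts,
                      end = starts + length, strand = strands,
                      n_ts = 0L, n_tv = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n_copies)) {
    mut <- mutateSequenceK2P(source_seq, target_k2p / 2, kappa)
    piece <- mut$seq
    if (strands[i] == "-") piece <- .revcomp_chr(piece)
    seqchr <- .splice_in(seqchr, starts[i], piece)
    truth$n_ts[i] <- mut$n_ts
    truth$n_tv[i] <- mut$n_tv
  }
  list(genome = GenomeSeq(genomeId(genome), seqchr,
                          circular = isCircular(genome)),
       truth = truth)
}

#' Generate a genome pair sharing a target fraction of blocks
#'
#' Two genomes of equal length whose shared blocks total `fraction` of each
#' genome, with the copies in genome 2 mutated to the stated K2P divergence
#' relative to genome 1; the remainder of genome 2 is independently random.
#' The truth table records block coordinates on both genomes.
#'
#' @param base_length genome length (bp).
#' @param fraction shared fraction in `[0, 1]`.
#' @param divergence K2P divergence of the shared blocks.
#' @param seed RNG seed.
#' @param block_length length of each shared block (bp; the last block is
#'   trimmed so the planted total matches `fraction * base_length`).
#' @param kappa transition/transversion rate ratio.
#' @param ids ids of the two genomes.
#' @return List with `g1`, `g2` ([GenomeSeq-class]) and `truth` (data.frame:
#'   `block`, `start1`, `end1`, `start2`, `end2`, `length`).
#' @export
genSharedPair <- function(base_length, fraction, divergence = 0, seed,
                          block_length = 2000L, kappa = 2,
                          ids = c("sim_species1", "sim_species2")) {
  stopifnot(fraction >= 0, fraction <= 1, base_length > 0)
  set.seed(seed)
  g1chr <- paste(sample(.BASES, base_length, replace = TRUE), collapse = "")
  g2chr <- paste(sample(.BASES, base_length, replace = TRUE), collapse = "")
  total <- round(fraction * base_length)
  truth <- data.frame(block = integer(), start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(), length = integer())
  if (total > 0) {
    lens <- rep(block_length, total %/% block_length)
    if (total %% block_length > 0) lens <- c(lens, total %% block_length)
    lens <- lens[lens > 0]
    starts1 <- .layout_blocks(base_length, lens)
    starts2 <- .layout_blocks(base_length, lens)
    for (i in seq_along(lens)) {
      block <- substr(g1chr, starts1[i] + 1L, starts1[i] + lens[i])
      mut <- mutateSequenceK2P(block, divergence, kappa)
      g2chr <- .splice_in(g2chr, starts2[i], mut$seq)
    }
    truth <- data.frame(block = seq_along(lens), start1 = starts1,
                        end1 = starts1 + lens, start2 = starts2,
                        end2 = starts2 + lens, length = lens)
  }
  list(g1 = GenomeSeq(ids[1], g1chr), g2 = GenomeSeq(ids[2], g2chr),
       truth = truth)
}

#' Generate depth profiles for origin classification
#'
#' Emulates the three-class copy-number separation of a plant cell: a
#' single-copy nuclear spike-in, a high-copy plastid spike-in, a panel of
#' mitochondrial reference genes whose per-gene means are log-spaced around
#' the mitochondrial class mean, and query genes with known labels. Depths
#' are drawn per position from a counting-noise model: Poisson by default,
#' negative binomial when `dispersion > 0`.
#'
#' @param n_query_genes number of query genes.
#' @param true_labels character vector over
#'   \{"nuclear","mitochondrial","plastid"\} (recycled; default cycles all
#'   three).
#' @param class_means named mean depths of the three compartments; defaults
#'   are the observed spike-in anchors of a conifer resequencing experiment
#'   (nuclear 15x, mitochondrial 600x, plastid 14,395x).
#' @param n_mito_refs number of mitochondrial reference genes.
#' @param mito_spread fold-spread of mitochondrial reference means around
#'   the class mean (log-spaced in `[mean/spread, mean*spread]`).
#' @param gene_length profile length per gene (bp).
#' @param dispersion negative-binomial overdispersion (0 = Poisson;
#'   variance = mean + dispersion * mean^2).
#' @param seed RNG seed.
#' @return List with `panel` ([ReferencePanel-class]), `queries` (named list
#'   of depth profiles) and `truth` (data.frame: `gene_id`, `label`).
#' @export
genDepthProfiles <- function(n_query_genes = 30L, true_labels = NULL,
                             class_means = c(nuclear = 15, mitochondrial = 600,
                                             plastid = 14395),
                             n_mito_refs = 32L, mito_spread = 2,
                             gene_length = 1000L, dispersion = 0, seed) {
  stopifnot(all(class_means > 0), dispersion >= 0)
  set.seed(seed)
  if (is.null(true_labels))
    true_labels <- rep(c("nuclear", "mitochondrial", "plastid"),
                       length.out = n_query_genes)
  true_labels <- rep(true_labels, length.out = n_query_genes)
  stopifnot(all(true_labels %in% names(class_means)))
  draw <- function(mu, n) {
    if (mu == 0) return(rep(0, n))
    if (dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
  mito_means <- exp(seq(log(class_means[["mitochondrial"]] / mito_spread),
                        log(class_means[["mitochondrial"]] * mito_spread),
                        length.out = n_mito_refs))
  panel <- ReferencePanel(
    nuclear = draw(class_means[["nuclear"]], gene_length),
    plastid = draw(class_means[["plastid"]], gene_length),
    mito = stats::setNames(lapply(mito_means, draw, n = gene_length),
                           sprintf("mito_ref_%02d", seq_len(n_mito_refs))))
  ids <- sprintf("query_%03d", seq_len(n_query_genes))
  queries <- stats::setNames(lapply(true_labels, function(lab)
    draw(class_means[[lab]], gene_length)), ids)
  list(panel = panel, queries = queries,
       truth = data.frame(gene_id = ids, label = true_labels,
                          stringsAsFactors = FALSE))
}

#' Generate a codon-sequence pair with target dS and dN
#'
#' A random stop-free ancestor sequence is evolved along two branches.
#' Synonymous and nonsynonymous substitution counts per branch are drawn as
#' Poisson with means `p_S * S / 2` and `p_N * N / 2`, where `p_S`/`p_N`
#' invert the Jukes-Cantor correction of the targets and `S`/`N` are the
#' NG86 site counts of the ancestor; individual changes are sampled
#' kappa-weighted (transitions `kappa / (kappa + 2)`), rejecting changes
#' that create stop codons or fall in the wrong category. Targets must be
#' below saturation (< 0.5).
#'
#' @param n_codons number of codons.
#' @param target_ds,target_dn expected pairwise dS and dN (each < 0.5).
#' @param kappa transition/transversion rate ratio.
#' @param seed RNG seed.
#' @param code genetic code (default the standard code).
#' @return List with `codons1`, `codons2` (character sequences) and `truth`
#'   (per-branch realized synonymous/nonsynonymous substitution counts and
#'   the ancestor site counts `S`, `N`).
#' @export
genCodonPair <- function(n_codons, target_ds, target_dn, kappa = 2, seed,
                         code = Biostrings::GENETIC_CODE) {
  stopifnot(n_codons > 0, target_ds >= 0, target_dn >= 0)
  if (target_ds >= 0.5 || target_dn >= 0.5)
    stop("targets must be below saturation (< 0.5)")
  set.seed(seed)
  codev <- unlist(as.list(code))
  nonstop <- names(codev)[codev != "*"]
  anc <- sample(nonstop, n_codons, replace = TRUE)
  st <- .syn_sites_table(codev)
  S <- sum(st[anc]); N <- 3 * n_codons - S
  jc_inv <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  nS_target <- jc_inv(target_ds) * S / 2
  nN_target <- jc_inv(target_dn) * N / 2
  evolve <- function(codons) {
    nS <- stats::rpois(1, nS_target)
    nN <- stats::rpois(1, nN_target)
    doneS <- 0L; doneN <- 0L; attempts <- 0L
    max_attempts <- 1000L * (nS + nN + 1L)
    while ((doneS < nS || doneN < nN) && attempts < max_attempts) {
      attempts <- attempts + 1L
      i <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      chars <- strsplit(codons[i], "")[[1]]
      base <- chars[pos]
      alt <- if (stats::runif(1) < kappa / (kappa + 2)) .TS_MAP[[base]]
             else sample(.TV_MAP[[base]], 1L)
      chars[pos] <- alt
      cand <- paste(chars, collapse = "")
      if (codev[[cand]] == "*") next
      syn <- codev[[cand]] == codev[[codons[i]]]
      if (syn && doneS < nS) { codons[i] <- cand; doneS <- doneS + 1L }
      else if (!syn && doneN < nN) { codons[i] <- cand; doneN <- doneN + 1L }
    }
    if (doneS < nS || doneN < nN)
      warning("substitution budget not exhausted within attempt limit")
    list(codons = codons, n_syn = doneS, n_nonsyn = doneN)
  }
  b1 <- evolve(anc); b2 <- evolve(anc)
  list(codons1 = paste(b1$codons, collapse = ""),
       codons2 = paste(b2$codons, collapse = ""),
       truth = data.frame(branch = c(1L, 2L),
                          n_syn = c(b1$n_syn, b2$n_syn),
                          n_nonsyn = c(b1$n_nonsyn, b2$n_nonsyn),
                          S = S, N = N))
}

#' Generate a synthetic RNA-editing-site table
#'
#' Distinct (gene, column) sites per species, sampled uniformly over a gene
#' x column grid.
#'
#' @param n_sites named integer vector: sites per species.
#' @param genes gene ids to sample from.
#' @param max_column columns per gene.
#' @param seed RNG seed.
#' @return data.frame with columns `species`, `gene`, `column`, `edit`
#'   (always `"C-to-U"`).
#' @export
genEditSites <- function(n_sites, genes = sprintf("gene%02d", 1:32),
                         max_column = 500L, seed) {
  stopifnot(!is.null(names(n_sites)), all(n_sites >= 0))
  ncells <- length(genes) * max_column
  if (any(n_sites > ncells)) stop("more sites requested than grid cells")
  set.seed(seed)
  out <- lapply(names(n_sites), function(sp) {
    cells <- sample.int(ncells, n_sites[[sp]])
    data.frame(species = sp, gene = genes[(cells - 1L) %/% max_column + 1L],
               column = (cells - 1L) %% max_column + 1L,
               edit = "C-to-U", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
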