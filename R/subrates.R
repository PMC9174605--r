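# Absolute substitution rates from per-branch dS/dN and divergence times,
# fold-range and clade summaries, and a pairwise NG86 dN/dS estimator for
# synthetic-recovery testing.

#' Absolute substitution rate per site per year
#'
#' Divides a branch's substitutions/site by its divergence time in years:
#' `d / (t_mya * 1e6)`.
#'
#' @param d substitutions per site (>= 0).
#' @param t_mya divergence time in million years (> 0).
#' @return Rate(s) in substitutions per site per year.
#' @examples
#' absoluteRate(0.002997, 87)  # 3.44483e-11
#' @export
absoluteRate <- function(d, t_mya) {
  if (any(t_mya <= 0)) stop("divergence time must be positive")
  if (any(d < 0)) stop("substitutions/site must be non-negative")
  d / (t_mya * 1e6)
}

#' Read a per-branch substitution-rate table
#'
#' Expects a TSV with columns `taxon`, `clade`, `t_mya`, `ds`, `dn` and
#' optionally `is_terminal` (terminal species vs internal-branch or
#' clade-summary rows; default TRUE), `is_clade_summary` (default FALSE) and
#' printed `rs_given`/`rn_given` columns. Absolute rates `rs` and `rn` are
#' recomputed from `ds`/`dn` and `t_mya` via [absoluteRate()].
#'
#' @param path TSV path (the bundled comparative table is
#'   `mitocompFixture("branch_rates.tsv")`).
#' @return data.frame with recomputed `rs`, `rn` columns appended.
#' @export
readBranchRates <- function(path) {
  spec <- tableSpec(taxon = "character", clade = "character",
                    t_mya = "numeric", ds = "numeric", dn = "numeric")
  df <- readTypedTable(path, spec)
  for (col in c("is_terminal", "is_clade_summary"))
    if (col %in% names(df)) df[[col]] <- as.logical(toupper(df[[col]]))
  if (!"is_terminal" %in% names(df)) df$is_terminal <- TRUE
  if (!"is_clade_summary" %in% names(df)) df$is_clade_summary <- FALSE
  for (col in c("rs_given", "rn_given"))
    if (col %in% names(df)) df[[col]] <- .parse_numeric_cell(df[[col]])
  df$rs <- absoluteRate(df$ds, df$t_mya)
  df$rn <- absoluteRate(df$dn, df$t_mya)
  df
}

.round_half_up <- function(x) floor(x + 0.5)

#' Fold range of a rate metric across species
#'
#' Ratio of the largest to the smallest value of a metric over terminal
#' species rows (internal-branch and clade-summary rows are excluded),
#' rounded half-up to the nearest integer.
#'
#' @param rates data.frame from [readBranchRates()].
#' @param metric one of `"ds"`, `"dn"`, `"rs"`, `"rn"`.
#' @param scope `"all species"` or a clade name.
#' @return List with `metric`, `scope`, `max_taxon`, `min_taxon`, `max`,
#'   `min`, `fold` (integer) and `fold_raw`.
#' @export
foldRange <- function(rates, metric = c("ds", "dn", "rs", "rn"),
                      scope = "all species") {
  metric <- match.arg(metric)
  rows <- rates[rates$is_terminal, , drop = FALSE]
  if (!identical(scope, "all species"))
    rows <- rows[rows$clade == scope, , drop = FALSE]
  if (nrow(rows) < 2L)
    stop("need at least 2 terminal rows in scope ", sQuote(scope))
  v <- rows[[metric]]
  if (any(v == 0))
    stop("zero ", metric, " value in scope ", sQuote(scope), "; fold undefined")
  imax <- which.max(v); imin <- which.min(v)
  list(metric = metric, scope = scope,
       max_taxon = rows$taxon[imax], min_taxon = rows$taxon[imin],
       max = v[imax], min = v[imin],
       fold = as.integer(.round_half_up(v[imax] / v[imin])),
       fold_raw = v[imax] / v[imin])
}

#' Ratio of a metric between two clade summaries
#'
#' Clade-level values are consumed as given summary rows, never recomputed
#' from member species.
#'
#' @param rates data.frame from [readBranchRates()].
#' @param clade_a,clade_b clade names (rows flagged `is_clade_summary`).
#' @param metric one of `"ds"`, `"dn"`, `"rs"`, `"rn"`.
#' @return `metric(clade_a) / metric(clade_b)`.
#' @export
cladeRatio <- function(rates, clade_a, clade_b, metric = c("ds", "dn", "rs", "rn")) {
  metric <- match.arg(metric)
  summ <- rates[rates$is_clade_summary, , drop = FALSE]
  pick <- function(cl) {
    i <- which(summ$taxon == cl | summ$clade == cl)
    if (!length(i)) stop("no clade summary row for ", sQuote(cl))
    summ[[metric]][i[1]]
  }
  pick(clade_a) / pick(clade_b)
}

# ---------------------------------------------------------------------------
# Nei-Gojobori (1986) pairwise estimator
# ---------------------------------------------------------------------------

.codon_vector <- function(x) {
  if (is(x, "XString")) x <- as.character(x)
  if (length(x) == 1L && nchar(x[1]) > 3L) {
    if (nchar(x) %% 3L != 0L) stop("sequence length not divisible by 3")
    x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  }
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x))) stop("codons must be gap-free over {A,C,G,T}")
  x
}

# per-codon synonymous site count: at each position, the fraction of the
# three possible changes that preserve the amino acid; changes to stop
# codons count as nonsynonymous
.syn_sites_table <- function(code) {
  codons <- names(code)
  sapply(codons, function(cd) {
    if (code[[cd]] == "*") return(NA_real_)
    chars <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
        alt <- chars; alt[pos] <- b
        altc <- paste(alt, collapse = "")
        if (code[[altc]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    s
  })
}

# average synonymous/nonsynonymous step counts between two codons over all
# minimal mutational pathways; pathways through stop codons are excluded
# (all pathways are used if every one is excluded)
.codon_path_diffs <- function(c1, c2, code) {
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  dpos <- which(p1 != p2)
  k <- length(dpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(dpos)
           else if (k == 2L) list(dpos, rev(dpos))
           else list(dpos[c(1, 2, 3)], dpos[c(1, 3, 2)], dpos[c(2, 1, 3)],
                     dpos[c(2, 3, 1)], dpos[c(3, 1, 2)], dpos[c(3, 2, 1)])
  res <- matrix(NA_real_, nrow = length(perms), ncol = 2)
  valid <- logical(length(perms))
  for (i in seq_along(perms)) {
    cur <- p1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in perms[[i]]) {
      nxt <- cur; nxt[pos] <- p2[pos]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") { ok <- FALSE }
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[i, ] <- c(sd, nd)
    valid[i] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, length(perms))
  c(sd = mean(res[use, 1]), nd = mean(res[use, 2]))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences), resolves observed codon differences by averaging over all
#' minimal mutational pathways (pathways through stop codons excluded), and
#' applies the Jukes-Cantor correction \eqn{d = -\tfrac34 \ln(1 - 4p/3)}
#' separately to the synonymous and nonsynonymous proportions. Symmetric in
#' its arguments. When a proportion reaches 3/4 the corrected distance is
#' saturated and reported as `Inf`.
#'
#' @param codons1,codons2 equal-length gap-free coding sequences (character
#'   string, `DNAString`, or codon vector); length divisible by 3, no stop
#'   codons.
#' @param code genetic code, a named character vector mapping codons to
#'   amino acids (default [Biostrings::GENETIC_CODE], the standard code used
#'   by plant mitochondria).
#' @return List with `dn`, `ds`, `pn`, `ps`, `N`, `S`, `Nd`, `Sd`.
#' @export
ng86Pairwise <- function(codons1, codons2, code = Biostrings::GENETIC_CODE) {
  c1 <- .codon_vector(codons1)
  c2 <- .codon_vector(codons2)
  if (length(c1) != length(c2)) stop("sequences differ in codon count")
  code <- as.list(code)
  if (any(vapply(c1, function(x) code[[x]] == "*", TRUE)) ||
      any(vapply(c2, function(x) code[[x]] == "*", TRUE)))
    stop("stop codon in coding sequence")
  st <- .syn_sites_table(unlist(code))
  S1 <- sum(st[c1]); S2 <- sum(st[c2])
  S <- (S1 + S2) / 2
  N <- 3 * length(c1) - S
  diffs <- mapply(function(a, b) if (a == b) c(sd = 0, nd = 0)
                  else .codon_path_diffs(a, b, code), c1, c2)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(dn = jc(pn), ds = jc(ps), pn = pn, ps = ps, N = N, S = S, Nd = Nd, Sd = Sd)
}
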