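# Comparative set statistics over C-to-U RNA-editing-site tables. Site
# homology across species is keyed by (gene, alignment column); the
# cross-species alignment producing the column indices is an input, not
# computed here.

.check_edit_table <- function(table) {
  need <- c("species", "gene", "column")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(table) && any(table$column < 1))
    stop("alignment columns are 1-based (column >= 1)")
  # duplicate (species, gene, column) rows collapse to one site
  table[!duplicated(table[, need]), , drop = FALSE]
}

#' Number of editing sites of one species
#'
#' Distinct (gene, column) sites recorded for the species; duplicate input
#' rows count once.
#'
#' @param table data.frame with columns `species`, `gene`, `column`.
#' @param species species id (must be present in the table).
#' @return Integer count.
#' @export
countSites <- function(table, species) {
  table <- .check_edit_table(table)
  if (!species %in% table$species) stop("unknown species ", sQuote(species))
  sum(table$species == species)
}

#' Species-unique editing sites
#'
#' A site of species `s` is unique iff no other species in the table has a
#' site at the same (gene, column). Requires at least two species.
#'
#' @inheritParams countSites
#' @return List with `n_unique` and `pct` (percent of the species' sites).
#' @export
uniqueFraction <- function(table, species) {
  table <- .check_edit_table(table)
  if (length(unique(table$species)) < 2L) stop("need at least 2 species")
  if (!species %in% table$species) stop("unknown species ", sQuote(species))
  key <- paste(table$gene, table$column, sep = "\r")
  mine <- table$species == species
  other_keys <- unique(key[!mine])
  n_unique <- sum(!key[mine] %in% other_keys)
  list(n_unique = n_unique, pct = 100 * n_unique / sum(mine))
}

#' Overlap between predicted and observed editing sites
#'
#' The overlap count is symmetric; the percentage is of the predicted set
#' (the usual prediction-validation convention), rounded to the nearest
#' integer.
#'
#' @param predicted,observed data.frames with columns `gene`, `column`
#'   (optionally `species`, ignored for keying) describing the two site sets.
#' @return List with `n_overlap`, `n_predicted`, `n_observed`,
#'   `pct_of_predicted` (integer percent; `NA` with a flag when the
#'   predicted set is empty).
#' @export
validationOverlap <- function(predicted, observed) {
  keyify <- function(df) {
    need <- c("gene", "column")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    unique(paste(df$gene, df$column, sep = "\r"))
  }
  kp <- keyify(predicted); ko <- keyify(observed)
  n_overlap <- length(intersect(kp, ko))
  if (length(kp) == 0L)
    return(list(n_overlap = n_overlap, n_predicted = 0L,
                n_observed = length(ko), pct_of_predicted = NA_real_,
                flag = "empty predicted set"))
  list(n_overlap = n_overlap, n_predicted = length(kp),
       n_observed = length(ko),
       pct_of_predicted = as.integer(.round_half_up(100 * n_overlap / length(kp))),
       flag = "")
}

#' Per-species editing-site summary
#'
#' Counts and unique-site percentages for every species in the table.
#'
#' @param table data.frame with columns `species`, `gene`, `column`.
#' @return data.frame with one row per species: `species`, `n_sites`,
#'   `n_unique`, `pct_unique`.
#' @export
editingSummary <- function(table) {
  table <- .check_edit_table(table)
  sp <- sort(unique(table$species))
  do.call(rbind, lapply(sp, function(s) {
    u <- if (length(sp) > 1L) uniqueFraction(table, s)
         else list(n_unique = NA_integer_, pct = NA_real_)
    data.frame(species = s, n_sites = countSites(table, s),
               n_unique = u$n_unique, pct_unique = u$pct,
               stringsAsFactors = FALSE)
  }))
}
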