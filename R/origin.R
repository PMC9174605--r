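# Genome-of-origin classification of candidate transferred genes from
# read-depth profiles, calibrated by spike-in reference genes. In a plant
# cell the three genomes differ by orders of magnitude in copy number
# (plastid highest, mitochondrial intermediate, nuclear lowest), so the
# median mapped-read depth of a gene places it in a compartment.

#' Median read depth of a profile
#'
#' Median over all positions including zero-depth ones; the even-length
#' median is the mean of the central pair.
#'
#' @param profile numeric vector of per-position depths.
#' @return The median depth.
#' @export
medianDepth <- function(profile) {
  if (!length(profile)) stop("empty depth profile")
  if (any(profile < 0)) stop("depths must be non-negative")
  stats::median(profile)
}

#' Classify the genomic compartment of a gene from its depth profile
#'
#' Class anchors are the median depth of the nuclear spike-in, the median of
#' the per-gene medians of the mitochondrial references, and the median of
#' the plastid spike-in. The gene is assigned to the anchor minimising
#' `|log2(gene median / anchor)|`; when the two smallest log2 distances
#' differ by less than `margin_threshold` the call is ambiguous. A gene with
#' zero median depth is ambiguous with flag `"no coverage"`. Calls are
#' scale-invariant: multiplying every depth (gene and panel) by a constant
#' leaves labels unchanged. Genes landing on the nuclear anchor but more
#' than 3-fold above it are flagged as possible multi-copy nuclear
#' insertions.
#'
#' @param gene numeric depth profile of the query gene, or a named list of
#'   profiles (one call per gene).
#' @param panel a [ReferencePanel-class].
#' @param margin_threshold ambiguity band in log2 units (default 1, a
#'   two-fold band; the compartments differ by orders of magnitude so this
#'   is conservative).
#' @param gene_id id used in the output when `gene` is a single profile.
#' @return data.frame with one row per gene: `gene_id`, `label`
#'   (nuclear/mitochondrial/plastid/ambiguous), `median_depth`,
#'   `log2_ratio_to_nuclear`, `log2_ratio_to_mito`, `log2_ratio_to_plastid`,
#'   `margin` (log2 gap between best and second-best class), `flag`.
#' @export
classifyOrigin <- function(gene, panel, margin_threshold = 1.0, gene_id = "gene") {
  stopifnot(is(panel, "ReferencePanel"))
  if (is.list(gene)) {
    ids <- names(gene)
    if (is.null(ids)) ids <- paste0("gene_", seq_along(gene))
    out <- do.call(rbind, lapply(seq_along(gene), function(i)
      classifyOrigin(gene[[i]], panel, margin_threshold, ids[i])))
    rownames(out) <- NULL
    return(out)
  }
  anchors <- panelAnchors(panel)
  med <- medianDepth(gene)
  row <- data.frame(gene_id = gene_id, label = "ambiguous",
                    median_depth = med,
                    log2_ratio_to_nuclear = NA_real_,
                    log2_ratio_to_mito = NA_real_,
                    log2_ratio_to_plastid = NA_real_,
                    margin = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  if (med == 0) {
    row$flag <- "no coverage"
    return(row)
  }
  lr <- log2(med / anchors)
  row$log2_ratio_to_nuclear <- unname(lr[["nuclear"]])
  row$log2_ratio_to_mito <- unname(lr[["mitochondrial"]])
  row$log2_ratio_to_plastid <- unname(lr[["plastid"]])
  d <- abs(lr)
  ord <- order(d)
  margin <- d[ord[2]] - d[ord[1]]
  row$margin <- unname(margin)
  if (margin < margin_threshold) {
    row$label <- "ambiguous"
    row$flag <- "ambiguous margin"
  } else {
    row$label <- names(anchors)[ord[1]]
    if (row$label == "nuclear" && med / anchors[["nuclear"]] > 3)
      row$flag <- "possible multi-copy nuclear insertion"
  }
  row
}

#' Depth-classification report
#'
#' Per-gene medians, anchors, log2 ratios and labels, plus the min-max span
#' of the mitochondrial reference gene medians (the "275-1,169x"-style range
#' that situates the mitochondrial class).
#'
#' @param calls data.frame from [classifyOrigin()] (>= 1 row).
#' @param panel the [ReferencePanel-class] used for the calls.
#' @return List with `table` (the calls with anchor columns appended),
#'   `anchors`, `mito_depth_range` (length-2 numeric) and
#'   `mito_depth_range_label` (e.g. `"275-1169"`).
#' @export
depthReport <- function(calls, panel) {
  stopifnot(is(panel, "ReferencePanel"), nrow(calls) >= 1L)
  anchors <- panelAnchors(panel)
  mito_med <- vapply(panel@mito, stats::median, 1.0)
  rng <- range(mito_med)
  tab <- calls
  tab$anchor_nuclear <- anchors[["nuclear"]]
  tab$anchor_mito <- anchors[["mitochondrial"]]
  tab$anchor_plastid <- anchors[["plastid"]]
  list(table = tab, anchors = anchors, mito_depth_range = rng,
       mito_depth_range_label = sprintf("%g-%g", rng[1], rng[2]))
}
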