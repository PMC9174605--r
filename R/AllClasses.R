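#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mitocomp, .registration = TRUE
NULL

#' GenomeSeq: a named, optionally circular nucleotide sequence
#'
#' The substrate for repeat and shared-DNA scans. Sequences are restricted to
#' the alphabet A, C, G, T, N; `N` never matches anything in downstream
#' alignments, itself included. Coordinates on a `GenomeSeq` are always
#' 0-based half-open.
#'
#' @slot id single non-empty identifier.
#' @slot seq a [Biostrings::DNAString] over \{A,C,G,T,N\}.
#' @slot circular logical; circular-mapping molecules are scanned with an
#'   origin-spanning pad so seeds crossing the origin are found.
#'
#' @seealso [readGenomeFasta()], [genGenome()]
#' @export
setClass("GenomeSeq",
  representation(id = "character", seq = "ANY", circular = "logical"))

setValidity("GenomeSeq", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msgs <- c(msgs, "id must be a single non-empty string")
  if (!methods::is(object@seq, "DNAString"))
    msgs <- c(msgs, "seq must be a DNAString")
  else if (length(object@seq) == 0L)
    msgs <- c(msgs, "sequence must be non-empty")
  else {
    bad <- setdiff(names(Biostrings::alphabetFrequency(object@seq)[
      Biostrings::alphabetFrequency(object@seq) > 0]), c("A", "C", "G", "T", "N"))
    if (length(bad))
      msgs <- c(msgs, sprintf("record '%s' contains characters outside {A,C,G,T,N}: %s",
                              object@id, paste(bad, collapse = ", ")))
  }
  if (length(object@circular) != 1L || is.na(object@circular))
    msgs <- c(msgs, "circular must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeSeq
#'
#' Sequences are uppercased, `U` is mapped to `T`, and IUPAC ambiguity codes
#' other than `N` are replaced with `N` (with a message). Characters outside
#' the IUPAC alphabet are rejected with an error naming the record.
#'
#' @param id record identifier.
#' @param seq character string or `DNAString`.
#' @param circular logical flag.
#' @return A [GenomeSeq-class] object.
#' @examples
#' g <- GenomeSeq("g1", "acguACGT")
#' genomeLength(g)
#' @export
GenomeSeq <- function(id, seq, circular = FALSE) {
  if (is(seq, "XString")) seq <- as.character(seq)
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  bad <- setdiff(chars, iupac)
  if (length(bad))
    stop(sprintf("record '%s' contains non-IUPAC characters: %s",
                 id, paste(bad, collapse = ", ")))
  amb <- setdiff(intersect(chars, iupac), c("A", "C", "G", "T", "N"))
  if (length(amb)) {
    message(sprintf("record '%s': replacing IUPAC ambiguity codes (%s) with N",
                    id, paste(amb, collapse = ",")))
    seq <- chartr(paste(amb, collapse = ""),
                  strrep("N", length(amb)), seq)
  }
  methods::new("GenomeSeq", id = id, seq = Biostrings::DNAString(seq),
               circular = isTRUE(circular))
}

#' @describeIn GenomeSeq-class record identifier.
#' @param x,object a `GenomeSeq`.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname GenomeSeq-class
#' @export
setMethod("genomeId", "GenomeSeq", function(x) x@id)

#' @describeIn GenomeSeq-class the sequence as a `DNAString`.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname GenomeSeq-class
#' @export
setMethod("genomeSeq", "GenomeSeq", function(x) x@seq)

#' @describeIn GenomeSeq-class is the molecule circular-mapping?
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname GenomeSeq-class
#' @export
setMethod("isCircular", "GenomeSeq", function(x) x@circular)

#' @describeIn GenomeSeq-class sequence length in bp.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname GenomeSeq-class
#' @export
setMethod("genomeLength", "GenomeSeq", function(x) length(x@seq))

#' @rdname GenomeSeq-class
#' @export
setMethod("show", "GenomeSeq", function(object) {
  cat(sprintf("GenomeSeq '%s': %d bp, %s\n", object@id, length(object@seq),
              if (object@circular) "circular" else "linear"))
})

#' RepeatHits: dispersed-repeat alignments on one genome
#'
#' One row per duplicated-sequence alignment (mirror duplicates collapsed so
#' the query copy starts at or before the subject copy). Coordinates are
#' 0-based half-open on the forward strand; for hits spanning the origin of a
#' circular genome, `q_end`/`s_end` may exceed the genome length (the interval
#' wraps).
#'
#' Columns of `hitTable()`: `q_start`, `q_end`, `s_start`, `s_end`, `strand`,
#' `length` (shorter copy), `score`, `identity`, `evalue`, `k2p`,
#' `size_class`, `age_class`, `aligned_q`, `aligned_s`.
#'
#' @slot genomeId id of the scanned genome.
#' @slot genomeLength its length in bp.
#' @slot circular its topology.
#' @slot hits data.frame of hits.
#' @slot params list of scan parameters (word size, scoring, E-value cutoff,
#'   Karlin-Altschul lambda and K).
#' @seealso [findDispersedRepeats()]
#' @export
setClass("RepeatHits",
  representation(genomeId = "character", genomeLength = "integer",
                 circular = "logical", hits = "data.frame", params = "list"))

setValidity("RepeatHits", function(object) {
  need <- c("q_start", "q_end", "s_start", "s_end", "strand", "length",
            "score", "identity", "evalue", "k2p", "size_class", "age_class")
  miss <- setdiff(need, names(object@hits))
  if (length(miss)) return(paste("missing hit columns:", paste(miss, collapse = ", ")))
  h <- object@hits
  if (nrow(h)) {
    if (any(h$q_start < 0 | h$s_start < 0)) return("negative coordinates")
    if (any(h$q_end <= h$q_start | h$s_end <= h$s_start)) return("empty intervals")
    if (any(h$evalue < 0)) return("negative E-values")
  }
  TRUE
})

#' @describeIn RepeatHits-class the per-hit table as a data.frame.
#' @param x,object a `RepeatHits`.
#' @export
setGeneric("hitTable", function(x) standardGeneric("hitTable"))

#' @rdname RepeatHits-class
#' @export
setMethod("hitTable", "RepeatHits", function(x) x@hits)

#' @rdname RepeatHits-class
#' @export
setMethod("length", "RepeatHits", function(x) nrow(x@hits))

#' @rdname RepeatHits-class
#' @export
setMethod("show", "RepeatHits", function(object) {
  cat(sprintf("RepeatHits on '%s' (%d bp, %s): %d repeat pair(s)\n",
              object@genomeId, object@genomeLength,
              if (object@circular) "circular" else "linear", nrow(object@hits)))
  if (nrow(object@hits)) {
    cat(sprintf("  size classes: %d small / %d medium / %d large\n",
                sum(object@hits$size_class == "small"),
                sum(object@hits$size_class == "medium"),
                sum(object@hits$size_class == "large")))
  }
})

#' @rdname RepeatHits-class
#' @param row.names,optional passed on (unused).
#' @param ... unused.
#' @export
as.data.frame.RepeatHits <- function(x, row.names = NULL, optional = FALSE, ...) x@hits

#' RepeatSummary: per-genome dispersed-repeat summary
#'
#' Counts per size class, merged repetitive bp ("overlapping regions counted
#' only once"), percent of genome, GC content and the K2P distance multiset
#' per size class.
#'
#' @slot genomeId,genomeLength genome identity and size.
#' @slot totalRepetitiveBp merged bp covered by any repeat copy.
#' @slot pctGenome percent of the genome that is repetitive.
#' @slot nPairs named integer vector: total, small, medium, large.
#' @slot gcByClass named numeric vector of GC fractions per size class.
#' @slot k2pByClass named list of K2P distance vectors per size class
#'   (saturated distances excluded).
#' @seealso [summarizeRepeats()]
#' @export
setClass("RepeatSummary",
  representation(genomeId = "character", genomeLength = "integer",
                 totalRepetitiveBp = "integer", pctGenome = "numeric",
                 nPairs = "integer", gcByClass = "numeric", k2pByClass = "list"))

setValidity("RepeatSummary", function(object) {
  if (object@totalRepetitiveBp > object@genomeLength)
    return("merged repetitive bp exceeds genome length")
  np <- object@nPairs
  if (!all(c("total", "small", "medium", "large") %in% names(np)))
    return("nPairs must contain total/small/medium/large")
  if (np[["total"]] != np[["small"]] + np[["medium"]] + np[["large"]])
    return("class counts do not sum to total")
  TRUE
})

#' @rdname RepeatSummary-class
#' @param object a `RepeatSummary`.
#' @export
setMethod("show", "RepeatSummary", function(object) {
  cat(sprintf("RepeatSummary for '%s' (%d bp)\n", object@genomeId, object@genomeLength))
  cat(sprintf("  merged repetitive: %d bp (%.2f%%)\n",
              object@totalRepetitiveBp, object@pctGenome))
  cat(sprintf("  pairs: %d total = %d small + %d medium + %d large\n",
              object@nPairs[["total"]], object@nPairs[["small"]],
              object@nPairs[["medium"]], object@nPairs[["large"]]))
})

#' ReferencePanel: spike-in depth references for origin classification
#'
#' Depth profiles of genes with known genomic compartment: a single-copy
#' nuclear gene (e.g. LEAFY), a plastid gene (e.g. matK), and the annotated
#' mitochondrial genes of the assembly. Class anchors are the nuclear median,
#' the plastid median, and the median of the per-gene mitochondrial medians.
#'
#' @slot nuclear numeric vector of per-position depths of the nuclear spike-in.
#' @slot plastid per-position depths of the plastid spike-in.
#' @slot mito named list of per-position depth vectors, one per mitochondrial
#'   gene; must be non-empty.
#' @seealso [classifyOrigin()], [genDepthProfiles()]
#' @export
setClass("ReferencePanel",
  representation(nuclear = "numeric", plastid = "numeric", mito = "list"))

setValidity("ReferencePanel", function(object) {
  if (!length(object@nuclear)) return("nuclear reference profile is empty")
  if (!length(object@plastid)) return("plastid reference profile is empty")
  if (!length(object@mito)) return("mito reference list is empty")
  if (any(vapply(object@mito, length, 1L) == 0L)) return("empty mito profile")
  if (any(object@nuclear < 0) || any(object@plastid < 0) ||
      any(unlist(object@mito) < 0)) return("depths must be non-negative")
  TRUE
})

#' Construct a ReferencePanel
#'
#' @param nuclear,plastid numeric depth vectors for the spike-in references.
#' @param mito named list of depth vectors for annotated mitochondrial genes.
#' @return A [ReferencePanel-class] object.
#' @export
ReferencePanel <- function(nuclear, plastid, mito) {
  if (is.null(names(mito))) names(mito) <- paste0("mito_", seq_along(mito))
  methods::new("ReferencePanel", nuclear = as.numeric(nuclear),
               plastid = as.numeric(plastid),
               mito = lapply(mito, as.numeric))
}

#' @describeIn ReferencePanel-class the three class anchor depths
#'   (named vector: nuclear, mitochondrial, plastid).
#' @param x,object a `ReferencePanel`.
#' @export
setGeneric("panelAnchors", function(x) standardGeneric("panelAnchors"))

#' @rdname ReferencePanel-class
#' @export
setMethod("panelAnchors", "ReferencePanel", function(x) {
  c(nuclear = stats::median(x@nuclear),
    mitochondrial = stats::median(vapply(x@mito, stats::median, 1.0)),
    plastid = stats::median(x@plastid))
})

#' @rdname ReferencePanel-class
#' @export
setMethod("show", "ReferencePanel", function(object) {
  a <- panelAnchors(object)
  cat(sprintf("ReferencePanel: anchors nuclear=%.1fx mito=%.1fx plastid=%.1fx (%d mito genes)\n",
              a[["nuclear"]], a[["mitochondrial"]], a[["plastid"]], length(object@mito)))
})
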