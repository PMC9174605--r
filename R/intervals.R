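# Interval accounting: "overlapping regions counted only once".

#' Merge intervals and total their coverage
#'
#' Computes the union of 0-based half-open intervals on one genome as a set
#' of disjoint intervals plus the total covered bp, the accounting used for
#' repetitive-content totals (each base counted once no matter how many
#' repeat copies cover it). On a circular genome, intervals whose `end`
#' exceeds the genome length wrap around the origin and are split before
#' merging.
#'
#' @param starts,ends integer vectors of 0-based half-open interval bounds.
#' @param genome_length genome length in bp (upper bound for coverage).
#' @param circular does the genome wrap?
#' @return List with `intervals` (data.frame `start`, `end`, disjoint and
#'   sorted) and `total_bp`.
#' @examples
#' mergeIntervals(c(0, 50), c(100, 150), 1000)$total_bp  # 150
#' @export
mergeIntervals <- function(starts, ends, genome_length, circular = FALSE) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L)
    return(list(intervals = data.frame(start = integer(), end = integer()),
                total_bp = 0L))
  if (any(starts < 0) || any(ends <= starts))
    stop("invalid interval: need 0 <= start < end")
  if (any(ends > genome_length)) {
    if (!circular) stop("interval end exceeds genome length on a linear genome")
    wrap <- ends > genome_length
    ws <- starts[wrap]; we <- ends[wrap]
    if (any(we - ws > genome_length)) stop("interval longer than the genome")
    starts <- c(starts[!wrap], ws, rep(0L, sum(wrap)))
    ends <- c(ends[!wrap], rep(genome_length, sum(wrap)), we - genome_length)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  out <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  list(intervals = out, total_bp = sum(IRanges::width(ir)))
}
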