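# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversion to/from 1-based formats happens
# only in the io layer.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ca <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stop_ca("'%s' must be a single finite number", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name)
  if (x < min || x != as.integer(x))
    stop_ca("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  check_scalar_number(x, name)
  if (x < lo || x > hi) stop_ca("'%s' must lie in [%g, %g]", name, lo, hi)
  x
}

# Derive a stage-specific seed from a global one so pipeline stages are
# independently reproducible.  Double-precision arithmetic (exact below
# 2^53) avoids integer overflow; the result stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% 2147483647) * 1000003 + as.numeric(stage) * 10007
  as.integer(s %% 2147483647)
}

# Convert an interval data.frame (chrom, start, end; 0-based half-open) to
# GRanges (1-based closed) for overlap machinery.
intervals_to_gr <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L))
  )
}

# Total bp of overlap between two interval data.frames.
overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ga <- intervals_to_gr(a)
  gb <- GenomicRanges::reduce(intervals_to_gr(b))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0L) return(0)
  ov <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                  gb[S4Vectors::subjectHits(hits)])
  sum(as.numeric(GenomicRanges::width(ov)))
}

# Per-row bp overlapped in `a` by the union of `b`.
overlap_bp_per_row <- function(a, b) {
  out <- numeric(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  ga <- intervals_to_gr(a)
  gb <- GenomicRanges::reduce(intervals_to_gr(b))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0L) return(out)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)]))
  agg <- tapply(as.numeric(ov), S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  out
}

# Maximal runs of TRUE in a logical vector; returns data.frame(start, end)
# of 1-based index ranges (end inclusive).  NA counts as FALSE.
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Column-wise standard deviation of a matrix (rows = individuals).
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}

# Jaccard index on covered bp between two interval sets.
interval_jaccard <- function(a, b) {
  ga <- GenomicRanges::reduce(intervals_to_gr(a))
  gb <- GenomicRanges::reduce(intervals_to_gr(b))
  inter <- overlap_bp(data.frame(chrom = as.character(GenomicRanges::seqnames(ga)),
                                 start = GenomicRanges::start(ga) - 1L,
                                 end = GenomicRanges::end(ga)),
                      b)
  uni <- sum(as.numeric(GenomicRanges::width(ga))) +
    sum(as.numeric(GenomicRanges::width(gb))) - inter
  if (uni == 0) return(NA_real_)
  inter / uni
}

# Lag-1 autocorrelation of a vector, NA-tolerant.
lag1_autocor <- function(x) {
  ok <- is.finite(x)
  x <- x[ok]
  if (length(x) < 3L) return(NA_real_)
  stats::cor(x[-1], x[-length(x)])
}
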