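#' Copy-number segment set
#'
#' Absolute copy-number segments for one sample. Coordinates are 0-based
#' half-open internally (BED convention); convert at VCF boundaries only.
#'
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open segment bounds (`start < end`).
#' @param copy_number absolute integer copy number (>= 0).
#' @return data.frame of class `cn_segments`.
#' @export
cn_segments <- function(chrom, start, end, copy_number) {
  chrom <- rep_len(as.character(chrom), length(start))
  copy_number <- rep_len(copy_number, length(start))
  stopifnot(length(start) == length(end))
  if (any(start >= end)) stop("segments require start < end")
  if (any(copy_number < 0) || any(copy_number != round(copy_number)))
    stop("copy_number must be a non-negative integer")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       copy_number = as.integer(copy_number),
                       stringsAsFactors = FALSE),
            class = c("cn_segments", "data.frame"))
}

as_granges_cn <- function(seg) {
  GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges = IRanges::IRanges(start = seg$start + 1L, end = seg$end),
    copy_number = seg$copy_number)
}

#' Copy-number segments uniquely amplified at one timepoint
#'
#' Intersects the pre- and post-treatment segmentations and reports the
#' resulting pieces amplified in one timepoint but not the other: the piece
#' must span at least `min_length` bp, the amplified side must have absolute
#' copy number within `amp_range` (4-8 by default), and at least
#' `min_ratio` (2x) the copy number of the other timepoint.
#'
#' @param pre,post [cn_segments()] for the pre- and post-treatment sample,
#'   on the same coordinate convention.
#' @param min_length minimum piece length in bp.
#' @param amp_range admissible copy-number range on the amplified side.
#' @param min_ratio minimum amplified/other copy-number ratio.
#' @return data.frame of class `cn_segments` plus a `direction` column
#'   (`"pre"` or `"post"`: which timepoint carries the amplification) and
#'   `other_cn`; BED-style 0-based half-open coordinates.
#' @export
unique_amplifications <- function(pre, post, min_length = 100,
                                  amp_range = c(4, 8), min_ratio = 2) {
  gpre <- as_granges_cn(pre); gpost <- as_granges_cn(post)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), copy_number = integer(0),
                      direction = character(0), other_cn = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cn_segments", "data.frame")
  hits <- GenomicRanges::findOverlaps(gpre, gpost)
  if (length(hits) == 0) return(empty)
  pieces <- GenomicRanges::pintersect(gpre[S4Vectors::queryHits(hits)],
                                      gpost[S4Vectors::subjectHits(hits)])
  cn_pre <- pre$copy_number[S4Vectors::queryHits(hits)]
  cn_post <- post$copy_number[S4Vectors::subjectHits(hits)]
  w <- GenomicRanges::width(pieces)
  test_dir <- function(amp, oth)
    amp >= amp_range[1] & amp <= amp_range[2] & amp >= min_ratio * oth
  post_amp <- test_dir(cn_post, cn_pre)
  pre_amp <- test_dir(cn_pre, cn_post)
  keep <- w >= min_length & (post_amp | pre_amp)
  direction <- ifelse(post_amp, "post", "pre")[keep]
  amp_cn <- ifelse(post_amp, cn_post, cn_pre)[keep]
  oth_cn <- ifelse(post_amp, cn_pre, cn_post)[keep]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(pieces))[keep],
    start = GenomicRanges::start(pieces)[keep] - 1L,
    end = GenomicRanges::end(pieces)[keep],
    copy_number = as.integer(amp_cn),
    direction = direction,
    other_cn = as.integer(oth_cn),
    stringsAsFactors = FALSE)
  class(out) <- c("cn_segments", "data.frame")
  out
}

#' Write amplified segments as BED
#'
#' @param segments output of [unique_amplifications()].
#' @param path BED file path.
#' @return `path`, invisibly.
#' @export
write_amplifications_bed <- function(segments, path) {
  bed <- data.frame(segments$chrom, segments$start, segments$end,
                    name = paste0(segments$direction, "_amp_cn",
                                  segments$copy_number))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
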