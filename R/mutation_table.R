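#' Multi-region mutation table
#'
#' The exchange object used throughout the package: a set of somatic SNVs
#' observed across several tumor regions, with per-region cancer cell
#' fraction (CCF), sequencing depth and variant-read counts. Regions carry a
#' timepoint tag (`"pre"` or `"post"`) so that temporal statistics
#' ([thfr()], [classify_timing()]) know which sample preceded treatment.
#'
#' CCF values may slightly exceed 1 (up to 1.5) as a consequence of noisy
#' purity/copy-number adjustment; variant reads never exceed depth.
#'
#' @param ccf numeric matrix, mutations x regions, values in `[0, 1.5]`.
#' @param depth integer matrix of total read counts, same dimensions.
#' @param alt_reads integer matrix of variant read counts, same dimensions.
#' @param timepoints character vector, one of `"pre"`/`"post"` per region
#'   (defaults to all `"post"` when absent).
#' @param mutations optional data.frame of mutation annotations
#'   (`mut_id`, and optionally `chrom`, `pos`, `ref`, `alt`); row order must
#'   match the matrices.
#'
#' @return An object of class `mutation_table`: a list with elements
#'   `ccf`, `depth`, `alt_reads` (matrices with mutation rownames and region
#'   colnames), `regions` (data.frame of `region`, `timepoint`) and
#'   `mutations` (annotation data.frame).
#' @export
mutation_table <- function(ccf, depth, alt_reads, timepoints = NULL,
                           mutations = NULL) {
  ccf <- as.matrix(ccf)
  depth <- as.matrix(depth)
  alt_reads <- as.matrix(alt_reads)
  if (!all(dim(ccf) == dim(depth)) || !all(dim(ccf) == dim(alt_reads)))
    stop("ccf, depth and alt_reads must have identical dimensions")
  if (is.null(colnames(ccf)))
    colnames(ccf) <- paste0("R", seq_len(ncol(ccf)))
  colnames(depth) <- colnames(alt_reads) <- colnames(ccf)
  if (is.null(rownames(ccf)) && nrow(ccf) > 0)
    rownames(ccf) <- paste0("m", seq_len(nrow(ccf)))
  rownames(depth) <- rownames(alt_reads) <- rownames(ccf)
  if (is.null(timepoints)) timepoints <- rep("post", ncol(ccf))
  timepoints <- as.character(timepoints)
  if (length(timepoints) != ncol(ccf))
    stop("one timepoint per region required")
  if (!all(timepoints %in% c("pre", "post")))
    stop("timepoints must be 'pre' or 'post'")
  if (any(is.na(ccf)) || any(is.na(depth)) || any(is.na(alt_reads)))
    stop("missing values not allowed: every mutation needs a value in every region")
  if (any(ccf < 0))
    stop("negative CCF")
  if (any(depth < 0) || any(alt_reads < 0))
    stop("negative read counts")
  if (any(alt_reads > depth))
    stop("alt_reads exceeds depth")
  if (is.null(mutations)) {
    mutations <- data.frame(
      mut_id = if (nrow(ccf) > 0) rownames(ccf) else character(0),
      stringsAsFactors = FALSE)
  } else {
    mutations <- as.data.frame(mutations)
    if (is.null(mutations$mut_id)) mutations$mut_id <- rownames(ccf)
    if (nrow(mutations) != nrow(ccf))
      stop("mutation annotation rows must match the matrices")
    if (nrow(ccf) > 0)
      rownames(ccf) <- rownames(depth) <- rownames(alt_reads) <-
        mutations$mut_id
  }
  structure(
    list(ccf = ccf, depth = depth, alt_reads = alt_reads,
         regions = data.frame(region = colnames(ccf), timepoint = timepoints,
                              stringsAsFactors = FALSE),
         mutations = mutations),
    class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("mutation_table: %d mutations x %d regions (%d pre, %d post)\n",
              nrow(x$ccf), ncol(x$ccf),
              sum(x$regions$timepoint == "pre"),
              sum(x$regions$timepoint == "post")))
  cat("regions:", paste(x$regions$region, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mutation_table <- function(x) dim(x$ccf)

#' Variant allele fractions of a mutation table
#'
#' `alt_reads/depth`, with 0 where depth is 0.
#' @param table a [mutation_table()].
#' @return numeric matrix of VAFs in `[0, 1]`.
#' @export
vaf_matrix <- function(table) {
  v <- table$alt_reads / table$depth
  v[table$depth == 0] <- 0
  v
}

region_names <- function(table) table$regions$region

pre_regions <- function(table)
  table$regions$region[table$regions$timepoint == "pre"]

post_regions <- function(table)
  table$regions$region[table$regions$timepoint == "post"]

check_region <- function(table, region) {
  if (!region %in% table$regions$region)
    stop(sprintf("region '%s' not present in table", region))
  region
}

#' Subset a mutation table
#'
#' @param x a [mutation_table()].
#' @param i mutation index (logical, integer or id).
#' @param j region index (logical, integer or name).
#' @param ... unused.
#' @return a [mutation_table()] restricted to the selected rows/columns.
#' @export
`[.mutation_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$ccf))
  if (missing(j)) j <- seq_len(ncol(x$ccf))
  jj <- if (is.character(j)) match(j, colnames(x$ccf)) else
    seq_len(ncol(x$ccf))[j]
  ii <- if (is.character(i)) match(i, rownames(x$ccf)) else
    seq_len(nrow(x$ccf))[i]
  mutation_table(x$ccf[ii, jj, drop = FALSE],
                 x$depth[ii, jj, drop = FALSE],
                 x$alt_reads[ii, jj, drop = FALSE],
                 timepoints = x$regions$timepoint[jj],
                 mutations = x$mutations[ii, , drop = FALSE])
}

#' Read a mutation table from TSV
#'
#' The table dialect has columns `mut_id`, `chrom`, `pos`, `ref`, `alt`
#' (annotation columns after `mut_id` are optional), followed by one triplet
#' `ccf_<R>`, `depth_<R>`, `alt_<R>` per region `R`. The region manifest is a
#' TSV with columns `region` and `timepoint` (`pre`/`post`); without a
#' manifest all regions are tagged `post`.
#'
#' Malformed rows (non-numeric CCF, `alt > depth`) abort with the offending
#' row number so problems in hand-edited tables are locatable.
#'
#' @param path path to the mutation TSV.
#' @param manifest_path optional path to the region manifest TSV.
#' @return a [mutation_table()].
#' @export
read_mutation_table <- function(path, manifest_path = NULL) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = "mut_id"))
  if (!"mut_id" %in% names(dt)) stop("missing required column 'mut_id'")
  ccf_cols <- grep("^ccf_", names(dt), value = TRUE)
  if (length(ccf_cols) == 0) stop("no ccf_<region> columns found")
  regions <- sub("^ccf_", "", ccf_cols)
  need <- c(paste0("depth_", regions), paste0("alt_", regions))
  if (!all(need %in% names(dt)))
    stop("missing region columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  getm <- function(prefix) {
    m <- as.matrix(dt[paste0(prefix, "_", regions)])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 1, as.numeric))))[1]
      stop(sprintf("non-numeric %s value at data row %d", prefix, bad))
    }
    colnames(m) <- regions
    m
  }
  ccf <- getm("ccf"); depth <- getm("depth"); alt <- getm("alt")
  bad <- which(rowSums(alt > depth) > 0)
  if (length(bad))
    stop(sprintf("alt reads exceed depth at data row %d (mut_id %s)",
                 bad[1], dt$mut_id[bad[1]]))
  tp <- rep("post", length(regions))
  if (!is.null(manifest_path)) {
    mf <- data.table::fread(manifest_path, sep = "\t", data.table = FALSE)
    if (!all(c("region", "timepoint") %in% names(mf)))
      stop("manifest needs columns 'region' and 'timepoint'")
    idx <- match(regions, mf$region)
    if (any(is.na(idx)))
      stop("manifest missing regions: ",
           paste(regions[is.na(idx)], collapse = ", "))
    tp <- mf$timepoint[idx]
  }
  ann_cols <- intersect(c("mut_id", "chrom", "pos", "ref", "alt"), names(dt))
  ann_cols <- setdiff(ann_cols, "alt")  # 'alt' is the allele only if character
  if ("alt" %in% names(dt) && is.character(dt$alt)) ann_cols <- c(ann_cols, "alt")
  mutation_table(ccf, depth, alt, timepoints = tp,
                 mutations = dt[ann_cols])
}

#' Read a multi-sample VCF into a VAF-level mutation table
#'
#' Minimal ingestion path for variant-caller output: per sample, variant and
#' total read counts are taken from the `AD` (allelic depths) FORMAT field,
#' giving VAFs only. The returned table sets CCF = 2 x VAF clipped to
#' `[0, 1.5]` (pure diploid heterozygous assumption); for impure or
#' copy-number-altered samples, recompute CCFs with [ccf_from_vaf()] before
#' running statistics. Only biallelic SNVs are kept.
#'
#' @param path path to an (uncompressed or bgzipped) VCF with an `AD` FORMAT
#'   field.
#' @param timepoints optional `pre`/`post` tags, one per VCF sample column.
#' @return a [mutation_table()] with one region per VCF sample.
#' @export
read_vcf_table <- function(path, timepoints = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
  split_ad <- function(x, i) {
    out <- suppressWarnings(as.numeric(vapply(strsplit(x, ","),
                                              `[`, character(1), i)))
    out[is.na(out)] <- 0
    out
  }
  ref_n <- matrix(apply(ad, 2, split_ad, 1), nrow = nrow(ad))
  alt_n <- matrix(apply(ad, 2, split_ad, 2), nrow = nrow(ad))
  depth <- ref_n + alt_n
  vaf <- ifelse(depth > 0, alt_n / depth, 0)
  ids <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"], "_",
                fix[keep, "REF"], ">", fix[keep, "ALT"])
  ccf <- pmin(2 * vaf, 1.5)
  dimnames(ccf) <- dimnames(depth) <- list(ids, colnames(ad))
  mutation_table(ccf, depth, matrix(alt_n, nrow(ccf), ncol(ccf),
                                    dimnames = dimnames(ccf)),
                 timepoints = timepoints,
                 mutations = data.frame(
                   mut_id = ids,
                   chrom = fix[keep, "CHROM"],
                   pos = as.integer(fix[keep, "POS"]),
                   ref = fix[keep, "REF"],
                   alt = fix[keep, "ALT"],
                   stringsAsFactors = FALSE))
}

#' Write a mutation table to TSV
#'
#' Inverse of [read_mutation_table()]; writes the shared triplet dialect so
#' that simulator output, synthetic fixtures and real data interoperate.
#'
#' @param table a [mutation_table()].
#' @param path output TSV path.
#' @param manifest_path optional path for the region manifest.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(table, path, manifest_path = NULL) {
  regions <- region_names(table)
  out <- table$mutations
  for (r in regions) {
    out[[paste0("ccf_", r)]] <- table$ccf[, r]
    out[[paste0("depth_", r)]] <- table$depth[, r]
    out[[paste0("alt_", r)]] <- table$alt_reads[, r]
  }
  data.table::fwrite(out, path, sep = "\t")
  if (!is.null(manifest_path))
    data.table::fwrite(table$regions, manifest_path, sep = "\t")
  invisible(path)
}
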