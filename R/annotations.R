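# Coordinate convention used throughout: intervals are BED-style 0-based
# half-open [start, end); SNP positions are 1-based. A SNP at position p lies
# inside [start, end) iff start <= p-1 < end, i.e. the 1-based closed interval
# [start+1, end] contains p.

intervals_to_gr <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = as.character(iv$chrom),
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
}

gr_to_intervals <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start), , drop = FALSE]
}

snps_to_gr <- function(snps) {
  GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
}

validate_intervals <- function(iv) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(iv)))
    stop("intervals need columns chrom, start, end", call. = FALSE)
  if (any(iv$start >= iv$end))
    stop("invalid interval: start >= end", call. = FALSE)
  if (any(iv$start < 0))
    stop("invalid interval: negative start", call. = FALSE)
  invisible(iv)
}

#' Merge interval sets into one normalized annotation
#'
#' Takes one or several BED-style interval tables (0-based half-open) and
#' returns their union with overlapping and book-ended intervals coalesced,
#' sorted by chromosome then start. This is the operation used to pool
#' developmental-stage-specific enhancer maps into a single annotation.
#'
#' @param interval_sets A data frame with columns chrom/start/end, or a list
#'   of such data frames.
#' @return A normalized interval data frame (chrom, start, end).
#' @examples
#' merge_intervals(list(
#'   data.frame(chrom = "1", start = 100, end = 200),
#'   data.frame(chrom = "1", start = 150, end = 250)
#' ))
#' @export
merge_intervals <- function(interval_sets) {
  if (is.data.frame(interval_sets)) interval_sets <- list(interval_sets)
  stopifnot(length(interval_sets) >= 1)
  iv <- do.call(rbind, lapply(interval_sets, function(x) {
    validate_intervals(x)
    x[, c("chrom", "start", "end"), drop = FALSE]
  }))
  gr <- GenomicRanges::reduce(intervals_to_gr(iv))
  out <- gr_to_intervals(gr)
  rownames(out) <- NULL
  out
}

resolve_membership_one <- function(category, snps) {
  memb <- rep(FALSE, nrow(snps))
  if (!is.null(category$intervals) && nrow(category$intervals)) {
    iv <- merge_intervals(category$intervals)
    hits <- GenomicRanges::findOverlaps(snps_to_gr(snps), intervals_to_gr(iv))
    memb[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  if (!is.null(category$snp_ids) && length(category$snp_ids))
    memb <- memb | snps$id %in% category$snp_ids
  memb
}

#' Build an annotation set resolved against a reference SNP list
#'
#' Each named category is defined by genomic intervals (BED 0-based
#' half-open), a SNP-id list, or both; membership of a SNP is interval
#' containment OR id listing. Intervals are normalized (merged, sorted) on
#' construction.
#'
#' @param categories Named list; each element a list with optional components
#'   `intervals` (data frame chrom/start/end) and `snp_ids` (character).
#' @param reference SNP metadata data frame with columns id, chrom, pos
#'   (e.g. `panel$snps`).
#' @return An `annotation_set` with components `categories`, `reference`,
#'   and `membership` (logical SNP x category matrix).
#' @export
annotation_set <- function(categories, reference) {
  stopifnot(is.list(categories), length(categories) >= 1,
            !is.null(names(categories)), all(nzchar(names(categories))))
  stopifnot(all(c("id", "chrom", "pos") %in% names(reference)))
  categories <- lapply(categories, function(cat) {
    if (!is.null(cat$intervals) && nrow(cat$intervals))
      cat$intervals <- merge_intervals(cat$intervals)
    cat
  })
  memb <- vapply(categories, resolve_membership_one,
                 logical(nrow(reference)), snps = reference)
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = nrow(reference))
  rownames(memb) <- reference$id
  colnames(memb) <- names(categories)
  structure(list(categories = categories,
                 reference = reference[, c("id", "chrom", "pos")],
                 membership = memb),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d categories over %d reference SNPs\n",
              ncol(x$membership), nrow(x$membership)))
  for (nm in colnames(x$membership))
    cat(sprintf("  %-20s %6d SNPs (%.2f%%)\n", nm, sum(x$membership[, nm]),
                100 * mean(x$membership[, nm])))
  invisible(x)
}

#' Membership matrix of an annotation set
#'
#' @param annotations An `annotation_set`.
#' @param ids Optional SNP ids to subset/reorder rows; must all be present.
#' @return Logical SNP x category matrix.
#' @export
annotation_membership <- function(annotations, ids = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  m <- annotations$membership
  if (is.null(ids)) return(m)
  idx <- match(ids, rownames(m))
  if (anyNA(idx)) stop("unknown SNP ids in membership lookup", call. = FALSE)
  m[idx, , drop = FALSE]
}

#' Expand a SNP set by linkage disequilibrium
#'
#' Returns the input SNPs plus every panel SNP whose squared dosage
#' correlation with any input SNP meets the threshold, searching within a
#' physical window. Two threshold conventions are supported in one code path,
#' matching the two curation uses: `r2_min = 1` means perfect proxies
#' (r2 >= 1, with numerical tolerance), while `r2_min < 1` is strict
#' (r2 > r2_min), as in haplotype removal at r2 > 0.6.
#'
#' @param snp_ids Character vector of seed SNP ids (must exist in the panel).
#' @param panel A `genotype_panel`.
#' @param r2_min LD threshold in `(0, 1]`.
#' @param window Physical search window in bp (default 1 Mb).
#' @return Character vector of SNP ids in panel order (superset of the input).
#' @export
ld_expand <- function(snp_ids, panel, r2_min, window = 1e6) {
  stopifnot(r2_min > 0, r2_min <= 1)
  ids <- panel$snps$id
  unknown <- setdiff(snp_ids, ids)
  if (length(unknown))
    stop("unknown SNP ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!length(snp_ids)) return(character(0))
  pos <- panel$snps$pos; chrom <- panel$snps$chrom
  strict <- r2_min < 1 - 1e-12
  hits <- logical(length(ids))
  hits[match(snp_ids, ids)] <- TRUE
  for (id in snp_ids) {
    j <- match(id, ids)
    K <- which(chrom == chrom[j] & abs(pos - pos[j]) <= window)
    r <- suppressWarnings(as.numeric(
      stats::cor(panel$dosages[, j], panel$dosages[, K, drop = FALSE])))
    r2 <- r^2
    r2[is.na(r2)] <- 0
    sel <- if (strict) r2 > r2_min else r2 >= r2_min - 1e-9
    hits[K[sel]] <- TRUE
  }
  ids[hits]
}

#' Refine an archaic-desert annotation by removing introgressed haplotypes
#'
#' Membership starts from all SNPs inside the desert intervals, then removes
#' introgressed SNPs located inside the deserts together with every SNP in LD
#' (r2 > `r2_exclude`) with them. The interval geometry is kept as metadata;
#' the exclusion is expressed at SNP level, so the returned category is
#' SNP-list based.
#'
#' @param deserts Interval data frame (chrom, start, end), 0-based half-open.
#' @param introgressed Character vector of introgressed SNP ids.
#' @param panel A `genotype_panel` providing positions and LD.
#' @param r2_exclude Strict LD threshold for haplotype removal (default 0.6).
#' @param window LD search window in bp.
#' @return A category list with `snp_ids` (members), `source_intervals`
#'   (normalized deserts) and `excluded_snp_ids`, usable in [annotation_set()].
#' @export
refine_deserts <- function(deserts, introgressed, panel,
                           r2_exclude = 0.6, window = 1e6) {
  deserts <- merge_intervals(deserts)
  inside <- panel$snps$id[resolve_membership_one(list(intervals = deserts),
                                                 panel$snps)]
  intro_in <- intersect(introgressed, inside)
  excl <- if (length(intro_in))
    ld_expand(intro_in, panel, r2_min = r2_exclude, window = window)
  else character(0)
  members <- setdiff(inside, excl)
  list(snp_ids = members,
       source_intervals = deserts,
       excluded_snp_ids = intersect(excl, inside))
}

#' SNP coverage of an annotation category against a reference list
#'
#' Computes the fraction of reference SNPs belonging to the category and
#' whether it meets the minimum-coverage rule used to admit annotations into
#' partitioned-heritability analysis (default: at least 1% of the
#' well-imputed, QC-passed reference SNPs).
#'
#' @param category A category list (`intervals` and/or `snp_ids`), as stored
#'   in an `annotation_set`.
#' @param reference SNP metadata data frame (id, chrom, pos) of QC-passed
#'   reference SNPs.
#' @param threshold Minimum admissible fraction (default 0.01); the rule is
#'   `fraction >= threshold`.
#' @return A `coverage_report` list: n_snps_in, n_reference, fraction,
#'   passes_threshold.
#' @export
snp_coverage <- function(category, reference, threshold = 0.01) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("empty reference SNP list", call. = FALSE)
  memb <- resolve_membership_one(category, reference)
  n_in <- sum(memb)
  frac <- n_in / nrow(reference)
  structure(list(n_snps_in = n_in, n_reference = nrow(reference),
                 fraction = frac, passes_threshold = frac >= threshold),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %d / %d reference SNPs (%.4f%%) -> %s\n",
              x$n_snps_in, x$n_reference, 100 * x$fraction,
              if (x$passes_threshold) "PASS" else "FAIL"))
  invisible(x)
}

#' Read / write BED interval files
#'
#' Minimal 3+-column BED support (chrom, start, end; extra columns ignored on
#' read, a name column written when present). Coordinates are kept 0-based
#' half-open.
#'
#' @param path File path.
#' @return `read_bed` returns an interval data frame.
#' @export
read_bed <- function(path) {
  iv <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(iv[[1]]), start = as.integer(iv[[2]]),
                    end = as.integer(iv[[3]]), stringsAsFactors = FALSE)
  validate_intervals(out)
  out
}

#' @rdname read_bed
#' @param intervals Interval data frame (chrom, start, end, optional name).
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write plain-text SNP lists (one id per line)
#' @param path File path.
#' @return `read_snp_list` returns a character vector.
#' @export
read_snp_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_snp_list
#' @param ids Character vector of SNP ids.
#' @export
write_snp_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
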