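#' LD clumping of genome-wide significant SNPs into loci
#'
#' Greedy clumping: repeatedly take the unassigned SNP with the smallest
#' p-value below `p_max` as a lead (ties broken by ascending genomic
#' position, making the result invariant to input row order), assign every
#' panel SNP within the physical window whose squared dosage correlation
#' with the lead exceeds `r2_min` to its locus, and continue until no
#' significant SNP is unassigned. Loci sharing any member are merged, after
#' which the lead is the member with the smallest p-value. Locus spans are
#' reported 0-based half-open, covering the member positions with no
#' padding.
#'
#' @param stats A `sumstats` data frame (SNPs present in the panel).
#' @param panel A `genotype_panel` providing LD.
#' @param p_max Significance threshold (default the genome-wide 5e-8).
#' @param r2_min Strict LD threshold for membership (default 0.6).
#' @param window Physical search window in bp around the lead.
#' @return A `locus_set`: data frame with one row per locus (lead_snp,
#'   p_lead, chrom, start, end, n_members) plus a `members` list-column of
#'   SNP ids. Empty (zero rows) when no SNP passes `p_max`.
#' @export
clump_loci <- function(stats, panel, p_max = 5e-8, r2_min = 0.6,
                       window = 1e6) {
  idx <- match(stats$id, panel$snps$id)
  if (anyNA(idx)) stop("stats contain SNPs absent from the panel", call. = FALSE)

  sig <- which(stats$p < p_max & !stats$missing)
  empty <- data.frame(lead_snp = character(0), p_lead = numeric(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  class(empty) <- c("locus_set", "data.frame")
  if (!length(sig)) return(empty)

  pos <- panel$snps$pos[idx]
  chrom <- panel$snps$chrom[idx]
  assigned <- rep(FALSE, nrow(stats))
  loci <- list()
  ord <- sig[order(stats$p[sig], pos[sig])]
  for (j in ord) {
    if (assigned[j]) next
    near <- which(chrom == chrom[j] & abs(pos - pos[j]) <= window)
    r <- suppressWarnings(as.numeric(stats::cor(
      panel$dosages[, idx[j]], panel$dosages[, idx[near], drop = FALSE])))
    r2 <- r^2; r2[is.na(r2)] <- 0
    members <- union(j, near[r2 > r2_min])
    assigned[members] <- TRUE
    loci[[length(loci) + 1]] <- members
  }

  # merge loci sharing any member
  merged <- list()
  for (mem in loci) {
    hit <- which(vapply(merged, function(m) length(intersect(m, mem)) > 0,
                        logical(1)))
    if (length(hit)) {
      mem <- Reduce(union, merged[hit], mem)
      merged[hit] <- NULL
    }
    merged[[length(merged) + 1]] <- mem
  }

  rows <- lapply(merged, function(mem) {
    mem <- mem[order(pos[mem])]
    lead <- mem[order(stats$p[mem], pos[mem])][1]
    data.frame(lead_snp = stats$id[lead], p_lead = stats$p[lead],
               chrom = chrom[lead],
               start = min(pos[mem]) - 1L, end = max(pos[mem]),
               n_members = length(mem), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(merged, function(mem) stats$id[mem[order(pos[mem])]])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("locus_set", "data.frame")
  out
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d loci\n", nrow(x)))
  if (nrow(x))
    print.data.frame(x[, c("lead_snp", "p_lead", "chrom", "start", "end",
                           "n_members")], row.names = FALSE)
  invisible(x)
}

#' Overlap loci with interval annotations
#'
#' Reports every (locus, category, interval) triple whose half-open
#' intersection is non-empty, plus per-category counts of overlapping loci
#' (a locus counts once per category however many intervals it touches).
#'
#' @param loci A `locus_set` from [clump_loci()].
#' @param intervals Named list of interval data frames (chrom, start, end;
#'   0-based half-open), one per category (e.g. HARs, AMH-derived DMRs).
#' @return A list with `records` (locus_id, lead_snp, category, interval
#'   chrom/start/end) and `counts` (category, n_loci).
#' @export
overlap_annotations <- function(loci, intervals) {
  stopifnot(is.list(intervals), !is.null(names(intervals)))
  recs <- list()
  counts <- data.frame(category = names(intervals),
                       n_loci = 0L, stringsAsFactors = FALSE)
  if (nrow(loci)) {
    loci_gr <- intervals_to_gr(loci[, c("chrom", "start", "end")])
    for (k in seq_along(intervals)) {
      iv <- intervals[[k]]
      validate_intervals(iv)
      hits <- GenomicRanges::findOverlaps(loci_gr, intervals_to_gr(iv))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      if (length(qh))
        recs[[length(recs) + 1]] <- data.frame(
          locus_id = qh, lead_snp = loci$lead_snp[qh],
          category = names(intervals)[k],
          chrom = iv$chrom[sh], start = iv$start[sh], end = iv$end[sh],
          stringsAsFactors = FALSE)
      counts$n_loci[k] <- length(unique(qh))
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(locus_id = integer(0), lead_snp = character(0),
               category = character(0), chrom = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  list(records = records, counts = counts)
}

#' Convert an allele age in generations to millions of years
#'
#' Multiplies by the generation time and divides by one million, rounding to
#' one decimal for reporting — the convention for quoting dated
#' polymorphisms (e.g. 47,675 generations at 25 y/generation is ~1.2 Ma).
#'
#' @param generations Non-negative number of generations.
#' @param years_per_generation Generation time in years (default 25).
#' @return Age in millions of years (Ma), rounded to one decimal.
#' @examples
#' generations_to_mya(47675)  # 1.2
#' @export
generations_to_mya <- function(generations, years_per_generation = 25) {
  if (any(generations < 0)) stop("generations must be non-negative", call. = FALSE)
  round(generations * years_per_generation / 1e6, 1)
}
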