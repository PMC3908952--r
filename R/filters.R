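#' PV4 bias statistics for a pileup
#'
#' Four p-values probing whether alternate-supporting reads look
#' systematically different from reference-supporting reads, the classic
#' signatures of alignment and sequencing artifacts:
#' \itemize{
#'   \item strand bias: two-sided Fisher exact test on the 2x2 table of
#'     (ref, alt) x (+, -) read counts;
#'   \item base-quality, mapping-quality and tail-distance bias:
#'     two-sided Welch t-tests comparing the respective per-read values
#'     between the reference- and alternate-supporting reads.  Tail
#'     distance is the distance from the nearer read end; mismatches
#'     piling up at read tails indicate misalignment.
#' }
#' Any t-test group with fewer than 2 reads, or with zero variance on
#' both sides and equal means, yields p = 1 (no evidence of bias).
#'
#' @param site A [site_pileup()].
#' @param alt_allele The alternate allele.
#' @return Named numeric vector `(strand, baseq, mapq, tail)`.
#' @export
pv4 <- function(site, alt_allele) {
  is_ref <- site$allele == site$ref_allele
  is_alt <- site$allele == alt_allele
  dp4 <- pileup_dp4(site, alt_allele)
  strand_p <- if (sum(dp4[1:2]) >= 1 && sum(dp4[3:4]) >= 1)
    stats::fisher.test(matrix(dp4, nrow = 2, byrow = TRUE))$p.value
  else 1
  welch <- function(x, y) {
    if (length(x) < 2 || length(y) < 2) return(1)
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y)$p.value
  }
  c(strand = min(strand_p, 1),
    baseq = welch(site$base_quality[is_ref], site$base_quality[is_alt]),
    mapq = welch(site$mapping_quality[is_ref],
                 site$mapping_quality[is_alt]),
    tail = welch(site$tail_dist[is_ref], site$tail_dist[is_alt]))
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness-of-fit (1 df) of observed genotype counts against
#' the Hardy-Weinberg expectation at the estimated allele frequency
#' `f = (n01 + 2 n11) / (2 n)`.  With at most one individual, or a
#' monomorphic site, the test is vacuous and returns 1.  Strong HWE
#' departure across samples flags systematic artifacts rather than real
#' polymorphism.
#'
#' @param counts Integer triple `(n00, n01, n11)` of genotype counts.
#' @return Two-sided p-value.
#' @examples
#' hwe_p(c(0, 3, 0))   # chi-square 3, p ~ 0.0833
#' @export
hwe_p <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n <= 1) return(1)
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (f == 0 || f == 1) return(1)
  expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Homopolymer adjacency test
#'
#' TRUE when a single-base run of at least `min_len` bases overlaps the
#' window `[site_offset - adjacency, site_offset + adjacency]` of the
#' reference context.  Variants inside or next to homopolymers are
#' enriched for alignment slippage artifacts.
#'
#' @param ref_context Reference bases around the site (a string).
#' @param site_offset 1-based offset of the site within `ref_context`.
#' @param min_len Minimum run length counting as a homopolymer; default 5.
#' @param adjacency Number of flanking bases that still count as
#'   "adjacent"; default 1.
#' @return Logical.
#' @examples
#' homopolymer_adjacent("TTAAAAAG", 8)    # TRUE: AAAAA run next to the G
#' homopolymer_adjacent("ACGTACGTA", 5)   # FALSE
#' @export
homopolymer_adjacent <- function(ref_context, site_offset, min_len = 5,
                                 adjacency = 1) {
  n <- nchar(ref_context)
  if (site_offset < 1 || site_offset > n)
    stop("site_offset outside the reference context")
  bases <- strsplit(ref_context, "")[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lo <- site_offset - adjacency
  hi <- site_offset + adjacency
  any(r$lengths >= min_len & starts <= hi & ends >= lo)
}

#' Hard-filter configuration
#'
#' Thresholds for the two filtering tiers.  Tier 1 (moderate): variant
#' quality Phred >= 10 (90% call accuracy), total depth >= 4, >= 2
#' alternate reads, strand-bias p >= 1e-4, base-quality-bias p >= 1e-100,
#' tail-bias p >= 1e-4, HWE p >= 1e-4, and exclusion of sites within or
#' adjacent to homopolymers >= 5 bp or masked repeats.  Tier 2
#' (stringent): >= 3 alternate reads with at least one on each strand,
#' all four bias p-values >= 0.01, and exclusion of genes flagged for
#' excessive spurious mutation calls.
#'
#' @param tier 1 or 2.
#' @param min_qual,min_dp,min_alt,strand_p,baseq_p,mapq_p,tail_p,hwe_p
#'   Threshold overrides; defaults depend on `tier`.
#' @param alt_on_both_strands Require >= 1 alternate read per strand
#'   (tier 2 default TRUE).
#' @param homopolymer_len Homopolymer run length triggering exclusion.
#' @param repeat_mask Optional data.frame of masked intervals with
#'   columns `chrom, start, end` (BED-style 0-based half-open), e.g.
#'   from [read_bed()].
#' @param flagged_genes Character vector of genes excluded in tier 2.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(tier = 1, min_qual = NULL, min_dp = NULL,
                          min_alt = NULL, strand_p = NULL, baseq_p = NULL,
                          mapq_p = NULL, tail_p = NULL, hwe_p = NULL,
                          alt_on_both_strands = NULL,
                          homopolymer_len = 5, repeat_mask = NULL,
                          flagged_genes = character(0)) {
  stopifnot(tier %in% c(1, 2))
  d <- if (tier == 1)
    list(min_qual = 10, min_dp = 4, min_alt = 2, strand_p = 1e-4,
         baseq_p = 1e-100, mapq_p = 0, tail_p = 1e-4, hwe_p = 1e-4,
         alt_on_both_strands = FALSE)
  else
    list(min_qual = 0, min_dp = 0, min_alt = 3, strand_p = 0.01,
         baseq_p = 0.01, mapq_p = 0.01, tail_p = 0.01, hwe_p = 0,
         alt_on_both_strands = TRUE)
  override <- list(min_qual = min_qual, min_dp = min_dp, min_alt = min_alt,
                   strand_p = strand_p, baseq_p = baseq_p, mapq_p = mapq_p,
                   tail_p = tail_p, hwe_p = hwe_p,
                   alt_on_both_strands = alt_on_both_strands)
  for (k in names(override)) if (!is.null(override[[k]])) d[[k]] <- override[[k]]
  ps <- unlist(d[c("strand_p", "baseq_p", "mapq_p", "tail_p", "hwe_p")])
  if (any(ps < 0 | ps > 1)) stop("probability thresholds must be in [0, 1]")
  structure(c(list(tier = tier, homopolymer_len = homopolymer_len,
                   repeat_mask = repeat_mask,
                   flagged_genes = flagged_genes), d),
            class = "filter_config")
}

#' Read a BED repeat mask
#'
#' Minimal three-column BED reader (chrom, start, end; 0-based half-open
#' intervals), for repeat masks consumed by the tier-1 filter.
#'
#' @param file Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df
}

in_repeat_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || !nrow(mask)) return(FALSE)
  any(mask$chrom == chrom & pos > mask$start & pos <= mask$end)
}

#' Apply a hard-filter tier to one variant record
#'
#' Evaluates every criterion of the configured tier against a variant
#' record and optional site context; the two tiers are independent (a
#' record can pass tier 1 and fail tier 2).  Returns the verdict together
#' with the list of failed criteria.
#'
#' @param record A one-row variant table ([variant_record()]).
#' @param config A [filter_config()].
#' @param context Optional list with any of: `ref_context` and
#'   `site_offset` (for the homopolymer test), `genotype_counts`
#'   (n00, n01, n11 across samples, for the HWE test).
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
apply_tier <- function(record, config, context = list()) {
  for (field in c("qual", "dp", "dp4_rf", "dp4_rr", "dp4_af", "dp4_ar",
                  "pv4_strand", "pv4_baseq", "pv4_mapq", "pv4_tail"))
    if (is.null(record[[field]]) || is.na(record[[field]]))
      stop("variant record lacks required field '", field, "'")
  reasons <- character(0)
  fail <- function(cond, why) if (cond) reasons <<- c(reasons, why)
  alt <- record$dp4_af + record$dp4_ar
  fail(record$qual < config$min_qual, "min_qual")
  fail(record$dp < config$min_dp, "min_dp")
  fail(alt < config$min_alt, "min_alt")
  fail(config$alt_on_both_strands &&
         (record$dp4_af < 1 || record$dp4_ar < 1), "alt_both_strands")
  fail(record$pv4_strand < config$strand_p, "strand_bias")
  fail(record$pv4_baseq < config$baseq_p, "baseq_bias")
  fail(record$pv4_mapq < config$mapq_p, "mapq_bias")
  fail(record$pv4_tail < config$tail_p, "tail_bias")
  if (!is.null(context$genotype_counts))
    fail(hwe_p(context$genotype_counts) < config$hwe_p, "hwe")
  if (config$tier == 1) {
    if (!is.null(context$ref_context))
      fail(homopolymer_adjacent(context$ref_context, context$site_offset,
                                config$homopolymer_len), "homopolymer")
    fail(in_repeat_mask(record$chrom, record$pos, config$repeat_mask),
         "repeat_mask")
  }
  if (config$tier == 2 && !is.na(record$gene))
    fail(record$gene %in% config$flagged_genes, "flagged_gene")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Annotate a variant table with a filter tier
#'
#' Runs [apply_tier()] over every row, writing "PASS" or the
#' semicolon-joined failure reasons into the `filter` column.
#'
#' @param records A variant table.
#' @inheritParams apply_tier
#' @return The annotated variant table.
#' @export
filter_variants <- function(records, config, context = list()) {
  if (!nrow(records)) return(records)
  records$filter <- vapply(seq_len(nrow(records)), function(i) {
    res <- apply_tier(records[i, ], config, context)
    if (res$pass) "PASS" else paste(res$reasons, collapse = ";")
  }, "")
  records
}

#' Genes with novel variants recurring across samples
#'
#' Counts, for each gene, the number of distinct samples that carry at
#' least one passing novel variant in it, and reports the genes reaching
#' `min_samples`.  Recurrence of novel variants in the same gene across
#' unrelated patients is the downstream prioritization signal for a
#' shared causal gene.
#'
#' @param tables Named list of per-sample data.frames, each with columns
#'   `gene` and `novel` (logical).  Names are the sample identifiers.
#' @param min_samples Minimum number of samples a gene must recur in.
#' @return data.frame with columns `gene`, `n_samples`, sorted by
#'   descending count then gene name.
#' @export
recurrent_genes <- function(tables, min_samples = 2) {
  if (length(tables) &&
      (is.null(names(tables)) || any(!nzchar(names(tables)))))
    names(tables) <- paste0("S", seq_along(tables))
  pairs <- unique(do.call(rbind, lapply(names(tables), function(s) {
    df <- tables[[s]]
    if (is.null(df) || !nrow(df)) return(NULL)
    keep <- !is.na(df$novel) & df$novel & !is.na(df$gene)
    if (!any(keep)) return(NULL)
    data.frame(sample = s, gene = unique(df$gene[keep]),
               stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(gene = character(0), n_samples = integer(0)))
  cnt <- table(pairs$gene)
  out <- data.frame(gene = names(cnt), n_samples = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out <- out[order(-out$n_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
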