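## SAM text parsing, pileup construction and the pileup TSV dialect.
## Coordinates are 1-based inclusive (SAM/VCF convention); query offsets
## are 0-based internally.

SAM_FLAG_UNMAPPED  <- 0x4L
SAM_FLAG_REVERSE   <- 0x10L
SAM_FLAG_SECONDARY <- 0x100L
SAM_FLAG_QCFAIL    <- 0x200L
SAM_FLAG_DUP       <- 0x400L

#' Construct a single aligned-read record
#'
#' A `read_record` holds one SAM alignment line: name, bitwise flag,
#' reference name, 1-based leftmost mapped position, mapping quality,
#' CIGAR, base string, per-base Phred qualities and the optional MD tag.
#' Reads flagged unmapped, secondary, QC-fail or duplicate are marked
#' `exclude = TRUE` so that pileup construction skips them (duplicate
#' removal itself is assumed to have happened upstream).
#'
#' @param name Read name.
#' @param flag Integer SAM flag bitfield.
#' @param chrom Reference sequence name.
#' @param pos 1-based leftmost mapped position.
#' @param mapq Phred-scaled mapping quality.
#' @param cigar CIGAR string; only operations M/=/X/I/D/N/S/H are understood.
#' @param seq Base string (A/C/G/T/N).
#' @param quals Integer vector of per-base Phred qualities, one per base.
#' @param md Optional MD tag value (the part after `MD:Z:`), or `NA`.
#' @return An object of class `read_record`.
#' @export
read_record <- function(name, flag, chrom, pos, mapq, cigar, seq, quals,
                        md = NA_character_) {
  flag <- as.integer(flag)
  if (nchar(seq) != length(quals))
    stop("read '", name, "': length(seq) != length(quals)")
  ops <- parse_cigar(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  if (qlen != nchar(seq))
    stop("read '", name, "': CIGAR query length (", qlen,
         ") != length(seq) (", nchar(seq), ")")
  if (!is.na(md) && !md_consistent(md, ops))
    stop("read '", name, "': MD tag inconsistent with CIGAR")
  structure(list(
    name = name, flag = flag, chrom = chrom, pos = as.integer(pos),
    mapq = as.numeric(mapq), cigar = cigar, seq = seq,
    quals = as.integer(quals), md = md,
    is_reverse = bitwAnd(flag, SAM_FLAG_REVERSE) != 0L,
    exclude = bitwAnd(flag, SAM_FLAG_UNMAPPED + SAM_FLAG_SECONDARY +
                        SAM_FLAG_QCFAIL + SAM_FLAG_DUP) != 0L
  ), class = "read_record")
}

## CIGAR -> data.frame(len, op)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(data.frame(len = integer(0), op = character(0)))
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^[0-9]+", "", toks),
             stringsAsFactors = FALSE)
}

## reference length consumed by a CIGAR
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])

## MD tag grammar: [0-9]+(([A-Z]|\^[A-Z]+)[0-9]+)* ; the match counts plus
## mismatch/deletion bases must consume exactly the reference span of the
## CIGAR (insertions and clips are invisible to MD).
md_consistent <- function(md, ops) {
  if (!grepl("^[0-9]+(([A-Z]|\\^[A-Z]+)[0-9]+)*$", md)) return(FALSE)
  nums <- as.integer(regmatches(md, gregexpr("[0-9]+", md))[[1]])
  mism <- regmatches(md, gregexpr("(?<![\\^A-Z])[A-Z]", md, perl = TRUE))[[1]]
  dels <- regmatches(md, gregexpr("\\^[A-Z]+", md))[[1]]
  span <- sum(nums) + length(mism) + sum(nchar(dels) - 1L)
  span == cigar_ref_len(ops)
}

#' Reconstruct the aligned reference and re-derive the MD tag
#'
#' `md_reference(read)` rebuilds the reference bases consumed by the read's
#' alignment from its `seq`, CIGAR and MD tag (matches copy the read base,
#' MD mismatch letters and `^`-deletions supply the reference base).
#' `md_rederive(read)` recomputes the MD string by comparing `seq` against
#' that reconstruction; for a well-formed read it reproduces the original
#' MD tag exactly.
#'
#' @param read A [read_record()] carrying an MD tag.
#' @return `md_reference`: character vector of reference bases, one per
#'   reference position consumed; `md_rederive`: an MD string.
#' @export
md_reference <- function(read) {
  if (is.na(read$md)) stop("read '", read$name, "' has no MD tag")
  ops <- parse_cigar(read$cigar)
  toks <- regmatches(read$md,
                     gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", read$md))[[1]]
  # query bases under ref-consuming ops, in reference order
  bases <- strsplit(read$seq, "")[[1]]
  qb <- character(0); qoff <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      qb <- c(qb, bases[qoff + seq_len(len)]); qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      qb <- c(qb, rep(NA_character_, len))    # deletion: no query base
    } else if (op %in% c("I", "S")) qoff <- qoff + len
  }
  ref <- character(length(qb)); rpos <- 0L
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      n <- as.integer(tok)
      if (n > 0L) {
        ref[rpos + seq_len(n)] <- qb[rpos + seq_len(n)]
        rpos <- rpos + n
      }
    } else if (startsWith(tok, "^")) {
      del <- strsplit(substring(tok, 2), "")[[1]]
      ref[rpos + seq_along(del)] <- del
      rpos <- rpos + length(del)
    } else {
      rpos <- rpos + 1L
      ref[rpos] <- tok
    }
  }
  ref
}

#' @rdname md_reference
#' @export
md_rederive <- function(read) {
  ref <- md_reference(read)
  ops <- parse_cigar(read$cigar)
  bases <- strsplit(read$seq, "")[[1]]
  out <- ""; run <- 0L; qoff <- 0L; rpos <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        rpos <- rpos + 1L
        b <- bases[qoff + j]
        if (identical(b, ref[rpos])) run <- run + 1L
        else { out <- paste0(out, run, ref[rpos]); run <- 0L }
      }
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      out <- paste0(out, run, "^",
                    paste(ref[rpos + seq_len(len)], collapse = ""))
      run <- 0L; rpos <- rpos + len
    } else if (op %in% c("I", "S")) qoff <- qoff + len
  }
  paste0(out, run)
}

#' Parse SAM text into read records
#'
#' Accepts raw SAM text (header lines optional, ignored) and returns one
#' [read_record()] per alignment line.  Unmapped, secondary, QC-fail and
#' duplicate-flagged reads are kept but marked for exclusion, mirroring the
#' preprocessing of a standard exome pipeline.
#'
#' @param text SAM text: a single string or a character vector of lines.
#' @return List of `read_record` objects.
#' @export
parse_sam <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "@")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop("SAM parse error at alignment line ", i, ": expected >= 11 ",
           "tab-separated columns, got ", length(f))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.numeric(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stop("SAM parse error at alignment line ", i,
           ": non-numeric FLAG, POS or MAPQ")
    md <- NA_character_
    if (length(f) > 11) {
      tags <- f[12:length(f)]
      hit <- tags[startsWith(tags, "MD:Z:")]
      if (length(hit)) md <- substring(hit[1], 6)
    }
    quals <- if (f[11] == "*") rep(0L, nchar(f[10])) else
      utf8ToInt(f[11]) - 33L
    out[[i]] <- read_record(name = f[1], flag = flag, chrom = f[3],
                            pos = pos, mapq = mapq, cigar = f[6],
                            seq = f[10], quals = quals, md = md)
  }
  out
}

#' Construct a per-site pileup
#'
#' A `site_pileup` collects every usable read observation overlapping one
#' genomic site for one sample: the data `D` that the genotype-likelihood
#' model conditions on.  Observations live in parallel vectors (allele,
#' base quality, mapping quality, strand and distance to the nearer read
#' end, the last feeding the tail-bias test).
#'
#' @param chrom,pos Site coordinate (1-based).
#' @param ref_allele Reference base, one of A/C/G/T.
#' @param sample_id Sample identifier.
#' @param allele Character vector of observed bases.
#' @param base_quality,mapping_quality Numeric Phred vectors.
#' @param strand Character vector of "+"/"-".
#' @param tail_dist Integer distances from the nearer read end.
#' @return Object of class `site_pileup`; `depth(x)` is `length(allele)`.
#' @export
site_pileup <- function(chrom, pos, ref_allele, sample_id = "S1",
                        allele = character(0),
                        base_quality = numeric(0),
                        mapping_quality = numeric(0),
                        strand = character(0),
                        tail_dist = integer(0)) {
  n <- length(allele)
  stopifnot(length(base_quality) == n, length(mapping_quality) == n,
            length(strand) == n, length(tail_dist) == n)
  if (n && !all(allele %in% c("A", "C", "G", "T")))
    stop("pileup alleles must be A/C/G/T")
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref_allele = ref_allele, sample_id = sample_id,
                 allele = allele, base_quality = as.numeric(base_quality),
                 mapping_quality = as.numeric(mapping_quality),
                 strand = strand, tail_dist = as.integer(tail_dist)),
            class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cat(sprintf("site_pileup %s:%d ref=%s sample=%s depth=%d\n",
              x$chrom, x$pos, x$ref_allele, x$sample_id, length(x$allele)))
  if (length(x$allele)) {
    tab <- table(x$allele)
    cat("  alleles:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

## depth helper
pileup_depth <- function(site) length(site$allele)

## DP4 = (ref+, ref-, alt+, alt-)
pileup_dp4 <- function(site, alt_allele) {
  r <- site$allele == site$ref_allele
  a <- site$allele == alt_allele
  p <- site$strand == "+"
  as.integer(c(sum(r & p), sum(r & !p), sum(a & p), sum(a & !p)))
}

#' Build a pileup at one site from aligned reads
#'
#' Walks each read's CIGAR to locate the query base aligned to `pos`.
#' Only reads whose operation at the site is an alignment match (M/=/X)
#' contribute; reads marked for exclusion (unmapped/secondary/QC-fail/
#' duplicate) are skipped, and reads with an unsupported operation at the
#' site are skipped with a warning.
#'
#' @param reads List of [read_record()]s.
#' @param chrom,pos Site coordinate (1-based).
#' @param ref_allele Reference base at the site.
#' @param sample_id Sample identifier stored in the pileup.
#' @return A [site_pileup()] with one observation per covering read.
#' @export
pileup_from_reads <- function(reads, chrom, pos, ref_allele,
                              sample_id = "S1") {
  allele <- character(0); bq <- numeric(0); mq <- numeric(0)
  strand <- character(0); tail <- integer(0)
  for (rd in reads) {
    if (rd$exclude || rd$chrom != chrom) next
    off <- query_offset_at(rd, pos)
    if (is.null(off)) next
    if (is.na(off)) {
      warning("read '", rd$name, "': unsupported CIGAR operation at site, ",
              "read skipped")
      next
    }
    len <- nchar(rd$seq)
    allele <- c(allele, substr(rd$seq, off + 1L, off + 1L))
    bq <- c(bq, rd$quals[off + 1L])
    mq <- c(mq, rd$mapq)
    strand <- c(strand, if (rd$is_reverse) "-" else "+")
    tail <- c(tail, min(off, len - 1L - off))
  }
  keep <- allele %in% c("A", "C", "G", "T")
  site_pileup(chrom, pos, ref_allele, sample_id,
              allele[keep], bq[keep], mq[keep], strand[keep],
              tail[keep])
}

## 0-based query offset of the base aligned to ref position pos;
## NULL if the read does not cover pos with any ref-consuming op,
## NA if it covers pos but not via M/=/X.
query_offset_at <- function(read, pos) {
  ops <- parse_cigar(read$cigar)
  rpos <- read$pos      # next reference position to consume
  qoff <- 0L            # next query offset to consume
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (pos >= rpos && pos < rpos + len) return(qoff + (pos - rpos))
      rpos <- rpos + len; qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      if (pos >= rpos && pos < rpos + len) return(NA_integer_)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    }                                      # H, P consume nothing
  }
  NULL
}

#' Read and write the pileup TSV dialect
#'
#' A minimal long-format table carrying one row per read observation:
#' columns `chrom, pos, ref, sample, allele, bq, mq, strand, tail_dist`.
#' It allows the caller to be driven without SAM input.
#'
#' @param file Path to a TSV file (with header).
#' @return `read_pileup_tsv` returns a list of [site_pileup()]s, one per
#'   distinct (chrom, pos, sample).
#' @export
read_pileup_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "sample", "allele", "bq", "mq",
            "strand", "tail_dist")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pileup TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(df$chrom, df$pos, df$sample, drop = TRUE)
  lapply(split(df, key), function(g)
    site_pileup(g$chrom[1], g$pos[1], g$ref[1], g$sample[1],
                g$allele, g$bq, g$mq, g$strand, g$tail_dist))
}

#' @rdname read_pileup_tsv
#' @param pileups List of [site_pileup()]s.
#' @export
write_pileup_tsv <- function(pileups, file) {
  rows <- lapply(pileups, function(s) {
    if (!length(s$allele)) return(NULL)
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref_allele,
               sample = s$sample_id, allele = s$allele, bq = s$base_quality,
               mq = s$mapping_quality, strand = s$strand,
               tail_dist = s$tail_dist, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
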