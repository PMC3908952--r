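#' Variant record table
#'
#' Variant calls are carried as a data.frame with one row per call and a
#' fixed column layout (a light-weight stand-in for a VCF body):
#' `chrom, pos, ref, alt, qual, genotype, gq, pl` (PL triple as
#' "a,b,c"), `dp`, `dp4_rf, dp4_rr, dp4_af, dp4_ar` (reference/alternate
#' reads on forward/reverse strands), `pv4_strand, pv4_baseq, pv4_mapq,
#' pv4_tail` (bias p-values), `gene`, `novel`, `filter`, `sample_id`.
#'
#' @param chrom,pos,ref,alt Site and alleles.
#' @param qual Phred-scaled variant quality (>= 0).
#' @param genotype Genotype string ("0/0", "0/1", "1/1").
#' @param gq Genotype quality (Phred integer).
#' @param pl Integer PL triple.
#' @param dp Total read depth; must equal `sum(dp4)`.
#' @param dp4 Integer quadruple (ref+, ref-, alt+, alt-).
#' @param pv4 Numeric quadruple of bias p-values
#'   (strand, base quality, mapping quality, tail distance), each in [0,1].
#' @param gene Optional gene symbol.
#' @param novel Optional logical: absent from the variant databases the
#'   annotation step consulted (consumed as a precomputed flag).
#' @param filter Filter column text; "." when unfiltered.
#' @param sample_id Sample name.
#' @return One-row data.frame of class `c("variant_table", "data.frame")`.
#' @export
variant_record <- function(chrom, pos, ref, alt, qual, genotype = "0/1",
                           gq = 0L, pl = c(0L, 0L, 0L), dp = sum(dp4),
                           dp4 = c(0L, 0L, 0L, 0L),
                           pv4 = c(1, 1, 1, 1), gene = NA_character_,
                           novel = NA, filter = ".", sample_id = "S1") {
  stopifnot(length(dp4) == 4, length(pv4) == 4, length(pl) == 3)
  if (qual < 0) stop("qual must be >= 0")
  if (dp != sum(dp4)) stop("dp (", dp, ") != sum(dp4) (", sum(dp4), ")")
  if (any(pv4 < 0 | pv4 > 1)) stop("pv4 entries must be in [0, 1]")
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, qual = as.numeric(qual), genotype = genotype,
                   gq = as.integer(gq),
                   pl = paste(as.integer(pl), collapse = ","),
                   dp = as.integer(dp),
                   dp4_rf = as.integer(dp4[1]), dp4_rr = as.integer(dp4[2]),
                   dp4_af = as.integer(dp4[3]), dp4_ar = as.integer(dp4[4]),
                   pv4_strand = pv4[1], pv4_baseq = pv4[2],
                   pv4_mapq = pv4[3], pv4_tail = pv4[4],
                   gene = gene, novel = novel, filter = filter,
                   sample_id = sample_id, stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

variant_table_cols <- c("chrom", "pos", "ref", "alt", "qual", "genotype",
                        "gq", "pl", "dp", "dp4_rf", "dp4_rr", "dp4_af",
                        "dp4_ar", "pv4_strand", "pv4_baseq", "pv4_mapq",
                        "pv4_tail", "gene", "novel", "filter", "sample_id")

## bind variant records into one table
bind_variant_records <- function(records) {
  records <- Filter(Negate(is.null), records)
  if (!length(records)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)),
                                            length(variant_table_cols)),
                                        variant_table_cols))
    class(df) <- c("variant_table", "data.frame")
    return(df)
  }
  df <- do.call(rbind, lapply(records, as.data.frame))
  class(df) <- c("variant_table", "data.frame")
  df
}

num_str <- function(x) vapply(x, function(v) format(v, digits = 15,
                                                    scientific = FALSE,
                                                    trim = TRUE), "")

#' Write and read the VCF representation of a variant table
#'
#' Emits VCF v4.2 text with the INFO keys `DP`, `DP4`, `PV4` (and `GENE`,
#' `NOVEL` when present) and the genotype FORMAT `GT:PL:GQ` -- the fields
#' the tier filters consume.  `read_vcf` parses that dialect back;
#' `read_vcf(write_vcf(x))` reproduces `x` for every emitted field.
#'
#' @param records A variant table ([variant_record()] rows).
#' @param file Optional path; when `NULL` the VCF text is returned as a
#'   character vector of lines.
#' @return `write_vcf`: the lines (invisibly when written to a file);
#'   `read_vcf`: a variant table.
#' @export
write_vcf <- function(records, file = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicall",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Raw read depth">',
    '##INFO=<ID=DP4,Number=4,Type=Integer,Description="Ref fwd, ref rev, alt fwd, alt rev read counts">',
    '##INFO=<ID=PV4,Number=4,Type=Float,Description="P-values: strand bias, baseQ bias, mapQ bias, tail distance bias">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=NOVEL,Number=0,Type=Flag,Description="Absent from consulted variant databases">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'
  )
  sample_name <- if (nrow(records)) records$sample_id[1] else "SAMPLE"
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample_name, sep = "\t"))
  body <- character(0)
  if (nrow(records)) {
    info <- sprintf("DP=%d;DP4=%d,%d,%d,%d;PV4=%s,%s,%s,%s",
                    records$dp, records$dp4_rf, records$dp4_rr,
                    records$dp4_af, records$dp4_ar,
                    num_str(records$pv4_strand), num_str(records$pv4_baseq),
                    num_str(records$pv4_mapq), num_str(records$pv4_tail))
    info <- ifelse(is.na(records$gene), info,
                   paste0(info, ";GENE=", records$gene))
    info <- ifelse(!is.na(records$novel) & records$novel,
                   paste0(info, ";NOVEL"), info)
    body <- paste(records$chrom, records$pos, ".", records$ref,
                  records$alt, num_str(records$qual), records$filter, info,
                  "GT:PL:GQ",
                  sprintf("%s:%s:%d", records$genotype, records$pl,
                          records$gq),
                  sep = "\t")
  }
  lines <- c(hdr, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @rdname write_vcf
#' @param text VCF text (path, single string, or vector of lines).
#' @export
read_vcf <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  sample_name <- "SAMPLE"
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  if (length(chrom_line)) {
    cols <- strsplit(chrom_line[1], "\t", fixed = TRUE)[[1]]
    if (length(cols) >= 10) sample_name <- cols[10]
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF line: ", ln)
    info <- vcf_info_map(f[8])
    for (key in c("DP", "DP4", "PV4"))
      if (is.null(info[[key]]))
        stop("VCF record at ", f[1], ":", f[2],
             " lacks required INFO key ", key)
    dp4 <- as.integer(strsplit(info$DP4, ",")[[1]])
    pv4 <- as.numeric(strsplit(info$PV4, ",")[[1]])
    gt <- "0/1"; gq <- 0L; pl <- c(0L, 0L, 0L)
    if (length(f) >= 10) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      val <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      g <- function(key) val[match(key, fmt)]
      if (!is.na(g("GT"))) gt <- g("GT")
      if (!is.na(g("GQ"))) gq <- as.integer(g("GQ"))
      if (!is.na(g("PL"))) pl <- as.integer(strsplit(g("PL"), ",")[[1]])
    }
    variant_record(chrom = f[1], pos = as.integer(f[2]), ref = f[4],
                   alt = f[5], qual = as.numeric(f[6]), genotype = gt,
                   gq = gq, pl = pl, dp = as.integer(info$DP), dp4 = dp4,
                   pv4 = pv4,
                   gene = if (is.null(info$GENE)) NA_character_ else
                     info$GENE,
                   novel = if (is.null(info$NOVEL)) NA else TRUE,
                   filter = f[7], sample_id = sample_name)
  })
  bind_variant_records(recs)
}

vcf_info_map <- function(s) {
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
    else out[[kv]] <- TRUE
  }
  out
}
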