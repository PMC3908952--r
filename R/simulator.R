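#' Mosaic-read simulation settings
#'
#' The simulator emulates a single variant site covered by 100 bp
#' paired-end reads: every read maps perfectly (CIGAR 100M) with mapping
#' quality Phred 60 and uniform base qualities Phred 30, the mismatch of
#' alternate-allele reads sits exactly in the middle of the read (query
#' offset 50, MD tag `50G49`), reads alternate between the forward and
#' reverse strand, and mates are proper-paired at the configured insert
#' size without covering the site.  The simulator is a pure function of
#' its arguments; there is no randomness anywhere.
#'
#' @param read_length Read length in bp; default 100.
#' @param base_quality Uniform per-base Phred quality; default 30.
#' @param mapping_quality Phred mapping quality; default 60.
#' @param mismatch_offset 0-based query offset of the variant base;
#'   default 50 (the middle of the read).
#' @param ref_allele,alt_allele Reference and alternate base at the site;
#'   defaults G and A (the reference base is pinned by the MD tag).
#' @param contig,contig_length Contig name and length of the synthetic
#'   reference.
#' @param site_pos 1-based position of the variant site.
#' @param insert_size Outer insert size of the simulated pairs; default
#'   300 bp, which places every mate clear of the site.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(read_length = 100L, base_quality = 30L,
                            mapping_quality = 60L, mismatch_offset = 50L,
                            ref_allele = "G", alt_allele = "A",
                            contig = "sim1", contig_length = 2000L,
                            site_pos = 1000L, insert_size = 300L) {
  if (mismatch_offset < 0 || mismatch_offset >= read_length)
    stop("mismatch_offset must lie within the read")
  if (ref_allele == alt_allele)
    stop("alt_allele must differ from ref_allele")
  if (insert_size < 2L * read_length)
    stop("insert_size must be at least twice the read length, or mates ",
         "would overlap the site")
  structure(list(read_length = as.integer(read_length),
                 base_quality = as.integer(base_quality),
                 mapping_quality = as.integer(mapping_quality),
                 mismatch_offset = as.integer(mismatch_offset),
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 contig = contig, contig_length = as.integer(contig_length),
                 site_pos = as.integer(site_pos),
                 insert_size = as.integer(insert_size)),
            class = "simulation_spec")
}

#' Synthetic reference sequence for the simulator
#'
#' A deterministic period-4 ACGT sequence, phase-shifted so the site
#' carries the spec's reference allele; by construction it contains no
#' homopolymers.
#'
#' @param spec A [simulation_spec()].
#' @return A single string of length `spec$contig_length`.
#' @export
reference_sequence <- function(spec = simulation_spec()) {
  alphabet <- c("A", "C", "G", "T")
  want <- match(spec$ref_allele, alphabet) - 1L
  shift <- (want - (spec$site_pos - 1L)) %% 4L
  idx <- ((seq_len(spec$contig_length) - 1L + shift) %% 4L) + 1L
  paste(alphabet[idx], collapse = "")
}

#' Simulate the reads covering one variant site
#'
#' Produces `depth` site-covering reads of which `n_alt` carry the
#' alternate allele at the central mismatch offset.  Within each of the
#' reference and alternate read classes, strands alternate starting on
#' the forward strand (an odd class size leaves the extra read on "+").
#' Reference reads carry `MD:Z:100`; alternate reads `MD:Z:50G49`.
#' Every read is flagged as a properly-paired first mate whose mate
#' starts `insert_size` away and never covers the site, so pileup depth
#' equals the read count exactly.
#'
#' @param depth Total read count at the site.
#' @param n_alt Number of alternate-allele reads, `0 <= n_alt <= depth`.
#' @param spec A [simulation_spec()].
#' @return List of [read_record()]s.
#' @export
simulate_site_reads <- function(depth, n_alt, spec = simulation_spec()) {
  if (n_alt < 0 || n_alt > depth)
    stop("n_alt must be between 0 and depth")
  ref <- reference_sequence(spec)
  start <- spec$site_pos - spec$mismatch_offset
  if (start < 1L || start + spec$read_length - 1L > spec$contig_length)
    stop("site_pos too close to a contig edge for the read length")
  ref_read_seq <- substr(ref, start, start + spec$read_length - 1L)
  alt_read_seq <- ref_read_seq
  substr(alt_read_seq, spec$mismatch_offset + 1L,
         spec$mismatch_offset + 1L) <- spec$alt_allele
  md_ref <- as.character(spec$read_length)
  md_alt <- paste0(spec$mismatch_offset, spec$ref_allele,
                   spec$read_length - spec$mismatch_offset - 1L)
  quals <- rep(spec$base_quality, spec$read_length)
  cigar <- paste0(spec$read_length, "M")
  mk <- function(i, is_alt, reverse) {
    ## paired, proper pair, first of pair; strand bits per orientation
    flag <- 0x1L + 0x2L + 0x40L +
      (if (reverse) 0x10L else 0x20L)
    read_record(name = sprintf("sim_%s_%03d", if (is_alt) "alt" else "ref",
                               i),
                flag = flag, chrom = spec$contig, pos = start,
                mapq = spec$mapping_quality, cigar = cigar,
                seq = if (is_alt) alt_read_seq else ref_read_seq,
                quals = quals, md = if (is_alt) md_alt else md_ref)
  }
  c(lapply(seq_len(depth - n_alt),
           function(i) mk(i, FALSE, reverse = i %% 2L == 0L)),
    lapply(seq_len(n_alt),
           function(i) mk(i, TRUE, reverse = i %% 2L == 0L)))
}

#' Render simulated reads as SAM text
#'
#' Adds an `@HD`/`@SQ` header and one alignment line per read, with mate
#' fields (RNEXT/PNEXT/TLEN) encoding the proper pair: forward-strand
#' reads point at a downstream mate, reverse-strand reads upstream, at
#' the spec's insert size.  The output round-trips through
#' [parse_sam()].
#'
#' @param reads List of [read_record()]s from [simulate_site_reads()].
#' @param spec The [simulation_spec()] used to generate them.
#' @return Character vector of SAM lines.
#' @export
sam_text <- function(reads, spec = simulation_spec()) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", spec$contig, spec$contig_length))
  lines <- vapply(reads, function(rd) {
    fwd <- !rd$is_reverse
    pnext <- if (fwd) rd$pos + spec$insert_size - spec$read_length
             else rd$pos - spec$insert_size + spec$read_length
    tlen <- if (fwd) spec$insert_size else -spec$insert_size
    paste(rd$name, rd$flag, rd$chrom, rd$pos, rd$mapq, rd$cigar, "=",
          pnext, tlen, rd$seq,
          intToUtf8(rd$quals + 33L),
          paste0("MD:Z:", rd$md),
          sprintf("NM:i:%d", as.integer(rd$md != as.character(nchar(rd$seq)))),
          sep = "\t")
  }, "")
  c(hdr, lines)
}

#' Simulated pileup at the variant site
#'
#' Fast path equivalent to
#' `pileup_from_reads(simulate_site_reads(depth, n_alt, spec), ...)`:
#' builds the [site_pileup()] directly.  Every observation has base
#' quality `spec$base_quality`, mapping quality `spec$mapping_quality`
#' and tail distance `min(offset, read_length - 1 - offset)`.
#'
#' @inheritParams simulate_site_reads
#' @param sample_id Sample name recorded in the pileup.
#' @return A [site_pileup()].
#' @export
simulate_site_pileup <- function(depth, n_alt, spec = simulation_spec(),
                                 sample_id = "sim") {
  if (n_alt < 0 || n_alt > depth)
    stop("n_alt must be between 0 and depth")
  n_ref <- depth - n_alt
  strands <- function(n) if (n) rep_len(c("+", "-"), n) else character(0)
  tail <- min(spec$mismatch_offset,
              spec$read_length - 1L - spec$mismatch_offset)
  site_pileup(spec$contig, spec$site_pos, spec$ref_allele, sample_id,
              allele = c(rep(spec$ref_allele, n_ref),
                         rep(spec$alt_allele, n_alt)),
              base_quality = rep(spec$base_quality, depth),
              mapping_quality = rep(spec$mapping_quality, depth),
              strand = c(strands(n_ref), strands(n_alt)),
              tail_dist = rep(tail, depth))
}

#' Simulate the full depth-by-mutant-fraction grid
#'
#' For each depth d in `depths`, builds pileups for alternate-read counts
#' 0..floor(d/2) (mutant fractions from 0% up to 50%).  Deterministic.
#'
#' @param depths Integer vector of total depths; default 4:100.
#' @param spec A [simulation_spec()].
#' @return Named list of [site_pileup()]s, keyed `"<depth>_<n_alt>"`.
#' @export
simulate_grid <- function(depths = 4:100, spec = simulation_spec()) {
  if (!length(depths)) stop("depth range is empty")
  out <- list()
  for (d in depths)
    for (na in 0:(d %/% 2L))
      out[[sprintf("%d_%d", d, na)]] <- simulate_site_pileup(d, na, spec)
  out
}
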