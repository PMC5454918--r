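#' COMBO-FISH oligonucleotide probe design by k-mer genome scanning
#'
#' COMBO-FISH probes are short oligonucleotides (default 17-mers drawn from
#' the ~300-bp ALU consensus) chosen to occur as often as possible in the
#' genome, but only inside the targeted repeat family. The module counts
#' exact occurrences of a candidate k-mer on either strand, bins them into
#' fixed-width chromosome sections (default 500 kb) for distribution maps,
#' and scores specificity against a repeat annotation (BED intervals).
#'
#' Coordinates are 0-based half-open throughout (BED convention). Positions
#' containing N never match; matching is case-insensitive unless
#' soft-masked bases were converted to N on input (see [read_fasta()]).
#'
#' @name probe_design
NULL

#' The ALU consensus sequence and its 17-mer probe
#'
#' `alu_consensus()` returns the ~285-bp ALU consensus sequence used for
#' probe design; `alu_probe()` the 17-mer COMBO-FISH probe
#' `TAATCCCAGCACTTTGG` drawn from it, which binds the complementary strand
#' by Watson-Crick pairing.
#'
#' @return a character scalar (DNA, 5'-3').
#' @export
alu_consensus <- function() {
  paste0(
    "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGAGGCGGGCGGATCACCTGAGG",
    "TCAGGAGTTCGAGACCAGCCTGGCCAACATGGTGAAACCCCGTCTCTACTAAAAATACAAAAATTAGCCG",
    "GGGCGTGGTGGCGCGCGCCTGTAATCCCAGCTACTCGGGAGGCTGAGGCAGGAGAATCGCTTGAACCCGG",
    "GAGGCGGAGGTTGCAGTGAGCCGAGATCGCGCCACTGCACTCCAGCCTGGGCGACAGAGCGAGACTCCGT",
    "CTC"
  )
}

#' @rdname alu_consensus
#' @export
alu_probe <- function() "TAATCCCAGCACTTTGG"

as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  cl_assert(is.character(genome) && length(genome) > 0 && !is.null(names(genome)),
            "genome must be a named character vector or a DNAStringSet")
  Biostrings::DNAStringSet(toupper(genome))
}

check_probe <- function(probe) {
  cl_assert(is.character(probe) && length(probe) == 1L && nchar(probe) > 0,
            "probe must be a single DNA string")
  probe <- toupper(probe)
  cl_assert(grepl("^[ACGT]+$", probe),
            "probe must contain only A, C, G, T (no ambiguity codes)")
  probe
}

#' Scan a genome for exact occurrences of a probe
#'
#' Reports every exact occurrence of the probe on the forward strand and —
#' with `strand_policy = "both"` (default, since the probe hybridizes
#' wherever either orientation of its sequence occurs) — every occurrence
#' of its reverse complement, recorded as a minus-strand hit at the
#' position of the site in forward coordinates. Overlapping occurrences are
#' all reported; sequences shorter than the probe yield no hits.
#'
#' @param genome named character vector of chromosome sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param probe DNA string over ACGT.
#' @param strand_policy "both" (default) or "forward".
#' @return tibble with `chrom`, `start` (0-based), `end` (half-open),
#'   `strand`; attributes `probe` and `k`.
#' @export
scan_kmer <- function(genome, probe, strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  probe <- check_probe(probe)
  genome <- as_dna_set(genome)
  k <- nchar(probe)
  pat <- Biostrings::DNAString(probe)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(rc) == probe
  rows <- list()
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    subj <- genome[[i]]
    if (length(subj) < k) next
    s_fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj))
    if (length(s_fwd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s_fwd - 1L, end = s_fwd - 1L + k, strand = "+")
    }
    if (strand_policy == "both" && !palindromic) {
      s_rev <- Biostrings::start(Biostrings::matchPattern(rc, subj))
      if (length(s_rev)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = s_rev - 1L, end = s_rev - 1L + k, strand = "-")
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character())
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  out <- tibble::as_tibble(hits)
  attr(out, "probe") <- probe
  attr(out, "k") <- k
  out
}

#' Bin probe hits into fixed-width chromosome sections
#'
#' A hit starting at s increments bin `floor(s / bin_size_bp)` of its
#' chromosome (half-open bins, so a hit exactly on a boundary falls in the
#' following bin); the last bin of a chromosome may be partial. Bin totals
#' conserve hit totals per chromosome.
#'
#' @param hits hit tibble from [scan_kmer()].
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param bin_size_bp section width in bp (default 500000, the 500-kb
#'   sections of the distribution maps).
#' @return tibble with `chrom`, `bin_start`, `count`, covering every bin of
#'   every chromosome in `chrom_lengths` (zeros included).
#' @export
bin_density <- function(hits, chrom_lengths, bin_size_bp = 500000) {
  cl_assert(bin_size_bp > 0, "bin_size_bp must be > 0")
  cl_assert(!is.null(names(chrom_lengths)), "chrom_lengths must be named")
  bad <- !(hits$chrom %in% names(chrom_lengths)) |
    hits$end > chrom_lengths[hits$chrom]
  cl_assert(!any(bad), "hit(s) beyond chromosome end or on unknown chromosome")
  out <- lapply(names(chrom_lengths), function(ch) {
    nb <- max(1L, ceiling(chrom_lengths[[ch]] / bin_size_bp))
    s <- hits$start[hits$chrom == ch]
    counts <- tabulate(floor(s / bin_size_bp) + 1L, nbins = nb)
    tibble::tibble(chrom = ch, bin_start = (seq_len(nb) - 1L) * bin_size_bp,
                   count = counts)
  })
  do.call(rbind, out)
}

ann_iranges <- function(annotation, chrom) {
  sel <- annotation$chrom == chrom
  IRanges::IRanges(start = annotation$start[sel] + 1L,
                   end = annotation$end[sel])
}

hits_contained <- function(hits, annotation) {
  if (nrow(hits) == 0L) return(logical(0))
  contained <- logical(nrow(hits))
  for (ch in unique(hits$chrom)) {
    hsel <- which(hits$chrom == ch)
    q <- IRanges::IRanges(start = hits$start[hsel] + 1L, end = hits$end[hsel])
    s <- ann_iranges(annotation, ch)
    if (length(s) == 0L) next
    ov <- IRanges::findOverlaps(q, s, type = "within")
    contained[hsel[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  contained
}

#' Fraction of probe hits contained in an annotation
#'
#' Fraction of hits whose full `[start, end)` interval lies inside some
#' annotation interval (full containment: a hit straddling an interval
#' edge does not count).
#'
#' @param hits hit tibble from [scan_kmer()].
#' @param annotation tibble with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return fraction in `[0, 1]` (NaN when there are no hits).
#' @export
annotation_overlap_fraction <- function(hits, annotation) {
  if (nrow(hits) == 0L) return(NaN)
  mean(hits_contained(hits, annotation))
}

#' Fraction of annotated elements covered by a probe
#'
#' Fraction of annotation intervals that contain at least one
#' fully-contained probe hit.
#'
#' @inheritParams annotation_overlap_fraction
#' @return fraction in `[0, 1]`.
#' @export
covered_element_fraction <- function(annotation, hits) {
  cl_assert(nrow(annotation) > 0, "annotation must not be empty")
  covered <- logical(nrow(annotation))
  for (ch in unique(annotation$chrom)) {
    asel <- which(annotation$chrom == ch)
    hsel <- hits$chrom == ch
    if (!any(hsel)) next
    q <- IRanges::IRanges(start = hits$start[hsel] + 1L, end = hits$end[hsel])
    s <- IRanges::IRanges(start = annotation$start[asel] + 1L,
                          end = annotation$end[asel])
    ov <- IRanges::findOverlaps(q, s, type = "within")
    covered[asel[unique(S4Vectors::subjectHits(ov))]] <- TRUE
  }
  mean(covered)
}

#' Rank all k-mers of a consensus as probe candidates
#'
#' Enumerates every k-mer of the consensus, counts its genome-wide exact
#' occurrences (per `strand_policy`) and its annotation specificity, then
#' ranks: candidates meeting the specificity floor first, by total hits
#' descending, ties broken by consensus offset (ascending). Candidates
#' whose k-mer contains characters outside ACGT are skipped.
#'
#' @param consensus consensus DNA string (length >= k).
#' @param genome genome as for [scan_kmer()].
#' @param annotation target-element annotation as for
#'   [annotation_overlap_fraction()].
#' @param k probe length (default 17).
#' @param specificity_floor minimum overlap fraction for a candidate to be
#'   considered specific (default 0.99).
#' @param strand_policy "both" (default) or "forward".
#' @return tibble, one row per candidate in rank order: `rank`, `sequence`,
#'   `source_offset` (0-based within the consensus), `total_hits`,
#'   `overlap_fraction`, `specific`.
#' @export
design_probe <- function(consensus, genome, annotation, k = 17L,
                         specificity_floor = 0.99,
                         strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  cl_assert(L >= k, "consensus is shorter than k")
  offsets <- 0:(L - k)
  kmers <- substring(consensus, offsets + 1L, offsets + k)
  ok <- grepl("^[ACGT]+$", kmers)
  offsets <- offsets[ok]; kmers <- kmers[ok]
  cl_assert(length(kmers) > 0, "consensus contains no clean ACGT k-mer")
  genome <- as_dna_set(genome)
  total_hits <- integer(length(kmers))
  ovfrac <- rep(NaN, length(kmers))
  for (i in seq_along(kmers)) {
    h <- scan_kmer(genome, kmers[i], strand_policy)
    total_hits[i] <- nrow(h)
    ovfrac[i] <- annotation_overlap_fraction(h, annotation)
  }
  specific <- !is.nan(ovfrac) & ovfrac >= specificity_floor
  ord <- order(!specific, -total_hits, offsets)
  tibble::tibble(rank = seq_along(kmers),
                 sequence = kmers[ord],
                 source_offset = offsets[ord],
                 total_hits = total_hits[ord],
                 overlap_fraction = ovfrac[ord],
                 specific = specific[ord])
}

#' Write probe hits as BED6
#'
#' Name column carries the probe sequence, score is 0.
#'
#' @param hits hit tibble from [scan_kmer()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  probe <- attr(hits, "probe") %||% "kmer"
  df <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                   name = probe, score = 0L, strand = hits$strand)
  write_bed(df, path)
}
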