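#' Genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that
#' every track, interval set and contact matrix in the package refers to.
#' It is represented as a [GenomeInfoDb::Seqinfo] object so that intervals
#' built on it are bounds-checked by the GenomicRanges machinery.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer-like vector of chromosome lengths in bp
#'   (strictly positive), parallel to `chrom_names`.
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c("chr2L", "chrX"), c(2e6, 1.5e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be strictly positive")
  GenomeInfoDb::Seqinfo(seqnames = chrom_names,
                        seqlengths = as.integer(chrom_lengths))
}

layout_lengths <- function(layout) {
  stats::setNames(GenomeInfoDb::seqlengths(layout),
                  GenomeInfoDb::seqnames(layout))
}

#' Build an interval set from 0-based half-open coordinates
#'
#' Convenience constructor converting BED-style 0-based half-open
#' coordinates into the 1-based closed `GRanges` used internally.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open coordinates; `start < end` required.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (default).
#' @param layout Optional [genome_layout()]; when given, intervals are
#'   validated against chromosome bounds.
#' @param label Optional per-interval labels stored in the `label` column.
#' @return A `GRanges`.
#' @export
bp_interval <- function(chrom, start, end, strand = "*", layout = NULL,
                        label = NULL) {
  if (any(start < 0) || any(end <= start))
    stop("need 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand)
  if (!is.null(label)) S4Vectors::mcols(gr)$label <- label
  if (!is.null(layout)) {
    check_on_layout(gr, layout)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  gr
}

check_on_layout <- function(gr, layout) {
  lens <- layout_lengths(layout)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- !(chr %in% names(lens))
  if (any(bad))
    stop("unknown chromosome(s) not in layout: ",
         paste(unique(chr[bad]), collapse = ", "))
  over <- GenomicRanges::end(gr) > lens[chr]
  if (any(over))
    stop(sum(over), " interval(s) extend beyond chromosome end (first: ",
         chr[which(over)[1]], ":", GenomicRanges::start(gr)[which(over)[1]],
         "-", GenomicRanges::end(gr)[which(over)[1]], ")")
  invisible(gr)
}

#' Tile a genome into fixed-size bins
#'
#' Bins are consecutive and non-overlapping; the last bin of each chromosome
#' is truncated at the chromosome end (partial bins are retained so that
#' track lengths agree across signals).
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (> 0).
#' @return `GRanges` of bins, ordered by (chromosome, start).
#' @export
bin_genome <- function(layout, bin_size) {
  if (!is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be > 0")
  bins <- GenomicRanges::tileGenome(layout_lengths(layout),
                                    tilewidth = as.integer(bin_size),
                                    cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqinfo(bins) <- layout
  bins
}

#' Intersect two interval sets
#'
#' Returns the overlap segments between two sets on the same layout.
#'
#' @param a,b `GRanges` on the same layout.
#' @return `GRanges` of overlap segments.
#' @export
intersect_sets <- function(a, b) {
  check_same_layout(a, b)
  GenomicRanges::intersect(a, b, ignore.strand = TRUE)
}

check_same_layout <- function(a, b) {
  la <- GenomeInfoDb::seqlengths(a); lb <- GenomeInfoDb::seqlengths(b)
  common <- intersect(names(la), names(lb))
  if (length(common)) {
    ka <- la[common]; kb <- lb[common]
    known <- !is.na(ka) & !is.na(kb)
    if (any(ka[known] != kb[known]))
      stop("interval sets are on mismatched layouts")
  }
  invisible(TRUE)
}

#' Fraction of each target interval covered by a query set
#'
#' @param targets `GRanges` whose per-interval covered fraction is wanted.
#' @param query `GRanges`; overlapping query intervals are unioned first, so
#'   double coverage never pushes the fraction above 1.
#' @return Numeric vector in `[0, 1]`, one value per target.
#' @export
coverage_fraction <- function(targets, query) {
  q <- GenomicRanges::reduce(query, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(targets, q, ignore.strand = TRUE)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(targets)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(q)[S4Vectors::subjectHits(hits)]))
  covered <- rep(0, length(targets))
  if (length(hits)) {
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered / GenomicRanges::width(targets)
}

#' Binned signal track
#'
#' A per-bin numeric signal over a genome layout with a validity mask.
#' Masked bins carry `NA` values.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @param values Numeric vector, one value per bin of `bin_genome(layout,
#'   bin_size)`; `NA` marks masked bins.
#' @param mask Optional logical vector (`TRUE` = valid); defaults to
#'   `is.finite(values)`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(layout, bin_size, values, mask = NULL) {
  bins <- bin_genome(layout, bin_size)
  values <- as.numeric(values)
  if (length(values) != length(bins))
    stop("values length (", length(values), ") != number of bins (",
         length(bins), ")")
  if (is.null(mask)) mask <- is.finite(values)
  if (length(mask) != length(values))
    stop("mask length must equal values length")
  values[!mask] <- NA_real_
  structure(list(layout = layout, bin_size = as.integer(bin_size),
                 bins = bins, values = values, mask = mask),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", length(x$values), "bins of", x$bin_size, "bp on",
      length(GenomeInfoDb::seqnames(x$layout)), "chromosome(s);",
      sum(!x$mask), "masked\n")
  invisible(x)
}

#' @export
length.binned_track <- function(x) length(x$values)

## Per-chromosome view: indices of a track's bins on one chromosome.
track_chrom_idx <- function(track, chrom) {
  which(as.character(GenomeInfoDb::seqnames(track$bins)) == chrom)
}

## ---------------------------------------------------------------------------
## I/O: BED, bedGraph, chromosome sizes, COO contact lists
## All on-disk formats are BED-family (0-based half-open); conversion to the
## in-memory 1-based representation is confined to this block.

#' Read a BED file as an interval set
#'
#' @param path BED3/BED6 file.
#' @param layout Optional layout; unknown chromosomes or out-of-bounds
#'   intervals are rejected.
#' @return `GRanges` (with `label`/`score` columns when present).
#' @export
read_bed <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(layout)) {
    check_on_layout(gr, layout)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) S4Vectors::mcols(gr)$label <- nm
  gr
}

#' Write an interval set as BED
#'
#' @param gr `GRanges`.
#' @param path Output file.
#' @export
write_bed <- function(gr, path) {
  lab <- S4Vectors::mcols(gr)$label
  if (!is.null(lab)) S4Vectors::mcols(gr)$name <- lab
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

check_table_lines <- function(path, n_fields, skip_comment = "#") {
  cf <- utils::count.fields(path, sep = "\t", comment.char = skip_comment,
                            blank.lines.skip = FALSE)
  keep <- !is.na(cf)
  bad <- which(keep & cf != n_fields)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": expected ", n_fields,
         " tab-separated fields, found ", cf[bad[1]])
  invisible(TRUE)
}

#' Read a bedGraph file into a binned track
#'
#' Bins absent from the file are masked. Records must align to the bin grid
#' of `bin_size` on `layout`.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param layout Genome layout.
#' @param bin_size Bin width in bp.
#' @return A [binned_track()].
#' @export
read_track_bedgraph <- function(path, layout, bin_size) {
  check_table_lines(path, 4L)
  gr <- rtracklayer::import(path, format = "bedGraph")
  check_on_layout(gr, layout)
  bins <- bin_genome(layout, bin_size)
  hit <- GenomicRanges::findOverlaps(gr, bins, type = "equal")
  if (length(hit) != length(gr))
    stop("bedGraph records do not align to the ", bin_size, "-bp bin grid")
  values <- rep(NA_real_, length(bins))
  values[S4Vectors::subjectHits(hit)] <-
    S4Vectors::mcols(gr)$score[S4Vectors::queryHits(hit)]
  binned_track(layout, bin_size, values)
}

#' Write a binned track as bedGraph
#'
#' Masked bins are omitted, so the mask round-trips through
#' [read_track_bedgraph()].
#'
#' @param track A [binned_track()].
#' @param path Output file.
#' @export
write_track_bedgraph <- function(track, path) {
  keep <- track$mask
  gr <- track$bins[keep]
  S4Vectors::mcols(gr)$score <- track$values[keep]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read/write a two-column chromosome-sizes file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  check_table_lines(path, 2L)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length)
}

#' @rdname read_chrom_sizes
#' @param layout A [genome_layout()] to write.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(
    data.frame(chrom = GenomeInfoDb::seqnames(layout),
               length = GenomeInfoDb::seqlengths(layout)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
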