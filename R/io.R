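## Readers and writers for the interchange formats: bedGraph (per-strand
## cut counts), BED6 intervals, TSV expression tables, FASTA genomes and
## JSON configuration echoes. All file coordinates are 0-based
## half-open; in-memory GRanges follow the usual 1-based convention.

#' Read a pair of strand-specific bedGraph files into cut profiles
#'
#' Builds dense per-base count vectors from 0-based half-open bedGraph
#' records. Missing regions are zero; overlapping records are an error.
#'
#' @param plus_path,minus_path bedGraph files of plus- and minus-strand
#'   cut counts.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param library_total Total cuts in the source library; defaults to the
#'   sum of the stored counts.
#' @param condition Optional condition label carried on the result.
#' @return A `cut_profiles` object.
#' @export
read_cut_bedgraphs <- function(plus_path, minus_path, chrom_lengths,
                               library_total = NULL, condition = NA) {
  read_one <- function(path) {
    dense <- lapply(chrom_lengths, function(len) integer(len))
    if (file.size(path) == 0)
      return(dense)
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = list(character = 1))
    bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                   !is.finite(dt$value) | dt$start < 0 | dt$end <= dt$start)
    if (length(bad))
      stop("malformed bedGraph record in ", path, " at line ", bad[1],
           call. = FALSE)
    if (any(dt$value < 0))
      stop("negative count in ", path, " at line ",
           which(dt$value < 0)[1], call. = FALSE)
    unknown <- setdiff(unique(dt$chrom), names(chrom_lengths))
    if (length(unknown))
      stop("unknown chromosome(s) in ", path, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    oob <- dt$end > chrom_lengths[dt$chrom]
    if (any(oob))
      stop("bedGraph interval beyond chromosome end in ", path,
           " at line ", which(oob)[1], call. = FALSE)
    for (ch in unique(dt$chrom)) {
      sub <- dt[dt$chrom == ch]
      ir <- IRanges::IRanges(sub$start + 1L, sub$end)  # to 1-based closed
      if (sum(IRanges::width(ir)) !=
          sum(IRanges::width(IRanges::reduce(ir))))
        stop("overlapping bedGraph records in ", path, " on ", ch,
             call. = FALSE)
      cov <- IRanges::coverage(ir, weight = sub$value,
                               width = chrom_lengths[[ch]])
      dense[[ch]] <- as.integer(cov)
    }
    dense
  }
  plus <- read_one(plus_path)
  minus <- read_one(minus_path)
  profs <- stats::setNames(lapply(names(chrom_lengths), function(ch)
    list(plus = plus[[ch]], minus = minus[[ch]])), names(chrom_lengths))
  total <- sum(vapply(profs, function(p)
    sum(as.numeric(p$plus)) + sum(as.numeric(p$minus)), numeric(1)))
  if (is.null(library_total)) library_total <- total
  if (library_total < total)
    stop("library_total (", library_total,
         ") is smaller than the stored counts (", total, ")", call. = FALSE)
  structure(list(chroms = profs, library_total = library_total,
                 condition = condition),
            class = "cut_profiles")
}

#' Write cut profiles as a pair of strand-specific bedGraph files
#'
#' Runs of equal non-zero counts are emitted as 0-based half-open
#' records; zero runs are omitted.
#'
#' @param profiles A `cut_profiles` object.
#' @param plus_path,minus_path Output paths.
#' @export
write_cut_bedgraphs <- function(profiles, plus_path, minus_path) {
  write_one <- function(strand, path) {
    rows <- list()
    for (ch in names(profiles$chroms)) {
      v <- profiles$chroms[[ch]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0L
      if (any(keep))
        rows[[ch]] <- data.table::data.table(
          chrom = ch, start = starts[keep] - 1L, end = ends[keep],
          value = r$values[keep])
    }
    if (length(rows) == 0L) {
      file.create(path)
    } else {
      data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                         col.names = FALSE, scipen = 50)
    }
    invisible(path)
  }
  write_one("plus", plus_path)
  write_one("minus", minus_path)
  invisible(c(plus_path, minus_path))
}

#' Read BED intervals into a GRanges
#'
#' Accepts BED3/BED6 (0-based half-open); the result is sorted by
#' (chrom, start) and converted to the 1-based closed GRanges
#' convention.
#'
#' @param path BED file.
#' @return `GRanges`, with `name` and `score` columns when present.
#' @export
read_bed_intervals <- function(path) {
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path,
                          call. = FALSE)
  names(dt)[1:3] <- c("chrom", "start", "end")
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                 dt$start < 0 | dt$start >= dt$end)
  if (length(bad))
    stop("invalid BED interval at line ", bad[1], " of ", path,
         " (need 0 <= start < end)", call. = FALSE)
  strand <- if (ncol(dt) >= 6L) dt[[6L]] else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(dt$start + 1L, dt$end),
    strand = strand)
  if (ncol(dt) >= 4L) S4Vectors::mcols(gr)$name <- as.character(dt[[4L]])
  if (ncol(dt) >= 5L) S4Vectors::mcols(gr)$score <- dt[[5L]]
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

#' Write a GRanges as BED6 (plus any extra metadata columns)
#'
#' Output is sorted by (chrom, start) and 0-based half-open. Metadata
#' columns other than `name` and `score` are appended after the six BED
#' fields.
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @export
write_bed_intervals <- function(gr, path) {
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr <- gr[ord]
  mc <- as.data.frame(S4Vectors::mcols(gr))
  name <- if ("name" %in% names(mc)) mc$name else "."
  score <- if ("score" %in% names(mc)) mc$score else 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = strand)
  extra <- mc[, setdiff(names(mc), c("name", "score")), drop = FALSE]
  if (ncol(extra) > 0) dt <- cbind(dt, data.table::as.data.table(extra))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Write/read a log2 expression table as TSV
#'
#' Tab-separated, header row, genes in rows (first column `gene_id`),
#' missing values as '.'.
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  dt <- data.table::data.table(gene_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @return `read_expression` returns the numeric matrix.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".")
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- dt[[1]]
  mat
}

#' Write genome sequences as FASTA
#' @param seqs Named character vector of chromosome sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write gene models as BED6
#'
#' One record per gene body; the TSS is the 5' end given the strand.
#' @param genes Gene `GRanges` with a `gene_id` column.
#' @param path Output path.
#' @export
write_genes_bed <- function(genes, path) {
  gr <- genes
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(genes)$gene_id, score = 0)
  write_bed_intervals(gr, path)
}

#' Read gene models from BED6
#' @param path BED6 file written by [write_genes_bed()].
#' @return Gene `GRanges` with `gene_id` and `tss` columns.
#' @export
read_genes_bed <- function(path) {
  gr <- read_bed_intervals(path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene BED must have explicit +/- strands", call. = FALSE)
  S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr)$tss <- ifelse(strand == "+",
                                     GenomicRanges::start(gr),
                                     GenomicRanges::end(gr))
  S4Vectors::mcols(gr)$name <- NULL
  S4Vectors::mcols(gr)$score <- NULL
  gr
}

## JSON helpers: stable, human-readable, byte-reproducible output.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
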